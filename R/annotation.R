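#' Load genome and annotation, building the region index
#'
#' Reads a GFF3 gene annotation and a genome FASTA and derives, for every
#' gene, the region intervals used for poly(A)-site assignment: 5'UTR, CDS,
#' intron (mRNA gaps between exons) and 3'UTR, with the 3'UTR extended
#' `extension_nt` nucleotides in the 3' direction. Region intervals are the
#' union over isoforms. The extension is truncated at the chromosome end and
#' at the start of the nearest downstream same-strand gene, so no position is
#' claimed by two genes through extensions alone. Genes lacking an annotated
#' 3'UTR get the extension appended directly to the transcript 3' end.
#'
#' @param gff3 path to a GFF3 file with `gene`, `mRNA`, `exon`, `CDS`,
#'   `five_prime_UTR`, `three_prime_UTR` features (1-based closed
#'   coordinates).
#' @param fasta path to the genome FASTA, or a [Biostrings::DNAStringSet].
#' @param extension_nt 3'UTR extension length in nt (default 200).
#' @return An object of class `"GenomeAnnotation"`: a list with the genome
#'   (`DNAStringSet`), chromosome lengths, a `genes` table, a
#'   [GenomicRanges::GRanges] of region intervals (`gene_id`, `region`,
#'   `part` = annotated/extension) and per-gene extended spans.
#' @export
load_annotation <- function(gff3, fasta, extension_nt = 200L) {
  genome <- if (methods::is(fasta, "DNAStringSet")) fasta else {
    g <- Biostrings::readDNAStringSet(fasta)
    names(g) <- sub("\\s.*$", "", names(g))
    g
  }
  chrom_len <- setNames(Biostrings::width(genome), names(genome))

  gr <- rtracklayer::import(gff3, format = "gff3")
  miss <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))), names(genome))
  if (length(miss))
    stop("chromosome(s) missing from FASTA: ", paste(miss, collapse = ", "))

  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent1 <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  gene_gr <- gr[typ == "gene"]
  gene_ids <- as.character(gene_gr$ID)
  if (anyNA(gene_ids)) stop("gene features without ID attribute")

  mrna_gr <- gr[typ == "mRNA"]
  mrna_ids <- as.character(mrna_gr$ID)
  mrna_parent <- parent1[typ == "mRNA"]
  bad <- which(!(mrna_parent %in% gene_ids))
  if (length(bad))
    stop("malformed GFF3 parentage for feature ", mrna_ids[bad[1]])
  mrna2gene <- setNames(mrna_parent, mrna_ids)

  feat_gene <- function(sel_typ) {
    f <- gr[typ == sel_typ]
    if (length(f) == 0) return(f)
    p <- parent1[typ == sel_typ]
    bad <- which(!(p %in% mrna_ids))
    if (length(bad))
      stop("malformed GFF3 parentage for feature ",
           ids[typ == sel_typ][bad[1]])
    f$gene_id <- unname(mrna2gene[p])
    f$mrna_id <- p
    f
  }
  exons <- feat_gene("exon")
  cds <- feat_gene("CDS")
  utr5 <- feat_gene("five_prime_UTR")
  utr3 <- feat_gene("three_prime_UTR")

  ## introns: per mRNA, transcript span minus exons
  introns <- GenomicRanges::GRanges()
  if (length(exons)) {
    ex_by_m <- GenomicRanges::split(exons, exons$mrna_id)
    spans <- unlist(range(ex_by_m))
    intr <- GenomicRanges::psetdiff(spans, ex_by_m)
    intr_flat <- unlist(intr)
    if (length(intr_flat)) {
      intr_flat$gene_id <- unname(mrna2gene[names(intr_flat)])
      names(intr_flat) <- NULL
      introns <- intr_flat
    }
  }

  union_by_gene <- function(f, label) {
    if (length(f) == 0) return(GenomicRanges::GRanges())
    u <- unlist(GenomicRanges::reduce(GenomicRanges::split(f, f$gene_id)))
    u$gene_id <- names(u)
    u$region <- label
    u$part <- "annotated"
    names(u) <- NULL
    u
  }
  reg <- suppressWarnings(  # empty feature classes carry no seqlevels
    c(union_by_gene(utr5, "5UTR"), union_by_gene(cds, "CDS"),
      union_by_gene(introns, "INTRON"), union_by_gene(utr3, "3UTR")))

  ## 3'UTR extension per gene
  gdf <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gene_gr)),
    strand = as.character(GenomicRanges::strand(gene_gr)),
    start = GenomicRanges::start(gene_gr),
    end = GenomicRanges::end(gene_gr),
    stringsAsFactors = FALSE
  )
  ext <- data.frame(chrom = character(), lo = integer(), hi = integer(),
                    strand = character(), gene_id = character())
  for (i in seq_len(nrow(gdf))) {
    gid <- gdf$gene_id[i]; str <- gdf$strand[i]; chr <- gdf$chrom[i]
    u3g <- reg[reg$gene_id == gid & reg$region == "3UTR"]
    if (str == "+") {
      from <- if (length(u3g)) max(GenomicRanges::end(u3g)) else gdf$end[i]
      lo <- from + 1L
      hi <- min(from + extension_nt, chrom_len[[chr]])
      dn <- gdf[gdf$chrom == chr & gdf$strand == str & gdf$start > gdf$end[i], ]
      if (nrow(dn)) hi <- min(hi, min(dn$start) - 1L)
    } else {
      from <- if (length(u3g)) min(GenomicRanges::start(u3g)) else gdf$start[i]
      hi <- from - 1L
      lo <- max(from - extension_nt, 1L)
      dn <- gdf[gdf$chrom == chr & gdf$strand == str & gdf$end < gdf$start[i], ]
      if (nrow(dn)) lo <- max(lo, max(dn$end) + 1L)
    }
    if (hi >= lo)
      ext <- rbind(ext, data.frame(chrom = chr, lo = lo, hi = hi,
                                   strand = str, gene_id = gid))
  }
  if (nrow(ext)) {
    e <- GenomicRanges::GRanges(ext$chrom, IRanges::IRanges(ext$lo, ext$hi),
                                strand = ext$strand)
    e$gene_id <- ext$gene_id; e$region <- "3UTR"; e$part <- "extension"
    reg <- suppressWarnings(c(reg, e))
  }

  ## per-gene extended span = annotated span U region ranges
  spans <- GenomicRanges::GRanges(gdf$chrom, IRanges::IRanges(gdf$start, gdf$end),
                                  strand = gdf$strand)
  spans$gene_id <- gdf$gene_id
  all_iv <- c(spans, GenomicRanges::granges(reg, use.mcols = FALSE))
  all_iv$gene_id <- c(spans$gene_id, reg$gene_id)
  gs <- unlist(range(GenomicRanges::split(all_iv, all_iv$gene_id)))
  gs$gene_id <- names(gs)
  names(gs) <- NULL

  structure(list(
    genome = genome,
    chrom_len = chrom_len,
    genes = gdf,
    regions = reg,
    gene_spans = gs,
    extension_nt = as.integer(extension_nt)
  ), class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s), 3'UTR extension %d nt\n",
              nrow(x$genes), length(x$genome), x$extension_nt))
  cat(sprintf("  region intervals: %d (%d extension segments)\n",
              length(x$regions), sum(x$regions$part == "extension")))
  invisible(x)
}

#' Fetch the sense-strand sequence window around a cleavage site
#'
#' Returns the sense-strand sequence of length `2 * flank + 1` centered on
#' `center` (reverse-complemented for minus-strand sites). Window positions
#' follow the convention -flank..-1, +1..+(flank+1) with the cleavage base
#' at +1 (there is no position 0). Windows that would run past either
#' chromosome end yield `NA` (the short-window signal); callers drop them.
#'
#' @param annotation a `"GenomeAnnotation"`.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param center 1-based cleavage coordinate.
#' @param flank flank size in nt (default 100).
#' @return A character scalar of length `2 * flank + 1`, or `NA_character_`
#'   for out-of-bounds windows.
#' @export
fetch_window <- function(annotation, chrom, strand, center, flank = 100L) {
  len <- annotation$chrom_len[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  if (center - flank < 1L || center + flank > len) return(NA_character_)
  s <- Biostrings::subseq(annotation$genome[[chrom]], center - flank, center + flank)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

## vectorized window fetch; returns DNAStringSet plus index of kept rows
fetch_windows <- function(annotation, chrom, strand, center, flank = 100L) {
  len <- annotation$chrom_len[chrom]
  keep <- which(center - flank >= 1L & center + flank <= len)
  if (length(keep) == 0)
    return(list(seqs = Biostrings::DNAStringSet(), kept = integer(0)))
  out <- vector("list", length(unique(chrom[keep])))
  seqs <- Biostrings::DNAStringSet(rep("", length(keep)))
  for (cc in unique(chrom[keep])) {
    m <- which(chrom[keep] == cc)
    v <- Biostrings::extractAt(
      annotation$genome[[cc]],
      IRanges::IRanges(center[keep][m] - flank, center[keep][m] + flank))
    seqs[m] <- Biostrings::DNAStringSet(v)
  }
  minus <- strand[keep] == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  list(seqs = seqs, kept = keep)
}

## window position labels: no 0, cleavage base at +1
window_positions <- function(flank = 100L) {
  d <- (-flank):flank
  ifelse(d >= 0L, d + 1L, d)
}

#' Empirical sweep of the 3'UTR extension length
#'
#' Counts tags assignable to any gene under a series of 3'UTR extension
#' lengths and picks the shortest extension at which the assigned-tag count
#' saturates (relative gain to the next step below `tol`). This reproduces
#' the empirical procedure of extending annotations in 100-bp increments and
#' choosing the point where mapped-read counts cease to increase.
#'
#' @param tags data frame of single-nucleotide tags
#'   (`chrom`, `pos`, `strand`).
#' @param gff3 path to the GFF3 annotation.
#' @param fasta genome FASTA path or `DNAStringSet`.
#' @param steps extension lengths to test (nt), increasing.
#' @param tol relative-gain saturation tolerance (default 0.01 = 1%).
#' @return A list with `table` (`extension`, `assigned`) and `chosen`.
#' @export
extension_sweep <- function(tags, gff3, fasta,
                            steps = c(100L, 200L, 300L, 400L), tol = 0.01) {
  if (is.null(tags) || nrow(tags) == 0) stop("empty tag set")
  steps <- sort(as.integer(steps))
  counts <- integer(length(steps))
  q <- GenomicRanges::GRanges(tags$chrom, IRanges::IRanges(tags$pos, tags$pos),
                              strand = tags$strand)
  for (i in seq_along(steps)) {
    ann <- load_annotation(gff3, fasta, extension_nt = steps[i])
    counts[i] <- sum(GenomicRanges::countOverlaps(q, ann$gene_spans) > 0)
  }
  chosen <- steps[length(steps)]
  for (i in seq_len(length(steps) - 1L)) {
    gain <- (counts[i + 1L] - counts[i]) / max(counts[i], 1L)
    if (gain < tol) { chosen <- steps[i]; break }
  }
  list(table = data.frame(extension = steps, assigned = counts),
       chosen = chosen)
}
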