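#' Simulate a toy genome with planted poly(A)-site architecture
#'
#' Generates a deterministic toy genome (FASTA-writable `DNAStringSet`), a
#' matching gene annotation (GFF3-writable table) and a ground-truth record
#' of every planted poly(A)-site cluster. Gene models have the structure
#' 5'UTR - CDS exon - intron - CDS exon - 3'UTR on alternating strands.
#' Sequence around each planted cleavage site is drawn from position-specific
#' base frequencies implementing the canonical plant signal architecture:
#' a U-rich far-upstream element, an A-rich near-upstream element (NUE)
#' spanning -30..-15, a U-rich stretch at -10..-2 and the YA cleavage
#' dinucleotide at -1/+1 for 3'UTR, intron and 5'UTR sites, and an
#' (A+G)-rich composition for CDS sites. Designated A8 tracts are written
#' into a configurable number of 3'UTRs and CDSs as internal-priming
#' substrate. Background composition is uniform over A/C/G/T.
#'
#' Coordinates are 1-based closed; the cleavage coordinate of a site is the
#' genomic position of the last transcribed base (window position +1).
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"apa_simulation"` with elements
#'   \describe{
#'     \item{genome}{named [Biostrings::DNAStringSet] of chromosomes}
#'     \item{gff}{data frame of GFF3 fields (see [write_gff3()])}
#'     \item{truth}{list with `genes`, `sites` (one row per planted cluster,
#'       per-tissue usage columns `usage_<tissue>`), `regions` (annotated
#'       region intervals) and `tracts` (designated A8 tracts)}
#'     \item{config}{the input configuration}
#'   }
#' @seealso [simulate_tags()], [write_simulation()]
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config
  bases <- c("A", "C", "G", "T")

  ## --- gene layout -------------------------------------------------------
  n <- cfg$n_genes
  L <- as.integer(round(runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2])))
  u5  <- pmax(60L,  as.integer(round(0.08 * L)))
  intr <- pmax(150L, as.integer(round(0.15 * L)))
  u3  <- pmax(350L, as.integer(round(0.20 * L)))
  cds <- L - u5 - intr - u3
  if (any(cds < 200)) stop("gene_length_range too small for gene architecture")
  cds1 <- as.integer(floor(0.55 * cds))
  cds2 <- cds - cds1

  chrom_idx <- ((seq_len(n) - 1L) %% cfg$n_chromosomes) + 1L
  strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))

  start <- integer(n); end <- integer(n)
  margin <- 300L
  chrom_len <- integer(cfg$n_chromosomes)
  for (ci in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom_idx == ci)
    cursor <- margin + 1L
    for (g in idx) {
      start[g] <- cursor
      end[g] <- cursor + L[g] - 1L
      cursor <- end[g] + cfg$intergenic_gap + 1L
    }
    need <- if (length(idx)) end[idx[length(idx)]] + 400L else 1000L
    if (!is.null(cfg$chromosome_length)) {
      if (need > cfg$chromosome_length)
        stop(sprintf(
          "gene placement overflow: %d nt needed on %s but chromosome_length is %d",
          need, chroms[ci], cfg$chromosome_length))
      chrom_len[ci] <- as.integer(cfg$chromosome_length)
    } else {
      chrom_len[ci] <- need
    }
  }

  gene_id <- sprintf("g%04d", seq_len(n))
  ## sense position p (1..L or beyond the 3' end) -> genomic coordinate
  sense2genomic <- function(g, p) {
    if (strand[g] == "+") start[g] + p - 1L else end[g] - p + 1L
  }

  ## --- PAC architecture --------------------------------------------------
  k <- as.integer(sample(1:4, n, replace = TRUE, prob = cfg$pacs_per_gene[as.character(1:4)]))
  multi <- which(k >= 2L)
  n_apa <- round(cfg$apa_genes_fraction * length(multi))
  apa_genes <- if (n_apa > 0) sort(sample(multi, n_apa)) else integer(0)
  is_apa <- seq_len(n) %in% apa_genes

  ## candidate slots per gene, in sense coordinates, keyed by region
  slot_list <- function(g) {
    s3 <- L[g] - u3[g]  # sense coordinate just before 3'UTR start
    list(
      "3UTR"  = as.integer(floor(s3 + c(0.20, 0.45, 0.70) * u3[g])),
      "CDS"   = as.integer(c(floor(u5[g] + 0.5 * cds1[g]),
                             floor(u5[g] + cds1[g] + intr[g] + 0.5 * cds2[g]))),
      "intron" = as.integer(floor(u5[g] + cds1[g] + c(0.30, 0.75) * intr[g])),
      "5UTR"  = as.integer(floor(0.5 * u5[g]))
    )
  }

  region_names <- names(cfg$region_mix)
  sites <- vector("list", n)
  for (g in seq_len(n)) {
    overrun <- sample(0:cfg$utr3_overrun_max, 1L)
    sense_pos <- as.integer(L[g] - 10L + overrun)
    regs <- "3UTR"
    slots <- slot_list(g)
    if (k[g] > 1L) {
      for (j in 2:k[g]) {
        forced <- if (is_apa[g] && j == 2L && !is.null(cfg$apa_target_region))
          cfg$apa_target_region else NULL
        placed <- FALSE
        for (try in 1:20) {
          r <- forced %||% sample(region_names, 1L, prob = cfg$region_mix)
          if (length(slots[[r]]) > 0) {
            pick <- slots[[r]][1L]
            slots[[r]] <- slots[[r]][-1L]
            sense_pos <- c(sense_pos, pick)
            regs <- c(regs, r)
            placed <- TRUE
            break
          }
          if (!is.null(forced)) break  # forced region full: give up on this PAC
        }
        if (!placed) next
      }
    }
    kk <- length(sense_pos)
    pos <- vapply(seq_len(kk), function(j) sense2genomic(g, sense_pos[j]), integer(1))
    sites[[g]] <- data.frame(
      gene_id = gene_id[g],
      pac_id = sprintf("%s.%d", gene_id[g], seq_len(kk)),
      rank = seq_len(kk),
      chrom = chroms[chrom_idx[g]],
      strand = strand[g],
      pos = pos,
      region = toupper(sub("intron", "INTRON", regs)),
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, sites)
  k_eff <- as.integer(table(factor(sites$gene_id, levels = gene_id)))

  ## --- per-tissue usage fractions ---------------------------------------
  usage <- matrix(NA_real_, nrow = nrow(sites), ncol = length(cfg$tissues),
                  dimnames = list(sites$pac_id, cfg$tissues))
  row0 <- c(0L, cumsum(k_eff))  # offsets into sites per gene
  for (g in seq_len(n)) {
    kk <- k_eff[g]
    rows <- (row0[g] + 1L):(row0[g] + kk)
    if (kk == 1L) {
      usage[rows, ] <- 1
      next
    }
    if (is_apa[g] && kk >= 2L) {
      w_other <- 0.05
      rem <- 1 - w_other * (kk - 2L)
      d <- min(cfg$apa_effect, rem)  # keep fractions in [0,1]
      base <- c((rem - d) / 2, (rem + d) / 2, rep(w_other, kk - 2L))
      shifted <- c((rem + d) / 2, (rem - d) / 2, rep(w_other, kk - 2L))
      for (t in cfg$tissues)
        usage[rows, t] <- if (t == cfg$apa_shift_tissue) shifted else base
    } else {
      w <- rgamma(kk, shape = c(5, rep(2, kk - 1L)))
      w <- w / sum(w)
      usage[rows, ] <- w
    }
  }
  colnames(usage) <- paste0("usage_", cfg$tissues)
  sites <- cbind(sites, as.data.frame(usage))
  rownames(sites) <- NULL

  ## per-gene expression level (dynamic range shared across samples)
  expr_mu <- if (cfg$expr_sdlog > 0)
    stats::rlnorm(n, log(cfg$tags_per_gene) - cfg$expr_sdlog^2 / 2,
                  cfg$expr_sdlog)
  else rep(cfg$tags_per_gene, n)

  ## --- genome sequence ---------------------------------------------------
  seqs <- lapply(chrom_len, function(len) sample(bases, len, replace = TRUE))
  names(seqs) <- chroms

  ## stamp position-specific motif composition around every planted site
  offs <- -100:100
  site_tab <- data.frame(
    chrom = rep(sites$chrom, each = length(offs)),
    strand = rep(sites$strand, each = length(offs)),
    region = rep(sites$region, each = length(offs)),
    d = rep(offs, times = nrow(sites)),
    center = rep(sites$pos, each = length(offs)),
    stringsAsFactors = FALSE
  )
  site_tab$gpos <- ifelse(site_tab$strand == "+",
                          site_tab$center + site_tab$d,
                          site_tab$center - site_tab$d)
  site_tab$grp <- ifelse(site_tab$region == "CDS", "CDS", "UTRLIKE")
  probs <- motif_probs_table(cfg$nue_a_freq)
  site_tab$key <- paste(site_tab$grp, site_tab$d)
  site_tab <- site_tab[site_tab$key %in% names(probs), ]
  keep <- site_tab$gpos >= 1 &
    site_tab$gpos <= chrom_len[match(site_tab$chrom, chroms)]
  site_tab <- site_tab[keep, ]
  for (key in unique(site_tab$key)) {
    sel <- site_tab[site_tab$key == key, ]
    draw <- sample(bases, nrow(sel), replace = TRUE, prob = probs[[key]])
    minus <- sel$strand == "-"
    if (any(minus)) draw[minus] <- chartr("ACGT", "TGCA", draw[minus])
    for (cc in unique(sel$chrom)) {
      m <- sel$chrom == cc
      seqs[[cc]][sel$gpos[m]] <- draw[m]
    }
  }

  ## --- designated A8 tracts (written last so nothing overwrites them) ----
  tracts <- list()
  n_u3 <- min(cfg$a8_utr3_genes, n)
  n_cds <- min(cfg$a8_cds_genes, max(0L, n - n_u3))
  tract_spec <- rbind(
    if (n_u3 > 0) data.frame(g = seq_len(n_u3), region = "3UTR"),
    if (n_cds > 0) data.frame(g = n_u3 + seq_len(n_cds), region = "CDS")
  )
  if (!is.null(tract_spec) && nrow(tract_spec) > 0) {
    for (i in seq_len(nrow(tract_spec))) {
      g <- tract_spec$g[i]
      sense_start <- if (tract_spec$region[i] == "3UTR")
        L[g] - u3[g] + 11L else u5[g] + 31L
      gpos <- vapply(sense_start:(sense_start + 7L),
                     function(p) sense2genomic(g, p), integer(1))
      base <- if (strand[g] == "+") "A" else "T"
      seqs[[chroms[chrom_idx[g]]]][gpos] <- base
      ## guard the tract boundaries so the run is exactly the designed one
      flank_pos <- c(min(gpos) - 1L, max(gpos) + 1L)
      flank_pos <- flank_pos[flank_pos >= 1 & flank_pos <= chrom_len[chrom_idx[g]]]
      cur <- seqs[[chroms[chrom_idx[g]]]][flank_pos]
      cur[cur == base] <- "C"
      seqs[[chroms[chrom_idx[g]]]][flank_pos] <- cur
      tracts[[i]] <- data.frame(
        chrom = chroms[chrom_idx[g]], strand = strand[g],
        start = min(gpos), end = max(gpos),
        gene_id = gene_id[g], region = tract_spec$region[i],
        stringsAsFactors = FALSE
      )
    }
  }
  tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(chrom = character(), strand = character(), start = integer(),
               end = integer(), gene_id = character(), region = character())

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms

  ## --- annotation table --------------------------------------------------
  genes_df <- data.frame(
    gene_id = gene_id, chrom = chroms[chrom_idx], strand = strand,
    start = start, end = end,
    u5 = u5, cds1 = cds1, intron = intr, cds2 = cds2, u3 = u3,
    n_pacs = k_eff, apa = is_apa, expr_mu = expr_mu,
    stringsAsFactors = FALSE
  )
  ann <- build_sim_annotation(genes_df)

  structure(list(genome = genome, gff = ann$gff, truth = list(
    genes = genes_df, sites = sites, regions = ann$regions, tracts = tracts
  ), config = cfg), class = "apa_simulation")
}

## position-specific base probability lookup (A,C,G,T), keyed "GRP offset"
motif_probs_table <- function(nue_a) {
  p <- list()
  third <- (1 - nue_a) / 3
  for (d in -100:100) {
    v <- NULL
    if (d == 0) v <- c(0.90, 1, 1, 1) / c(1, 30, 30, 30)
    else if (d == -1) v <- c(0.05, 0.45, 0.05, 0.45)
    else if (d >= -10 && d <= -2) v <- c(0.10, 0.10, 0.10, 0.70)
    else if (d >= -30 && d <= -15) v <- c(nue_a, third, third, third)
    else if (d >= -100 && d <= -31) v <- c(0.20, 0.20, 0.20, 0.40)
    if (!is.null(v)) p[[paste("UTRLIKE", d)]] <- v
    if (d >= -40 && d <= 10)
      p[[paste("CDS", d)]] <- c(0.40, 0.125, 0.35, 0.125)
  }
  p
}

## expand per-gene architecture into GFF3 rows and region intervals
build_sim_annotation <- function(genes) {
  gff <- list(); regions <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- g$end - g$start + 1L
    ## sense intervals [start,end] of the five ordered segments
    segs <- cumsum(c(0L, g$u5, g$cds1, g$intron, g$cds2, g$u3))
    sense <- cbind(start = head(segs, -1) + 1L, end = tail(segs, -1))
    rownames(sense) <- c("5UTR", "CDS1", "INTRON", "CDS2", "3UTR")
    tog <- function(p) if (g$strand == "+") g$start + p - 1L else g$end - p + 1L
    giv <- function(s, e) { a <- tog(s); b <- tog(e); c(min(a, b), max(a, b)) }
    iv <- t(apply(sense, 1, function(r) giv(r[1], r[2])))
    exon1 <- giv(1L, g$u5 + g$cds1)
    exon2 <- giv(g$u5 + g$cds1 + g$intron + 1L, L)
    mid <- paste0(g$gene_id, ".m1")
    row <- function(type, s, e, id, parent = NA, phase = ".") {
      attr <- if (is.na(parent)) sprintf("ID=%s", id) else
        sprintf("ID=%s;Parent=%s", id, parent)
      data.frame(seqid = g$chrom, source = "patseqr_sim", type = type,
                 start = s, end = e, score = ".", strand = g$strand,
                 phase = phase, attributes = attr, stringsAsFactors = FALSE)
    }
    gff[[i]] <- rbind(
      row("gene", g$start, g$end, g$gene_id),
      row("mRNA", g$start, g$end, mid, g$gene_id),
      row("exon", exon1[1], exon1[2], paste0(mid, ".e1"), mid),
      row("exon", exon2[1], exon2[2], paste0(mid, ".e2"), mid),
      row("five_prime_UTR", iv["5UTR", 1], iv["5UTR", 2], paste0(mid, ".u5"), mid),
      row("CDS", iv["CDS1", 1], iv["CDS1", 2], paste0(mid, ".c1"), mid, "0"),
      row("CDS", iv["CDS2", 1], iv["CDS2", 2], paste0(mid, ".c2"), mid, "0"),
      row("three_prime_UTR", iv["3UTR", 1], iv["3UTR", 2], paste0(mid, ".u3"), mid)
    )
    regions[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      region = c("5UTR", "CDS", "INTRON", "CDS", "3UTR"),
      start = iv[c("5UTR", "CDS1", "INTRON", "CDS2", "3UTR"), 1],
      end = iv[c("5UTR", "CDS1", "INTRON", "CDS2", "3UTR"), 2],
      stringsAsFactors = FALSE
    )
  }
  list(gff = do.call(rbind, gff), regions = do.call(rbind, regions))
}

#' Simulate strand-aware poly(A)-tag records for every sample
#'
#' Draws per-gene tag counts from a negative binomial, assigns tags to the
#' gene's planted clusters according to the tissue's ground-truth usage
#' fractions, jitters cleavage positions by a discrete bounded kernel, and
#' re-assigns a configured fraction of tags to designated genomic A8 tracts
#' to emulate internal priming. Replicates of a tissue share the tissue-level
#' usage fractions; only counts differ.
#'
#' @param config a [sim_config()] object.
#' @param truth an `"apa_simulation"` object from [simulate_genome()] (or its
#'   `truth` element).
#' @return A list of class `"apa_tag_sim"` with `tags` (data frame
#'   `chrom, pos, strand, sample`; `pos` is the 1-based cleavage base) and
#'   `map` (per-tag origin: `gene_id`, `pac_id`, `tissue`, `ip` flag).
#' @export
simulate_tags <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(truth, "apa_simulation")) truth <- truth$truth
  sites <- truth$sites
  tracts <- truth$tracts
  cfg <- config
  set.seed(cfg$seed + 1L)
  if (cfg$internal_priming_rate > 0 && nrow(tracts) == 0)
    stop("internal_priming_rate > 0 but no designated A8 tracts in truth")

  jmax <- cfg$jitter_max
  jit_vals <- (-jmax):jmax
  jit_probs <- if (cfg$cluster_sd > 0)
    dnorm(jit_vals, 0, cfg$cluster_sd) else as.numeric(jit_vals == 0)
  jit_probs <- jit_probs / sum(jit_probs)

  genes <- unique(sites$gene_id)
  site_rows <- split(seq_len(nrow(sites)), sites$gene_id)[genes]
  expr_mu <- truth$genes$expr_mu[match(genes, truth$genes$gene_id)]
  if (is.null(expr_mu) || anyNA(expr_mu))
    expr_mu <- rep(cfg$tags_per_gene, length(genes))
  out <- list()
  for (t in cfg$tissues) {
    ucol <- paste0("usage_", t)
    for (r in seq_len(cfg$replicates_per_tissue)) {
      sample_id <- paste(t, r, sep = "_")
      ng <- rnbinom(length(genes), mu = expr_mu, size = cfg$tag_dispersion)
      rows_list <- vector("list", length(genes))
      for (gi in seq_along(genes)) {
        n <- ng[gi]
        if (n == 0) next
        sr <- site_rows[[gi]]
        alloc <- if (length(sr) == 1L) n else
          as.integer(rmultinom(1, n, sites[[ucol]][sr]))
        pac_idx <- rep(sr, alloc)
        rows_list[[gi]] <- pac_idx
      }
      pac_idx <- unlist(rows_list, use.names = FALSE)
      ntag <- length(pac_idx)
      if (ntag == 0) next
      jit <- sample(jit_vals, ntag, replace = TRUE, prob = jit_probs)
      df <- data.frame(
        chrom = sites$chrom[pac_idx],
        pos = sites$pos[pac_idx] + jit,
        strand = sites$strand[pac_idx],
        sample = sample_id,
        gene_id = sites$gene_id[pac_idx],
        pac_id = sites$pac_id[pac_idx],
        tissue = t,
        ip = FALSE,
        stringsAsFactors = FALSE
      )
      if (cfg$internal_priming_rate > 0) {
        hit <- which(rbinom(ntag, 1, cfg$internal_priming_rate) == 1L)
        if (length(hit)) {
          tr <- sample(seq_len(nrow(tracts)), length(hit), replace = TRUE)
          df$chrom[hit] <- tracts$chrom[tr]
          df$strand[hit] <- tracts$strand[tr]
          df$pos[hit] <- ifelse(tracts$strand[tr] == "+",
                                tracts$start[tr] - 1L, tracts$end[tr] + 1L)
          df$gene_id[hit] <- tracts$gene_id[tr]
          df$pac_id[hit] <- NA_character_
          df$ip[hit] <- TRUE
        }
      }
      out[[sample_id]] <- df
    }
  }
  all <- do.call(rbind, out)
  rownames(all) <- NULL
  structure(list(
    tags = all[, c("chrom", "pos", "strand", "sample")],
    map = all
  ), class = "apa_tag_sim")
}

#' Write a simulation to FASTA/GFF3/BED/TSV files
#'
#' Writes `genome.fa`, `annotation.gff3`, per-sample BED6 tag files
#' (`tags_<sample>.bed`) and tab-separated ground-truth tables into `dir`.
#' All writers are deterministic: the same simulation yields byte-identical
#' files.
#'
#' @param sim an `"apa_simulation"` object.
#' @param dir output directory (created if needed).
#' @param tags optional `"apa_tag_sim"` object from [simulate_tags()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, tags = NULL) {
  stopifnot(inherits(sim, "apa_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"), width = 70L)
  write_gff3(sim$gff, file.path(dir, "annotation.gff3"))
  for (nm in c("genes", "sites", "regions", "tracts")) {
    write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tags)) {
    for (s in unique(tags$tags$sample)) {
      write_bed_tags(tags$tags[tags$tags$sample == s, ],
                     file.path(dir, paste0("tags_", s, ".bed")))
    }
  }
  invisible(dir)
}

#' @export
print.apa_simulation <- function(x, ...) {
  cat(sprintf("Synthetic APA genome: %d genes, %d chromosome(s) (%s nt)\n",
              nrow(x$truth$genes), length(x$genome),
              paste(Biostrings::width(x$genome), collapse = "+")))
  cat(sprintf("  planted clusters: %d (%d genes multi-PAC, %d APA-shifted)\n",
              nrow(x$truth$sites), sum(x$truth$genes$n_pacs >= 2),
              sum(x$truth$genes$apa)))
  cat(sprintf("  designated A8 tracts: %d\n", nrow(x$truth$tracts)))
  invisible(x)
}
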