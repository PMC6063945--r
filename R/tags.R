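#' Reduce mapped records to single-nucleotide poly(A) tags
#'
#' Each strand-aware mapped record is reduced to the genomic position of its
#' 3'-most aligned base: for a plus-strand BED record `[start, end)` the tag
#' sits at `end` (1-based), for a minus-strand record at `start + 1`
#' (1-based). Records without a strand are rejected and counted. The output
#' is sorted by chromosome, coordinate and strand; tag counts are conserved
#' (one tag per stranded input record).
#'
#' @param bed data frame of mapped records as read by [read_bed()]
#'   (0-based half-open `start`/`end`, strand in column 6).
#' @param sample_id sample label attached to every tag.
#' @return A list with `tags` (data frame `chrom, pos, strand, sample`) and
#'   `n_rejected` (strandless records dropped).
#' @export
reduce_to_tags <- function(bed, sample_id) {
  ok <- bed$strand %in% c("+", "-")
  n_rejected <- sum(!ok)
  b <- bed[ok, , drop = FALSE]
  tags <- data.frame(
    chrom = b$chrom,
    pos = ifelse(b$strand == "+", b$end, b$start + 1L),
    strand = b$strand,
    sample = sample_id,
    stringsAsFactors = FALSE
  )
  tags <- tags[order(tags$chrom, tags$pos, tags$strand), , drop = FALSE]
  rownames(tags) <- NULL
  list(tags = tags, n_rejected = n_rejected)
}

#' Extract poly(A)-tail-bearing reads from FASTQ
#'
#' A read qualifies if its 3' terminus carries a run of at least `min_tail`
#' A residues with at most `max_mismatch` interspersed non-A bases; the tail
#' is trimmed before output. Because library orientation may be unknown, the
#' 5' end is also scanned for a complementary T-initiated tail; such reads
#' are trimmed and reverse-complemented. Both counts are reported.
#'
#' @param fastq path to an (uncompressed or gzipped) FASTQ file.
#' @param min_tail minimum number of A residues in the tail (default 8).
#' @param max_mismatch maximum non-A bases tolerated inside the tail
#'   (default 1).
#' @return A list with `reads` (trimmed [Biostrings::DNAStringSet]) and
#'   `summary` (data frame: reads scanned, 3' A-tails, 5' T-tails,
#'   qualifying reads).
#' @export
extract_polya_reads <- function(fastq, min_tail = 8L, max_mismatch = 1L) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) stop("malformed FASTQ: ", conditionMessage(e)))
  seqs <- as.character(reads)
  tail_a <- vapply(seqs, function(s) tail_run_length(s, "A", max_mismatch, from3p = TRUE),
                   integer(1), USE.NAMES = FALSE)
  head_t <- vapply(seqs, function(s) tail_run_length(s, "T", max_mismatch, from3p = FALSE),
                   integer(1), USE.NAMES = FALSE)
  a_ok <- attr_count(seqs, tail_a, "A", from3p = TRUE) >= min_tail
  t_ok <- attr_count(seqs, head_t, "T", from3p = FALSE) >= min_tail
  qual <- a_ok | t_ok
  out <- character(sum(qual))
  j <- 0L
  for (i in which(qual)) {
    j <- j + 1L
    s <- seqs[i]
    if (a_ok[i]) {
      out[j] <- substr(s, 1L, nchar(s) - tail_a[i])
    } else {
      trimmed <- substr(s, head_t[i] + 1L, nchar(s))
      out[j] <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(trimmed)))
    }
  }
  trimmed_reads <- Biostrings::DNAStringSet(out)
  names(trimmed_reads) <- names(reads)[qual]
  list(
    reads = trimmed_reads,
    summary = data.frame(
      n_reads = length(seqs),
      n_a_tail_3p = sum(a_ok),
      n_t_tail_5p = sum(t_ok & !a_ok),
      n_qualifying = sum(qual)
    )
  )
}

## length of the terminal segment scanned greedily from the read end
## (3' suffix if from3p, else 5' prefix), stopping when mismatches to
## `base` would exceed max_mismatch; trailing mismatches are not included.
tail_run_length <- function(s, base, max_mismatch, from3p = TRUE) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (from3p) ch <- rev(ch)
  mism <- 0L
  len <- 0L
  last_match <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == base) {
      len <- i
      last_match <- i
    } else {
      mism <- mism + 1L
      if (mism > max_mismatch) break
    }
  }
  last_match
}

## number of `base` residues inside the accepted terminal segment
attr_count <- function(seqs, seg_len, base, from3p = TRUE) {
  vapply(seq_along(seqs), function(i) {
    n <- seg_len[i]
    if (n == 0L) return(0L)
    s <- seqs[i]
    seg <- if (from3p) substr(s, nchar(s) - n + 1L, nchar(s)) else substr(s, 1L, n)
    sum(strsplit(seg, "", fixed = TRUE)[[1]] == base)
  }, integer(1))
}
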