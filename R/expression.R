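#' Gene-level expression from tag counts
#'
#' Counts tags per gene per sample over the extended gene spans
#' (same-strand containment). Tags matching several genes are counted as
#' ambiguous and excluded from every gene row; tags matching no gene are
#' counted as unassigned. Column sums plus ambiguous plus unassigned equal
#' the per-sample tag totals.
#'
#' @param tags data frame of tags (`chrom, pos, strand, sample`).
#' @param annotation a `"GenomeAnnotation"`.
#' @return A list of class `"expr_matrix"`: `counts` (gene x sample integer
#'   matrix), `unassigned` and `ambiguous` per-sample vectors, and
#'   `stage = "raw"`.
#' @export
count_gene_expression <- function(tags, annotation) {
  samples <- sort(unique(tags$sample))
  genes <- sort(unique(annotation$gene_spans$gene_id))
  q <- GenomicRanges::GRanges(tags$chrom, IRanges::IRanges(tags$pos, tags$pos),
                              strand = tags$strand)
  hits <- GenomicRanges::findOverlaps(q, annotation$gene_spans)
  qh <- S4Vectors::queryHits(hits)
  nhit <- tabulate(qh, nbins = nrow(tags))
  gene_of <- rep(NA_character_, nrow(tags))
  one <- nhit == 1L
  gene_of[one] <- annotation$gene_spans$gene_id[
    S4Vectors::subjectHits(hits)[match(which(one), qh)]]

  counts <- table(factor(gene_of[one], levels = genes),
                  factor(tags$sample[one], levels = samples))
  counts <- matrix(as.integer(counts), nrow = length(genes),
                   dimnames = list(genes, samples))
  amb <- table(factor(tags$sample[nhit >= 2L], levels = samples))
  unas <- table(factor(tags$sample[nhit == 0L], levels = samples))
  structure(list(
    counts = counts,
    ambiguous = as.integer(amb),
    unassigned = as.integer(unas),
    samples = samples,
    stage = "raw"
  ), class = "expr_matrix")
}

#' Quantile normalization (rank-mean procedure)
#'
#' Classic quantile normalization: each column is sorted, the across-column
#' mean is computed at every rank, and each value is replaced by the mean at
#' its rank. Ties within a column receive the mean over their rank range.
#' After normalization all columns share an identical multiset of values,
#' and the procedure is idempotent.
#'
#' @param m numeric matrix (or an `"expr_matrix"`, whose counts are
#'   normalized in place and whose stage is advanced).
#' @return The normalized matrix (or `"expr_matrix"`).
#' @export
quantile_normalize <- function(m) {
  if (inherits(m, "expr_matrix")) {
    m$counts <- quantile_normalize(m$counts)
    m$stage <- "quantile"
    return(m)
  }
  stopifnot(is.matrix(m), !anyNA(m))
  rank_means <- rowMeans(apply(m, 2, sort))
  cms <- c(0, cumsum(rank_means))
  out <- m
  for (j in seq_len(ncol(m))) {
    r_min <- rank(m[, j], ties.method = "min")
    r_max <- rank(m[, j], ties.method = "max")
    out[, j] <- (cms[r_max + 1L] - cms[r_min]) / (r_max - r_min + 1L)
  }
  out
}

#' Pearson correlation between expression profiles
#'
#' Applies `log2` and computes the Pearson correlation coefficient for each
#' requested column pair of two expression matrices sharing a gene set
#' (e.g. PAT-based vs RNA-seq-based estimates of the same samples).
#' Zero-variance columns yield `NA` and are flagged.
#'
#' @param a,b numeric matrices (same rows, typically `+1`-shifted and
#'   quantile-normalized) or `"expr_matrix"` objects.
#' @param pairing two-column data frame (`col_a`, `col_b`); default pairs
#'   columns positionally.
#' @param log2_transform apply `log2` first (default `TRUE`).
#' @return Data frame `col_a, col_b, r` with attribute
#'   `zero_variance` listing degenerate columns.
#' @export
correlate_expression <- function(a, b, pairing = NULL, log2_transform = TRUE) {
  if (inherits(a, "expr_matrix")) a <- a$counts
  if (inherits(b, "expr_matrix")) b <- b$counts
  stopifnot(nrow(a) == nrow(b))
  if (is.null(pairing))
    pairing <- data.frame(col_a = seq_len(min(ncol(a), ncol(b))),
                          col_b = seq_len(min(ncol(a), ncol(b))))
  la <- if (log2_transform) log2(a) else a
  lb <- if (log2_transform) log2(b) else b
  zv <- character(0)
  r <- numeric(nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    x <- la[, pairing$col_a[i]]; y <- lb[, pairing$col_b[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[i] <- NA_real_
      zv <- c(zv, paste(pairing$col_a[i], pairing$col_b[i], sep = "/"))
    } else {
      r[i] <- cor(x, y)
    }
  }
  out <- data.frame(col_a = pairing$col_a, col_b = pairing$col_b, r = r)
  attr(out, "zero_variance") <- zv
  out
}

#' All-pairs replicate correlation table
#'
#' Pearson correlations between every pair of columns of one matrix (after
#' `log2`), as used to assess replicate agreement.
#'
#' @param m numeric matrix or `"expr_matrix"`.
#' @param log2_transform apply `log2` first (default `TRUE`).
#' @return Symmetric correlation matrix.
#' @export
replicate_correlations <- function(m, log2_transform = TRUE) {
  if (inherits(m, "expr_matrix")) m <- m$counts
  if (log2_transform) m <- log2(m)
  cor(m)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix [%s]: %d genes x %d samples\n",
              x$stage, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
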