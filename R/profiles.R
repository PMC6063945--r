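#' Per-PAS normalized tag counts for a tissue
#'
#' Per replicate, a PAS's tag count is scaled by the replicate's total tag
#' count over all PASs and expressed per million; the replicate-wise values
#' are then averaged.
#'
#' @param pas a `"pas_set"` from [build_pas()].
#' @param samples sample ids of the tissue's replicates.
#' @return Numeric vector of mean normalized counts (tags per million), one
#'   per PAS row.
#' @export
normalize_pas_counts <- function(pas, samples) {
  cols <- paste0("count.", samples)
  miss <- setdiff(cols, names(pas))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(as.data.frame(pas)[, cols, drop = FALSE])
  tot <- colSums(m)
  if (any(tot == 0)) stop("replicate with zero total tag count")
  rowMeans(sweep(m, 2, tot, "/") * 1e6)
}

#' Nucleotide-composition profiles around PASs, by region class
#'
#' Retains PASs of one tissue with mean normalized count >= `min_norm` tags
#' per million that are assigned to a gene and a concrete region class,
#' fetches the sense-strand window of `2 * flank + 1` nt around each
#' cleavage site (windows running off a chromosome are dropped), and
#' computes per-position base frequencies per region class.
#'
#' @param pas a `"pas_set"`.
#' @param annotation a `"GenomeAnnotation"`.
#' @param samples replicate sample ids of the tissue.
#' @param min_norm normalized-count retention threshold (default 2 per
#'   million).
#' @param flank window flank in nt (default 100).
#' @param regions region classes to profile.
#' @return A list of class `"nt_profile_set"`; per region class, a list with
#'   `freq` (4 x (2*flank+1) matrix, rows A/C/G/T, columns labeled by window
#'   position with the cleavage base at +1), `n_sites` and `positions`.
#' @export
pas_profile <- function(pas, annotation, samples, min_norm = 2, flank = 100L,
                        regions = c("3UTR", "CDS", "INTRON", "5UTR")) {
  norm <- normalize_pas_counts(pas, samples)
  p <- as.data.frame(pas)
  p$norm <- norm
  if ("retained" %in% names(p)) p <- p[p$retained, , drop = FALSE]  # master list
  p <- p[p$norm >= min_norm, , drop = FALSE]
  p <- assign_regions(p, annotation)
  p <- p[!is.na(p$gene_id) & p$region %in% regions, , drop = FALSE]
  out <- list()
  for (r in regions) {
    pr <- p[p$region == r, , drop = FALSE]
    out[[r]] <- profile_windows(annotation, pr$chrom, pr$strand, pr$pos, flank)
  }
  structure(out, class = "nt_profile_set", flank = flank)
}

profile_windows <- function(annotation, chrom, strand, center, flank) {
  pos_lab <- window_positions(flank)
  w <- 2L * flank + 1L
  if (length(center) == 0) {
    return(list(freq = matrix(NA_real_, 4, w,
                              dimnames = list(c("A", "C", "G", "T"), pos_lab)),
                n_sites = 0L, positions = pos_lab, empty = TRUE))
  }
  fw <- fetch_windows(annotation, chrom, strand, center, flank)
  if (length(fw$kept) == 0) {
    return(list(freq = matrix(NA_real_, 4, w,
                              dimnames = list(c("A", "C", "G", "T"), pos_lab)),
                n_sites = 0L, positions = pos_lab, empty = TRUE))
  }
  cm <- Biostrings::consensusMatrix(fw$seqs, as.prob = TRUE)
  freq <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  colnames(freq) <- pos_lab
  list(freq = freq, n_sites = length(fw$kept), positions = pos_lab,
       empty = FALSE)
}

#' N6A8 internal-priming control profiles
#'
#' Locates every maximal run of >= `run_len` A residues (sense-strand, both
#' strands scanned) preceded by at least `n_prefix` arbitrary nucleotides,
#' anchors the window at the first A of the run (the pseudo-cleavage
#' position an internally primed read would produce), assigns anchors to
#' genes/regions, and profiles the requested region classes exactly as
#' [pas_profile()] does. These control profiles characterize what genuine
#' internal-priming artifacts look like.
#'
#' @param annotation a `"GenomeAnnotation"`.
#' @param regions region classes to profile (default 3'UTR and CDS).
#' @param flank window flank in nt (default 100).
#' @param run_len minimum A-run length (default 8).
#' @param n_prefix required upstream sequence length (default 6).
#' @return A `"nt_profile_set"` (one entry per region class) with an
#'   additional attribute `anchors`: the labeled anchor table.
#' @export
internal_priming_profile <- function(annotation, regions = c("3UTR", "CDS"),
                                     flank = 100L, run_len = 8L, n_prefix = 6L) {
  anchors <- find_a_runs(annotation$genome, run_len = run_len,
                         n_prefix = n_prefix)
  anchors <- assign_regions(anchors, annotation)
  out <- list()
  for (r in regions) {
    ar <- anchors[!is.na(anchors$gene_id) & anchors$region == r, , drop = FALSE]
    out[[r]] <- profile_windows(annotation, ar$chrom, ar$strand, ar$pos, flank)
  }
  structure(out, class = "nt_profile_set", flank = flank, anchors = anchors)
}

## maximal sense-strand A-runs of length >= run_len on both strands;
## pos = first A of the run in sense orientation
find_a_runs <- function(genome, run_len = 8L, n_prefix = 6L) {
  pat_a <- sprintf("A{%d,}", run_len)
  pat_t <- sprintf("T{%d,}", run_len)
  res <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    len <- nchar(s)
    for (str in c("+", "-")) {
      m <- gregexpr(if (str == "+") pat_a else pat_t, s)[[1]]
      if (m[1] == -1) next
      starts <- as.integer(m)
      ends <- starts + attr(m, "match.length") - 1L
      anchor <- if (str == "+") starts else ends
      upstream_ok <- if (str == "+") (anchor - n_prefix >= 1L) else
        (anchor + n_prefix <= len)
      if (!any(upstream_ok)) next
      res[[paste(chrom, str)]] <- data.frame(
        chrom = chrom, strand = str,
        pos = anchor[upstream_ok],
        run_start = starts[upstream_ok], run_end = ends[upstream_ok],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), run_start = integer(),
                      run_end = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.nt_profile_set <- function(x, ...) {
  cat("Nucleotide-composition profiles (cleavage base at +1)\n")
  for (r in names(x)) {
    cat(sprintf("  %-7s %d site(s)%s\n", r, x[[r]]$n_sites,
                if (isTRUE(x[[r]]$empty)) " [empty]" else ""))
  }
  invisible(x)
}

#' Plot a nucleotide-composition profile
#'
#' Line plot of per-position A/C/G/U(T) frequencies for one region class.
#'
#' @param x a `"nt_profile_set"`.
#' @param region region class to plot (default the first non-empty one).
#' @param ... passed to [graphics::matplot].
#' @return `x`, invisibly.
#' @export
plot.nt_profile_set <- function(x, region = NULL, ...) {
  region <- region %||% names(x)[!vapply(x, function(p) isTRUE(p$empty), logical(1))][1]
  p <- x[[region]]
  if (is.null(p) || isTRUE(p$empty)) stop("no sites to plot for region ", region)
  graphics::matplot(p$positions, t(p$freq), type = "l", lty = 1,
                    col = c("forestgreen", "blue", "orange", "red"),
                    xlab = "position relative to cleavage site (+1)",
                    ylab = "base frequency",
                    main = sprintf("%s (n=%d)", region, p$n_sites), ...)
  graphics::legend("topright", legend = c("A", "C", "G", "U"), lty = 1,
                   col = c("forestgreen", "blue", "orange", "red"), bty = "n")
  invisible(x)
}
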