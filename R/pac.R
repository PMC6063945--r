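#' Flag tags likely caused by internal priming at genomic A-tracts
#'
#' A tag is flagged when the sense-strand genomic sequence immediately
#' downstream of its cleavage coordinate (positions +1..+`window`) contains a
#' run of at least `run_len` consecutive A residues, or when the tag itself
#' lies inside such a run. This is the post-mapping equivalent of masking
#' A8-containing genomic regions before mapping.
#'
#' @param tags data frame of tags (`chrom`, `pos`, `strand`, ...).
#' @param annotation a `"GenomeAnnotation"` (the genome is used).
#' @param run_len minimum A-run length (default 8).
#' @param window downstream scan width in nt (default 10).
#' @return A list with `kept` and `flagged` tag data frames and the
#'   corresponding counts `n_kept`, `n_flagged`.
#' @export
flag_internal_priming <- function(tags, annotation, run_len = 8L, window = 10L) {
  n <- nrow(tags)
  if (n == 0)
    return(list(kept = tags, flagged = tags, n_kept = 0L, n_flagged = 0L))
  run <- strrep("A", run_len)

  dn <- sense_segment(annotation, tags$chrom, tags$strand, tags$pos,
                      from = 1L, to = window)
  flag_down <- grepl(run, dn, fixed = TRUE)

  seg <- sense_segment(annotation, tags$chrom, tags$strand, tags$pos,
                       from = -(run_len - 1L), to = run_len - 1L)
  ## maximal A-run through the center base (position run_len in seg)
  left <- substr(seg, 1L, run_len)
  right <- substr(seg, run_len, 2L * run_len - 1L)
  center_a <- substr(seg, run_len, run_len) == "A"
  left_as <- nchar(sub("^.*?(A*)$", "\\1", left))
  right_as <- nchar(sub("^(A*).*$", "\\1", right))
  flag_in <- center_a & (left_as + right_as - 1L) >= run_len

  f <- flag_down | flag_in
  list(kept = tags[!f, , drop = FALSE],
       flagged = tags[f, , drop = FALSE],
       n_kept = sum(!f), n_flagged = sum(f))
}

## sense-strand sequence at offsets [from, to] relative to pos (offset 0 =
## the tagged base); truncated at chromosome boundaries
sense_segment <- function(annotation, chrom, strand, pos, from, to) {
  len <- annotation$chrom_len[chrom]
  plus <- strand == "+"
  lo <- ifelse(plus, pos + from, pos - to)
  hi <- ifelse(plus, pos + to, pos - from)
  lo_c <- pmax(lo, 1L)
  hi_c <- pmin(hi, len)
  out <- character(length(pos))
  empty <- hi_c < lo_c
  for (cc in unique(chrom)) {
    m <- which(chrom == cc & !empty)
    if (!length(m)) next
    v <- Biostrings::extractAt(annotation$genome[[cc]],
                               IRanges::IRanges(lo_c[m], hi_c[m]))
    v <- Biostrings::DNAStringSet(v)
    mm <- !plus[m]
    if (any(mm)) v[mm] <- Biostrings::reverseComplement(v[mm])
    out[m] <- as.character(v)
  }
  out
}

#' Build the poly(A)-site (PAS) list from tags
#'
#' Aggregates tags into one PAS per (chromosome, strand, coordinate) with
#' per-sample tag counts. PASs supported by fewer than `min_tags` tags in
#' the complete dataset are marked not retained (the pre-filter set is kept
#' so tag accounting stays exact).
#'
#' @param tags data frame of tags (`chrom`, `pos`, `strand`, `sample`).
#' @param min_tags dataset-level retention threshold (default 8).
#' @return A data frame of class `"pas_set"`: `chrom, strand, pos`,
#'   one `count.<sample>` column per sample, `total`, `retained`.
#' @export
build_pas <- function(tags, min_tags = 8L) {
  stopifnot(nrow(tags) >= 1)
  dt <- data.table::as.data.table(tags[, c("chrom", "pos", "strand", "sample")])
  agg <- dt[, .N, by = c("chrom", "strand", "pos", "sample")]
  wide <- data.table::dcast(agg, chrom + strand + pos ~ sample,
                            value.var = "N", fill = 0L)
  samples <- sort(unique(tags$sample))
  data.table::setnames(wide, samples, paste0("count.", samples))
  df <- as.data.frame(wide)
  cnt <- df[, paste0("count.", samples), drop = FALSE]
  df$total <- as.integer(rowSums(cnt))
  df$retained <- df$total >= min_tags
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "samples") <- samples
  attr(df, "min_tags") <- as.integer(min_tags)
  class(df) <- c("pas_set", "data.frame")
  df
}

#' Group PASs into poly(A)-site clusters (PACs)
#'
#' Single-linkage chaining along each (chromosome, strand): scanning sorted
#' PAS coordinates, a new PAC starts whenever the gap to the previous PAS
#' exceeds `max_gap` nt; PASs within `max_gap` of one another therefore end
#' up in one PAC even if the cluster span exceeds `max_gap`. PACs supported
#' by fewer than `min_pac_tags` tags in the complete dataset are marked not
#' retained. The representative coordinate is the highest-count member PAS
#' (ties broken toward the 3'-most member, strand-aware).
#'
#' @param pas a `"pas_set"` from [build_pas()].
#' @param max_gap maximum within-PAC gap between consecutive PASs (default
#'   24 nt).
#' @param min_pac_tags dataset-level PAC retention threshold (default 20).
#' @param use_filtered cluster only PASs passing the PAS-level threshold
#'   (default `TRUE`); set `FALSE` to cluster the pre-filter PAS list.
#' @return A data frame of class `"pac_set"`: `pac_id, chrom, strand, start,
#'   end, representative, n_pas, members` (comma-joined PAS coordinates),
#'   per-sample `count.<sample>` columns, `total`, `retained`.
#' @export
cluster_pacs <- function(pas, max_gap = 24L, min_pac_tags = 20L,
                         use_filtered = TRUE) {
  samples <- attr(pas, "samples")
  cols <- paste0("count.", samples)
  p <- as.data.frame(pas)
  if (use_filtered) p <- p[p$retained, , drop = FALSE]
  if (nrow(p) == 0) {
    out <- data.frame(pac_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      representative = integer(), n_pas = integer(),
                      members = character(), total = integer(),
                      retained = logical())
    attr(out, "samples") <- samples
    class(out) <- c("pac_set", "data.frame")
    return(out)
  }
  p <- p[order(p$chrom, p$strand, p$pos), , drop = FALSE]
  grp_key <- paste(p$chrom, p$strand)
  new_grp <- c(TRUE, grp_key[-1] != grp_key[-nrow(p)])
  gap_break <- c(TRUE, diff(p$pos) > max_gap)
  cluster <- cumsum(new_grp | gap_break)

  dt <- data.table::as.data.table(p)
  dt$cluster <- cluster
  rep_pick <- function(pos, total, strand) {
    best <- total == max(total)
    cand <- pos[best]
    if (strand[1] == "+") max(cand) else min(cand)
  }
  agg <- dt[, c(list(chrom = chrom[1], strand = strand[1],
                     start = min(pos), end = max(pos),
                     representative = rep_pick(pos, total, strand),
                     n_pas = .N,
                     members = paste(pos, collapse = ",")),
                lapply(.SD, sum)),
            by = "cluster", .SDcols = c(cols, "total")]
  out <- as.data.frame(agg)
  out$cluster <- NULL
  out$total <- as.integer(out$total)
  out$retained <- out$total >= min_pac_tags
  out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
  out$pac_id <- sprintf("PAC%05d", seq_len(nrow(out)))
  out <- out[, c("pac_id", "chrom", "strand", "start", "end", "representative",
                 "n_pas", "members", cols, "total", "retained")]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  attr(out, "max_gap") <- as.integer(max_gap)
  attr(out, "min_pac_tags") <- as.integer(min_pac_tags)
  class(out) <- c("pac_set", "data.frame")
  out
}

#' Assess coordinate overlap between two PAC sets
#'
#' Counts PACs in each set whose span intersects at least one same-strand
#' PAC span in the other set, and lists the intersecting pairs. Used to
#' validate PAC calls against an independent dataset.
#'
#' @param pacs_a,pacs_b `"pac_set"` data frames on the same genome.
#' @return A list with `n_a_overlapping`, `n_b_overlapping`, and `pairs`
#'   (data frame of overlapping `pac_a`/`pac_b` ids).
#' @export
overlap_pacs <- function(pacs_a, pacs_b) {
  mk <- function(p) GenomicRanges::GRanges(p$chrom,
                                           IRanges::IRanges(p$start, p$end),
                                           strand = p$strand)
  if (nrow(pacs_a) == 0 || nrow(pacs_b) == 0) {
    return(list(n_a_overlapping = 0L, n_b_overlapping = 0L,
                pairs = data.frame(pac_a = character(), pac_b = character())))
  }
  # sets may cover different chromosome subsets; that is not an error here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mk(pacs_a), mk(pacs_b)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  list(
    n_a_overlapping = length(unique(qh)),
    n_b_overlapping = length(unique(sh)),
    pairs = data.frame(pac_a = pacs_a$pac_id[qh], pac_b = pacs_b$pac_id[sh],
                       stringsAsFactors = FALSE)
  )
}

#' Tag-accounting summary across the PAS/PAC pipeline
#'
#' Verifies the conservation identity: every input tag is either flagged as
#' internal priming, in a sub-threshold PAS, in a discarded PAC, or in a
#' retained PAC.
#'
#' @param n_input total input tag count.
#' @param n_flagged tags flagged by [flag_internal_priming()].
#' @param pas the `"pas_set"` built from the kept tags.
#' @param pacs the `"pac_set"` clustered from the retained PASs.
#' @return A one-row data frame of the four tallies plus `balanced`.
#' @export
tag_accounting <- function(n_input, n_flagged, pas, pacs) {
  sub_pas <- sum(pas$total[!pas$retained])
  disc_pac <- sum(pacs$total[!pacs$retained])
  kept_pac <- sum(pacs$total[pacs$retained])
  data.frame(
    n_input = n_input,
    n_flagged = n_flagged,
    n_subthreshold_pas = sub_pas,
    n_discarded_pac = disc_pac,
    n_retained_pac = kept_pac,
    balanced = n_input == n_flagged + sub_pas + disc_pac + kept_pac
  )
}
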