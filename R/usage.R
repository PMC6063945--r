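#' Relative PAC usage per sample
#'
#' For every PAC of a multi-PAC gene, usage in a sample is the PAC's tag
#' count divided by the total tag count of all the gene's (retained) PACs in
#' that sample. Genes with zero tags in a sample yield `NA` entries there;
#' single-PAC genes are excluded (their usage is identically 1 and carries
#' no APA information).
#'
#' @param pacs a labeled, retained `"pac_set"` (see [assign_regions()]);
#'   rows with `retained == FALSE` or without a `gene_id` are dropped.
#' @return A data frame of class `"usage_table"`: `pac_id, gene_id, region`,
#'   one `usage.<sample>` column per sample.
#' @export
relative_usage <- function(pacs) {
  samples <- attr(pacs, "samples")
  cols <- paste0("count.", samples)
  p <- as.data.frame(pacs)
  if ("retained" %in% names(p)) p <- p[p$retained, , drop = FALSE]
  p <- p[!is.na(p$gene_id), , drop = FALSE]
  multi <- names(which(table(p$gene_id) >= 2))
  p <- p[p$gene_id %in% multi, , drop = FALSE]
  cnt <- as.matrix(p[, cols, drop = FALSE])
  out <- p[, c("pac_id", "gene_id", "region")]
  if (nrow(p)) {
    gene_tot <- rowsum(cnt, p$gene_id)
    denom <- gene_tot[p$gene_id, , drop = FALSE]
    frac <- cnt / denom
    frac[denom == 0] <- NA_real_
  } else {
    frac <- matrix(numeric(0), 0, length(samples))
  }
  colnames(frac) <- paste0("usage.", samples)
  out <- cbind(out, as.data.frame(frac))
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  class(out) <- c("usage_table", "data.frame")
  out
}

#' Between-group usage differences with per-region aggregation
#'
#' The difference for a PAC is its mean usage over the samples of group A
#' minus its mean usage over the samples of group B (undefined entries
#' excluded from the means; a PAC with no defined usage in either group is
#' dropped). Differences are aggregated by region label into boxplot-ready
#' summaries.
#'
#' @param usage a `"usage_table"` from [relative_usage()].
#' @param group_a,group_b character vectors of sample ids.
#' @return A list with `differences` (per-PAC data frame: usage means and
#'   difference) and `by_region` (region, n, median, q1, q3, whiskers).
#' @export
usage_differences <- function(usage, group_a, group_b) {
  ua <- group_mean_usage(usage, group_a)
  ub <- group_mean_usage(usage, group_b)
  keep <- !is.na(ua) & !is.na(ub)
  diffs <- data.frame(
    pac_id = usage$pac_id[keep],
    gene_id = usage$gene_id[keep],
    region = usage$region[keep],
    usage_a = ua[keep], usage_b = ub[keep],
    difference = ua[keep] - ub[keep],
    stringsAsFactors = FALSE
  )
  by_region <- do.call(rbind, lapply(split(diffs$difference, diffs$region),
                                     boxplot_stats))
  if (!is.null(by_region)) {
    by_region <- data.frame(region = rownames(by_region), by_region,
                            row.names = NULL)
  }
  list(differences = diffs, by_region = by_region)
}

group_mean_usage <- function(usage, samples) {
  cols <- paste0("usage.", samples)
  miss <- setdiff(cols, names(usage))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(usage[, cols, drop = FALSE])
  rowMeans(m, na.rm = TRUE)
}

boxplot_stats <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lw <- min(x[x >= q[1] - 1.5 * iqr])
  uw <- max(x[x <= q[3] + 1.5 * iqr])
  data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
             whisker_low = lw, whisker_high = uw)
}

#' Per-gene poly(A) usage dissimilarity metric
#'
#' Total-variation distance between two per-gene usage-fraction vectors over
#' the union of the gene's PACs: `0.5 * sum(|a - b|)`. The metric is 0 for
#' identical usage, 1 for disjoint support, and satisfies the metric axioms
#' on the probability simplex. A gene unexpressed in either library (zero
#' vector) is undefined and returns `NA`.
#'
#' @param usage_a,usage_b numeric usage-fraction vectors of equal length,
#'   each summing to 1 (or all zero if the gene is unexpressed).
#' @return Dissimilarity in `[0, 1]`, or `NA` if undefined.
#' @export
polya_metric <- function(usage_a, usage_b) {
  stopifnot(length(usage_a) == length(usage_b))
  if (anyNA(usage_a) || anyNA(usage_b)) return(NA_real_)
  if (sum(usage_a) == 0 || sum(usage_b) == 0) return(NA_real_)
  0.5 * sum(abs(usage_a - usage_b))
}

#' Differential PAC usage between tissue groups
#'
#' For every pair of groups and every PAC of a qualifying multi-PAC gene, a
#' 2x2 table of replicate-summed counts (PAC tags vs the gene's other tags,
#' group A vs group B) is tested with a two-sided conditional exact test
#' (Fisher). P values are BH-adjusted across all tested PACs within the
#' comparison. A PAC is called significant when the adjusted p value is
#' below `alpha` *and* the usage-difference sign is consistent in every
#' defined between-group replicate pairing (a guard against calls driven by
#' a single replicate). Genes below `min_gene_tags` in either group's pooled
#' counts are skipped and counted.
#'
#' @param pacs labeled, retained `"pac_set"` with per-sample counts.
#' @param groups named list mapping group label to its sample ids (each
#'   group needs >= 2 replicates).
#' @param alpha significance level on the adjusted p value (default 0.05).
#' @param min_gene_tags minimum pooled gene tag count per group (default 20).
#' @return A list of class `"apa_differential"`:
#'   `results` (per PAC x comparison), `summary` (per comparison: PACs and
#'   distinct genes significant, genes skipped), and `sharing` (how many
#'   significant PACs appear in exactly 1, 2, ... comparisons).
#' @export
differential_usage <- function(pacs, groups, alpha = 0.05, min_gene_tags = 20L) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  for (g in names(groups))
    if (length(groups[[g]]) < 2)
      stop("group '", g, "' has fewer than 2 replicates")
  samples <- attr(pacs, "samples")
  p <- as.data.frame(pacs)
  if ("retained" %in% names(p)) p <- p[p$retained, , drop = FALSE]
  p <- p[!is.na(p$gene_id), , drop = FALSE]
  multi <- names(which(table(p$gene_id) >= 2))
  p <- p[p$gene_id %in% multi, , drop = FALSE]

  cnt <- as.matrix(p[, paste0("count.", samples), drop = FALSE])
  colnames(cnt) <- samples
  gene_tot <- rowsum(cnt, p$gene_id)  # gene x sample

  combos <- combn(names(groups), 2, simplify = FALSE)
  res_list <- list(); summ_list <- list()
  for (cmb in combos) {
    ga <- groups[[cmb[1]]]; gb <- groups[[cmb[2]]]
    comparison <- paste(cmb[1], cmb[2], sep = "_vs_")
    a_pac <- rowSums(cnt[, ga, drop = FALSE])
    b_pac <- rowSums(cnt[, gb, drop = FALSE])
    a_gene <- rowSums(gene_tot[p$gene_id, ga, drop = FALSE])
    b_gene <- rowSums(gene_tot[p$gene_id, gb, drop = FALSE])
    testable <- a_gene >= min_gene_tags & b_gene >= min_gene_tags
    n_skipped_genes <- length(unique(p$gene_id[!testable]))

    idx <- which(testable)
    pval <- rep(NA_real_, nrow(p))
    for (i in idx) {
      tabm <- matrix(c(a_pac[i], a_gene[i] - a_pac[i],
                       b_pac[i], b_gene[i] - b_pac[i]), nrow = 2)
      pval[i] <- fisher.test(tabm, alternative = "two.sided")$p.value
    }
    padj <- rep(NA_real_, nrow(p))
    padj[idx] <- p.adjust(pval[idx], method = "BH")
    ua <- ifelse(a_gene > 0, a_pac / a_gene, NA_real_)
    ub <- ifelse(b_gene > 0, b_pac / b_gene, NA_real_)
    diff <- ua - ub

    consistent <- rep(FALSE, nrow(p))
    frac <- cnt / gene_tot[p$gene_id, samples, drop = FALSE]
    for (i in idx) {
      fa <- frac[i, ga]; fb <- frac[i, gb]
      d <- as.vector(outer(fa[!is.na(fa)], fb[!is.na(fb)], "-"))
      consistent[i] <- length(d) > 0 && !is.na(diff[i]) && diff[i] != 0 &&
        all(sign(d) == sign(diff[i]))
    }
    sig <- !is.na(padj) & padj < alpha & consistent

    res_list[[comparison]] <- data.frame(
      pac_id = p$pac_id, gene_id = p$gene_id, region = p$region,
      comparison = comparison,
      usage_a = ua, usage_b = ub, difference = diff,
      p_value = pval, p_adjusted = padj,
      tested = testable, significant = sig,
      stringsAsFactors = FALSE
    )
    summ_list[[comparison]] <- data.frame(
      comparison = comparison,
      n_tested = length(idx),
      n_significant_pacs = sum(sig),
      n_significant_genes = length(unique(p$gene_id[sig])),
      n_skipped_genes = n_skipped_genes,
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, res_list)
  rownames(results) <- NULL
  sig_tab <- table(results$pac_id[results$significant])
  sharing <- table(factor(as.integer(sig_tab), levels = seq_along(combos)))
  structure(list(
    results = results,
    summary = do.call(rbind, c(summ_list, list(make.row.names = FALSE))),
    sharing = sharing,
    alpha = alpha
  ), class = "apa_differential")
}

#' @export
print.apa_differential <- function(x, ...) {
  cat("Differential PAC usage\n")
  print(x$summary, row.names = FALSE)
  cat("PAC sharing across comparisons:\n")
  print(x$sharing)
  invisible(x)
}
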