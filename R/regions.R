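#' Assign gene identifiers and genomic-region labels
#'
#' Each item (PAS, or PAC via its representative coordinate) receives the
#' same-strand gene whose extended span contains it and one region label
#' from `3UTR, CDS, INTRON, 5UTR, AMBIGUOUS, INTERGENIC`. The 3'UTR label
#' uses the extended interval. Items contained in more than one gene, or
#' covered by conflicting region labels of one gene's isoforms (including a
#' position inside one gene's extension and another gene's annotated
#' feature), are `AMBIGUOUS`; items outside every gene are `INTERGENIC`.
#'
#' @param items data frame with `chrom`, `strand` and either `pos` (PAS) or
#'   `representative` (PAC) columns.
#' @param annotation a `"GenomeAnnotation"`.
#' @return `items` with `gene_id` (NA unless uniquely assigned) and `region`
#'   columns appended.
#' @export
assign_regions <- function(items, annotation) {
  pos <- if ("pos" %in% names(items)) items$pos else items$representative
  if (is.null(pos)) stop("items need a 'pos' or 'representative' column")
  n <- nrow(items)
  gene_id <- rep(NA_character_, n)
  region <- rep("INTERGENIC", n)
  if (n > 0) {
    q <- GenomicRanges::GRanges(items$chrom, IRanges::IRanges(pos, pos),
                                strand = items$strand)
    ghits <- GenomicRanges::findOverlaps(q, annotation$gene_spans)
    qh <- S4Vectors::queryHits(ghits)
    genes_hit <- annotation$gene_spans$gene_id[S4Vectors::subjectHits(ghits)]
    ngenes <- tabulate(qh, nbins = n)
    one <- ngenes == 1L
    gene_id[one] <- genes_hit[match(which(one), qh)]
    region[ngenes >= 2L] <- "AMBIGUOUS"

    ## region label within the uniquely assigned gene
    idx <- which(one)
    if (length(idx)) {
      rhits <- GenomicRanges::findOverlaps(q[idx], annotation$regions)
      rq <- S4Vectors::queryHits(rhits)
      rr <- S4Vectors::subjectHits(rhits)
      same_gene <- annotation$regions$gene_id[rr] == gene_id[idx][rq]
      rq <- rq[same_gene]; rr <- rr[same_gene]
      lab <- annotation$regions$region[rr]
      nlab <- vapply(split(lab, factor(rq, levels = seq_along(idx))),
                     function(x) length(unique(x)), integer(1))
      first_lab <- rep(NA_character_, length(idx))
      first_lab[unique(rq)] <- lab[match(unique(rq), rq)]
      region[idx[nlab == 1L]] <- first_lab[nlab == 1L]
      region[idx[nlab >= 2L]] <- "AMBIGUOUS"
      ## inside the extended span but in no region interval (isoform gaps)
      region[idx[nlab == 0L]] <- "INTERGENIC"
      gene_id[idx[nlab == 0L]] <- NA_character_
    }
  }
  items$gene_id <- gene_id
  items$region <- region
  items
}

#' Genomic-distribution summaries of labeled PASs/PACs
#'
#' Computes (a) the percentage of items per region class, (b) the percentage
#' of tags (PATs) per region per sample when per-sample count columns are
#' present, and (c) the clusters-per-gene histogram with the count of genes
#' carrying two or more clusters.
#'
#' @param labeled items labeled by [assign_regions()].
#' @return A list with `item_pct` (data frame region/n/pct),
#'   `pat_pct` (region x sample percentage matrix, or NULL),
#'   `pacs_per_gene` (named table) and `n_genes_multi`.
#' @export
distribution_summary <- function(labeled) {
  if (nrow(labeled) == 0) stop("empty input")
  reg <- factor(labeled$region, levels = REGION_LEVELS)
  tab <- table(reg)
  item_pct <- data.frame(region = names(tab), n = as.integer(tab),
                         pct = 100 * as.integer(tab) / nrow(labeled))

  cols <- grep("^count\\.", names(labeled), value = TRUE)
  pat_pct <- NULL
  if (length(cols)) {
    m <- rowsum(as.matrix(labeled[, cols, drop = FALSE]), reg)
    # rowsum drops empty levels; re-expand
    full <- matrix(0, nrow = length(REGION_LEVELS), ncol = length(cols),
                   dimnames = list(REGION_LEVELS, sub("^count\\.", "", cols)))
    full[rownames(m), ] <- m
    tot <- colSums(full)
    pat_pct <- sweep(full, 2, ifelse(tot == 0, 1, tot), "/") * 100
  }

  assigned <- labeled[!is.na(labeled$gene_id), , drop = FALSE]
  per_gene <- table(assigned$gene_id)
  hist <- table(factor(pmin(as.integer(per_gene), 4L), levels = 1:4))
  names(hist) <- c("1", "2", "3", ">=4")
  list(item_pct = item_pct,
       pat_pct = pat_pct,
       pacs_per_gene = hist,
       n_genes_multi = sum(per_gene >= 2))
}
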