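#' Configuration for the synthetic APA experiment
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genome()] and [simulate_tags()]. Defaults emulate the design of
#' a three-tissue, three-replicate poly(A)-tag study on a small plant-like
#' toy genome: every gene carries a canonical 3'UTR poly(A)-site cluster,
#' a configurable fraction of genes carry 2-4 clusters, and a subset of the
#' multi-cluster genes receives a planted between-tissue usage shift.
#'
#' @param n_genes number of genes to simulate.
#' @param gene_length_range numeric length-2, annotated gene span range (nt).
#' @param n_chromosomes number of chromosomes; genes are laid out round-robin.
#' @param pacs_per_gene named probability vector over `"1".."4"`: distribution
#'   of the number of poly(A)-site clusters per gene.
#' @param region_mix named probability vector over
#'   `c("3UTR","CDS","intron","5UTR")`: region placement of non-primary
#'   clusters (the primary cluster is always 3'UTR-terminal).
#' @param tissues character vector of sample-group labels.
#' @param replicates_per_tissue replicates per tissue.
#' @param tags_per_gene mean tag count per gene per sample (negative binomial).
#' @param tag_dispersion negative-binomial size parameter for per-gene tag
#'   counts; larger is less overdispersed.
#' @param expr_sdlog log-normal standard deviation of the per-gene expression
#'   level (drawn once per gene, shared by all samples). The default 1 gives
#'   a realistic dynamic range and replicate correlations around 0.9; set 0
#'   to give every gene exactly `tags_per_gene` expected tags.
#' @param apa_genes_fraction fraction of multi-cluster genes with a planted
#'   between-tissue usage shift.
#' @param apa_effect usage-fraction shift Delta in `[0,1]` planted between the
#'   primary cluster and one non-primary cluster.
#' @param apa_shift_tissue tissue receiving the shifted usage vector; default
#'   the second tissue.
#' @param apa_target_region if set (e.g. `"intron"`), the shifted non-primary
#'   cluster of every APA gene is placed in this region.
#' @param internal_priming_rate fraction of tags re-assigned to designated
#'   genomic A8 tracts (internal-priming artifacts).
#' @param cluster_sd standard deviation (nt) of the discrete, bounded cleavage
#'   jitter within a cluster.
#' @param jitter_max hard bound (nt) on cleavage jitter; keeps true clusters
#'   within one 24-nt clustering window.
#' @param nue_a_freq A frequency planted across the near-upstream element
#'   (NUE) window (-30..-15) of 3'UTR/intron/5'UTR sites.
#' @param utr3_overrun_max maximum distance (nt) the primary cleavage site may
#'   lie past the annotated 3'UTR end (exercises the extension rule).
#' @param a8_utr3_genes,a8_cds_genes number of genes receiving a designated A8
#'   tract in their 3'UTR / CDS (internal-priming test substrate).
#' @param intergenic_gap gap (nt) between consecutive genes on a chromosome.
#' @param chromosome_length optional fixed chromosome length; genes that do
#'   not fit trigger an explicit placement-overflow error. `NULL` sizes each
#'   chromosome to its content.
#' @param seed integer RNG seed; fully determines all simulator outputs.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' cfg$tissues
#' @export
sim_config <- function(n_genes = 50,
                       gene_length_range = c(2000, 3000),
                       n_chromosomes = 2,
                       pacs_per_gene = c("1" = 0.4, "2" = 0.3, "3" = 0.2, "4" = 0.1),
                       region_mix = c("3UTR" = 0.6, "CDS" = 0.2, "intron" = 0.1, "5UTR" = 0.1),
                       tissues = c("leaf", "root", "flower"),
                       replicates_per_tissue = 3,
                       tags_per_gene = 100,
                       tag_dispersion = 10,
                       expr_sdlog = 1,
                       apa_genes_fraction = 0.3,
                       apa_effect = 0.4,
                       apa_shift_tissue = NULL,
                       apa_target_region = NULL,
                       internal_priming_rate = 0.02,
                       cluster_sd = 1.5,
                       jitter_max = 5,
                       nue_a_freq = 0.8,
                       utr3_overrun_max = 150,
                       a8_utr3_genes = 5,
                       a8_cds_genes = 5,
                       intergenic_gap = 500,
                       chromosome_length = NULL,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.numeric(gene_length_range),
    n_chromosomes = as.integer(n_chromosomes),
    pacs_per_gene = pacs_per_gene,
    region_mix = region_mix,
    tissues = as.character(tissues),
    replicates_per_tissue = as.integer(replicates_per_tissue),
    tags_per_gene = as.numeric(tags_per_gene),
    tag_dispersion = as.numeric(tag_dispersion),
    expr_sdlog = as.numeric(expr_sdlog),
    apa_genes_fraction = as.numeric(apa_genes_fraction),
    apa_effect = as.numeric(apa_effect),
    apa_shift_tissue = apa_shift_tissue,
    apa_target_region = apa_target_region,
    internal_priming_rate = as.numeric(internal_priming_rate),
    cluster_sd = as.numeric(cluster_sd),
    jitter_max = as.integer(jitter_max),
    nue_a_freq = as.numeric(nue_a_freq),
    utr3_overrun_max = as.integer(utr3_overrun_max),
    a8_utr3_genes = as.integer(a8_utr3_genes),
    a8_cds_genes = as.integer(a8_cds_genes),
    intergenic_gap = as.integer(intergenic_gap),
    chromosome_length = chromosome_length,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  if (is.null(cfg$apa_shift_tissue)) {
    cfg$apa_shift_tissue <- cfg$tissues[min(2L, length(cfg$tissues))]
  }
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_chromosomes >= 1,
            length(cfg$gene_length_range) == 2,
            cfg$gene_length_range[1] >= 1500,
            diff(cfg$gene_length_range) >= 0,
            cfg$replicates_per_tissue >= 1,
            length(cfg$tissues) >= 1,
            cfg$tags_per_gene > 0, cfg$tag_dispersion > 0,
            cfg$expr_sdlog >= 0,
            cfg$jitter_max >= 0, cfg$cluster_sd >= 0)
  if (abs(sum(cfg$region_mix) - 1) > 1e-8)
    stop("region_mix must sum to 1")
  if (!setequal(names(cfg$region_mix), c("3UTR", "CDS", "intron", "5UTR")))
    stop("region_mix must be named over 3UTR, CDS, intron, 5UTR")
  if (abs(sum(cfg$pacs_per_gene) - 1) > 1e-8)
    stop("pacs_per_gene must sum to 1")
  if (!setequal(names(cfg$pacs_per_gene), as.character(1:4)))
    stop("pacs_per_gene must be named over 1..4")
  for (fld in c("apa_genes_fraction", "apa_effect", "internal_priming_rate")) {
    v <- cfg[[fld]]
    if (v < 0 || v > 1) stop(fld, " must be in [0,1]")
  }
  if (cfg$nue_a_freq < 0 || cfg$nue_a_freq > 1) stop("nue_a_freq must be in [0,1]")
  if (!is.null(cfg$apa_shift_tissue) && !cfg$apa_shift_tissue %in% cfg$tissues)
    stop("apa_shift_tissue must be one of tissues")
  if (!is.null(cfg$apa_target_region) &&
      !cfg$apa_target_region %in% c("3UTR", "CDS", "intron", "5UTR"))
    stop("apa_target_region must be one of 3UTR, CDS, intron, 5UTR")
  if (anyDuplicated(cfg$tissues)) stop("tissue labels must be unique")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic APA experiment configuration\n")
  cat(sprintf("  %d genes on %d chromosome(s), span %g-%g nt\n",
              x$n_genes, x$n_chromosomes,
              x$gene_length_range[1], x$gene_length_range[2]))
  cat(sprintf("  tissues: %s (x%d replicates), ~%g tags/gene\n",
              paste(x$tissues, collapse = ", "),
              x$replicates_per_tissue, x$tags_per_gene))
  cat(sprintf("  APA: %.0f%% of multi-PAC genes shifted by Delta=%.2f in %s\n",
              100 * x$apa_genes_fraction, x$apa_effect, x$apa_shift_tissue))
  cat(sprintf("  internal priming rate %.3f, cleavage jitter sd %.2g (max %d)\n",
              x$internal_priming_rate, x$cluster_sd, x$jitter_max))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
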