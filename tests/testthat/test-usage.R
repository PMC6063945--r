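make_pacs <- function(df, samples) {
  attr(df, "samples") <- samples
  class(df) <- c("pac_set", "data.frame")
  df
}

test_that("relative usage divides PAC counts by gene totals per sample", {
  pacs <- make_pacs(data.frame(
    pac_id = c("P1", "P2", "P3", "P4"),
    gene_id = c("g1", "g1", "g2", "g2"),
    region = c("3UTR", "CDS", "3UTR", "INTRON"),
    count.s1 = c(30L, 10L, 5L, 15L),
    count.s2 = c(8L, 2L, 0L, 0L),
    retained = TRUE
  ), c("s1", "s2"))
  u <- relative_usage(pacs)
  expect_equal(u$usage.s1, c(0.75, 0.25, 0.25, 0.75))
  # per-gene column sums are 1 where the gene is expressed
  expect_equal(sum(u$usage.s1[u$gene_id == "g1"]), 1)
  # gene absent in a sample: marked-undefined entries
  expect_true(all(is.na(u$usage.s2[u$gene_id == "g2"])))
  # single-PAC genes are excluded
  pacs1 <- make_pacs(data.frame(
    pac_id = "P9", gene_id = "g9", region = "3UTR",
    count.s1 = 50L, count.s2 = 50L, retained = TRUE), c("s1", "s2"))
  expect_equal(nrow(relative_usage(pacs1)), 0)
})

test_that("usage differences subtract group means and aggregate by region", {
  pacs <- make_pacs(data.frame(
    pac_id = c("P1", "P2"), gene_id = "g1", region = c("3UTR", "INTRON"),
    count.a1 = c(80L, 20L), count.a2 = c(79L, 21L),
    count.b1 = c(40L, 60L), count.b2 = c(41L, 59L),
    retained = TRUE
  ), c("a1", "a2", "b1", "b2"))
  u <- relative_usage(pacs)
  d <- usage_differences(u, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d$differences$difference[d$differences$pac_id == "P1"],
               mean(c(0.8, 0.79)) - mean(c(0.4, 0.41)))
  # identical groups: all differences zero
  d0 <- usage_differences(u, c("a1", "a2"), c("a1", "a2"))
  expect_true(all(d0$differences$difference == 0))
  expect_true(all(c("median", "q1", "q3", "n") %in% names(d$by_region)))
})

test_that("a planted intronic shift appears in the per-region aggregation", {
  cfg <- sim_config(n_genes = 60, tissues = c("leaf", "root"),
                    replicates_per_tissue = 3, tags_per_gene = 150,
                    expr_sdlog = 0, apa_genes_fraction = 1, apa_effect = 0.4,
                    apa_target_region = "intron",
                    pacs_per_gene = c("1" = 0.2, "2" = 0.5, "3" = 0.2, "4" = 0.1),
                    internal_priming_rate = 0, seed = 17)
  sim <- simulate_genome(cfg)
  ann <- load_annotation_from_sim(sim)
  tg <- simulate_tags(cfg, sim)
  pas <- build_pas(tg$tags)
  pacs <- assign_regions(cluster_pacs(pas), ann)
  u <- relative_usage(pacs)
  d <- usage_differences(u, paste0("leaf_", 1:3), paste0("root_", 1:3))
  intron_med <- d$by_region$median[d$by_region$region == "INTRON"]
  # the shifted tissue (root) uses the intronic PAC less by Delta = 0.4
  expect_lt(abs(intron_med - cfg$apa_effect), 0.05)
  utr_med <- d$by_region$median[d$by_region$region == "3UTR"]
  expect_lte(utr_med, 0)  # the canonical site gains what introns lose
})

test_that("the poly(A) metric is a metric with the stated fixtures", {
  expect_equal(polya_metric(c(1, 0), c(0, 1)), 1.0)
  expect_equal(polya_metric(c(0.3, 0.7), c(0.3, 0.7)), 0.0)
  expect_equal(polya_metric(c(0.75, 0.25), c(0.25, 0.75)), 0.5)
  expect_true(is.na(polya_metric(c(0, 0), c(1, 0))))  # unexpressed gene
  set.seed(8)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    rnd <- function() { w <- rgamma(k, 1); w / sum(w) }
    a <- rnd(); b <- rnd(); c <- rnd()
    expect_equal(polya_metric(a, a), 0)
    expect_equal(polya_metric(a, b), polya_metric(b, a))
    expect_lte(polya_metric(a, c),
               polya_metric(a, b) + polya_metric(b, c) + 1e-12)
    expect_gte(polya_metric(a, b), 0)
    expect_lte(polya_metric(a, b), 1)
  }
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("the exact test matches the hypergeometric oracle on a clear table", {
  tab <- matrix(c(90, 10, 10, 90), nrow = 2)
  p_fisher <- fisher.test(tab, alternative = "two.sided")$p.value
  # two-sided conditional exact p: sum of hypergeometric point masses
  # not exceeding the observed one
  m <- 100; nn <- 100; kk <- 100
  dens <- dhyper(0:100, m, nn, kk)
  p_oracle <- sum(dens[dens <= dhyper(90, m, nn, kk) * (1 + 1e-7)])
  expect_equal(p_fisher, p_oracle, tolerance = 1e-6)
  expect_lt(p_fisher, 1e-15)

  pacs <- make_pacs(data.frame(
    pac_id = c("P1", "P2"), gene_id = "g1", region = "3UTR",
    count.a1 = c(45L, 5L), count.a2 = c(45L, 5L),
    count.b1 = c(5L, 45L), count.b2 = c(5L, 45L),
    retained = TRUE
  ), c("a1", "a2", "b1", "b2"))
  res <- differential_usage(pacs, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_true(all(res$results$significant))
  expect_equal(res$results$p_value[1], p_fisher, tolerance = 1e-6)
})

test_that("differential usage controls type I error on identical groups", {
  # six replicates of one tissue, labels permuted into two pseudo-groups
  cfg <- sim_config(n_genes = 80, tissues = "leaf", replicates_per_tissue = 6,
                    tags_per_gene = 200, expr_sdlog = 0, apa_genes_fraction = 0,
                    internal_priming_rate = 0, seed = 23)
  sim <- simulate_genome(cfg)
  tg <- simulate_tags(cfg, sim)
  ann <- load_annotation_from_sim(sim)
  pacs <- assign_regions(cluster_pacs(build_pas(tg$tags)), ann)
  groups <- list(A = paste0("leaf_", c(1, 3, 5)), B = paste0("leaf_", c(2, 4, 6)))
  res <- differential_usage(pacs, groups)
  n_tested <- res$summary$n_tested
  expect_gt(n_tested, 30)
  expect_lte(res$summary$n_significant_pacs / n_tested, 0.05)
  expect_error(differential_usage(pacs, list(A = "leaf_1", B = paste0("leaf_", 2:3))),
               "fewer than 2")
})

test_that("power and APA-gene tallies behave under a planted shift", {
  cfg <- sim_config(n_genes = 60, tissues = c("A", "B"),
                    replicates_per_tissue = 3, tags_per_gene = 200,
                    pacs_per_gene = c("1" = 0.2, "2" = 0.5, "3" = 0.2, "4" = 0.1),
                    expr_sdlog = 0, apa_genes_fraction = 1, apa_effect = 0.4,
                    internal_priming_rate = 0, seed = 29)
  sim <- simulate_genome(cfg)
  tg <- simulate_tags(cfg, sim)
  ann <- load_annotation_from_sim(sim)
  pacs <- assign_regions(cluster_pacs(build_pas(tg$tags)), ann)
  res <- differential_usage(pacs, list(A = paste0("A_", 1:3), B = paste0("B_", 1:3)))
  # planted shifted clusters: rank-2 site of every APA gene
  tr <- sim$truth$sites
  targets <- tr[tr$rank == 2 & tr$gene_id %in%
                  sim$truth$genes$gene_id[sim$truth$genes$apa], ]
  sig <- res$results[res$results$significant, ]
  found <- vapply(seq_len(nrow(targets)), function(i) {
    any(sig$pac_id %in% pacs$pac_id[
      pacs$chrom == targets$chrom[i] & pacs$strand == targets$strand[i] &
        abs(pacs$representative - targets$pos[i]) <= 12])
  }, logical(1))
  expect_gte(mean(found), 0.9)
  # consistency: genes-displaying-APA = distinct genes over significant PACs
  expect_equal(res$summary$n_significant_genes,
               length(unique(res$results$gene_id[res$results$significant])))
  # sharing breakdown covers all significant PACs once each
  expect_equal(sum(res$sharing), length(unique(sig$pac_id)))
})

test_that("detection power is monotone in the planted effect size", {
  power_at <- function(delta, seed) {
    cfg <- sim_config(n_genes = 40, tissues = c("A", "B"),
                      replicates_per_tissue = 3, tags_per_gene = 120,
                      pacs_per_gene = c("1" = 0, "2" = 1, "3" = 0, "4" = 0),
                      expr_sdlog = 0, apa_genes_fraction = 1, apa_effect = delta,
                      internal_priming_rate = 0, seed = seed)
    sim <- simulate_genome(cfg)
    tg <- simulate_tags(cfg, sim)
    ann <- load_annotation_from_sim(sim)
    pacs <- assign_regions(cluster_pacs(build_pas(tg$tags)), ann)
    res <- differential_usage(pacs, list(A = paste0("A_", 1:3),
                                         B = paste0("B_", 1:3)))
    res$summary$n_significant_genes / cfg$n_genes
  }
  p <- vapply(c(0.1, 0.25, 0.4), power_at, numeric(1), seed = 37)
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], 0.8)
})
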