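test_that("internal-priming flagging follows the A8 downstream rule", {
  # chrT: tag at 20 followed by A8 at 21..28; tag at 60 followed by A7+C
  s <- paste0(strrep("C", 20), strrep("A", 8), strrep("C", 31),
              "C", strrep("A", 7), "C", strrep("C", 40))
  ann <- seq_only_annotation(c(chrT = s))
  tags <- data.frame(chrom = "chrT", pos = c(20L, 60L), strand = "+",
                     sample = "s1", stringsAsFactors = FALSE)
  res <- flag_internal_priming(tags, ann)
  expect_equal(res$flagged$pos, 20L)
  expect_equal(res$kept$pos, 60L)

  # a tag inside the run is flagged too; minus-strand tags see sense T-runs
  tags2 <- data.frame(chrom = "chrT", pos = 24L, strand = "+", sample = "s1")
  expect_equal(flag_internal_priming(tags2, ann)$n_flagged, 1L)
  sm <- paste0(strrep("G", 20), strrep("T", 8), strrep("G", 30))
  annm <- seq_only_annotation(c(chrM = sm))
  tagm <- data.frame(chrom = "chrM", pos = 29L, strand = "-", sample = "s1")
  expect_equal(flag_internal_priming(tagm, annm)$n_flagged, 1L)
  tagm_plus <- data.frame(chrom = "chrM", pos = 29L, strand = "+", sample = "s1")
  expect_equal(flag_internal_priming(tagm_plus, annm)$n_flagged, 0L)
})

test_that("planted internal-priming artifacts are flagged with few false flags", {
  ms <- mid_sim()
  res <- flag_internal_priming(ms$tags$tags, ms$ann)
  ip <- ms$tags$map$ip
  key <- function(df) paste(df$chrom, df$pos, df$strand, df$sample)
  flagged_keys <- key(res$flagged)
  all_keys <- key(ms$tags$tags)
  is_flagged <- all_keys %in% flagged_keys
  expect_gte(mean(is_flagged[ip]), 0.95)     # planted artifacts caught
  expect_lte(mean(is_flagged[!ip]), 0.01)    # true tags rarely flagged
})

test_that("PAS construction aggregates counts and applies the >=8 filter", {
  tags <- data.frame(
    chrom = "chr1",
    pos = c(rep(100L, 10), rep(300L, 7), 500L, 500L),
    strand = c(rep("+", 17), "+", "-"),
    sample = rep(c("a", "b", "c"), length.out = 19),
    stringsAsFactors = FALSE
  )
  pas <- build_pas(tags, min_tags = 8)
  expect_equal(nrow(pas), 4)                        # opposite strands distinct
  p100 <- pas[pas$pos == 100, ]
  expect_equal(p100$total, 10L)
  expect_true(p100$retained)
  expect_equal(sum(p100[, paste0("count.", c("a", "b", "c"))]), 10)
  expect_false(pas$retained[pas$pos == 300])        # 7 tags: pre-filter only
  expect_equal(sum(pas$total), nrow(tags))          # conservation
})

test_that("the worked clustering fixture yields one retained PAC", {
  tags <- data.frame(
    chrom = "chr1",
    pos = c(rep(100L, 10), rep(110L, 15), rep(140L, 8)),
    strand = "+", sample = "s1", stringsAsFactors = FALSE
  )
  pas <- build_pas(tags, min_tags = 8)
  pacs <- cluster_pacs(pas, max_gap = 24, min_pac_tags = 20)
  expect_equal(nrow(pacs), 2)                       # {100,110} and {140}
  kept <- pacs[pacs$retained, ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$total, 25L)
  expect_equal(kept$representative, 110L)
  expect_equal(kept$start, 100L)
  expect_equal(kept$end, 110L)
})

test_that("single-linkage chaining spans beyond the gap threshold", {
  tags <- data.frame(chrom = "chr1",
                     pos = rep(c(100L, 120L, 140L), each = 8),
                     strand = "+", sample = "s1")
  pacs <- cluster_pacs(build_pas(tags), max_gap = 24, min_pac_tags = 20)
  expect_equal(nrow(pacs), 1)
  expect_equal(pacs$end - pacs$start, 40L)          # span > 24 via chaining
  # representative tie-break is 3'-most, strand-aware
  tags_m <- transform(tags, strand = "-")
  pacs_m <- cluster_pacs(build_pas(tags_m), max_gap = 24, min_pac_tags = 20)
  expect_equal(pacs$representative, 140L)
  expect_equal(pacs_m$representative, 100L)
})

test_that("clustering matches the brute-force transitive-closure oracle", {
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    pos <- sort(sample(1:300, n))
    tags <- data.frame(chrom = "chr1", pos = rep(pos, each = 1),
                       strand = "+", sample = "s1")
    pas <- build_pas(tags, min_tags = 1)
    pacs <- cluster_pacs(pas, max_gap = 24, min_pac_tags = 1)
    got <- rep(seq_len(nrow(pacs)),
               vapply(strsplit(pacs$members, ","), length, integer(1)))
    want <- oracle_cluster(pos, 24)
    expect_equal(got, want)
  }
})

test_that("clustering is invariant to input order and gaps stay <= 24", {
  ms <- small_sim()
  res <- flag_internal_priming(ms$tags$tags, ms$ann)
  pas <- build_pas(res$kept)
  set.seed(5)
  shuffled <- res$kept[sample(nrow(res$kept)), ]
  pas2 <- build_pas(shuffled)
  pacs <- cluster_pacs(pas)
  pacs2 <- cluster_pacs(pas2)
  expect_equal(pacs, pacs2, ignore_attr = TRUE)
  # member gaps <= 24 within each PAC; merging adjacent same-strand PACs
  # would always violate the gap rule
  for (i in seq_len(nrow(pacs))) {
    mem <- as.integer(strsplit(pacs$members[i], ",")[[1]])
    if (length(mem) > 1) expect_lte(max(diff(mem)), 24)
  }
  by_grp <- split(pacs, paste(pacs$chrom, pacs$strand))
  for (grp in by_grp) {
    if (nrow(grp) < 2) next
    grp <- grp[order(grp$start), ]
    expect_true(all(grp$start[-1] - grp$end[-nrow(grp)] > 24))
  }
})

test_that("tag accounting balances exactly end to end", {
  ms <- small_sim()
  res <- flag_internal_priming(ms$tags$tags, ms$ann)
  pas <- build_pas(res$kept)
  pacs <- cluster_pacs(pas)
  acct <- tag_accounting(nrow(ms$tags$tags), res$n_flagged, pas, pacs)
  expect_true(acct$balanced)
  expect_equal(acct$n_input,
               acct$n_flagged + acct$n_subthreshold_pas +
                 acct$n_discarded_pac + acct$n_retained_pac)
})

test_that("PAC overlap counting matches an all-pairs oracle", {
  mk_pacs <- function(df) {
    df$pac_id <- sprintf("P%03d", seq_len(nrow(df)))
    class(df) <- c("pac_set", "data.frame")
    df
  }
  a <- mk_pacs(data.frame(chrom = "chr1", strand = "+",
                          start = c(10L, 100L), end = c(20L, 120L)))
  expect_equal(overlap_pacs(a, a)$n_a_overlapping, 2)  # identical sets
  b <- mk_pacs(data.frame(chrom = "chr2", strand = "+",
                          start = c(10L, 100L), end = c(20L, 120L)))
  expect_equal(overlap_pacs(a, b)$n_a_overlapping, 0)  # disjoint chromosomes

  set.seed(99)
  for (i in 1:25) {
    na <- sample(1:15, 1); nb <- sample(1:15, 1)
    rnd <- function(n) {
      s <- sample(1:200, n, replace = TRUE)
      mk_pacs(data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                         strand = sample(c("+", "-"), n, TRUE),
                         start = s, end = s + sample(5:30, n, TRUE)))
    }
    A <- rnd(na); B <- rnd(nb)
    got <- overlap_pacs(A, B)
    want <- 0L
    for (x in seq_len(na)) {
      hit <- any(A$chrom[x] == B$chrom & A$strand[x] == B$strand &
                   A$start[x] <= B$end & B$start <= A$end[x])
      want <- want + hit
    }
    expect_equal(got$n_a_overlapping, want)
  }
})
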