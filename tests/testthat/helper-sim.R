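# Shared simulation fixtures, built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small default-style experiment used by several files
small_sim <- function() cached("small", {
  cfg <- sim_config(n_genes = 30, seed = 42)
  sim <- simulate_genome(cfg)
  list(cfg = cfg, sim = sim,
       ann = load_annotation_from_sim(sim),
       tags = simulate_tags(cfg, sim))
})

# mid-size two-tissue experiment with internal priming for recovery tests
mid_sim <- function() cached("mid", {
  cfg <- sim_config(n_genes = 150, tissues = c("leaf", "root"),
                    replicates_per_tissue = 2, tags_per_gene = 80,
                    internal_priming_rate = 0.05, seed = 7)
  sim <- simulate_genome(cfg)
  list(cfg = cfg, sim = sim,
       ann = load_annotation_from_sim(sim),
       tags = simulate_tags(cfg, sim))
})

# large single-tissue experiment for motif-recovery tests (>= 1000 3'UTR sites)
motif_sim <- function() cached("motif", {
  cfg <- sim_config(n_genes = 700, tissues = "leaf",
                    replicates_per_tissue = 3, tags_per_gene = 60,
                    expr_sdlog = 0, apa_genes_fraction = 0, seed = 101)
  sim <- simulate_genome(cfg)
  ann <- load_annotation_from_sim(sim)
  tg <- simulate_tags(cfg, sim)
  ipf <- flag_internal_priming(tg$tags, ann)
  pas <- build_pas(ipf$kept)
  list(cfg = cfg, sim = sim, ann = ann, tags = tg, pas = pas)
})

# minimal GenomeAnnotation wrapper around a raw sequence, for sequence-level
# operations that need no gene models
seq_only_annotation <- function(seqs) {
  genome <- Biostrings::DNAStringSet(seqs)
  structure(list(genome = genome,
                 chrom_len = stats::setNames(Biostrings::width(genome),
                                             names(genome))),
            class = "GenomeAnnotation")
}

# write a GFF3 file from inline rows; each row is
# list(seqid, type, start, end, strand, id, parent)
write_mini_gff <- function(rows, path = tempfile(fileext = ".gff3")) {
  df <- do.call(rbind, lapply(rows, function(r) {
    attrs <- if (is.na(r$parent)) sprintf("ID=%s", r$id) else
      sprintf("ID=%s;Parent=%s", r$id, r$parent)
    data.frame(seqid = r$seqid, source = "test", type = r$type,
               start = r$start, end = r$end, score = ".", strand = r$strand,
               phase = ".", attributes = attrs, stringsAsFactors = FALSE)
  }))
  write_gff3(df, path)
  path
}

# single-gene single-exon model: gene/mRNA/exon spanning [start,end] with
# 5'UTR, CDS and 3'UTR given as sense-ordered sub-intervals
mini_gene_rows <- function(seqid, strand, gene_start, gene_end,
                           utr5, cds, utr3, gid = "gx") {
  mid <- paste0(gid, ".m1")
  list(
    list(seqid = seqid, type = "gene", start = gene_start, end = gene_end,
         strand = strand, id = gid, parent = NA),
    list(seqid = seqid, type = "mRNA", start = gene_start, end = gene_end,
         strand = strand, id = mid, parent = gid),
    list(seqid = seqid, type = "exon", start = gene_start, end = gene_end,
         strand = strand, id = paste0(mid, ".e1"), parent = mid),
    list(seqid = seqid, type = "five_prime_UTR", start = utr5[1], end = utr5[2],
         strand = strand, id = paste0(mid, ".u5"), parent = mid),
    list(seqid = seqid, type = "CDS", start = cds[1], end = cds[2],
         strand = strand, id = paste0(mid, ".c1"), parent = mid),
    list(seqid = seqid, type = "three_prime_UTR", start = utr3[1], end = utr3[2],
         strand = strand, id = paste0(mid, ".u3"), parent = mid)
  )
}

uniform_genome <- function(len = 3000, chrom = "chr1", seed = 5) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  Biostrings::DNAStringSet(stats::setNames(s, chrom))
}

# brute-force transitive-closure partition over the "within max_gap" relation
oracle_cluster <- function(pos, max_gap = 24L) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 0) return(integer(0))
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# brute-force Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# brute-force rank-mean quantile normalization with mean-of-rank-range ties
oracle_quantile_normalize <- function(m) {
  means <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    for (i in seq_along(x)) {
      rmin <- sum(x < x[i]) + 1L
      rmax <- sum(x <= x[i])
      out[i, j] <- mean(means[rmin:rmax])
    }
  }
  out
}
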