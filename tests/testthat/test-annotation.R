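test_that("3'UTR extension follows strand and truncates at boundaries", {
  genome <- uniform_genome(3000)
  # + strand gene: 3'UTR 1001..1200 -> extension 1201..1400
  gff <- write_mini_gff(mini_gene_rows("chr1", "+", 501, 1200,
                                       utr5 = c(501, 600), cds = c(601, 1000),
                                       utr3 = c(1001, 1200)))
  ann <- load_annotation(gff, genome)
  ext <- ann$regions[ann$regions$part == "extension"]
  expect_equal(GenomicRanges::start(ext), 1201)
  expect_equal(GenomicRanges::end(ext), 1400)
  expect_equal(ext$region, "3UTR")

  # - strand gene: 3'UTR 501..700 -> extension 301..500
  gffm <- write_mini_gff(mini_gene_rows("chr1", "-", 501, 1200,
                                        utr5 = c(1101, 1200), cds = c(701, 1100),
                                        utr3 = c(501, 700)))
  annm <- load_annotation(gffm, genome)
  extm <- annm$regions[annm$regions$part == "extension"]
  expect_equal(GenomicRanges::start(extm), 301)
  expect_equal(GenomicRanges::end(extm), 500)

  # 3'UTR ending 50 nt from the chromosome end: extension truncated there
  gfft <- write_mini_gff(mini_gene_rows("chr1", "+", 2401, 2950,
                                        utr5 = c(2401, 2500), cds = c(2501, 2800),
                                        utr3 = c(2801, 2950)))
  annt <- load_annotation(gfft, genome)
  extt <- annt$regions[annt$regions$part == "extension"]
  expect_equal(GenomicRanges::start(extt), 2951)
  expect_equal(GenomicRanges::end(extt), 3000)

  # extension stops at a downstream same-strand gene
  rows2 <- c(mini_gene_rows("chr1", "+", 501, 1200,
                            utr5 = c(501, 600), cds = c(601, 1000),
                            utr3 = c(1001, 1200), gid = "ga"),
             mini_gene_rows("chr1", "+", 1301, 2000,
                            utr5 = c(1301, 1400), cds = c(1401, 1800),
                            utr3 = c(1801, 2000), gid = "gb"))
  ann2 <- load_annotation(write_mini_gff(rows2), genome)
  exta <- ann2$regions[ann2$regions$part == "extension" &
                         ann2$regions$gene_id == "ga"]
  expect_equal(GenomicRanges::end(exta), 1300)
})

test_that("missing chromosomes and malformed parentage are explicit errors", {
  genome <- uniform_genome(3000)
  gff <- write_mini_gff(mini_gene_rows("chr9", "+", 501, 1200,
                                       utr5 = c(501, 600), cds = c(601, 1000),
                                       utr3 = c(1001, 1200)))
  expect_error(load_annotation(gff, genome), "chr9")
  rows <- mini_gene_rows("chr1", "+", 501, 1200,
                         utr5 = c(501, 600), cds = c(601, 1000),
                         utr3 = c(1001, 1200))
  rows[[2]]$parent <- "nosuchgene"
  expect_error(load_annotation(write_mini_gff(rows), genome), "gx.m1")
})

test_that("fetch_window returns the sense-strand window with the site at +1", {
  genome <- uniform_genome(3000)
  gff <- write_mini_gff(mini_gene_rows("chr1", "+", 501, 1200,
                                       utr5 = c(501, 600), cds = c(601, 1000),
                                       utr3 = c(1001, 1200)))
  ann <- load_annotation(gff, genome)
  w <- fetch_window(ann, "chr1", "+", 1500, flank = 100)
  expect_equal(nchar(w), 201)
  expect_equal(substr(w, 101, 101),
               as.character(Biostrings::subseq(genome[[1]], 1500, 1500)))
  # minus-strand window is the reverse complement of the mirrored plus fetch
  wm <- fetch_window(ann, "chr1", "-", 1500, flank = 100)
  expect_equal(wm, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(w))))
  # windows running off the chromosome give the short-window signal
  expect_true(is.na(fetch_window(ann, "chr1", "+", 50, flank = 100)))
  expect_true(is.na(fetch_window(ann, "chr1", "+", 2990, flank = 100)))
  # position labels skip 0 and put the cleavage base at +1
  lab <- patseqr:::window_positions(100)
  expect_equal(length(lab), 201)
  expect_false(0 %in% lab)
  expect_equal(lab[101], 1)
  expect_equal(lab[81], -20)
})

test_that("annotated regions tile each transcript span without overlap", {
  ann <- small_sim()$ann
  for (gid in ann$genes$gene_id[1:10]) {
    reg <- ann$regions[ann$regions$gene_id == gid &
                         ann$regions$part == "annotated"]
    red <- GenomicRanges::reduce(reg, ignore.strand = TRUE)
    g <- ann$genes[ann$genes$gene_id == gid, ]
    expect_equal(sum(GenomicRanges::width(red)), g$end - g$start + 1)
    expect_equal(sum(GenomicRanges::width(reg)), sum(GenomicRanges::width(red)))
  }
})

test_that("extension sweep saturates at the planted overrun distance", {
  # primary sites up to 150 nt past the annotated 3'UTR end: counts level
  # off from 200 nt on, so 200 is chosen
  ss <- small_sim()
  dir <- file.path(tempdir(), "sweep1")
  write_simulation(ss$sim, dir)
  sw <- extension_sweep(ss$tags$tags, file.path(dir, "annotation.gff3"),
                        file.path(dir, "genome.fa"))
  expect_equal(sw$chosen, 200)
  expect_true(all(diff(sw$table$assigned) >= 0))  # monotone in extension
  expect_equal(sw$table$assigned[2], sw$table$assigned[3])
  expect_equal(sw$table$assigned[3], sw$table$assigned[4])

  # all sites inside annotated UTRs: saturation at the first step
  cfg0 <- sim_config(n_genes = 15, utr3_overrun_max = 0,
                     internal_priming_rate = 0, seed = 9)
  sim0 <- simulate_genome(cfg0)
  tg0 <- simulate_tags(cfg0, sim0)
  dir0 <- file.path(tempdir(), "sweep0")
  write_simulation(sim0, dir0)
  sw0 <- extension_sweep(tg0$tags, file.path(dir0, "annotation.gff3"),
                         file.path(dir0, "genome.fa"))
  expect_equal(sw0$chosen, 100)
  expect_error(extension_sweep(ss$tags$tags[0, ], file.path(dir, "annotation.gff3"),
                               file.path(dir, "genome.fa")), "empty")
})
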