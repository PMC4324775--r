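mk_read <- function(id, ...) {
  b <- rbind(...)
  tibble::tibble(read_id = id, chrom = "chr1",
                 blocks = list(cbind(start = as.integer(b[, 1]),
                                     end = as.integer(b[, 2]))),
                 source = "mate")
}

test_that("TAR detection applies both thresholds on maximal runs", {
  cov <- mk_coverage(1000, list(c(101, 140, 5),    # 40 bp at depth 5: TAR
                                c(301, 335, 100),  # 35 bp: not longer than 35
                                c(501, 560, 4)))   # 60 bp at the depth floor
  tars <- detect_tars(cov)
  expect_equal(tars$start, c(101L, 501L))
  expect_equal(tars$end, c(140L, 560L))
  # an interior dip splits the run and both halves are re-tested
  cov2 <- mk_coverage(1000, list(c(101, 180, 4)))
  cov2$chr1[140] <- 3L
  t2 <- detect_tars(cov2)
  expect_equal(nrow(t2), 2)
  expect_equal(t2$start, c(101L, 141L))
  # maximality: extending any TAR by one base violates a threshold
  for (i in seq_len(nrow(tars))) {
    lo <- tars$start[i] - 1L; hi <- tars$end[i] + 1L
    expect_true(as.integer(cov$chr1[lo]) < 4 || as.integer(cov$chr1[hi]) < 4)
  }
})

test_that("transcript units require a pair bridge and pass the size gates", {
  cov <- mk_coverage(2000, list(c(101, 200, 20), c(401, 500, 20),
                                c(801, 900, 20)))
  tars <- detect_tars(cov)
  expect_equal(nrow(tars), 3)
  bridge <- tibble::tibble(
    pair_id = "b1", sample = "s1", chrom = "chr1", strand = "+",
    blocks1 = list(cbind(start = 150L, end = 190L)),
    blocks2 = list(cbind(start = 420L, end = 470L)),
    ori1 = "+", ori2 = "+", interval_length = 229L)
  units <- link_units(tars, bridge, cov)
  # tar1+tar2 bridged (200 bp total); tar3 alone is 100 bp and fails > 150
  expect_equal(nrow(units), 1)
  expect_equal(units$n_tars, 2L)
  expect_equal(units$length, 200L)

  # total length of exactly 150 fails ("longer than 150 bp")
  cov150 <- mk_coverage(1000, list(c(101, 250, 20)))
  t150 <- detect_tars(cov150)
  expect_equal(sum(t150$width), 150)
  expect_equal(nrow(link_units(t150, bridge[0, ], cov150)), 0)
  cov151 <- mk_coverage(1000, list(c(101, 251, 20)))
  expect_equal(nrow(link_units(detect_tars(cov151), bridge[0, ], cov151)), 1)

  # mean depth below 10 fails
  cov9 <- mk_coverage(1000, list(c(101, 300, 9)))
  expect_equal(nrow(link_units(detect_tars(cov9), bridge[0, ], cov9)), 0)
})

test_that("artificial reads follow the interval and junction rules", {
  sjs <- mk_sj("chr1", 100, 159)   # one 60 bp junction
  mk_pr <- function(id, b1, b2) tibble::tibble(
    pair_id = id, sample = "s1", chrom = "chr1", strand = "+",
    blocks1 = list(cbind(start = b1[1], end = b1[2])),
    blocks2 = list(cbind(start = b2[1], end = b2[2])),
    ori1 = "+", ori2 = "+",
    interval_length = b2[1] - b1[2] - 1L)
  # overlapping mates merge into one read of length sum - overlap
  r1 <- make_artificial_reads(mk_pr("m", c(1, 75), c(66, 140)), sjs)
  expect_equal(r1$blocks[[1]], cbind(start = 1L, end = 140L))
  expect_equal(sum(r1$blocks[[1]][, 2] - r1$blocks[[1]][, 1] + 1), 150 - 10)

  # no junction in the interval: gap filled as exonic
  r2 <- make_artificial_reads(mk_pr("f", c(200, 274), c(350, 424)), sjs)
  expect_equal(r2$blocks[[1]], cbind(start = 200L, end = 424L))

  # one junction inside, interval - junction length = 120 - 60 < 85: embed
  r3 <- make_artificial_reads(mk_pr("j", c(1, 75), c(196, 270)), sjs)
  expect_equal(r3$blocks[[1]],
               cbind(start = c(1L, 160L), end = c(99L, 270L)))

  # remainder >= 85: no artificial read, mates pass through
  sj100 <- mk_sj("chr1", 101, 200)  # 100 bp junction
  r4 <- make_artificial_reads(mk_pr("n", c(1, 75), c(276, 350)), sj100)
  expect_equal(nrow(r4), 2)
  expect_setequal(r4$source, "mate")
})

test_that("assembly chains compatible reads and enforces support rules", {
  # two reads overlapping by 20 bp, each duplicated: depth >= 2 everywhere
  reads <- dplyr::bind_rows(
    mk_read("a1", c(1, 75)), mk_read("a2", c(1, 75)),
    mk_read("b1", c(56, 130)), mk_read("b2", c(56, 130)))
  m <- assemble_models(reads)
  expect_equal(nrow(m), 1)
  expect_equal(m$blocks[[1]], cbind(start = 1L, end = 130L))
  expect_equal(m$length, 130L)

  # covered length 99 is dropped, 100 kept
  r99 <- dplyr::bind_rows(mk_read("c1", c(1, 99)), mk_read("c2", c(1, 99)))
  expect_equal(nrow(assemble_models(r99)), 0)
  r100 <- dplyr::bind_rows(mk_read("d1", c(1, 100)), mk_read("d2", c(1, 100)))
  expect_equal(nrow(assemble_models(r100)), 1)

  # any base under 2 reads kills the model
  rlow <- dplyr::bind_rows(mk_read("e1", c(1, 120)), mk_read("e2", c(1, 119)))
  expect_equal(nrow(assemble_models(rlow)), 0)

  # contradictory junction content blocks chaining (no chimeras): the
  # lone unspliced read cannot join the spliced contig, so it fails the
  # per-base support rule alone instead of poisoning the spliced model
  spliced <- dplyr::bind_rows(
    mk_read("s1", c(1, 60), c(121, 180)), mk_read("s2", c(1, 60), c(121, 180)),
    mk_read("u1", c(41, 160)))
  ms <- assemble_models(spliced)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$blocks[[1]],
               cbind(start = c(1L, 121L), end = c(60L, 180L)))

  # loci at distance 10 link, at 11 they stay apart
  near <- dplyr::bind_rows(
    mk_read("f1", c(1, 120)), mk_read("f2", c(1, 120)),
    mk_read("g1", c(131, 250)), mk_read("g2", c(131, 250)))
  expect_equal(nrow(assemble_models(near)), 1)
  far <- dplyr::bind_rows(
    mk_read("f1", c(1, 120)), mk_read("f2", c(1, 120)),
    mk_read("g1", c(132, 250)), mk_read("g2", c(132, 250)))
  expect_equal(nrow(assemble_models(far)), 2)
})

test_that("ORF finding matches the documented boundary cases", {
  # 33 aa: ATG + 96 coding nt + TAA. GCT repeats carry no start or stop
  # codon in any frame on either strand, so the planted ORF is the only one.
  mid <- strrep("GCT", 32)
  orf33 <- paste0("ATG", mid, "TAA")
  pad <- "CCCCC"
  g <- toy_genome(paste0(pad, orf33, pad))
  m <- tibble::tibble(model_id = "m1", chrom = "chr1",
                      blocks = list(cbind(start = 1L,
                                          end = nchar(orf33) + 10L)),
                      length = nchar(orf33) + 10L, n_reads = 2L,
                      span_start = 1L, span_end = nchar(orf33) + 10L)
  r <- find_longest_orf(m, g)
  expect_equal(r$cds_aa, 33L)
  expect_true(r$cds_complete)
  expect_true(r$coding)      # > 30 aa
  expect_equal(nchar(r$protein), 33L)
  expect_equal(substr(r$protein, 1, 1), "M")

  # exactly 30 aa is not coding ("> 30 aa")
  orf30 <- paste0("ATG", strrep("GCT", 29), "TAA")
  g30 <- toy_genome(paste0(pad, orf30, pad))
  m30 <- m
  m30$blocks <- list(cbind(start = 1L, end = nchar(orf30) + 10L))
  r30 <- find_longest_orf(m30, g30)
  expect_equal(r30$cds_aa, 30L)
  expect_false(r30$coding)

  # ORF missing its stop codon is partial
  open_end <- paste0(pad, "ATG", mid)
  gopen <- toy_genome(open_end)
  mo <- m
  mo$blocks <- list(cbind(start = 6L, end = nchar(open_end)))
  ro <- find_longest_orf(mo, gopen)
  expect_false(ro$cds_complete)
  expect_gt(ro$cds_aa, 30)
})

test_that("a junction-fixed strand restricts the frame scan", {
  # long ORF on the minus strand only; a plus-strand junction in the model
  orf <- paste0("ATG", strrep("GCT", 40), "TAA")
  minus_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(orf)))
  g <- toy_genome(paste0(minus_seq, strrep("C", 100), minus_seq))
  b <- cbind(start = c(1L, nchar(minus_seq) + 101L),
             end = c(nchar(minus_seq), 2L * nchar(minus_seq) + 100L))
  m <- tibble::tibble(model_id = "m1", chrom = "chr1", blocks = list(b),
                      length = 2L * nchar(minus_seq), n_reads = 2L,
                      span_start = 1L, span_end = max(b))
  free <- find_longest_orf(m, g)
  expect_equal(free$cds_strand, "-")
  expect_gt(free$cds_aa, 40)
  sj <- mk_sj("chr1", nchar(minus_seq) + 1L, nchar(minus_seq) + 100L,
              strand = "+")
  fixed <- find_longest_orf(m, g, sjs = sj)
  expect_equal(fixed$cds_strand, "+")
  expect_lt(fixed$cds_aa, free$cds_aa)
})

test_that("ORF finding agrees with a six-frame translation oracle", {
  set.seed(62)
  for (k in 1:300) {
    L <- sample(30:240, 1)
    nt <- random_intron(L, prob = c(.3, .2, .2, .3))
    g <- toy_genome(nt)
    m <- tibble::tibble(model_id = "m", chrom = "chr1",
                        blocks = list(cbind(start = 1L, end = L)),
                        length = L, n_reads = 2L, span_start = 1L,
                        span_end = L)
    got <- find_longest_orf(m, g)
    exp <- oracle_orf(nt)
    expect_equal(got$cds_aa, exp$aa, info = nt)
    if (exp$aa > 0) expect_equal(got$cds_complete, exp$complete, info = nt)
  }
})

test_that("reference screening uses the stated overlap bounds", {
  models <- tibble::tibble(
    model_id = c("m1", "m2", "m3"), chrom = "chr1",
    blocks = list(cbind(1L, 200L), cbind(300L, 500L), cbind(700L, 900L)),
    length = c(200L, 201L, 201L), n_reads = 2L,
    span_start = c(1L, 300L, 700L), span_end = c(200L, 500L, 900L))
  reference <- tibble::tibble(chrom = "chr1",
                              start = c(190L, 491L), end = c(250L, 600L))
  # m1 overlaps by 11 (dropped), m2 by exactly 10 (retained)
  kept <- screen_against_reference(models, reference)
  expect_setequal(kept$model_id, c("m2", "m3"))
  # structural RNA overlap of even 1 base drops the model
  trna <- tibble::tibble(chrom = "chr1", start = 900L, end = 950L)
  kept2 <- screen_against_reference(models, reference, trna)
  expect_setequal(kept2$model_id, "m2")
})

test_that("planted genes are covered by transcript units on synthetic data", {
  lib <- small_dataset()
  pooled <- Reduce(`+`, lib$sq$coverage)
  tars <- detect_tars(pooled)
  # bridge TARs with synthetic pairs spanning each gene (depth 50 exons)
  sim <- lib$sim
  bridges <- tibble::tibble(
    pair_id = sim$genes$gene_id, sample = "s1", chrom = sim$genes$chrom,
    strand = sim$genes$strand,
    blocks1 = lapply(seq_len(nrow(sim$genes)), function(i) {
      cbind(start = sim$genes$start[i], end = sim$genes$start[i] + 20L)
    }),
    blocks2 = lapply(seq_len(nrow(sim$genes)), function(i) {
      cbind(start = sim$genes$end[i] - 20L, end = sim$genes$end[i])
    }),
    ori1 = "+", ori2 = "+", interval_length = 0L)
  units <- link_units(tars, bridges, pooled)
  ug <- GenomicRanges::GRanges(units$chrom,
                               IRanges::IRanges(units$span_start,
                                                units$span_end))
  exg <- GenomicRanges::GRanges(sim$exons$chrom,
                                IRanges::IRanges(sim$exons$start,
                                                 sim$exons$end))
  cov_frac <- sum(IRanges::width(GenomicRanges::intersect(ug, exg))) /
    sum(IRanges::width(GenomicRanges::reduce(exg)))
  expect_gte(cov_frac, 0.9)
})
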