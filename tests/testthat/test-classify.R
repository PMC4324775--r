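test_that("clustering follows the one-base overlap rule", {
  sjs <- dplyr::bind_rows(
    mk_sj("chr1", 100, 200, id = "a"),
    mk_sj("chr1", 150, 250, id = "b"),
    mk_sj("chr1", 251, 300, id = "c"),
    mk_sj("chr2", 100, 200, id = "d"))
  cl <- cluster_junctions(sjs)
  ids <- cl$junctions$cluster_id
  names(ids) <- cl$junctions$sj_id
  expect_equal(ids[["a"]], ids[["b"]])       # share bases
  expect_false(ids[["b"]] == ids[["c"]])     # adjacent, no shared base
  expect_false(ids[["a"]] == ids[["d"]])     # different chromosome
  expect_equal(cl$n_mixed_strand_excluded, 0L)

  # mixed-strand component is dropped and tallied
  sjs2 <- dplyr::bind_rows(
    mk_sj("chr1", 100, 200, strand = "+"),
    mk_sj("chr1", 150, 250, strand = "-"))
  cl2 <- cluster_junctions(sjs2)
  expect_equal(nrow(cl2$junctions), 0)
  expect_equal(cl2$n_mixed_strand_excluded, 1L)
})

test_that("pairwise classification matches the coordinate definitions", {
  p <- function(s1, e1, s2, e2, st = "+") {
    classify_pair(mk_sj("chr1", s1, e1, strand = st),
                  mk_sj("chr1", s2, e2, strand = st))
  }
  expect_equal(p(100, 200, 150, 200), "A5SS")          # shared acceptor
  expect_equal(p(100, 200, 100, 250), "A3SS")          # shared donor
  expect_equal(p(100, 250, 120, 200), "A5SS_AND_A3SS") # nested
  expect_equal(p(100, 200, 150, 260), "A5SS_OR_A3SS")  # staggered
  expect_equal(p(100, 200, 201, 300), "disjoint")
  # on the minus strand shared genomic start is the shared acceptor
  expect_equal(p(100, 200, 100, 250, "-"), "A5SS")
  expect_equal(p(100, 200, 150, 200, "-"), "A3SS")
  expect_error(classify_pair(mk_sj("chr1", 1, 50, strand = "+"),
                             mk_sj("chr1", 1, 60, strand = "-")),
               "strand")
})

test_that("pair classification is symmetric and shift/strand invariant", {
  set.seed(50)
  for (k in 1:200) {
    s1 <- sample(1:25, 1); e1 <- s1 + sample(3:12, 1)
    s2 <- sample(1:25, 1); e2 <- s2 + sample(3:12, 1)
    if (s1 == s2 && e1 == e2) next
    st <- sample(c("+", "-"), 1)
    a <- mk_sj("chr1", s1, e1, strand = st)
    b <- mk_sj("chr1", s2, e2, strand = st)
    l1 <- classify_pair(a, b)
    expect_equal(classify_pair(b, a), l1)          # symmetry
    expect_equal(oracle_pair(s1, e1, s2, e2, st), l1)
    # translation invariance
    a2 <- mk_sj("chr1", s1 + 1000, e1 + 1000, strand = st)
    b2 <- mk_sj("chr1", s2 + 1000, e2 + 1000, strand = st)
    expect_equal(classify_pair(a2, b2), l1)
    # strand flip with coordinate mirroring preserves the label
    M <- 10000
    st2 <- if (st == "+") "-" else "+"
    a3 <- mk_sj("chr1", M - e1, M - s1, strand = st2)
    b3 <- mk_sj("chr1", M - e2, M - s2, strand = st2)
    expect_equal(classify_pair(a3, b3), l1)
  }
})

test_that("multi-junction clusters are classified per the taxonomy", {
  tri <- function(spans, st = "+") {
    classify_multi(dplyr::bind_rows(lapply(seq_len(nrow(spans)), function(i) {
      mk_sj("chr1", spans[i, 1], spans[i, 2], strand = st)
    })))
  }
  # all share the acceptor
  r <- tri(rbind(c(100, 500), c(200, 500), c(300, 500)))
  expect_equal(r$event_type, "MA5SS(3)")
  # all share the donor
  r <- tri(rbind(c(100, 300), c(100, 400), c(100, 500), c(100, 600)))
  expect_equal(r$event_type, "MA3SS(4)")
  # the documented three-junction skipping pattern
  r <- tri(rbind(c(100, 200), c(300, 400), c(100, 400)))
  expect_equal(r$event_type, "EXON_SKIPPING")
  # documented complex code
  cl <- rbind(c(100, 200), c(150, 200), c(100, 250), c(400, 500))
  r <- tri(cl)
  expect_equal(r$event_type, "COMPLEX")
  expect_match(r$complex_code, "^n=4;A5SS=")
  # the code's tallies equal an all-pairs oracle count
  labs <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    labs <- c(labs, oracle_pair(cl[i, 1], cl[i, 2], cl[j, 1], cl[j, 2], "+"))
  }
  expect_equal(
    r$complex_code,
    sprintf("n=4;A5SS=%d;A3SS=%d;AND=%d;OR=%d",
            sum(labs == "A5SS"), sum(labs == "A3SS"),
            sum(labs == "A5SS_AND_A3SS"), sum(labs == "A5SS_OR_A3SS")))
})

test_that("enumerated small clusters match the brute-force oracle", {
  set.seed(51)
  for (trial in 1:400) {
    k <- sample(3:4, 1)
    spans <- cbind(sample(1:24, k, replace = TRUE), 0)
    spans[, 2] <- spans[, 1] + sample(3:8, k, replace = TRUE)
    spans <- unique(spans)
    if (nrow(spans) < 3) next
    st <- sample(c("+", "-"), 1)
    got <- classify_multi(dplyr::bind_rows(
      lapply(seq_len(nrow(spans)), function(i) {
        mk_sj("chr1", spans[i, 1], spans[i, 2], strand = st)
      })))$event_type
    expect_equal(got, oracle_multi(spans, st), info = paste(st,
      paste(apply(spans, 1, paste, collapse = "-"), collapse = " ")))
  }
})

test_that("single-junction clusters follow the coverage rules", {
  sj <- mk_sj("chr1", 101, 160, support = 50L)
  # all intronic coverage zero: constitutive
  cov0 <- mk_coverage(300)
  r0 <- classify_single(sj, cov0)
  expect_equal(r0$event_type, "IC")
  expect_null(r0$ir)
  # one covered base flips it to retained (monotone, never the reverse)
  cov1 <- mk_coverage(300, list(c(130, 130, 1)))
  r1 <- classify_single(sj, cov1)
  expect_equal(r1$event_type, "IR")
  # median 5 over the intron, support 50: IRR 0.1, bin [0.1, 1)
  cov5 <- mk_coverage(300, list(c(101, 160, 5)))
  r5 <- classify_single(sj, cov5)
  expect_equal(r5$ir$irr, 0.1)
  expect_equal(r5$ir$irr_bin, "[0.1,1)")
  expect_equal(r5$ir$coverage_class, "high")   # every base >= 2
  # a single base below 2 demotes the coverage class
  covlow <- mk_coverage(300, list(c(101, 160, 5), c(120, 120, 1)))
  expect_equal(classify_single(sj, covlow)$ir$coverage_class, "low")
})

test_that("IRR bins use left-closed edges", {
  expect_equal(as.character(irr_bin_for_test(c(0.005, 0.01, 0.0999, 0.1,
                                               0.99, 1, 3))),
               c("[0,0.01)", "[0.01,0.1)", "[0.01,0.1)", "[0.1,1)",
                 "[0.1,1)", "[1,Inf)", "[1,Inf)"))
})

test_that("the accounting summary reproduces the printed-count arithmetic", {
  # category counts as inputs: 12509 single (9369 IR + 3140 IC),
  # 503 two-junction, 162 multi-junction clusters
  ev <- tibble::tibble(
    cluster_id = sprintf("c%05d", 1:13174),
    chrom = "chr1", strand = "+",
    n_sj = c(rep(1L, 12509), rep(2L, 503), rep(3L, 162)),
    event_type = c(rep("IR", 9369), rep("IC", 3140),
                   rep("A5SS", 167), rep("A3SS", 302),
                   rep("A5SS_AND_A3SS", 19), rep("A5SS_OR_A3SS", 15),
                   rep("MA5SS(3)", 13), rep("MA3SS(3)", 28),
                   rep("COMPLEX", 121)),
    complex_code = NA_character_,
    is_AS = c(rep(TRUE, 9369), rep(FALSE, 3140), rep(TRUE, 503 + 162)))
  s <- summarize_events(ev)
  expect_equal(s$n_clusters, 13174L)
  expect_equal(s$n_AS_events, 10034L)
  expect_equal(s$n_IR, 9369L)
  expect_equal(s$n_IC, 3140L)
  expect_equal(round(100 * s$as_cluster_ratio, 1), 76.2)
  expect_equal(s$n_AS_events, s$n_clusters - s$n_IC)  # identity

  # degenerate: all constitutive
  ev0 <- ev[ev$event_type == "IC", ]
  s0 <- summarize_events(ev0)
  expect_equal(s0$n_AS_events, 0L)
  expect_equal(s0$as_cluster_ratio, 0)
})

test_that("gene mapping counts distinct models once and splits by exon count", {
  ev <- tibble::tibble(cluster_id = c("c1", "c2"), chrom = "chr1",
                       strand = "+", n_sj = 1L,
                       event_type = c("IR", "IC"),
                       complex_code = NA_character_, is_AS = c(TRUE, FALSE))
  js <- dplyr::bind_rows(mk_sj("chr1", 150, 200, id = "j1"),
                         mk_sj("chr1", 600, 650, id = "j2"))
  js$cluster_id <- c("c1", "c2")
  models <- tibble::tibble(
    chrom = "chr1",
    start = c(100, 100, 250, 500, 500),
    end = c(400, 180, 400, 900, 900),
    strand = "+",
    type = c("gene", "exon", "exon", "gene", "exon"),
    id = c("g1", "g1.e1", "g1.e2", "g2", "g2.e1"),
    parent = c(NA, "g1", "g1", NA, "g2"))
  s <- summarize_events(ev, js, models)
  # only g1 overlaps an AS junction (twice would still count once)
  expect_equal(s$n_AS_genes, 1L)
  expect_equal(s$n_multiexonic_AS_genes, 1L)
  expect_equal(s$n_monoexonic_AS_genes, 0L)
})

test_that("planted events round-trip through the classifier", {
  lib <- small_dataset()
  truth <- lib$sim
  # recovered junction set joined back to the planted truth
  jj <- dplyr::inner_join(
    truth$junctions,
    lib$junctions[, c("chrom", "strand", "intron_start", "intron_end",
                      "cluster_id")],
    by = c(chrom = "chrom", strand = "strand", start = "intron_start",
           end = "intron_end"))
  ev <- lib$events
  # every planted pair event recovered as a 2-junction cluster has the
  # planted label
  pair_classes <- c("A5SS", "A3SS", "A5SS_AND_A3SS", "A5SS_OR_A3SS")
  planted_pairs <- jj %>%
    dplyr::filter(.data$class %in% pair_classes) %>%
    dplyr::distinct(.data$event_id, .data$class, .data$cluster_id)
  got <- ev$event_type[match(planted_pairs$cluster_id, ev$cluster_id)]
  two <- ev$n_sj[match(planted_pairs$cluster_id, ev$cluster_id)] == 2
  expect_true(all(got[two] == planted_pairs$class[two]))

  # IR recovery at planted IRR >= 0.2
  ir_events <- truth$events %>%
    dplyr::filter(.data$class == "IR", .data$planted_irr >= 0.2)
  ir_j <- jj %>% dplyr::filter(.data$event_id %in% ir_events$event_id)
  got_ir <- ev$event_type[match(ir_j$cluster_id, ev$cluster_id)]
  expect_gte(mean(got_ir == "IR"), 0.95)
})
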