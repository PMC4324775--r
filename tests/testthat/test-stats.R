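test_that("feature table assigns classes exhaustively and computes GC", {
  lib <- small_dataset()
  feats <- compute_features(lib$junctions, lib$events, lib$ir)
  expect_equal(nrow(feats), nrow(lib$junctions))
  expect_true(all(feats$cls %in% c("IC", "IR", "IA_minus_IR")))
  # GC against a direct character count
  j1 <- lib$junctions[1, ]
  ch <- strsplit(j1$intron_seq, "")[[1]]
  expect_equal(feats$gc[feats$sj_id == j1$sj_id],
               sum(ch %in% c("G", "C")) / length(ch))
  # members of multi-junction clusters are IA_minus_IR
  multi <- lib$events$cluster_id[lib$events$n_sj > 1]
  expect_true(all(feats$cls[feats$cluster_id %in% multi] == "IA_minus_IR"))
  # retained singletons carry their IRR bin
  irj <- feats[feats$cls == "IR", ]
  expect_true(all(!is.na(irj$irr)))
  # a junction outside any classified cluster is an error
  orphan <- lib$junctions[1, ]
  orphan$cluster_id <- "nope"
  orphan$sj_id <- "orphan"
  expect_error(compute_features(dplyr::bind_rows(lib$junctions, orphan),
                                lib$events, lib$ir),
               "exhaustive")
})

test_that("class comparisons follow the rank-sum contract", {
  f <- tibble::tibble(
    cls = rep(c("IC", "IR"), each = 3),
    length = c(1, 2, 3, 101, 102, 103))
  r <- compare_classes(f, "length", "IC", "IR")
  expect_equal(r$direction, "IR")
  # complete separation at n = 3 vs 3: exact two-sided p is 2/choose(6,3)
  expect_equal(r$p_value, 0.1)
  # identical value multisets: p = 1, no direction
  f2 <- tibble::tibble(cls = rep(c("IC", "IR"), each = 4),
                       length = rep(c(5, 6, 7, 8), 2))
  r2 <- compare_classes(f2, "length", "IC", "IR")
  expect_equal(r2$direction, "none")
  expect_gt(r2$p_value, 0.5)
  # all values identical: defined statistic, p = 1
  f3 <- tibble::tibble(cls = rep(c("IC", "IR"), each = 4), length = 7)
  r3 <- compare_classes(f3, "length", "IC", "IR")
  expect_equal(r3$p_value, 1)
  expect_error(compare_classes(f3[f3$cls == "IC", ], "length", "IC", "IR"),
               "non-empty")
})

test_that("rank-sum p-values match an exact permutation oracle at small n", {
  set.seed(70)
  for (k in 1:25) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    xa <- sample(seq(1, 400), na)   # distinct values: no ties
    xb <- sample(seq(401, 800), nb) * 0 + sample(seq(2, 798, by = 2), nb)
    xa <- xa + 0.5                  # guarantee no ties with xb
    f <- tibble::tibble(cls = rep(c("a", "b"), c(na, nb)), v = c(xa, xb))
    got <- compare_classes(f, "v", "a", "b")$p_value
    # oracle: enumerate all group assignments of the pooled values
    pool <- c(xa, xb)
    obs <- sum(rank(pool)[seq_len(na)])
    combos <- utils::combn(length(pool), na)
    stat <- apply(combos, 2, function(idx) sum(rank(pool)[idx]))
    mu <- na * (length(pool) + 1) / 2
    p_exact <- mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
    expect_lt(abs(got - p_exact), 0.02)
  }
})

test_that("a planted length shift is detected with the expected direction", {
  set.seed(71)
  f <- tibble::tibble(
    cls = rep(c("IC", "IR"), each = 2000),
    length = c(rlnorm(2000, log(66), 0.4), rlnorm(2000, log(66 * 1.2), 0.4)))
  r <- compare_classes(f, "length", "IC", "IR")
  expect_equal(r$direction, "IR")
  expect_lt(r$p_value, 1e-6)
})

test_that("isoform frequencies and the documented ratios are computed", {
  js <- dplyr::bind_rows(
    mk_sj("chr1", 100, 200, support = 30L, id = "j1"),
    mk_sj("chr1", 150, 200, support = 10L, id = "j2"))
  js$cluster_id <- "c1"
  js$five_score <- c(8, 5)
  js$three_score <- c(3, 3)
  js$reads_s1 <- c(20L, 5L)
  js$reads_s2 <- c(10L, 5L)
  ev <- tibble::tibble(cluster_id = "c1", chrom = "chr1", strand = "+",
                       n_sj = 2L, event_type = "A5SS",
                       complex_code = NA_character_, is_AS = TRUE)
  iso <- isoform_stats(js, ev)
  row <- iso$isoforms
  expect_equal(row$freq_1, 0.75)
  expect_equal(row$freq_2, 0.25)
  expect_equal(row$log_freq_ratio, log(3))
  expect_equal(row$delta_score, 3)       # A5SS uses the donor score
  expect_equal(row$freq1_s1, 0.8)
  expect_equal(row$freq1_s2, 2 / 3)
  # per-sample frequencies sum to one over the cluster
  expect_equal(row$freq1_s1 + (1 - row$freq1_s1), 1)
  # fewer than 3 usable clusters: regression undefined
  expect_false(any(iso$regressions$defined))
})

test_that("degenerate regressors and zero counts are handled", {
  mkclu <- function(i, s1, s2, d) {
    js <- dplyr::bind_rows(
      mk_sj("chr1", 100 + 1000 * i, 200 + 1000 * i, support = s1,
            id = sprintf("a%d", i)),
      mk_sj("chr1", 150 + 1000 * i, 200 + 1000 * i, support = s2,
            id = sprintf("b%d", i)))
    js$cluster_id <- sprintf("c%d", i)
    js$five_score <- c(d, 0)
    js$three_score <- 0
    js$reads_s1 <- as.integer(c(s1, s2))
    js
  }
  js <- dplyr::bind_rows(lapply(1:5, function(i) mkclu(i, 20L, 10L, 0)))
  ev <- tibble::tibble(cluster_id = sprintf("c%d", 1:5), chrom = "chr1",
                       strand = "+", n_sj = 2L, event_type = "A5SS",
                       complex_code = NA_character_, is_AS = TRUE)
  iso <- isoform_stats(js, ev)
  r <- iso$regressions[iso$regressions$pair_type == "A5SS", ]
  expect_false(r$defined)   # zero-variance regressor

  # clusters with a zero count are excluded from the regression
  js2 <- dplyr::bind_rows(lapply(1:6, function(i) {
    mkclu(i, 20L + 3L * (i %% 3L), if (i <= 2) 0L else 10L, d = i)
  }))
  ev2 <- tibble::tibble(cluster_id = sprintf("c%d", 1:6), chrom = "chr1",
                        strand = "+", n_sj = 2L, event_type = "A5SS",
                        complex_code = NA_character_, is_AS = TRUE)
  iso2 <- isoform_stats(js2, ev2)
  r2 <- iso2$regressions[iso2$regressions$pair_type == "A5SS", ]
  expect_true(r2$defined)
  expect_equal(r2$n, 4L)
})

test_that("a zero usage link yields no spurious slope (type-I control)", {
  set.seed(72)
  n_rep <- 200
  rejections <- 0L
  for (rep in seq_len(n_rep)) {
    n_cl <- 30
    delta <- rnorm(n_cl)
    rows <- lapply(seq_len(n_cl), function(i) {
      total <- 60L
      c1 <- rbinom(1, total, 0.5)
      js <- dplyr::bind_rows(
        mk_sj("chr1", 100 + 1000 * i, 200 + 1000 * i, support = c1,
              id = sprintf("a%d", i)),
        mk_sj("chr1", 150 + 1000 * i, 200 + 1000 * i, support = total - c1,
              id = sprintf("b%d", i)))
      js$cluster_id <- sprintf("c%d", i)
      js$five_score <- c(delta[i], 0)
      js$three_score <- 0
      js$reads_s1 <- as.integer(c(c1, total - c1))
      js
    })
    js <- dplyr::bind_rows(rows)
    ev <- tibble::tibble(cluster_id = sprintf("c%d", seq_len(n_cl)),
                         chrom = "chr1", strand = "+", n_sj = 2L,
                         event_type = "A5SS", complex_code = NA_character_,
                         is_AS = TRUE)
    p <- isoform_stats(js, ev)$regressions
    p <- p$p_value[p$pair_type == "A5SS"]
    if (!is.na(p) && p < 0.05) rejections <- rejections + 1L
  }
  # nominal 5%: allow Monte-Carlo slack (binomial sd ~ 1.5%)
  expect_lt(rejections / n_rep, 0.10)
  expect_gt(rejections / n_rep, 0.005)
})

test_that("the pipeline is deterministic and degrades without coverage", {
  cfg <- list(mode = "synthetic", outdir = file.path(tempdir(), "det1"),
              genome_spec = genome_spec(n_chroms = 1, chrom_length = 60000,
                                        seed = 33),
              gene_spec = gene_spec(n_genes = 25),
              read_spec = read_sim_spec(seed = 33))
  r1 <- run_pipeline(cfg)
  cfg2 <- cfg
  cfg2$outdir <- file.path(tempdir(), "det2")
  r2 <- run_pipeline(cfg2)
  for (f in c("summary.tsv", "junctions.tsv", "counts.tsv", "clusters.tsv",
              "ir.tsv", "report.tsv")) {
    expect_identical(readLines(file.path(cfg$outdir, f)),
                     readLines(file.path(cfg2$outdir, f)), label = f)
  }
  expect_true(file.exists(file.path(cfg$outdir, "manifest.json")))

  # file mode without coverage: notice given, cluster classification intact
  d3 <- file.path(tempdir(), "nocov")
  expect_message(
    r3 <- run_pipeline(list(
      mode = "files", outdir = d3,
      genome_fa = file.path(cfg$outdir, "genome.fa"),
      counts_tsv = file.path(cfg$outdir, "counts.tsv"))),
    "retention")
  expect_true(is.null(r3$summary))
  expect_true(file.exists(file.path(d3, "clusters.tsv")))
  ev3 <- readr::read_tsv(file.path(d3, "clusters.tsv"),
                         show_col_types = FALSE)
  expect_true(all(ev3$event_type[ev3$n_sj > 1] != "NOT_ASSESSED"))
  expect_true(all(ev3$event_type[ev3$n_sj == 1] == "NOT_ASSESSED"))
  # two-junction labels equal the coverage-aware run's labels
  ev1 <- readr::read_tsv(file.path(cfg$outdir, "clusters.tsv"),
                         show_col_types = FALSE)
  key <- function(x) paste(x$chrom, x$span_start, x$span_end)
  m <- merge(ev1[ev1$n_sj > 1, ], ev3[ev3$n_sj > 1, ], by.x = "cluster_id",
             by.y = "cluster_id")
  expect_true(all(m$event_type.x == m$event_type.y))
})

test_that("tidiers expose regression and matrix results", {
  lib <- small_dataset()
  iso <- isoform_stats(lib$junctions, lib$events)
  td <- generics::tidy(iso)
  expect_true(all(c("pair_type", "slope", "r_squared") %in% names(td)))
  gl <- generics::glance(iso)
  expect_equal(gl$log_base, "natural")
  win <- extract_site_windows(lib$junctions, lib$sim$genome)
  m <- build_matrices(win)
  tm <- generics::tidy(m$five)
  expect_true(all(c("base", "position", "log_odds") %in% names(tm)))
})

test_that("result plots build without error", {
  lib <- small_dataset()
  expect_s3_class(plot_event_classes(lib$events), "ggplot")
  expect_s3_class(plot_irr_bins(lib$ir), "ggplot")
  feats <- compute_features(lib$junctions, lib$events, lib$ir)
  expect_s3_class(plot_feature_by_class(feats, "gc"), "ggplot")
  iso <- isoform_stats(lib$junctions, lib$events)
  expect_s3_class(ggplot2::autoplot(iso), "ggplot")
  win <- extract_site_windows(lib$junctions, lib$sim$genome)
  expect_s3_class(ggplot2::autoplot(build_matrices(win)$five), "ggplot")
})
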