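#' Per-intron feature table
#'
#' One row per catalogued junction with its length, GC content, the three
#' raw splice-site scores, and the intron class: IC (constitutive
#' singleton), IR (retained singleton), or IA_minus_IR (member of any
#' multi-junction cluster — alternatively spliced introns except retained
#' ones). Sentinel (-Inf) and unscorable scores become NA so they are
#' excluded from feature statistics.
#'
#' @param junctions junction tibble with cluster_id and scores.
#' @param events events tibble from [classify_clusters()].
#' @param ir retained-intron tibble from [classify_clusters()].
#' @return tibble: sj_id, cluster_id, length, gc, five_score, three_score,
#'   branch_score, cls, irr, irr_bin.
#' @export
compute_features <- function(junctions, events, ir = NULL) {
  if (!all(junctions$cluster_id %in% events$cluster_id)) {
    abort("classification must be exhaustive: junction in no classified cluster")
  }
  ev <- events %>% dplyr::select("cluster_id", "n_sj", "event_type")
  clean <- function(x) ifelse(is.finite(x), x, NA_real_)
  out <- junctions %>%
    dplyr::left_join(ev, by = "cluster_id") %>%
    dplyr::mutate(
      length = .data$intron_end - .data$intron_start + 1L,
      gc = gc_fraction(.data$intron_seq),
      five_score = clean(.data$five_score),
      three_score = clean(.data$three_score),
      branch_score = clean(.data$branch_score),
      cls = dplyr::case_when(
        .data$n_sj > 1 ~ "IA_minus_IR",
        .data$event_type == "IR" ~ "IR",
        TRUE ~ "IC"))
  if (!is.null(ir) && nrow(ir)) {
    out <- out %>%
      dplyr::left_join(ir %>% dplyr::select("sj_id", "irr", "irr_bin"),
                       by = "sj_id")
  } else {
    out$irr <- NA_real_
    out$irr_bin <- NA_character_
  }
  out %>%
    dplyr::select("sj_id", "cluster_id", "length", "gc", "five_score",
                  "three_score", "branch_score", "cls", "irr", "irr_bin")
}

#' Rank-sum comparison of a feature between two intron classes
#'
#' Two-sided Mann-Whitney-Wilcoxon test: exact for small groups (both at
#' most 20 observations and no ties), normal approximation with tie and
#' continuity correction otherwise. Direction reports which class has the
#' greater median.
#'
#' @param features tibble from [compute_features()].
#' @param feature_name column to compare.
#' @param cls_a,cls_b class labels.
#' @return one-row tibble: feature, cls_a, cls_b, n_a, n_b, statistic,
#'   p_value, direction.
#' @export
compare_classes <- function(features, feature_name, cls_a, cls_b) {
  xa <- features[[feature_name]][features$cls == cls_a]
  xb <- features[[feature_name]][features$cls == cls_b]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (!length(xa) || !length(xb)) abort("both classes must be non-empty")
  all_same <- length(unique(c(xa, xb))) == 1
  if (all_same) {
    w <- length(xa) * length(xb) / 2
    p <- 1
  } else {
    use_exact <- max(length(xa), length(xb)) <= 20 &&
      !any(duplicated(c(xa, xb)))
    tst <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided",
                         exact = use_exact, correct = TRUE))
    w <- unname(tst$statistic)
    p <- min(1, tst$p.value)
  }
  ma <- median2(xa); mb <- median2(xb)
  tibble::tibble(
    feature = feature_name, cls_a = cls_a, cls_b = cls_b,
    n_a = length(xa), n_b = length(xb), statistic = w, p_value = p,
    direction = if (ma > mb) cls_a else if (mb > ma) cls_b else "none")
}

#' Isoform relative frequencies and the score-difference regression
#'
#' For every two-junction cluster of type A5SS, A3SS, "A5SS and A3SS" or
#' "A5SS or A3SS": per-sample and pooled isoform relative frequencies, the
#' score difference appropriate to the type (donor score for A5SS,
#' acceptor score for A3SS, their sum for the combined types), and the
#' natural log of the pooled isoform frequency ratio (defined only when
#' both isoform counts are positive). Per pair type (combined types are
#' pooled, as their regressor is the same score sum) an ordinary
#' least-squares regression of the log frequency ratio on the score
#' difference is fitted over clusters with both counts positive.
#'
#' @param junctions junction tibble with cluster_id, scores and per-sample
#'   reads_<sample> columns.
#' @param events events tibble from [classify_clusters()].
#' @return object of class `isoform_regressions`: list with `isoforms`
#'   (one row per cluster), `regressions` (one row per pair type), and
#'   `fits` (the lm objects).
#' @export
isoform_stats <- function(junctions, events) {
  types2 <- c("A5SS", "A3SS", "A5SS_AND_A3SS", "A5SS_OR_A3SS")
  cl2 <- events %>%
    dplyr::filter(.data$n_sj == 2, .data$event_type %in% types2)
  rcol <- grep("^reads_", names(junctions), value = TRUE)
  samples <- sub("^reads_", "", rcol)
  rows <- vector("list", nrow(cl2))
  for (i in seq_len(nrow(cl2))) {
    g <- junctions %>%
      dplyr::filter(.data$cluster_id == cl2$cluster_id[i]) %>%
      dplyr::arrange(.data$intron_start, .data$intron_end)
    type <- cl2$event_type[i]
    delta <- switch(type,
                    A5SS = g$five_score[1] - g$five_score[2],
                    A3SS = g$three_score[1] - g$three_score[2],
                    (g$five_score[1] + g$three_score[1]) -
                      (g$five_score[2] + g$three_score[2]))
    pooled <- g$support_pooled
    row <- tibble::tibble(
      cluster_id = cl2$cluster_id[i], pair_type = type,
      delta_score = if (is.finite(delta)) delta else NA_real_,
      count_1 = pooled[1], count_2 = pooled[2],
      freq_1 = pooled[1] / sum(pooled), freq_2 = pooled[2] / sum(pooled),
      log_freq_ratio = if (all(pooled > 0)) log(pooled[1] / pooled[2]) else
        NA_real_)
    for (s in samples) {
      cs <- g[[paste0("reads_", s)]]
      tot <- sum(cs)
      row[[paste0("freq1_", s)]] <- if (tot > 0) cs[1] / tot else NA_real_
    }
    rows[[i]] <- row
  }
  iso <- dplyr::bind_rows(rows)

  reg_groups <- list(A5SS = "A5SS", A3SS = "A3SS",
                     combined = c("A5SS_AND_A3SS", "A5SS_OR_A3SS"))
  fits <- list()
  regs <- purrr::imap(reg_groups, function(types, nm) {
    d <- iso %>%
      dplyr::filter(.data$pair_type %in% types,
                    !is.na(.data$log_freq_ratio), !is.na(.data$delta_score))
    if (nrow(d) < 3 || stats::var(d$delta_score) == 0) {
      return(tibble::tibble(pair_type = nm, slope = NA_real_,
                            intercept = NA_real_, r_squared = NA_real_,
                            p_value = NA_real_, n = nrow(d),
                            defined = FALSE))
    }
    fit <- stats::lm(log_freq_ratio ~ delta_score, data = d)
    fits[[nm]] <<- fit
    sm <- summary(fit)
    tibble::tibble(
      pair_type = nm, slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients[2, 4]), n = nrow(d),
      defined = TRUE)
  })
  structure(list(isoforms = iso, regressions = dplyr::bind_rows(regs),
                 fits = fits, log_base = "natural"),
            class = "isoform_regressions")
}

#' @export
print.isoform_regressions <- function(x, ...) {
  cat("<isoform_regressions>", nrow(x$isoforms),
      "two-junction clusters; log base:", x$log_base, "\n")
  print(x$regressions)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.isoform_regressions <- function(x, ...) x$regressions

#' @export
glance.isoform_regressions <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$isoforms),
                 n_defined_regressions = sum(x$regressions$defined),
                 log_base = x$log_base)
}

#' @export
tidy.pwm <- function(x, ...) {
  matrices_to_tibble(list(site = x)) %>% dplyr::select(-"site_type")
}
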