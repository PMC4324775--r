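#' Cluster splice junctions by intron-span overlap
#'
#' Single-linkage components under "intron spans share at least one base on
#' the same chromosome". Components containing junctions from both strands
#' are excluded and tallied.
#'
#' @param sjs junction tibble.
#' @return list with `junctions` (cluster_id column added, mixed-strand
#'   members removed) and `n_mixed_strand_excluded` (count of dropped
#'   clusters).
#' @export
cluster_junctions <- function(sjs) {
  if (nrow(sjs) == 0) {
    sjs$cluster_id <- character(0)
    return(list(junctions = sjs, n_mixed_strand_excluded = 0L))
  }
  gr <- GenomicRanges::GRanges(sjs$chrom,
                               IRanges::IRanges(sjs$intron_start,
                                                sjs$intron_end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)  # >= 1 shared base
  hit <- GenomicRanges::findOverlaps(gr, red)
  comp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  sjs$cluster_id <- sprintf("cl%05d", comp)
  mixed <- sjs %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(mixed = dplyr::n_distinct(.data$strand) > 1,
                     .groups = "drop") %>%
    dplyr::filter(.data$mixed)
  out <- sjs %>% dplyr::filter(!.data$cluster_id %in% mixed$cluster_id)
  list(junctions = out, n_mixed_strand_excluded = nrow(mixed))
}

# donor / acceptor genomic coordinates in transcription orientation
donor_coord <- function(start, end, strand) {
  ifelse(rep_len(strand == "+", length(start)), start, end)
}
acceptor_coord <- function(start, end, strand) {
  ifelse(rep_len(strand == "+", length(start)), end, start)
}

#' Classify a pair of overlapping junctions
#'
#' With donor and acceptor taken in transcription orientation: a common
#' acceptor gives alternative donors (A5SS); a common donor gives
#' alternative acceptors (A3SS); one junction strictly nested in the other
#' is "A5SS and A3SS"; a staggered overlap is "A5SS or A3SS"; no shared
#' base is disjoint.
#'
#' @param a,b one-row junction tibbles (or lists) with intron_start,
#'   intron_end, strand.
#' @return one of "A5SS", "A3SS", "A5SS_AND_A3SS", "A5SS_OR_A3SS",
#'   "disjoint".
#' @export
classify_pair <- function(a, b) {
  if (a$strand != b$strand) abort("junction pair on different strands")
  pair_label(a$intron_start, a$intron_end,
             b$intron_start, b$intron_end, a$strand)
}

pair_label <- function(s1, e1, s2, e2, strand) {
  if (e1 < s2 || e2 < s1) return("disjoint")
  d1 <- donor_coord(s1, e1, strand); a1 <- acceptor_coord(s1, e1, strand)
  d2 <- donor_coord(s2, e2, strand); a2 <- acceptor_coord(s2, e2, strand)
  if (a1 == a2) return("A5SS")
  if (d1 == d2) return("A3SS")
  if ((s1 < s2 && e1 > e2) || (s2 < s1 && e2 > e1)) return("A5SS_AND_A3SS")
  "A5SS_OR_A3SS"
}

#' Classify a cluster of three or more junctions
#'
#' All members sharing the acceptor is a multiple-alternative donor event
#' MA5SS(k); all sharing the donor is MA3SS(k). Exactly three members where
#' two are base-disjoint and the third shares its donor with the upstream
#' one and its acceptor with the downstream one is exon skipping. Anything
#' else is complex and is encoded by the total junction count plus the
#' tallies of pairwise labels over all member pairs.
#'
#' @param cluster junction tibble (>= 3 rows, one strand).
#' @return list with event_type (e.g. "MA5SS(3)", "EXON_SKIPPING",
#'   "COMPLEX") and complex_code (NA unless complex).
#' @export
classify_multi <- function(cluster) {
  k <- nrow(cluster)
  stopifnot(k >= 3, length(unique(cluster$strand)) == 1)
  st <- cluster$strand[1]
  d <- donor_coord(cluster$intron_start, cluster$intron_end, st)
  a <- acceptor_coord(cluster$intron_start, cluster$intron_end, st)
  if (length(unique(a)) == 1) {
    return(list(event_type = sprintf("MA5SS(%d)", k),
                complex_code = NA_character_))
  }
  if (length(unique(d)) == 1) {
    return(list(event_type = sprintf("MA3SS(%d)", k),
                complex_code = NA_character_))
  }
  if (k == 3) {
    idx <- seq_len(3)
    for (i in idx) for (j in setdiff(idx, i)) {
      m <- setdiff(idx, c(i, j))
      disjointij <- cluster$intron_end[i] < cluster$intron_start[j] ||
        cluster$intron_end[j] < cluster$intron_start[i]
      if (disjointij && d[m] == d[i] && a[m] == a[j]) {
        return(list(event_type = "EXON_SKIPPING",
                    complex_code = NA_character_))
      }
    }
  }
  tal <- c(A5SS = 0L, A3SS = 0L, A5SS_AND_A3SS = 0L, A5SS_OR_A3SS = 0L,
           disjoint = 0L)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    lb <- pair_label(cluster$intron_start[i], cluster$intron_end[i],
                     cluster$intron_start[j], cluster$intron_end[j], st)
    tal[lb] <- tal[lb] + 1L
  }
  code <- sprintf("n=%d;A5SS=%d;A3SS=%d;AND=%d;OR=%d",
                  k, tal["A5SS"], tal["A3SS"], tal["A5SS_AND_A3SS"],
                  tal["A5SS_OR_A3SS"])
  list(event_type = "COMPLEX", complex_code = code)
}

irr_bin <- function(irr) {
  cut(irr, breaks = c(0, 0.01, 0.1, 1, Inf), right = FALSE,
      labels = c("[0,0.01)", "[0.01,0.1)", "[0.1,1)", "[1,Inf)"))
}

#' Classify a single-junction cluster as retained or constitutive
#'
#' An intron with any base covered by at least one read is a retained
#' intron (IR), otherwise constitutive (IC). For IR the intron retention
#' ratio is the median intronic per-base coverage divided by the pooled
#' junction support; the coverage class is "high" when every intronic base
#' is covered by at least two reads.
#'
#' @param sj one-row junction tibble.
#' @param coverage an RleList of pooled per-base coverage.
#' @return list with event_type ("IR"/"IC") and ir (one-row tibble or NULL).
#' @export
classify_single <- function(sj, coverage) {
  v <- as.integer(S4Vectors::decode(
    coverage[[sj$chrom]][sj$intron_start:sj$intron_end]))
  if (!any(v >= 1L)) return(list(event_type = "IC", ir = NULL))
  irr <- median2(v) / sj$support_pooled
  list(event_type = "IR",
       ir = tibble::tibble(
         sj_id = sj$sj_id, irr = irr,
         irr_bin = as.character(irr_bin(irr)),
         coverage_class = if (all(v >= 2L)) "high" else "low",
         median_intron_coverage = median2(v)))
}

#' Classify every junction cluster into the AS taxonomy
#'
#' @param sjs junction tibble with cluster_id (from [cluster_junctions()]).
#' @param coverage pooled per-base coverage (RleList), a named list of
#'   per-sample RleLists (summed into pooled coverage, with per-sample IRRs
#'   emitted as extra columns), or NULL to skip the retention analysis of
#'   single-junction clusters.
#' @return list with `events` (one row per cluster: cluster_id, chrom,
#'   strand, n_sj, event_type, complex_code, is_AS) and `ir` (one row per
#'   retained intron).
#' @export
classify_clusters <- function(sjs, coverage = NULL) {
  per_sample <- NULL
  pooled <- coverage
  if (is.list(coverage) && !methods::is(coverage, "RleList")) {
    per_sample <- coverage
    pooled <- Reduce(`+`, coverage)
  }
  cl <- sjs %>% dplyr::group_by(.data$cluster_id)
  keys <- dplyr::group_keys(cl)$cluster_id
  groups <- dplyr::group_split(cl)
  ev <- vector("list", length(groups))
  irs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    base <- tibble::tibble(cluster_id = keys[i], chrom = g$chrom[1],
                           strand = g$strand[1], n_sj = nrow(g),
                           span_start = min(g$intron_start),
                           span_end = max(g$intron_end))
    if (nrow(g) == 1) {
      if (is.null(pooled)) {
        ev[[i]] <- base %>%
          dplyr::mutate(event_type = "NOT_ASSESSED",
                        complex_code = NA_character_, is_AS = NA)
        next
      }
      res <- classify_single(g, pooled)
      ir <- res$ir
      if (!is.null(ir) && !is.null(per_sample)) {
        for (nm in names(per_sample)) {
          v <- as.integer(S4Vectors::decode(
            per_sample[[nm]][[g$chrom]][g$intron_start:g$intron_end]))
          supp <- g[[paste0("reads_", nm)]]
          ir[[paste0("irr_", nm)]] <-
            if (!is.null(supp) && supp > 0) median2(v) / supp else NA_real_
        }
      }
      if (!is.null(ir)) ir$cluster_id <- keys[i]
      irs[[i]] <- ir
      ev[[i]] <- base %>%
        dplyr::mutate(event_type = res$event_type,
                      complex_code = NA_character_,
                      is_AS = res$event_type == "IR")
    } else if (nrow(g) == 2) {
      lab <- pair_label(g$intron_start[1], g$intron_end[1],
                        g$intron_start[2], g$intron_end[2], g$strand[1])
      ev[[i]] <- base %>%
        dplyr::mutate(event_type = lab, complex_code = NA_character_,
                      is_AS = TRUE)
    } else {
      res <- classify_multi(g)
      ev[[i]] <- base %>%
        dplyr::mutate(event_type = res$event_type,
                      complex_code = res$complex_code, is_AS = TRUE)
    }
  }
  list(events = dplyr::bind_rows(ev), ir = dplyr::bind_rows(irs))
}

#' Summarise classified clusters into the event accounting table
#'
#' Reproduces the accounting identities of the cluster taxonomy: the number
#' of AS events is the number of retained introns plus all two-junction and
#' multi-junction clusters, and the AS ratio is AS events over clusters.
#' When gene models are supplied, an AS gene is any model whose span
#' overlaps at least one junction of an AS-classified cluster (counted
#' once), and multiexonic genes are models with two or more annotated
#' exons.
#'
#' @param events events tibble from [classify_clusters()].
#' @param junctions junction tibble with cluster_id (needed for gene
#'   mapping).
#' @param gene_models optional tibble from [read_gene_models_gff3()] (rows
#'   of type "gene" and "exon").
#' @return one-row tibble (the accounting summary).
#' @export
summarize_events <- function(events, junctions = NULL, gene_models = NULL) {
  stopifnot(!anyNA(events$event_type))
  single <- events$n_sj == 1
  two <- events$n_sj == 2
  multi <- events$n_sj >= 3
  cnt <- function(type, sel = TRUE) sum(events$event_type == type & sel)
  n_ic <- cnt("IC"); n_ir <- cnt("IR")
  out <- tibble::tibble(
    n_clusters = nrow(events),
    n_single = sum(single), n_IC = n_ic, n_IR = n_ir,
    n_two_sj = sum(two),
    n_A5SS = cnt("A5SS", two), n_A3SS = cnt("A3SS", two),
    n_A5SS_AND_A3SS = cnt("A5SS_AND_A3SS", two),
    n_A5SS_OR_A3SS = cnt("A5SS_OR_A3SS", two),
    n_multi = sum(multi),
    n_MA5SS = sum(grepl("^MA5SS", events$event_type) & multi),
    n_MA3SS = sum(grepl("^MA3SS", events$event_type) & multi),
    n_exon_skipping = cnt("EXON_SKIPPING", multi),
    n_complex = cnt("COMPLEX", multi),
    n_AS_events = n_ir + sum(two) + sum(multi),
    as_cluster_ratio = (n_ir + sum(two) + sum(multi)) / nrow(events),
    n_AS_genes = NA_integer_, n_multiexonic_AS_genes = NA_integer_,
    n_monoexonic_AS_genes = NA_integer_)
  stopifnot(out$n_AS_events == out$n_clusters - out$n_IC)

  if (!is.null(gene_models) && !is.null(junctions)) {
    as_clusters <- events$cluster_id[events$is_AS %in% TRUE]
    asj <- junctions %>% dplyr::filter(.data$cluster_id %in% as_clusters)
    genes <- gene_models %>% dplyr::filter(.data$type == "gene")
    exn <- gene_models %>% dplyr::filter(.data$type == "exon")
    nex <- exn %>% dplyr::count(.data$parent, name = "n_exons")
    if (nrow(asj) && nrow(genes)) {
      gg <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
      jj <- GenomicRanges::GRanges(asj$chrom,
                                   IRanges::IRanges(asj$intron_start,
                                                    asj$intron_end))
      hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gg, jj)))
      as_genes <- genes$id[hit]
      kex <- nex$n_exons[match(as_genes, nex$parent)]
      kex[is.na(kex)] <- 1L
      out$n_AS_genes <- length(as_genes)
      out$n_multiexonic_AS_genes <- sum(kex >= 2)
      out$n_monoexonic_AS_genes <- sum(kex < 2)
    } else {
      out$n_AS_genes <- 0L
      out$n_multiexonic_AS_genes <- 0L
      out$n_monoexonic_AS_genes <- 0L
    }
  }
  out
}
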