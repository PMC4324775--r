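#' Run the full splicing-discovery pipeline
#'
#' Executes filter, junction catalog, scoring, classification and
#' downstream statistics in order, writing every artifact plus a manifest
#' to `outdir`. In synthetic mode the inputs come from the seeded
#' simulator, so two runs with the same config are byte-identical.
#'
#' @param config a list. Synthetic mode: `genome_spec`, `gene_spec`,
#'   `event_spec`, `read_spec` (objects or NULL for defaults) and
#'   `mode = "synthetic"`. File mode: `genome_fa` plus either `sam` or
#'   `counts_tsv`, optional `coverage_bedgraph` (named character vector,
#'   one per sample) and `models_gff3`. Common keys: `outdir`,
#'   `min_support` (default 2), `secondary_motif` (default "TTRAY"),
#'   `max_branch_offset` (60), `overlap_shift` (10), `run_models` (FALSE).
#' @return (invisibly) a list with all intermediate tables and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    written <<- c(written, name)
    path
  }
  mode <- config$mode %||% "synthetic"
  pairs <- NULL
  truth <- NULL

  if (mode == "synthetic") {
    ds <- simulate_splicing_dataset(
      genome_spec = config$genome_spec %||% genome_spec(),
      gene_spec = config$gene_spec %||% gene_spec(),
      event_spec = config$event_spec %||% event_spec(),
      read_spec = config$read_spec %||% read_sim_spec())
    truth <- ds$sim
    genome <- truth$genome
    counts <- ds$counts
    coverage <- ds$coverage
    emit("genome.fa", function(p) write_genome_fasta(genome, p))
    emit("truth.gff3", function(p) write_truth_gff3(truth, p))
    emit("counts.tsv", function(p) write_counts_tsv(counts, p))
    for (s in names(coverage)) {
      emit(sprintf("coverage.%s.bedgraph", s),
           local({ ss <- s; function(p)
             write_coverage_bedgraph(coverage[[ss]], p) }))
    }
    if (!is.null(ds$sam)) {
      emit("reads.sam", function(p) write_sam(ds$sam, genome, p))
      flt <- filter_pairs(read_sam_alignments(file.path(outdir, "reads.sam")),
                          genome)
      pairs <- trim_anchors(flt$pairs)$pairs
      emit("filter_tally.tsv", function(p) readr::write_tsv(flt$tally, p))
    }
    gene_models <- truth_gene_models(truth)
  } else {
    genome <- read_genome_fasta(config$genome_fa)
    gene_models <- if (!is.null(config$models_gff3)) {
      read_gene_models_gff3(config$models_gff3)
    } else NULL
    coverage <- NULL
    if (!is.null(config$coverage_bedgraph)) {
      coverage <- lapply(config$coverage_bedgraph, read_coverage_bedgraph,
                         genome = genome)
      if (is.null(names(coverage))) {
        names(coverage) <- paste0("s", seq_along(coverage))
      }
    }
    if (!is.null(config$sam)) {
      flt <- filter_pairs(read_sam_alignments(config$sam), genome)
      pairs <- trim_anchors(flt$pairs)$pairs
      emit("filter_tally.tsv", function(p) readr::write_tsv(flt$tally, p))
      counts <- NULL
    } else if (!is.null(config$counts_tsv)) {
      counts <- read_counts_tsv(config$counts_tsv)
    } else {
      abort("file mode needs either `sam` or `counts_tsv`")
    }
  }

  min_support <- config$min_support %||% 2L
  js <- if (!is.null(pairs) && is.null(config$counts_tsv) &&
            mode != "synthetic") {
    extract_junctions(pairs, genome, min_support = min_support)
  } else {
    junctions_from_counts(counts, genome, min_support = min_support)
  }
  ann <- annotate_junctions(js, secondary_motif = config$secondary_motif %||%
                              "TTRAY")
  ref <- refine_junctions(ann, genome,
                          max_branch_offset = config$max_branch_offset %||% 60L,
                          overlap_shift = config$overlap_shift %||% 10L)
  sjs <- ref$junctions
  emit("junctions.tsv", function(p) readr::write_tsv(sjs, p))
  emit("report.tsv", function(p) readr::write_tsv(ref$report, p))
  emit("junctions.bed", function(p) write_junctions_bed(sjs, p))
  mats <- attr(sjs, "matrices")
  if (!is.null(mats)) {
    emit("matrices.tsv",
         function(p) readr::write_tsv(matrices_to_tibble(mats), p))
  }

  clu <- cluster_junctions(sjs)
  res <- classify_clusters(clu$junctions, coverage)
  emit("clusters.tsv", function(p) readr::write_tsv(
    res$events %>% dplyr::mutate(
      n_mixed_strand_excluded = clu$n_mixed_strand_excluded), p))

  summary_tbl <- NULL
  features <- NULL
  comparisons <- NULL
  iso <- NULL
  if (is.null(coverage)) {
    message("no coverage input: intron-retention analysis skipped; ",
            "two-junction and multi-junction classification produced")
  } else {
    if (nrow(res$ir)) {
      emit("ir.tsv", function(p) readr::write_tsv(res$ir, p))
    }
    summary_tbl <- summarize_events(res$events, clu$junctions, gene_models)
    emit("summary.tsv", function(p) readr::write_tsv(summary_tbl, p))
    emit("summary.json", function(p) jsonlite::write_json(
      as.list(summary_tbl), p, auto_unbox = TRUE, digits = NA, na = "null"))
    features <- compute_features(clu$junctions, res$events, res$ir)
    emit("features.tsv", function(p) readr::write_tsv(features, p))
    comparisons <- feature_comparisons(features)
    if (nrow(comparisons)) {
      emit("comparisons.tsv", function(p) readr::write_tsv(comparisons, p))
    }
    iso <- isoform_stats(clu$junctions, res$events)
    emit("isoforms.tsv", function(p) readr::write_tsv(iso$isoforms, p))
    emit("regressions.tsv", function(p) readr::write_tsv(
      iso$regressions %>% dplyr::mutate(log_base = iso$log_base,
                                        zero_count_clusters = "excluded"), p))
  }

  models <- NULL
  if (isTRUE(config$run_models) && !is.null(pairs) && !is.null(coverage)) {
    pooled <- Reduce(`+`, coverage)
    tars <- detect_tars(pooled)
    units <- link_units(tars, pairs, pooled)
    reads <- make_artificial_reads(pairs, sjs)
    models <- assemble_models(reads)
    models <- find_longest_orf(models, genome, sjs)
    emit("tars.bed", function(p) writeLines(sprintf(
      "%s\t%d\t%d\t%s", tars$chrom, tars$start - 1L, tars$end,
      tars$tar_id), p))
    emit("units.tsv", function(p) readr::write_tsv(
      units %>% dplyr::select(-"tar_ids"), p))
    emit("models.tsv", function(p) readr::write_tsv(
      models %>% dplyr::mutate(blocks = vapply(
        .data$blocks, function(b) paste(sprintf("%d-%d", b[, 1], b[, 2]),
                                        collapse = ","), character(1))), p))
    prot <- models %>% dplyr::filter(.data$coding, !is.na(.data$protein))
    if (nrow(prot)) {
      emit("proteins.fa", function(p) {
        aa <- Biostrings::AAStringSet(prot$protein)
        names(aa) <- prot$model_id
        Biostrings::writeXStringSet(aa, p)
      })
    }
  }

  manifest <- list(mode = mode, outdir = outdir, files = written,
                   n_junctions = nrow(sjs),
                   n_clusters = if (!is.null(res$events)) nrow(res$events)
                   else 0L)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)

  invisible(list(junctions = sjs, report = ref$report, clusters = clu,
                 events = res$events, ir = res$ir, summary = summary_tbl,
                 features = features, comparisons = comparisons,
                 isoforms = iso, models = models, truth = truth,
                 manifest = manifest))
}

# gene models tibble in the shape of read_gene_models_gff3(), from truth
truth_gene_models <- function(truth) {
  dplyr::bind_rows(
    truth$genes %>%
      dplyr::transmute(chrom = .data$chrom, start = .data$start,
                       end = .data$end, strand = .data$strand,
                       type = "gene", id = .data$gene_id,
                       parent = NA_character_),
    truth$exons %>%
      dplyr::transmute(chrom = .data$chrom, start = .data$start,
                       end = .data$end, strand = .data$strand,
                       type = "exon",
                       id = paste0(.data$gene_id, ".e", .data$exon_rank),
                       parent = .data$gene_id))
}

# the standard class-pair comparisons over all features
feature_comparisons <- function(features) {
  feats <- c("length", "gc", "five_score", "three_score", "branch_score")
  pairs <- list(c("IC", "IR"), c("IR", "IA_minus_IR"), c("IC", "IA_minus_IR"))
  rows <- list()
  for (f in feats) for (p in pairs) {
    na <- sum(features$cls == p[1] & !is.na(features[[f]]))
    nb <- sum(features$cls == p[2] & !is.na(features[[f]]))
    if (na > 0 && nb > 0) {
      rows[[length(rows) + 1L]] <- compare_classes(features, f, p[1], p[2])
    }
  }
  dplyr::bind_rows(rows)
}
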