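union_find <- function(n, edges) {
  parent <- seq_len(n)
  findp <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- findp(edges[k, 1]); b <- findp(edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), findp, integer(1))
}

#' Detect transcriptionally active regions from per-base coverage
#'
#' Maximal runs longer than `min_len` bases in which every base is covered
#' by at least `min_depth` reads.
#'
#' @param coverage RleList of per-base depth.
#' @param min_depth minimum per-base depth (default 4).
#' @param min_len runs must be strictly longer than this (default 35 bp).
#' @return tibble: tar_id, chrom, start, end, width, mean_depth.
#' @export
detect_tars <- function(coverage, min_depth = 4L, min_len = 35L) {
  rows <- purrr::imap(as.list(coverage), function(rle, ch) {
    v <- IRanges::slice(rle, lower = min_depth, rangesOnly = TRUE)
    v <- v[IRanges::width(v) > min_len]
    if (length(v) == 0) return(NULL)
    md <- vapply(seq_along(v), function(i) {
      mean(S4Vectors::decode(
        rle[IRanges::start(v)[i]:IRanges::end(v)[i]]))
    }, numeric(1))
    tibble::tibble(chrom = ch, start = IRanges::start(v),
                   end = IRanges::end(v), width = IRanges::width(v),
                   mean_depth = md)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(tar_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          width = integer(), mean_depth = numeric()))
  }
  out$tar_id <- sprintf("tar%05d", seq_len(nrow(out)))
  out[, c("tar_id", "chrom", "start", "end", "width", "mean_depth")]
}

#' Group TARs into transcript units via read-pair bridges
#'
#' Two TARs join one unit when at least one pair has one mate overlapping
#' the first and the other mate overlapping the second (single-linkage).
#' Units whose total TAR length is not greater than `min_len` or whose mean
#' depth over TAR bases is below `min_mean_depth` are dropped.
#'
#' @param tars tibble from [detect_tars()].
#' @param pairs pair tibble from [filter_pairs()].
#' @param coverage RleList used for the mean-depth criterion.
#' @param min_len minimum total length, exclusive (default 150 bp).
#' @param min_mean_depth minimum mean reads per base (default 10).
#' @return tibble: unit_id, chrom, span_start, span_end, n_tars, length,
#'   mean_depth, tar_ids (list).
#' @export
link_units <- function(tars, pairs, coverage, min_len = 150L,
                       min_mean_depth = 10) {
  if (nrow(tars) == 0) {
    return(tibble::tibble(unit_id = character(), chrom = character(),
                          span_start = integer(), span_end = integer(),
                          n_tars = integer(), length = integer(),
                          mean_depth = numeric(), tar_ids = list()))
  }
  tgr <- GenomicRanges::GRanges(tars$chrom,
                                IRanges::IRanges(tars$start, tars$end))
  edges <- matrix(integer(0), ncol = 2)
  if (nrow(pairs)) {
    mate_tars <- function(blist) {
      nb <- vapply(blist, nrow, integer(1))
      g <- GenomicRanges::GRanges(
        rep(pairs$chrom, nb),
        IRanges::IRanges(unlist(lapply(blist, function(b) b[, 1])),
                         unlist(lapply(blist, function(b) b[, 2]))))
      hit <- GenomicRanges::findOverlaps(g, tgr)
      unique(data.frame(
        pair = rep(seq_along(blist), nb)[S4Vectors::queryHits(hit)],
        tar = S4Vectors::subjectHits(hit)))
    }
    d1 <- mate_tars(pairs$blocks1)
    d2 <- mate_tars(pairs$blocks2)
    hits <- merge(d1, d2, by = "pair")
    hits <- unique(hits[hits$tar.x != hits$tar.y, c("tar.x", "tar.y")])
    if (nrow(hits)) edges <- as.matrix(hits)
  }
  comp <- union_find(nrow(tars), edges)
  tars$unit <- comp
  units <- tars %>%
    dplyr::group_by(.data$unit) %>%
    dplyr::summarise(chrom = .data$chrom[1],
                     span_start = min(.data$start),
                     span_end = max(.data$end),
                     n_tars = dplyr::n(),
                     length = sum(.data$width),
                     mean_depth = sum(.data$mean_depth * .data$width) /
                       sum(.data$width),
                     tar_ids = list(.data$tar_id),
                     .groups = "drop") %>%
    dplyr::filter(.data$length > min_len,
                  .data$mean_depth >= min_mean_depth) %>%
    dplyr::arrange(.data$chrom, .data$span_start)
  units$unit_id <- sprintf("tu%05d", seq_len(nrow(units)))
  units[, c("unit_id", "chrom", "span_start", "span_end", "n_tars",
            "length", "mean_depth", "tar_ids")]
}

blocks_to_ir <- function(blocks) IRanges::IRanges(blocks[, 1], blocks[, 2])
ir_to_blocks <- function(ir) cbind(start = IRanges::start(ir),
                                   end = IRanges::end(ir))

# merge sorted block matrices, coalescing touching/overlapping blocks
merge_blocks <- function(...) {
  b <- do.call(rbind, list(...))
  dimnames(b) <- NULL
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  s <- b[, 1]; e <- b[, 2]
  keep_s <- s[1]; out_s <- integer(0); out_e <- integer(0)
  cur_s <- s[1]; cur_e <- e[1]
  for (k in seq_along(s)[-1]) {
    if (s[k] <= cur_e + 1L) {
      cur_e <- max(cur_e, e[k])
    } else {
      out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
      cur_s <- s[k]; cur_e <- e[k]
    }
  }
  cbind(start = c(out_s, cur_s), end = c(out_e, cur_e))
}

clip_blocks <- function(b, lo, hi) {
  s <- pmax(b[, 1], lo); e <- pmin(b[, 2], hi)
  k <- s <= e
  cbind(s[k], e[k])
}

#' Build artificial reads spanning mate intervals
#'
#' Overlapping mates are merged into one read. For a non-negative interval
#' shorter than 5 kb with no catalogued junction inside, the interval bases
#' are filled as exonic; with exactly one junction inside and interval
#' minus junction length below `max_fill`, the junction is embedded as a
#' skip; otherwise the mates pass through individually.
#'
#' @param pairs pair tibble from [filter_pairs()].
#' @param sjs junction tibble (the finalized catalog).
#' @param max_fill threshold on interval length minus junction length
#'   (default 85 bp).
#' @return tibble of reads: read_id, chrom, blocks (list), source
#'   ("artificial" or "mate").
#' @export
make_artificial_reads <- function(pairs, sjs, max_fill = 85L) {
  nmax <- nrow(pairs) * 2L
  acc <- list(read_id = character(nmax), chrom = character(nmax),
              blocks = vector("list", nmax), source = character(nmax))
  i <- 0L
  push <- function(chrom, blocks, src, id) {
    i <<- i + 1L
    acc$read_id[i] <<- id; acc$chrom[i] <<- chrom
    acc$blocks[[i]] <<- blocks; acc$source[i] <<- src
  }
  for (r in seq_len(nrow(pairs))) {
    ch <- pairs$chrom[r]
    b1 <- pairs$blocks1[[r]]; b2 <- pairs$blocks2[[r]]
    itv <- pairs$interval_length[r]
    pid <- pairs$pair_id[r]
    if (itv < 0) {
      push(ch, merge_blocks(b1, b2), "artificial", paste0(pid, ".m"))
      next
    }
    gap_s <- b1[nrow(b1), 2] + 1L
    gap_e <- b2[1, 1] - 1L
    inside <- sjs$chrom == ch & sjs$intron_start >= gap_s &
      sjs$intron_end <= gap_e
    n_in <- sum(inside)
    if (n_in == 0) {
      gapb <- if (itv > 0) cbind(gap_s, gap_e) else NULL
      push(ch, merge_blocks(b1, b2, gapb), "artificial", paste0(pid, ".a"))
    } else if (n_in == 1 &&
               itv - (sjs$intron_end[inside] - sjs$intron_start[inside] + 1L) <
                 max_fill) {
      js <- sjs$intron_start[inside]; je <- sjs$intron_end[inside]
      fill <- rbind(
        if (gap_s < js) cbind(gap_s, js - 1L) else NULL,
        if (je < gap_e) cbind(je + 1L, gap_e) else NULL)
      push(ch, merge_blocks(b1, b2, fill), "artificial", paste0(pid, ".j"))
    } else {
      push(ch, b1, "mate", paste0(pid, ".1"))
      push(ch, b2, "mate", paste0(pid, ".2"))
    }
  }
  tibble::as_tibble(lapply(acc, function(x) x[seq_len(i)]))
}

# do two reads agree (same exon/intron structure) within their span overlap?
reads_compatible <- function(b1, b2) {
  lo <- max(b1[1, 1], b2[1, 1])
  hi <- min(b1[nrow(b1), 2], b2[nrow(b2), 2])
  if (lo > hi) return(TRUE)
  c1 <- clip_blocks(b1, lo, hi)
  c2 <- clip_blocks(b2, lo, hi)
  nrow(c1) == nrow(c2) && all(c1 == c2)
}

#' Assemble reads into gene models by overlap chaining
#'
#' Reads chain when their spans share at least one base and their
#' exon/intron structure agrees in the shared region (contradictory
#' junction content blocks chaining, preventing chimeric models). A model's
#' exon blocks are the union of member-read blocks; models shorter than
#' `min_len` covered bases, or with any base supported by fewer than
#' `min_reads` reads, are dropped. Surviving models that overlap are merged
#' into loci, and neighbouring loci at most `link_locus_gap` apart
#' (inclusive) are linked. Since a locus is the overlap-closure of its
#' models, any two models of one locus are already connected through
#' overlaps, so no separate within-locus linking distance is needed.
#'
#' @param reads tibble from [make_artificial_reads()].
#' @param min_len minimum covered length (default 100).
#' @param min_reads minimum per-base read support (default 2).
#' @param link_locus_gap inclusive locus-linking distance (default 10 bp).
#' @return tibble of models: model_id, chrom, blocks (list), length,
#'   n_reads, span_start, span_end.
#' @export
assemble_models <- function(reads, min_len = 100L, min_reads = 2L,
                            link_locus_gap = 10L) {
  models <- list()
  for (ch in unique(reads$chrom)) {
    rd <- reads[reads$chrom == ch, , drop = FALSE]
    bl <- rd$blocks
    spans <- IRanges::IRanges(
      vapply(bl, function(x) x[1, 1], numeric(1)),
      vapply(bl, function(x) x[nrow(x), 2], numeric(1)))
    hit <- IRanges::findOverlaps(spans, spans)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    sel <- qh < sh
    qh <- qh[sel]; sh <- sh[sel]
    ok <- vapply(seq_along(qh), function(k) {
      reads_compatible(bl[[qh[k]]], bl[[sh[k]]])
    }, logical(1))
    comp <- union_find(length(bl), cbind(qh[ok], sh[ok]))
    for (cc in unique(comp)) {
      member <- which(comp == cc)
      allb <- blocks_to_ir(do.call(rbind, bl[member]))
      cov <- IRanges::coverage(allb)
      blocks <- IRanges::reduce(allb, min.gapwidth = 1L)
      covered <- sum(IRanges::width(blocks))
      minsup <- min(vapply(seq_along(blocks), function(i) {
        min(S4Vectors::decode(
          cov[IRanges::start(blocks)[i]:IRanges::end(blocks)[i]]))
      }, numeric(1)))
      if (covered < min_len || minsup < min_reads) next
      sp_s <- min(IRanges::start(blocks))
      sp_e <- max(IRanges::end(blocks))
      models[[length(models) + 1L]] <- tibble::tibble(
        chrom = ch, blocks = list(ir_to_blocks(blocks)),
        length = covered, n_reads = length(member),
        span_start = sp_s, span_end = sp_e)
    }
  }
  models <- dplyr::bind_rows(models)
  if (nrow(models) == 0) {
    return(tibble::tibble(model_id = character(), chrom = character(),
                          blocks = list(), length = integer(),
                          n_reads = integer(), span_start = integer(),
                          span_end = integer()))
  }
  # merge overlapping models into loci, then link neighbouring loci
  for (gap in c(-1L, link_locus_gap)) {
    sp <- GenomicRanges::GRanges(models$chrom,
                                 IRanges::IRanges(models$span_start,
                                                  models$span_end))
    hit <- GenomicRanges::findOverlaps(sp, sp, maxgap = gap)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    sel <- qh < sh
    comp <- union_find(nrow(models), cbind(qh[sel], sh[sel]))
    models$grp <- comp
    models <- models %>%
      dplyr::group_by(.data$chrom, .data$grp) %>%
      dplyr::summarise(
        blocks = list(ir_to_blocks(IRanges::reduce(
          do.call(c, lapply(.data$blocks, blocks_to_ir)),
          min.gapwidth = 1L))),
        length = sum(vapply(.data$blocks, function(b)
          sum(b[, 2] - b[, 1] + 1L), integer(1))),
        n_reads = sum(.data$n_reads),
        span_start = min(.data$span_start),
        span_end = max(.data$span_end), .groups = "drop") %>%
      dplyr::select(-"grp") %>%
      dplyr::mutate(length = vapply(.data$blocks, function(b)
        as.integer(sum(b[, 2] - b[, 1] + 1L)), integer(1)))
  }
  models <- models %>% dplyr::arrange(.data$chrom, .data$span_start)
  models$model_id <- sprintf("m%05d", seq_len(nrow(models)))
  models[, c("model_id", "chrom", "blocks", "length", "n_reads",
             "span_start", "span_end")]
}

# longest ORF in one nucleotide string, scanning the 3 forward frames;
# returns aa length (start codon included, stop excluded), completeness,
# and the protein sequence
scan_orfs_forward <- function(nt) {
  L <- nchar(nt)
  best <- list(aa = 0L, complete = FALSE, has_start = FALSE,
               has_stop = FALSE, protein = NA_character_, frame = NA_integer_)
  if (L < 3) return(best)
  codon_at <- function(p) substr(nt, p, p + 2L)
  for (f in 0:2) {
    starts_at <- seq.int(1L + f, L - 2L, by = 3L)
    codons <- vapply(starts_at, codon_at, character(1))
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    # segment boundaries between stops
    seg_start <- 1L
    idx_stops <- c(which(is_stop), length(codons) + 1L)
    for (sp in idx_stops) {
      seg <- seq.int(seg_start, sp - 1L)
      if (length(seg)) {
        atgs <- seg[is_atg[seg]]
        has_stop <- sp <= length(codons)
        cand_start <- if (length(atgs)) atgs[1] else NA_integer_
        if (!is.na(cand_start)) {
          aa <- sp - cand_start
          if (aa > best$aa) {
            prot <- paste(vapply(
              seq.int(cand_start, sp - 1L),
              function(i) GENETIC_CODE_1[[codons[i]]], character(1)),
              collapse = "")
            best <- list(aa = aa, complete = has_stop, has_start = TRUE,
                         has_stop = has_stop, protein = prot, frame = f + 1L)
          }
        }
      }
      seg_start <- sp + 1L
    }
  }
  best
}

GENETIC_CODE_1 <- as.list(Biostrings::GENETIC_CODE)

#' Find the longest open reading frame of each model
#'
#' Scans the spliced exon sequence in all six frames (three when the
#' strand is fixed by an embedded junction found in the catalog): every
#' start codon is combined with the nearest in-frame stop codon and the
#' longest coding sequence is kept. A model is coding when the longest ORF
#' exceeds `min_aa` amino acids, and complete when bounded by both a start
#' and a stop codon within the model.
#'
#' @param models tibble from [assemble_models()].
#' @param genome DNAStringSet.
#' @param sjs optional junction catalog used to fix strand from embedded
#'   skips.
#' @param min_aa coding threshold, exclusive (default 30 aa).
#' @return models with cds_aa, cds_complete, cds_strand, coding, protein
#'   columns.
#' @export
find_longest_orf <- function(models, genome, sjs = NULL, min_aa = 30L) {
  n <- nrow(models)
  res <- vector("list", n)
  for (r in seq_len(n)) {
    b <- models$blocks[[r]]
    ch <- models$chrom[r]
    fwd <- paste(slice_seq(genome, ch, b[, 1], b[, 2], "+"), collapse = "")
    strand_fixed <- NA_character_
    if (!is.null(sjs) && nrow(b) > 1) {
      gaps <- cbind(b[-nrow(b), 2] + 1L, b[-1, 1] - 1L)
      for (k in seq_len(nrow(gaps))) {
        m <- sjs$chrom == ch & sjs$intron_start == gaps[k, 1] &
          sjs$intron_end == gaps[k, 2]
        if (any(m)) strand_fixed <- sjs$strand[which(m)[1]]
      }
    }
    cand <- list()
    if (is.na(strand_fixed) || strand_fixed == "+") {
      cand$`+` <- scan_orfs_forward(fwd)
    }
    if (is.na(strand_fixed) || strand_fixed == "-") {
      cand$`-` <- scan_orfs_forward(revcomp(fwd))
    }
    aa <- vapply(cand, function(x) x$aa, integer(1))
    pick <- names(cand)[which.max(aa)]
    bb <- cand[[pick]]
    res[[r]] <- tibble::tibble(cds_aa = bb$aa, cds_complete = bb$complete,
                               cds_strand = pick,
                               coding = bb$aa > min_aa,
                               protein = bb$protein)
  }
  dplyr::bind_cols(models, dplyr::bind_rows(res))
}

#' Screen assembled models against reference annotations
#'
#' Drops models whose span overlaps any reference model by more than
#' `max_ref_overlap` bases, and models overlapping structural-RNA
#' annotations (rRNA/tRNA) by any amount.
#'
#' @param models tibble from [assemble_models()].
#' @param reference tibble with chrom, start, end (gene rows).
#' @param structural_rna tibble with chrom, start, end, or NULL.
#' @param max_ref_overlap retained models overlap references by at most
#'   this many bases (default 10).
#' @return the retained models.
#' @export
screen_against_reference <- function(models, reference = NULL,
                                     structural_rna = NULL,
                                     max_ref_overlap = 10L) {
  if (nrow(models) == 0) return(models)
  sp <- GenomicRanges::GRanges(models$chrom,
                               IRanges::IRanges(models$span_start,
                                                models$span_end))
  drop <- rep(FALSE, nrow(models))
  if (!is.null(reference) && nrow(reference)) {
    rg <- GenomicRanges::GRanges(reference$chrom,
                                 IRanges::IRanges(reference$start,
                                                  reference$end))
    hit <- GenomicRanges::findOverlaps(sp, rg)
    ovw <- IRanges::width(IRanges::pintersect(
      sp[S4Vectors::queryHits(hit)], rg[S4Vectors::subjectHits(hit)]))
    drop[unique(S4Vectors::queryHits(hit)[ovw > max_ref_overlap])] <- TRUE
  }
  if (!is.null(structural_rna) && nrow(structural_rna)) {
    sg <- GenomicRanges::GRanges(structural_rna$chrom,
                                 IRanges::IRanges(structural_rna$start,
                                                  structural_rna$end))
    hit <- GenomicRanges::findOverlaps(sp, sg)
    drop[unique(S4Vectors::queryHits(hit))] <- TRUE
  }
  models[!drop, , drop = FALSE]
}
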