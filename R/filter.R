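#' Anchor-trimming policy
#'
#' @param min_anchor minimum terminal-anchor length kept (bp).
#' @param junction_window distance from a read end to a candidate junction
#'   boundary that triggers the proximity trim (bp).
#' @param min_total_anchor the proximity trim applies only when the
#'   terminal anchor is longer than this (bp).
#' @export
anchor_policy <- function(min_anchor = 5L, junction_window = 6L,
                          min_total_anchor = 12L) {
  stopifnot(min_anchor >= 0, junction_window >= 0, min_total_anchor >= 0)
  list(min_anchor = as.integer(min_anchor),
       junction_window = as.integer(junction_window),
       min_total_anchor = as.integer(min_total_anchor))
}

# strand implied by the splice dinucleotides of one reference skip;
# `gch` is the genome as a named character vector (one string per chrom)
skip_strand <- function(gch, chrom, gap_start, gap_end) {
  if (gap_end - gap_start + 1 < 4) return(NA_character_)
  pair <- paste0(substr(gch[[chrom]], gap_start, gap_start + 1L), "-",
                 substr(gch[[chrom]], gap_end - 1L, gap_end))
  if (pair %in% c("GT-AG", "GC-AG", "AT-AC")) return("+")
  if (pair %in% c("CT-AC", "CT-GC", "GT-AT")) return("-")
  NA_character_
}

# per-reference-position read bases for one mate (names are ref positions)
ref_base_map <- function(blocks, seq) {
  if (is.na(seq) || seq == "*" || seq == "") return(NULL)
  refpos <- unlist(apply(blocks, 1, function(b) b[1]:b[2], simplify = FALSE))
  bases <- strsplit(seq, "")[[1]]
  if (length(bases) < length(refpos)) return(NULL)
  stats::setNames(bases[seq_along(refpos)], refpos)
}

#' Filter raw spliced paired-end alignments
#'
#' Keeps uniquely mapped pairs (exactly one alignment per mate) on one
#' chromosome with an inter-mate interval shorter than 5 kb. Overlapping
#' mates (negative interval) are kept only when their alignments agree in
#' the overlap — identical aligned reference positions and, when sequence
#' is available, identical bases. Transcript strand is inferred from the
#' splice dinucleotides of reference skips; pairs whose mates imply
#' opposite strands are rejected. Malformed records are skipped with a
#' warning and tallied.
#'
#' @param alignments tibble from [read_sam_alignments()].
#' @param genome named DNAStringSet (for dinucleotide strand inference).
#' @param max_interval pairs with interval_length at or above this are
#'   rejected (default 5000).
#' @return list with `pairs` (tibble: pair_id, sample, chrom, strand,
#'   blocks1, blocks2, ori1, ori2, interval_length) and `tally` (tibble:
#'   reason, n).
#' @export
filter_pairs <- function(alignments, genome, max_interval = 5000L) {
  tally <- c(malformed = 0L, not_unique_pair = 0L, different_chrom = 0L,
             interval = 0L, overlap_contradiction = 0L,
             strand_conflict = 0L, kept = 0L)
  bad <- is.na(alignments$pos) | is.na(alignments$cigar) |
    is.na(alignments$chrom) | vapply(alignments$blocks, is.null, logical(1))
  if (any(bad)) {
    warn(sprintf("skipping %d malformed alignment records", sum(bad)))
    tally["malformed"] <- sum(bad)
    alignments <- alignments[!bad, , drop = FALSE]
  }
  nmax <- length(unique(alignments$qname))
  acc <- list(pair_id = character(nmax), sample = character(nmax),
              chrom = character(nmax), strand = character(nmax),
              blocks1 = vector("list", nmax), blocks2 = vector("list", nmax),
              ori1 = character(nmax), ori2 = character(nmax),
              interval_length = integer(nmax))
  i <- 0L
  gch <- as.character(genome)
  v_qname <- alignments$qname; v_sample <- alignments$sample
  v_chrom <- alignments$chrom; v_blocks <- alignments$blocks
  v_seq <- alignments$seq; v_first <- alignments$first_mate
  v_ms <- alignments$mate_strand
  for (grp in split(seq_len(nrow(alignments)), v_qname)) {
    if (length(grp) != 2 || sum(v_first[grp]) != 1) {
      tally["not_unique_pair"] <- tally["not_unique_pair"] + 1L
      next
    }
    if (v_chrom[grp[1]] != v_chrom[grp[2]]) {
      tally["different_chrom"] <- tally["different_chrom"] + 1L
      next
    }
    # order mates left to right on the reference
    ord <- grp[order(vapply(v_blocks[grp], function(b) b[1, 1], numeric(1)))]
    b1 <- v_blocks[[ord[1]]]; b2 <- v_blocks[[ord[2]]]
    interval <- b2[1, 1] - b1[nrow(b1), 2] - 1L
    if (interval >= max_interval) {
      tally["interval"] <- tally["interval"] + 1L
      next
    }
    if (interval < 0) {
      ov_lo <- b2[1, 1]; ov_hi <- min(b1[nrow(b1), 2], b2[nrow(b2), 2])
      ir1 <- IRanges::IRanges(b1[, 1], b1[, 2])
      ir2 <- IRanges::IRanges(b2[, 1], b2[, 2])
      ov <- IRanges::IRanges(ov_lo, ov_hi)
      c1 <- IRanges::intersect(ir1, ov); c2 <- IRanges::intersect(ir2, ov)
      agree <- identical(IRanges::start(c1), IRanges::start(c2)) &&
        identical(IRanges::end(c1), IRanges::end(c2))
      if (agree) {
        m1 <- ref_base_map(b1, v_seq[ord[1]])
        m2 <- ref_base_map(b2, v_seq[ord[2]])
        if (!is.null(m1) && !is.null(m2)) {
          shared <- intersect(names(m1), names(m2))
          agree <- all(m1[shared] == m2[shared])
        }
      }
      if (!agree) {
        tally["overlap_contradiction"] <- tally["overlap_contradiction"] + 1L
        next
      }
    }
    # transcript strand from splice dinucleotides of each skip
    strands <- unlist(lapply(list(b1, b2), function(b) {
      if (nrow(b) < 2) return(character(0))
      vapply(seq_len(nrow(b) - 1L), function(k) {
        skip_strand(gch, v_chrom[grp[1]], b[k, 2] + 1L, b[k + 1L, 1] - 1L)
      }, character(1))
    }))
    strands <- unique(strands[!is.na(strands)])
    if (length(strands) > 1) {
      tally["strand_conflict"] <- tally["strand_conflict"] + 1L
      next
    }
    i <- i + 1L
    acc$pair_id[i] <- v_qname[grp[1]]; acc$sample[i] <- v_sample[grp[1]]
    acc$chrom[i] <- v_chrom[grp[1]]
    acc$strand[i] <- if (length(strands) == 1) strands else "unknown"
    acc$blocks1[[i]] <- b1; acc$blocks2[[i]] <- b2
    acc$ori1[i] <- v_ms[ord[1]]; acc$ori2[i] <- v_ms[ord[2]]
    acc$interval_length[i] <- interval
  }
  tally["kept"] <- i
  pairs <- tibble::as_tibble(lapply(acc, function(x) x[seq_len(i)]))
  list(pairs = pairs,
       tally = tibble::tibble(reason = names(tally), n = unname(tally)))
}

# drop terminal blocks shorter than min_anchor, to a fixed point
drop_short_terminals <- function(blocks, min_anchor) {
  repeat {
    if (is.null(blocks) || nrow(blocks) == 0) return(NULL)
    w <- blocks[, 2] - blocks[, 1] + 1L
    if (w[1] < min_anchor) {
      blocks <- blocks[-1, , drop = FALSE]
    } else if (w[nrow(blocks)] < min_anchor) {
      blocks <- blocks[-nrow(blocks), , drop = FALSE]
    } else {
      return(blocks)
    }
  }
}

# trim bases of a terminal block that fall inside a candidate intron when
# the junction boundary sits within `window` of the read end and the
# terminal anchor is longer than `min_total`
trim_junction_proximal <- function(blocks, ori, cands, window, min_total) {
  if (is.null(blocks) || nrow(blocks) == 0 || nrow(cands) == 0) return(blocks)
  left <- blocks[1, ]; right <- blocks[nrow(blocks), ]
  # which genomic side holds the read's 5' end
  p5_side <- if (ori == "+") "left" else "right"
  acc <- ifelse(cands$strand == "+", cands$intron_end, cands$intron_start)
  don <- ifelse(cands$strand == "+", cands$intron_start, cands$intron_end)
  trim_left <- 0L; trim_right <- 0L
  for (k in seq_len(nrow(cands))) {
    js <- cands$intron_start[k]; je <- cands$intron_end[k]
    # left read end inside the intron, boundary within `window` of it
    if (js <= left[1] && left[1] <= je) {
      over <- je - left[1] + 1L
      bound_is_acc <- acc[k] == je
      side_is_5p <- p5_side == "left"
      if (over <= window && over < left[2] - left[1] + 1L &&
          ((bound_is_acc && side_is_5p) || (!bound_is_acc && !side_is_5p))) {
        trim_left <- max(trim_left, over)
      }
    }
    if (js <= right[2] && right[2] <= je) {
      over <- right[2] - js + 1L
      bound_is_acc <- acc[k] == js
      side_is_5p <- p5_side == "right"
      if (over <= window && over < right[2] - right[1] + 1L &&
          ((bound_is_acc && side_is_5p) || (!bound_is_acc && !side_is_5p))) {
        trim_right <- max(trim_right, over)
      }
    }
  }
  if (trim_left > 0 && left[2] - left[1] + 1L > min_total) {
    blocks[1, 1] <- blocks[1, 1] + trim_left
  }
  if (trim_right > 0 &&
      blocks[nrow(blocks), 2] - blocks[nrow(blocks), 1] + 1L > min_total) {
    blocks[nrow(blocks), 2] <- blocks[nrow(blocks), 2] - trim_right
  }
  blocks
}

#' Trim unreliable terminal anchors from filtered pairs
#'
#' Two corrections against alignment error at read ends: terminal aligned
#' blocks shorter than `min_anchor` are removed outright; and when a
#' candidate junction's acceptor lies within `junction_window` of a read's
#' 5' end (or its donor within `junction_window` of the 3' end), the read
#' bases falling inside the intron are trimmed, provided the terminal
#' anchor is longer than `min_total_anchor`. A mate trimmed to nothing is
#' dropped (tallied); the operation is idempotent.
#'
#' @param pairs pair tibble from [filter_pairs()].
#' @param sj_candidates tibble of candidate junctions (chrom, intron_start,
#'   intron_end, strand); may be empty.
#' @param policy an [anchor_policy()].
#' @return list with `pairs` and `n_mates_dropped`.
#' @export
trim_anchors <- function(pairs, sj_candidates = NULL, policy = anchor_policy()) {
  if (is.null(sj_candidates)) {
    sj_candidates <- tibble::tibble(chrom = character(),
                                    intron_start = integer(),
                                    intron_end = integer(),
                                    strand = character())
  }
  dropped <- 0L
  n <- nrow(pairs)
  keep <- rep(TRUE, n)
  bl1 <- pairs$blocks1; bl2 <- pairs$blocks2
  ori1 <- pairs$ori1; ori2 <- pairs$ori2
  chv <- pairs$chrom; itv <- pairs$interval_length
  cand_by_chrom <- split(sj_candidates, sj_candidates$chrom)
  for (r in seq_len(n)) {
    cands <- cand_by_chrom[[chv[r]]]
    if (is.null(cands)) cands <- sj_candidates[0, , drop = FALSE]
    fix <- function(blocks, ori) {
      b <- drop_short_terminals(blocks, policy$min_anchor)
      if (is.null(b)) return(NULL)
      b <- trim_junction_proximal(b, ori, cands, policy$junction_window,
                                  policy$min_total_anchor)
      drop_short_terminals(b, policy$min_anchor)
    }
    b1 <- fix(bl1[[r]], ori1[r])
    b2 <- fix(bl2[[r]], ori2[r])
    if (is.null(b1) || is.null(b2)) {
      dropped <- dropped + is.null(b1) + is.null(b2)
      keep[r] <- FALSE
      next
    }
    bl1[[r]] <- b1
    bl2[[r]] <- b2
    itv[r] <- b2[1, 1] - b1[nrow(b1), 2] - 1L
  }
  pairs$blocks1 <- bl1
  pairs$blocks2 <- bl2
  pairs$interval_length <- itv
  list(pairs = pairs[keep, , drop = FALSE], n_mates_dropped = dropped)
}
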