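#' Extract splice junctions from filtered alignment pairs
#'
#' One junction per distinct (chrom, strand, intron span) with pooled
#' support of at least `min_support` read pairs; a pair supports a junction
#' once even if both mates span it. Strand is taken from the pair's
#' inferred strand where known, else from the boundary dinucleotides.
#'
#' @param pairs filtered pair tibble from [filter_pairs()] (after
#'   [trim_anchors()]).
#' @param genome named DNAStringSet.
#' @param min_support minimum pooled read-pair support (default 2).
#' @return junction tibble: sj_id, chrom, strand, intron_start, intron_end,
#'   donor_dinucleotide, acceptor_dinucleotide, intron_seq, support_pooled
#'   and one reads_<sample> column per sample.
#' @export
extract_junctions <- function(pairs, genome, min_support = 2L) {
  gaps_of <- function(blocks) {
    if (is.null(blocks) || nrow(blocks) < 2) return(NULL)
    cbind(blocks[-nrow(blocks), 2] + 1L, blocks[-1, 1] - 1L)
  }
  n <- nrow(pairs)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    g <- unique(rbind(gaps_of(pairs$blocks1[[r]]),
                      gaps_of(pairs$blocks2[[r]])))
    if (is.null(g) || nrow(g) == 0) next
    rows[[r]] <- data.frame(chrom = pairs$chrom[r], intron_start = g[, 1],
                            intron_end = g[, 2], strand = pairs$strand[r],
                            sample = pairs$sample[r])
  }
  obs <- dplyr::bind_rows(rows)
  if (nrow(obs) == 0) {
    return(empty_junctions())
  }
  counts <- obs %>%
    dplyr::count(.data$chrom, .data$intron_start, .data$intron_end,
                 .data$strand, .data$sample, name = "reads")
  junctions_from_counts(counts, genome, min_support = min_support)
}

empty_junctions <- function() {
  tibble::tibble(sj_id = character(), chrom = character(),
                 strand = character(), intron_start = integer(),
                 intron_end = integer(), donor_dinucleotide = character(),
                 acceptor_dinucleotide = character(), intron_seq = character(),
                 support_pooled = integer())
}

#' Build a junction table from a per-sample count table
#'
#' The count-table route to the catalog: aggregates per-sample reads into
#' pooled support, applies the support threshold, resolves strand from the
#' boundary dinucleotides when the table's strand is missing, and extracts
#' the intron sequence in transcription orientation.
#'
#' @param counts tibble: chrom, intron_start, intron_end, strand, sample,
#'   reads (strand may be NA to request dinucleotide inference).
#' @inheritParams extract_junctions
#' @export
junctions_from_counts <- function(counts, genome, min_support = 2L) {
  wide <- counts %>%
    dplyr::group_by(.data$chrom, .data$intron_start, .data$intron_end,
                    .data$strand, .data$sample) %>%
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "reads",
                       names_prefix = "reads_", values_fill = 0L)
  rcol <- grep("^reads_", names(wide), value = TRUE)
  wide$support_pooled <- as.integer(rowSums(wide[, rcol, drop = FALSE]))
  wide <- wide %>% dplyr::filter(.data$support_pooled >= min_support)
  if (nrow(wide) == 0) return(empty_junctions())
  if (any(!fits_chrom(genome, wide$chrom, wide$intron_start,
                      wide$intron_end))) {
    abort("intron span exceeds chromosome bounds")
  }
  fwd <- slice_seq(genome, wide$chrom, wide$intron_start, wide$intron_end, "+")
  d_f <- substr(fwd, 1, 2); a_f <- substr(fwd, nchar(fwd) - 1, nchar(fwd))
  canon_f <- paste0(d_f, "-", a_f) %in% c("GT-AG", "GC-AG", "AT-AC")
  # reverse-complement boundary pairs seen on the forward strand
  canon_r <- paste0(d_f, "-", a_f) %in% c("CT-AC", "CT-GC", "GT-AT")
  strand <- wide$strand
  missing_strand <- is.na(strand) | strand == "*" | strand == "."
  strand[missing_strand] <- ifelse(canon_r[missing_strand] &
                                     !canon_f[missing_strand], "-", "+")
  seqs <- fwd
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(fwd[neg])
  out <- wide
  out$strand <- strand
  out$intron_seq <- seqs
  out$donor_dinucleotide <- substr(seqs, 1, 2)
  out$acceptor_dinucleotide <- substr(seqs, nchar(seqs) - 1, nchar(seqs))
  out <- out %>%
    dplyr::arrange(.data$chrom, .data$intron_start, .data$intron_end,
                   .data$strand)
  out$sj_id <- sprintf("sj%06d", seq_len(nrow(out)))
  out %>%
    dplyr::select("sj_id", "chrom", "strand", "intron_start", "intron_end",
                  "donor_dinucleotide", "acceptor_dinucleotide", "intron_seq",
                  "support_pooled", dplyr::all_of(rcol))
}

# ---- branch site -----------------------------------------------------------

iupac_to_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", N = "[ACGT]", W = "[AT]", S = "[CG]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
           V = "[ACG]")
  paste(map[strsplit(toupper(motif), "")[[1]]], collapse = "")
}

# all start positions of overlapping regex matches
regex_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Locate the branch point within an intron sequence
#'
#' Hierarchical motif search in DNA alphabet (U = T): the 3'-most instance
#' of the primary motif CURAY; failing that, the 3'-most instance of the
#' secondary motif (default UURAY, configurable); failing that, the 3'-most
#' instance of the degenerate YURAY family in which the first, third or
#' fifth position may be any base (NURAY, YUNAY, YURAN). The branch point
#' is the A at the fourth motif position. The search never consumes the
#' final two intron bases (the acceptor dinucleotide).
#'
#' @param intron_seq character vector of intron sequences (A/C/G/T/N).
#' @param secondary_motif IUPAC string for the second search tier.
#' @return tibble with one row per input: branch_pos (1-based intron
#'   position of the branch A, NA when no tier matched), branch_offset3
#'   (distance to the intron 3' end), motif_tier, motif_seq, window_seq
#'   (11 bases, NA where it would leave the intron).
#' @export
find_branch_site <- function(intron_seq, secondary_motif = "TTRAY") {
  primary <- "CT[AG]A[CT]"
  secondary <- iupac_to_regex(secondary_motif)
  alternate <- "([ACGT]T[AG]A[CT]|[CT]T[ACGT]A[CT]|[CT]T[AG]A[ACGT])"
  one <- function(seq) {
    seq <- toupper(chartr("U", "T", seq))
    L <- nchar(seq)
    if (is.na(seq) || L < 5) {
      return(list(pos = NA_integer_, tier = NA_character_,
                  motif = NA_character_))
    }
    lim <- L - 2L  # last allowed match end: spare the acceptor dinucleotide
    for (tier in c("primary", "secondary", "alternate")) {
      pat <- switch(tier, primary = primary, secondary = secondary,
                    alternate = alternate)
      st <- regex_starts(seq, pat)
      st <- st[st + 4L <= lim]
      if (length(st)) {
        s <- max(st)
        return(list(pos = s + 3L, tier = tier,
                    motif = substr(seq, s, s + 4L)))
      }
    }
    list(pos = NA_integer_, tier = NA_character_, motif = NA_character_)
  }
  res <- lapply(intron_seq, one)
  pos <- vapply(res, function(x) x$pos, integer(1))
  L <- nchar(intron_seq)
  win <- ifelse(!is.na(pos) & pos - 6L >= 1L & pos + 4L <= L,
                substr(intron_seq, pos - 6L, pos + 4L), NA_character_)
  tibble::tibble(
    branch_pos = pos,
    branch_offset3 = ifelse(is.na(pos), NA_integer_, L - pos),
    motif_tier = vapply(res, function(x) x$tier, character(1)),
    motif_seq = vapply(res, function(x) x$motif, character(1)),
    window_seq = win)
}

# ---- polypyrimidine tract --------------------------------------------------

#' Locate the polypyrimidine tract within an intron sequence
#'
#' A tract is six consecutive non-adenine bases containing at least three
#' T; among qualifying windows those with the maximal T count are kept and
#' the 3'-most of these is reported. The tract is assigned to the region
#' 5' of the branch point or between branch point and 3'ss by its own
#' 3'-most base (a window can never contain the branch A itself, since the
#' branch base is an A).
#'
#' @param intron_seq character vector of intron sequences.
#' @param branch_pos 1-based intron position of the branch A (NA if none).
#' @return tibble: ppt_start (1-based window start, NA if no tract),
#'   ppt_seq, ppt_t_count, ppt_region (five_to_branch / branch_to_three /
#'   no_branch).
#' @export
find_ppt <- function(intron_seq, branch_pos = NA_integer_) {
  n <- length(intron_seq)
  branch_pos <- rep_len(branch_pos, n)
  one <- function(seq, bp) {
    seq <- toupper(chartr("U", "T", seq))
    L <- nchar(seq)
    if (is.na(seq) || L < 6) {
      return(list(start = NA_integer_, seq = NA_character_,
                  t = NA_integer_, region = NA_character_))
    }
    ch <- strsplit(seq, "")[[1]]
    ok_base <- ch %in% c("C", "G", "T")
    is_t <- ch == "T"
    starts <- seq_len(L - 5L)
    runs_ok <- vapply(starts, function(i) all(ok_base[i:(i + 5L)]),
                      logical(1))
    tc <- vapply(starts, function(i) sum(is_t[i:(i + 5L)]), integer(1))
    cand <- starts[runs_ok & tc >= 3L]
    if (!length(cand)) {
      return(list(start = NA_integer_, seq = NA_character_,
                  t = NA_integer_, region = NA_character_))
    }
    best_t <- max(tc[cand])
    cand <- cand[tc[cand] == best_t]
    i <- max(cand)
    region <- if (is.na(bp)) "no_branch" else if (i + 5L < bp) {
      "five_to_branch"
    } else "branch_to_three"
    list(start = i, seq = substr(seq, i, i + 5L), t = best_t,
         region = region)
  }
  res <- purrr::map2(intron_seq, branch_pos, one)
  tibble::tibble(
    ppt_start = vapply(res, function(x) x$start, integer(1)),
    ppt_seq = vapply(res, function(x) x$seq, character(1)),
    ppt_t_count = vapply(res, function(x) x$t, integer(1)),
    ppt_region = vapply(res, function(x) x$region, character(1)))
}

#' Annotate a junction table with branch sites and tracts
#'
#' @param sjs junction tibble (needs intron_seq).
#' @param secondary_motif see [find_branch_site()].
#' @return the tibble with branch and PPT columns appended.
#' @export
annotate_junctions <- function(sjs, secondary_motif = "TTRAY") {
  br <- find_branch_site(sjs$intron_seq, secondary_motif = secondary_motif)
  ppt <- find_ppt(sjs$intron_seq, br$branch_pos)
  dplyr::bind_cols(
    sjs %>% dplyr::select(-dplyr::any_of(c(names(br), names(ppt)))),
    br, ppt)
}

# ---- refinement ------------------------------------------------------------

# same-length overlapping junction pairs with starts closer than `shift`
overlap_pair_candidates <- function(sjs, shift) {
  x <- sjs %>%
    dplyr::mutate(.row = dplyr::row_number(),
                  .len = .data$intron_end - .data$intron_start + 1L)
  dplyr::inner_join(
    x %>% dplyr::select(".row", ".len", "chrom", "strand",
                        s = "intron_start", e = "intron_end"),
    x %>% dplyr::select(.row2 = ".row", ".len", "chrom", "strand",
                        s2 = "intron_start", e2 = "intron_end"),
    by = c("chrom", "strand", ".len"),
    relationship = "many-to-many") %>%
    dplyr::filter(.data$.row < .data$.row2,
                  abs(.data$s - .data$s2) < shift,
                  .data$s <= .data$e2, .data$s2 <= .data$e)
}

#' Refine a junction catalog
#'
#' Applies, in order: removal of junctions with no branch site; removal of
#' junctions whose branch point lies more than `max_branch_offset` bases
#' from the 3'ss; correction of same-length overlapping junction pairs
#' whose starts differ by fewer than `overlap_shift` bases (these are
#' alignment artefacts — the member with the lower donor-site score is
#' deleted and its support added to the survivor, using matrices built on
#' the branch-filtered, pre-correction set); and removal of junctions whose
#' intron sequence contains an N. Ties on donor score are broken by higher
#' pooled support, then by the 5'-most start, so the result is
#' permutation-invariant.
#'
#' @param sjs annotated junction tibble (from [annotate_junctions()]).
#' @param genome DNAStringSet (for donor-site scoring).
#' @param max_branch_offset maximal branch-A-to-3'ss distance kept.
#' @param overlap_shift start-distance threshold of the correction rule.
#' @return list with `junctions` (refined, with final scores rebuilt on the
#'   corrected set) and `report` (one-row tibble: n_input, n_no_branch,
#'   n_branch_too_far, n_overlap_corrected, n_n_excluded, n_final).
#' @export
refine_junctions <- function(sjs, genome, max_branch_offset = 60L,
                             overlap_shift = 10L) {
  n_input <- nrow(sjs)
  keep <- !is.na(sjs$branch_pos)
  n_no_branch <- sum(!keep)
  sjs <- sjs[keep, , drop = FALSE]

  too_far <- sjs$branch_offset3 > max_branch_offset
  n_branch_too_far <- sum(too_far)
  sjs <- sjs[!too_far, , drop = FALSE]

  # pre-correction donor scores on the branch-filtered set
  n_overlap <- 0L
  if (nrow(sjs) > 1) {
    win <- extract_site_windows(sjs, genome)
    mat5 <- build_one_matrix(win$five_seq[win$five_ok])
    sc5 <- rep(NA_real_, nrow(sjs))
    ok <- win$five_ok & !grepl("[^ACGT]", win$five_seq)
    sc5[ok] <- score_window(win$five_seq[ok], mat5)
    cand <- overlap_pair_candidates(sjs, overlap_shift)
    if (nrow(cand)) {
      # union-find over candidate pairs
      parent <- seq_len(nrow(sjs))
      findp <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
      }
      for (k in seq_len(nrow(cand))) {
        a <- findp(cand$.row[k]); b <- findp(cand$.row2[k])
        if (a != b) parent[b] <- a
      }
      comp <- vapply(seq_len(nrow(sjs)), findp, integer(1))
      rcol <- grep("^reads_", names(sjs), value = TRUE)
      drop_rows <- integer(0)
      for (cc in unique(comp[duplicated(comp) | duplicated(comp, fromLast = TRUE)])) {
        rows <- which(comp == cc)
        sc <- sc5[rows]
        sc[is.na(sc)] <- -Inf
        best <- rows[order(-sc, -sjs$support_pooled[rows],
                           sjs$intron_start[rows])][1]
        losers <- setdiff(rows, best)
        sjs$support_pooled[best] <- sjs$support_pooled[best] +
          sum(sjs$support_pooled[losers])
        for (col in rcol) {
          sjs[[col]][best] <- sjs[[col]][best] + sum(sjs[[col]][losers])
        }
        drop_rows <- c(drop_rows, losers)
      }
      n_overlap <- length(drop_rows)
      if (n_overlap) sjs <- sjs[-drop_rows, , drop = FALSE]
    }
  }

  has_n <- grepl("N", sjs$intron_seq, fixed = TRUE)
  n_n_excluded <- sum(has_n)
  sjs <- sjs[!has_n, , drop = FALSE]

  report <- tibble::tibble(
    n_input = n_input, n_no_branch = n_no_branch,
    n_branch_too_far = n_branch_too_far, n_overlap_corrected = n_overlap,
    n_n_excluded = n_n_excluded, n_final = nrow(sjs))
  stopifnot(report$n_final == report$n_input - report$n_no_branch -
              report$n_branch_too_far - report$n_overlap_corrected -
              report$n_n_excluded)

  # final scores are rebuilt on the corrected set
  if (nrow(sjs)) {
    scored <- score_junctions(sjs, genome)
    sjs <- scored$junctions
    attr(sjs, "matrices") <- scored$matrices
  }
  list(junctions = sjs, report = report)
}
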