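#' Extract splice-site windows for a junction table
#'
#' Windows are taken in transcription orientation, anchored on the
#' exon-intron boundaries and the branch-point A: the donor (5'ss) window
#' is 13 bases (3 exonic + 10 intronic), the acceptor (3'ss) window is 17
#' bases (14 intronic + 3 exonic), and the branch window is 11 bases (6
#' upstream of the branch A, the A, 4 downstream). Only the branch window
#' may extend past the intron boundary into flanking sequence. Introns
#' shorter than a window's intronic span, or windows running off the
#' chromosome, are flagged unscorable for that window.
#'
#' @param sjs junction tibble with columns sj_id, chrom, strand,
#'   intron_start, intron_end (1-based inclusive) and, unless
#'   `branch_offset3` is supplied, a `branch_offset3` column (distance from
#'   the branch A to the intron 3' end; NA when no branch was found).
#' @param genome named DNAStringSet.
#' @param branch_offset3 optional vector overriding the column.
#' @return tibble: sj_id, five_seq, three_seq, branch_seq and logical
#'   five_ok, three_ok, branch_ok flags.
#' @export
extract_site_windows <- function(sjs, genome, branch_offset3 = NULL) {
  n <- nrow(sjs)
  bo3 <- branch_offset3 %||% sjs[["branch_offset3"]] %||% rep(NA_integer_, n)
  len <- sjs$intron_end - sjs$intron_start + 1L
  pos <- sjs$strand == "+"

  g1 <- ifelse(pos, sjs$intron_start - 3L, sjs$intron_end - 9L)
  g2 <- ifelse(pos, sjs$intron_start + 9L, sjs$intron_end + 3L)
  five_ok <- len >= 10L & fits_chrom(genome, sjs$chrom, g1, g2)
  five_seq <- rep(NA_character_, n)
  if (any(five_ok)) {
    five_seq[five_ok] <- slice_seq(genome, sjs$chrom[five_ok], g1[five_ok],
                                   g2[five_ok], sjs$strand[five_ok])
  }

  h1 <- ifelse(pos, sjs$intron_end - 13L, sjs$intron_start - 3L)
  h2 <- ifelse(pos, sjs$intron_end + 3L, sjs$intron_start + 13L)
  three_ok <- len >= 14L & fits_chrom(genome, sjs$chrom, h1, h2)
  three_seq <- rep(NA_character_, n)
  if (any(three_ok)) {
    three_seq[three_ok] <- slice_seq(genome, sjs$chrom[three_ok], h1[three_ok],
                                     h2[three_ok], sjs$strand[three_ok])
  }

  bpos <- len - bo3                      # branch A, intron position
  bg <- ifelse(pos, sjs$intron_start + bpos - 1L, sjs$intron_end - bpos + 1L)
  b1 <- ifelse(pos, bg - 6L, bg - 4L)
  b2 <- ifelse(pos, bg + 4L, bg + 6L)
  branch_ok <- !is.na(bo3) & fits_chrom(genome, sjs$chrom,
                                        ifelse(is.na(b1), 1L, b1),
                                        ifelse(is.na(b2), 1L, b2))
  branch_seq <- rep(NA_character_, n)
  if (any(branch_ok)) {
    branch_seq[branch_ok] <- slice_seq(genome, sjs$chrom[branch_ok],
                                       b1[branch_ok], b2[branch_ok],
                                       sjs$strand[branch_ok])
  }

  tibble::tibble(sj_id = sjs$sj_id, five_seq = five_seq,
                 three_seq = three_seq, branch_seq = branch_seq,
                 five_ok = five_ok, three_ok = three_ok,
                 branch_ok = branch_ok)
}

#' Build position frequency and log-odds matrices
#'
#' Frequencies are plain counts over total per column (no pseudocount); the
#' log-odds matrix is the base-2 log of frequency over a 0.25 background,
#' so a zero frequency yields a `-Inf` sentinel and any sequence hitting it
#' scores `-Inf` (flagged downstream, never silently replaced).
#'
#' @param windows either a window tibble from [extract_site_windows()] or a
#'   character vector of equal-length sequences.
#' @return for a tibble input, a named list (`five`, `three`, `branch`) of
#'   `pwm` objects; for a character vector, one `pwm` object with elements
#'   `freq` and `log_odds` (rows A, T, G, C).
#' @export
build_matrices <- function(windows) {
  if (is.character(windows)) return(build_one_matrix(windows))
  out <- list(
    five = build_one_matrix(windows$five_seq[windows$five_ok]),
    three = build_one_matrix(windows$three_seq[windows$three_ok]),
    branch = build_one_matrix(windows$branch_seq[windows$branch_ok]))
  out
}

build_one_matrix <- function(seqs) {
  seqs <- seqs[!is.na(seqs) & !grepl("[^ACGT]", seqs)]
  if (length(seqs) == 0) abort("no scorable windows to build a matrix from")
  if (length(unique(nchar(seqs))) != 1) {
    abort("windows of unequal length")
  }
  x <- Biostrings::DNAStringSet(seqs)
  cm <- Biostrings::consensusMatrix(x, baseOnly = TRUE)
  freq <- cm[c("A", "T", "G", "C"), , drop = FALSE] / length(x)
  structure(list(freq = freq, log_odds = log2(freq / 0.25),
                 n = length(x)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", ncol(x$freq), "positions, built from", x$n, "windows\n")
  print(round(x$log_odds, 2))
  invisible(x)
}

#' Score a sequence window against a log-odds matrix
#'
#' The raw score is the positional sum of matrix entries for the observed
#' bases (no rescaling). Sequences hitting a zero-frequency (`-Inf`)
#' sentinel return `-Inf`.
#'
#' @param seq character vector of sequences, each exactly as long as the
#'   matrix has columns; bases must be A/C/G/T.
#' @param matrix a `pwm` object (or bare log-odds matrix with rows
#'   A, T, G, C).
#' @return numeric vector of raw scores (bits).
#' @export
score_window <- function(seq, matrix) {
  lom <- if (inherits(matrix, "pwm")) matrix$log_odds else matrix
  L <- ncol(lom)
  if (any(nchar(seq) != L)) abort("sequence length does not match matrix")
  if (any(grepl("[^ACGT]", seq))) {
    abort("sequences must contain only A/C/G/T (N-containing junctions are excluded upstream)")
  }
  m <- matrix(unlist(strsplit(seq, "")), ncol = L, byrow = TRUE)
  idx <- matrix(match(m, rownames(lom)), ncol = L)
  sc <- vapply(seq_along(seq), function(i) {
    sum(lom[cbind(idx[i, ], seq_len(L))])
  }, numeric(1))
  sc
}

#' Score the three site windows of every junction
#'
#' @param windows tibble from [extract_site_windows()].
#' @param matrices list of `pwm` objects from [build_matrices()].
#' @return tibble: sj_id, five_score, three_score, branch_score (NA where
#'   the window was unscorable, -Inf where a sentinel was hit).
#' @export
score_junction_windows <- function(windows, matrices) {
  one <- function(seqs, ok, mat) {
    out <- rep(NA_real_, length(seqs))
    use <- ok & !is.na(seqs) & !grepl("[^ACGT]", seqs)
    if (any(use)) out[use] <- score_window(seqs[use], mat)
    out
  }
  tibble::tibble(
    sj_id = windows$sj_id,
    five_score = one(windows$five_seq, windows$five_ok, matrices$five),
    three_score = one(windows$three_seq, windows$three_ok, matrices$three),
    branch_score = one(windows$branch_seq, windows$branch_ok,
                       matrices$branch))
}

#' Tidy a set of site matrices for export
#'
#' @param matrices list of `pwm` objects from [build_matrices()].
#' @return tibble: site_type, base, position, frequency, log_odds.
#' @export
matrices_to_tibble <- function(matrices) {
  purrr::imap(matrices, function(m, nm) {
    f <- m$freq
    tibble::tibble(
      site_type = nm,
      base = rep(rownames(f), ncol(f)),
      position = rep(seq_len(ncol(f)), each = nrow(f)),
      frequency = as.vector(f),
      log_odds = as.vector(m$log_odds))
  }) %>% dplyr::bind_rows()
}

#' Rebuild matrices from a junction table and attach scores
#'
#' Builds the three matrices from all scorable windows of `sjs` (the
#' all-junction matrix avoids zero frequencies without pseudocounts) and
#' scores every junction against them.
#'
#' @param sjs annotated junction tibble (needs branch_offset3).
#' @param genome DNAStringSet.
#' @return list with `junctions` (scores merged in) and `matrices`.
#' @export
score_junctions <- function(sjs, genome) {
  win <- extract_site_windows(sjs, genome)
  mats <- build_matrices(win)
  sc <- score_junction_windows(win, mats)
  sjs <- sjs %>%
    dplyr::select(-dplyr::any_of(c("five_score", "three_score",
                                   "branch_score"))) %>%
    dplyr::left_join(sc, by = "sj_id")
  list(junctions = sjs, matrices = mats)
}
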