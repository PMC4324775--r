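# Independent brute-force oracles. These deliberately re-derive results by
# direct enumeration (position-by-position scans, all-pairs comparisons,
# codon-by-codon translation) so they share no code path with the package.

base_in <- function(ch, set) ch %in% set

# exhaustive branch-site scan: check every 5-mer against the tier
# definitions, honouring the terminal-dinucleotide exclusion
oracle_branch <- function(seq, secondary = "TTRAY") {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  if (L < 5) return(NULL)
  R <- c("A", "G"); Y <- c("C", "T"); N <- c("A", "C", "G", "T")
  sec <- strsplit(secondary, "")[[1]]
  sec_sets <- lapply(sec, function(s) switch(s, R = R, Y = Y, N = N,
                                             U = "T", s))
  match_at <- function(i, sets) {
    all(vapply(1:5, function(k) base_in(ch[i + k - 1], sets[[k]]),
               logical(1)))
  }
  tiers <- list(
    primary = list("C", "T", R, "A", Y),
    secondary = sec_sets,
    alternate = NULL)
  lim <- L - 2L
  for (tier in c("primary", "secondary", "alternate")) {
    hit <- NA_integer_
    for (i in seq_len(L - 4L)) {
      if (i + 4L > lim) break
      ok <- if (tier == "alternate") {
        match_at(i, list(N, "T", R, "A", Y)) ||
          match_at(i, list(Y, "T", N, "A", Y)) ||
          match_at(i, list(Y, "T", R, "A", N))
      } else {
        match_at(i, tiers[[tier]])
      }
      if (ok) hit <- i
    }
    if (!is.na(hit)) {
      return(list(pos = hit + 3L, tier = tier,
                  motif = substr(seq, hit, hit + 4L)))
    }
  }
  NULL
}

# exhaustive PPT scan: every 6-window, no A (or N), >= 3 T, maximal T,
# 3'-most
oracle_ppt <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  if (L < 6) return(NULL)
  best <- NULL
  for (i in seq_len(L - 5L)) {
    w <- ch[i:(i + 5L)]
    if (all(w %in% c("C", "G", "T")) && sum(w == "T") >= 3) {
      if (is.null(best) || sum(w == "T") > best$t ||
          (sum(w == "T") == best$t && i > best$start)) {
        best <- list(start = i, t = sum(w == "T"),
                     seq = paste(w, collapse = ""))
      }
    }
  }
  best
}

# pairwise event label from first principles on coordinates
oracle_pair <- function(s1, e1, s2, e2, strand) {
  if (e1 < s2 || e2 < s1) return("disjoint")
  don <- function(s, e) if (strand == "+") s else e
  acc <- function(s, e) if (strand == "+") e else s
  if (acc(s1, e1) == acc(s2, e2)) return("A5SS")
  if (don(s1, e1) == don(s2, e2)) return("A3SS")
  nested <- (s1 < s2 && e2 < e1) || (s2 < s1 && e1 < e2)
  if (nested) "A5SS_AND_A3SS" else "A5SS_OR_A3SS"
}

# multi-junction cluster label by direct rule evaluation
oracle_multi <- function(spans, strand) {
  k <- nrow(spans)
  don <- if (strand == "+") spans[, 1] else spans[, 2]
  acc <- if (strand == "+") spans[, 2] else spans[, 1]
  if (length(unique(acc)) == 1) return(sprintf("MA5SS(%d)", k))
  if (length(unique(don)) == 1) return(sprintf("MA3SS(%d)", k))
  if (k == 3) {
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    for (p in perms) {
      a <- p[1]; b <- p[2]; m <- p[3]
      disj <- spans[a, 2] < spans[b, 1] || spans[b, 2] < spans[a, 1]
      if (disj && don[m] == don[a] && acc[m] == acc[b]) {
        return("EXON_SKIPPING")
      }
    }
  }
  "COMPLEX"
}

# six-frame longest-ORF by naive codon walking over both strands;
# aa counts the start codon and every codon before the stop (or the last
# complete codon when no stop exists)
oracle_orf <- function(nt) {
  rc <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  best <- list(aa = 0L, complete = FALSE)
  for (s in c(nt, rc(nt))) {
    L <- nchar(s)
    if (L < 3) next
    for (f in 0:2) {
      i <- 1L + f
      while (i + 2L <= L) {
        if (substr(s, i, i + 2L) == "ATG") {
          j <- i
          complete <- FALSE
          while (j + 2L <= L) {
            if (substr(s, j, j + 2L) %in% stops) {
              complete <- TRUE
              break
            }
            j <- j + 3L
          }
          aa <- if (complete) (j - i) %/% 3L else (L - i + 1L) %/% 3L
          if (aa > best$aa) best <- list(aa = aa, complete = complete)
        }
        i <- i + 3L
      }
    }
  }
  best
}

random_intron <- function(len, prob = c(.3, .2, .2, .3)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}
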