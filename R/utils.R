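#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

# One reproducible stream per (module, seed): the stream seed is derived from
# the module name so adding draws in one module never perturbs another.
stream_seed <- function(seed, module) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

with_stream <- function(seed, module, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, module))
  force(code)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# strand-aware genomic slice, 1-based inclusive, returned in transcription
# orientation. `genome` is a DNAStringSet keyed by chromosome name.
slice_seq <- function(genome, chrom, start, end, strand = "+") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  widths <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(is.na(widths))) abort("unknown chromosome in slice_seq()")
  if (any(start < 1 | end > widths | start > end)) {
    abort("slice outside chromosome bounds")
  }
  out <- as.character(Biostrings::subseq(genome[chrom], start, end))
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  unname(out)
}

# TRUE where [s,e] (still 1-based inclusive) fits on its chromosome
fits_chrom <- function(genome, chrom, start, end) {
  widths <- Biostrings::width(genome)[match(chrom, names(genome))]
  !is.na(widths) & start >= 1 & end <= widths & start <= end
}

gc_fraction <- function(seq) {
  s <- Biostrings::DNAStringSet(seq)
  f <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  unname(rowSums(f) / Biostrings::width(s))
}

# median with the even-count convention fixed to the mean of the central pair
median2 <- function(x) stats::median(as.numeric(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
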