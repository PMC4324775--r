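#' Specification objects for the synthetic splicing simulator
#'
#' The simulator emulates a compact, intron-dense fungal genome: short
#' introns (median 72 bp by default), GT..AG boundaries with a small
#' configurable noncanonical rate, a CURAY-family branch motif 11-18 bp
#' from the 3' splice site, and pyrimidine-biased acceptor regions. Every
#' planted structure is recorded in a truth set so downstream recovery can
#' be measured.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param gc_background GC fraction of intergenic background sequence.
#' @param seed integer seed; every simulator stage draws from its own
#'   stream derived from this seed.
#' @return a list of class `genome_spec`.
#' @export
genome_spec <- function(n_chroms = 3L, chrom_length = 200000L,
                        gc_background = 0.5, seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_length >= 1000,
            gc_background > 0, gc_background < 1)
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 gc_background = gc_background, seed = as.integer(seed)),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @param n_genes number of genes to place.
#' @param exons_per_gene function(n) returning exon counts (>= 2 for any
#'   gene that should host introns).
#' @param exon_length function(n) returning exon lengths (bp, >= 60).
#' @param intron_length_median median of the (lognormal) intron length
#'   distribution; the default 72 bp matches short fungal introns.
#' @param intron_length_sdlog log-scale spread of intron lengths.
#' @param intron_gc GC fraction of intron interiors.
#' @param consensus_strength in (0, 1]: how faithfully splice-site windows
#'   follow the full-strength position profiles (1 = profile itself,
#'   0 = uniform). Donor/acceptor dinucleotides and the branch core are
#'   always emitted as valid instances.
#' @param p_gc_ag,p_at_ac per-intron probabilities of the noncanonical
#'   GC-AG / AT-AC boundary pairs.
#' @export
gene_spec <- function(n_genes = 200L,
                      exons_per_gene = function(n) sample(2:5, n, replace = TRUE),
                      exon_length = function(n) sample(70:220, n, replace = TRUE),
                      intron_length_median = 72,
                      intron_length_sdlog = 0.45,
                      intron_gc = 0.49,
                      consensus_strength = 0.9,
                      p_gc_ag = 0.017, p_at_ac = 0.005) {
  stopifnot(n_genes >= 1, intron_length_median >= 30,
            consensus_strength > 0, consensus_strength <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = exons_per_gene, exon_length = exon_length,
                 intron_length_median = intron_length_median,
                 intron_length_sdlog = intron_length_sdlog,
                 intron_gc = intron_gc,
                 consensus_strength = consensus_strength,
                 p_gc_ag = p_gc_ag, p_at_ac = p_at_ac),
            class = "gene_spec")
}

#' @rdname genome_spec
#' @param class_fractions named numeric summing to 1 over the event
#'   taxonomy (IC, IR, A5SS, A3SS, A5SS_AND_A3SS, A5SS_OR_A3SS, MA5SS,
#'   MA3SS). The default is the cluster composition observed in deep
#'   fungal RNA-seq.
#' @param irr_distribution function(n) drawing planted intron-retention
#'   ratios; the default lognormal reproduces the observed IRR bin
#'   fractions (about a third below 0.01, two thirds below 0.1).
#' @param usage_link_beta coefficient linking splice-site score difference
#'   (bits) to the log odds of isoform usage.
#' @export
event_spec <- function(class_fractions = c(
                         IC = 0.238348, IR = 0.711174,
                         A5SS = 0.012676, A3SS = 0.022924,
                         A5SS_AND_A3SS = 0.001442, A5SS_OR_A3SS = 0.001139,
                         MA5SS = 0.000987, MA3SS = 0.002125),
                       irr_distribution = function(n)
                         stats::rlnorm(n, meanlog = log(0.036), sdlog = 2.93),
                       usage_link_beta = 1.0) {
  class_fractions <- class_fractions / sum(class_fractions)
  known <- c("IC", "IR", "A5SS", "A3SS", "A5SS_AND_A3SS", "A5SS_OR_A3SS",
             "MA5SS", "MA3SS")
  if (!all(names(class_fractions) %in% known)) {
    abort("unknown event class in class_fractions")
  }
  structure(list(class_fractions = class_fractions,
                 irr_distribution = irr_distribution,
                 usage_link_beta = usage_link_beta),
            class = "event_spec")
}

#' @rdname genome_spec
#' @param junction_depth_mean mean read support per junction cluster per
#'   sample.
#' @param n_samples number of samples (libraries); the default 2 emulates
#'   a rich-medium / induction-medium pair.
#' @param coverage_noise negative-binomial overdispersion (variance =
#'   mu + noise * mu^2); 0 gives Poisson-like counts.
#' @param emit_sam also synthesize minimal spliced paired-end alignments
#'   consistent with the junction counts (read length 75).
#' @export
read_sim_spec <- function(junction_depth_mean = 50, n_samples = 2L,
                          coverage_noise = 0.1, emit_sam = FALSE,
                          seed = 1L) {
  stopifnot(junction_depth_mean > 0, n_samples >= 1)
  structure(list(junction_depth_mean = junction_depth_mean,
                 n_samples = as.integer(n_samples),
                 coverage_noise = coverage_noise, emit_sam = emit_sam,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

# ---- site profiles ---------------------------------------------------------

# Full-strength per-position base probabilities for the three site windows.
# Rows A,C,G,T. The acceptor's intronic region suppresses A so that planted
# branch points stay the 3'-most CURAY instance; flanking degeneracy is kept
# moderate so that splice-site scores span the informative range of the
# logistic usage link rather than its saturated tails.
site_profile_full <- function(site = c("five", "three", "branch")) {
  site <- match.arg(site)
  col <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
  weakex <- col(.3, .25, .25, .2)
  if (site == "five") {
    # 3 exonic + 10 intronic; positions 4-5 (GT) forced at emission
    m <- cbind(col(.25, .4, .15, .2),   # exonic -3 (C)
               col(.45, .2, .15, .2),   # exonic -2 (A)
               col(.15, .15, .5, .2),   # exonic -1 (G)
               col(0, 0, 1, 0),         # G (forced)
               col(0, 0, 0, 1),         # T (forced)
               col(.55, .1, .2, .15),   # +3 A
               col(.5, .15, .15, .2),   # +4 A
               col(.15, .15, .45, .25), # +5 G
               col(.15, .15, .2, .5),   # +6 T
               col(.2, .2, .2, .4),     # +7 t
               col(.3, .2, .2, .3),     # +8
               col(.2, .25, .2, .35),   # +9
               col(.2, .3, .2, .3))     # +10
  } else if (site == "three") {
    ppt <- col(.03, .29, .16, .52)      # pyrimidine-rich, A suppressed
    m <- cbind(ppt, ppt, ppt, ppt, ppt, ppt, ppt, ppt, ppt, ppt, ppt,
               col(.05, .55, .1, .3),   # -3 C
               col(0, 0, 0, 0),         # A (forced)
               col(0, 0, 0, 0),         # G (forced)
               weakex, weakex, weakex)  # 3 exonic
    m[, 13] <- col(1, 0, 0, 0)
    m[, 14] <- col(0, 0, 1, 0)
  } else {
    flank5 <- col(.2, .25, .2, .35)
    flank3 <- col(.02, .32, .16, .5)    # A suppressed 3' of the branch A
    m <- cbind(flank5, flank5, flank5,
               col(0, 1, 0, 0),         # C (forced)
               col(0, 0, 0, 1),         # T (forced)
               col(.75, 0, .25, 0),     # R, biased A
               col(1, 0, 0, 0),         # branch A (forced)
               col(0, .7, 0, .3),       # Y, biased C
               flank3, flank3, flank3)
  }
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# blend toward uniform by consensus strength, keeping forced columns and the
# branch core (positions 4-8: CURAY must stay a valid instance) intact
site_profile <- function(site, strength) {
  m <- site_profile_full(site)
  keep <- apply(m, 2, function(p) any(p == 1))
  if (site == "branch") keep[4:8] <- TRUE
  out <- strength * m + (1 - strength) * 0.25
  out[, keep] <- m[, keep]
  out
}

sample_window <- function(profile, n = 1) {
  L <- ncol(profile)
  draws <- vapply(seq_len(L), function(j) {
    sample(rownames(profile), n, replace = TRUE, prob = profile[, j])
  }, character(n))
  if (n == 1) paste(draws, collapse = "") else apply(draws, 1, paste, collapse = "")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# The genome is manipulated as a list of per-chromosome character vectors
# (one base per element) while sites are being planted, and converted to a
# DNAStringSet once at the end: in-place slice assignment on vectors is far
# cheaper than repeated XString subsequence replacement.
genome_to_basevec <- function(genome) {
  lapply(stats::setNames(as.character(genome), names(genome)),
         function(s) strsplit(s, "")[[1]])
}

basevec_to_genome <- function(bv) {
  g <- Biostrings::DNAStringSet(vapply(bv, paste, character(1),
                                       collapse = ""))
  names(g) <- names(bv)
  g
}

# Patches are collected in an environment and applied per chromosome in one
# vectorized assignment (later patches overwrite earlier ones, preserving
# planting order) — repeated slice assignment would copy the chromosome on
# every call.
new_patchset <- function(chrlen) {
  e <- new.env(parent = emptyenv())
  e$chrlen <- chrlen
  e$patches <- vector("list", 1024L)
  e$n <- 0L
  e
}

# record `seq` (given in transcription orientation) for genomic
# [start, end]; reverse-complemented for "-" strand; off-chromosome
# windows are skipped
patch_window <- function(pw, chrom, start, end, seq, strand) {
  if (strand == "-") seq <- revcomp(seq)
  if (start < 1 || end > pw$chrlen[[chrom]]) return(pw)
  pw$n <- pw$n + 1L
  if (pw$n > length(pw$patches)) {
    pw$patches <- c(pw$patches, vector("list", length(pw$patches)))
  }
  pw$patches[[pw$n]] <- list(chrom = chrom, idx = start:end,
                             chars = strsplit(seq, "")[[1]])
  pw
}

apply_patches <- function(bv, pw) {
  if (pw$n == 0L) return(bv)
  ps <- pw$patches[seq_len(pw$n)]
  chs <- vapply(ps, function(p) p$chrom, character(1))
  for (ch in unique(chs)) {
    sel <- ps[chs == ch]
    idx <- unlist(lapply(sel, `[[`, "idx"), use.names = FALSE)
    chars <- unlist(lapply(sel, `[[`, "chars"), use.names = FALSE)
    v <- bv[[ch]]
    v[idx] <- chars
    bv[[ch]] <- v
  }
  bv
}

# transcription-oriented intron positions -> genomic range
tx_range <- function(s, e, strand, p_from, p_to) {
  if (strand == "+") c(s + p_from - 1L, s + p_to - 1L)
  else c(e - p_to + 1L, e - p_from + 1L)
}

# ---- genome + gene generation ---------------------------------------------

#' Generate a synthetic genome with planted multi-exon genes
#'
#' Places non-overlapping genes on a random background, builds introns with
#' a lognormal length distribution (median `intron_length_median`), and
#' writes donor, acceptor and branch site windows drawn from position
#' profiles into every intron. Returns a `splice_sim` truth object carrying
#' the genome and the complete planted structure.
#'
#' @param genome_spec,gene_spec see [genome_spec()] and [gene_spec()].
#' @return object of class `splice_sim`: list with `genome`
#'   (DNAStringSet), `genes`, `exons`, `introns` tibbles, and `params`.
#' @export
generate_genome <- function(genome_spec, gene_spec) {
  gs <- genome_spec; ps <- gene_spec
  with_stream(gs$seed, "genome", {
    chroms <- paste0("chr", seq_len(gs$n_chroms))
    gcp <- gs$gc_background
    bv <- lapply(stats::setNames(chroms, chroms), function(x) {
      sample(c("A", "C", "G", "T"), gs$chrom_length, replace = TRUE,
             prob = c((1 - gcp) / 2, gcp / 2, gcp / 2, (1 - gcp) / 2))
    })

    n <- ps$n_genes
    n_ex <- pmax(1L, as.integer(ps$exons_per_gene(n)))
    strands <- sample(c("+", "-"), n, replace = TRUE)

    draw_introns <- function(k) {
      if (k == 0) return(integer(0))
      len <- round(stats::rlnorm(k, log(ps$intron_length_median),
                                 ps$intron_length_sdlog))
      while (any(len < 30)) {
        bad <- len < 30
        len[bad] <- round(stats::rlnorm(sum(bad), log(ps$intron_length_median),
                                        ps$intron_length_sdlog))
      }
      as.integer(len)
    }

    genes <- vector("list", n)
    exons <- vector("list", n)
    introns <- vector("list", n)
    margin <- 150L
    cursor <- stats::setNames(rep(margin + 1L, gs$n_chroms), chroms)
    ci <- 1L
    intron_counter <- 0L
    for (i in seq_len(n)) {
      k <- n_ex[i]
      ex_len <- pmax(60L, as.integer(ps$exon_length(k)))
      in_len <- draw_introns(k - 1L)
      glen <- sum(ex_len) + sum(in_len)
      gap <- sample(150:400, 1)
      placed <- FALSE
      for (try in seq_len(gs$n_chroms)) {
        ch <- chroms[ci]
        if (cursor[ch] + glen + margin <= gs$chrom_length) {
          gstart <- cursor[ch]
          cursor[ch] <- cursor[ch] + glen + gap
          placed <- TRUE
          break
        }
        ci <- ci %% gs$n_chroms + 1L
      }
      if (!placed) {
        abort(sprintf(
          "gene placement failure: chromosomes too small for %d genes", n))
      }
      gid <- sprintf("g%04d", i)
      # exon/intron layout in genomic coordinates
      starts <- integer(k); ends <- integer(k)
      pos <- gstart
      istarts <- integer(max(k - 1L, 0)); iends <- integer(max(k - 1L, 0))
      for (j in seq_len(k)) {
        starts[j] <- pos; ends[j] <- pos + ex_len[j] - 1L
        pos <- ends[j] + 1L
        if (j < k) {
          istarts[j] <- pos; iends[j] <- pos + in_len[j] - 1L
          pos <- iends[j] + 1L
        }
      }
      genes[[i]] <- tibble::tibble(
        gene_id = gid, chrom = ch, strand = strands[i],
        start = gstart, end = pos - 1L, n_exons = k)
      exons[[i]] <- tibble::tibble(
        gene_id = gid, exon_rank = seq_len(k), chrom = ch,
        strand = strands[i], start = starts, end = ends)
      if (k > 1L) {
        ids <- sprintf("i%05d", intron_counter + seq_len(k - 1L))
        intron_counter <- intron_counter + k - 1L
        introns[[i]] <- tibble::tibble(
          intron_id = ids, gene_id = gid, chrom = ch, strand = strands[i],
          start = istarts, end = iends, length = in_len)
      }
      ci <- ci %% gs$n_chroms + 1L
    }
    genes <- dplyr::bind_rows(genes)
    exons <- dplyr::bind_rows(exons)
    introns <- dplyr::bind_rows(introns)

    # intron interiors at intron GC, then site windows
    prof5 <- site_profile("five", ps$consensus_strength)
    prof3 <- site_profile("three", ps$consensus_strength)
    profb <- site_profile("branch", ps$consensus_strength)

    if (nrow(introns)) {
      introns$branch_offset3 <- sample(11:18, nrow(introns), replace = TRUE)
      u <- stats::runif(nrow(introns))
      introns$site_pair <- ifelse(u < ps$p_at_ac, "AT-AC",
                           ifelse(u < ps$p_at_ac + ps$p_gc_ag, "GC-AG",
                                  "GT-AG"))
      pw <- new_patchset(vapply(bv, length, integer(1)))
      for (r in seq_len(nrow(introns))) {
        it <- introns[r, ]
        pw <- patch_window(pw, it$chrom, it$start, it$end,
                           random_dna(it$length, ps$intron_gc), "+")
        pw <- plant_sites(pw, it$chrom, it$start, it$end, it$strand,
                          it$branch_offset3, it$site_pair,
                          prof5, prof3, profb)
      }
      bv <- apply_patches(bv, pw)
    } else {
      introns$branch_offset3 <- integer(0)
      introns$site_pair <- character(0)
    }

    genome <- basevec_to_genome(bv)
    structure(list(genome = genome, genes = genes, exons = exons,
                   introns = introns, junctions = NULL, events = NULL,
                   params = list(genome_spec = gs, gene_spec = ps)),
              class = "splice_sim")
  })
}

# Plant donor window (3 exonic + 10 intronic), acceptor window (14 intronic
# + 3 exonic), then the branch window so its core survives any overlap.
# All coordinates are transcription-oriented intron positions 1..L.
plant_sites <- function(pw, chrom, s, e, strand, d3, site_pair,
                        prof5, prof3, profb, donor_at = 1L, acc_at = NULL) {
  L <- e - s + 1L
  acc_at <- acc_at %||% L  # intron position of the acceptor's last base
  w5 <- sample_window(prof5)
  pair <- strsplit(site_pair, "-")[[1]]
  substr(w5, 4, 5) <- pair[1]
  r5 <- tx_range(s, e, strand, donor_at - 3L, donor_at + 9L)
  pw <- patch_window(pw, chrom, r5[1], r5[2], w5, strand)

  w3 <- sample_window(prof3)
  substr(w3, 13, 14) <- pair[2]
  r3 <- tx_range(s, e, strand, acc_at - 13L, acc_at + 3L)
  pw <- patch_window(pw, chrom, r3[1], r3[2], w3, strand)

  wb <- sample_window(profb)  # core CTRAY always valid by construction
  bpos <- acc_at - d3         # branch A intron position
  rb <- tx_range(s, e, strand, bpos - 6L, bpos + 4L)
  patch_window(pw, chrom, rb[1], rb[2], wb, strand)
}

# ---- event planting --------------------------------------------------------

# minimum intron length needed to host a class
class_min_len <- function(class, k = 3L) {
  switch(class,
         IC = 30L, IR = 30L,
         A5SS = 50L, A5SS_OR_A3SS = 50L,
         A3SS = 65L, A5SS_AND_A3SS = 75L,
         MA5SS = 35L + 10L + 13L * (k - 1L),
         MA3SS = 35L + 25L * (k - 1L),
         30L)
}

#' Plant alternative-splicing events into a synthetic truth set
#'
#' Selects introns for each taxonomy class, patches alternative donor /
#' acceptor (and, where needed, branch) sites into the genome, and draws
#' isoform usage as logistic in `usage_link_beta` times the difference in
#' splice-site scores, where scores come from log-odds matrices built from
#' all planted site windows. Planted IRRs are attached to IR introns.
#'
#' @param sim a `splice_sim` from [generate_genome()].
#' @param event_spec see [event_spec()].
#' @return the `splice_sim` with `junctions` and `events` tibbles filled
#'   and the genome patched.
#' @export
plant_events <- function(sim, event_spec) {
  stopifnot(inherits(sim, "splice_sim"))
  es <- event_spec
  seed <- sim$params$genome_spec$seed
  ps <- sim$params$gene_spec
  with_stream(seed, "events", {
    introns <- sim$introns
    n <- nrow(introns)
    if (n == 0) abort("no introns to plant events on")
    fr <- es$class_fractions
    target <- floor(fr * n)
    rem <- n - sum(target)
    if (rem > 0) {
      extra <- order(fr * n - target, decreasing = TRUE)[seq_len(rem)]
      target[extra] <- target[extra] + 1L
    }
    # assign hardest (longest-requirement) classes first
    classes <- names(target)[target > 0]
    classes <- classes[order(vapply(classes, class_min_len, integer(1), k = 4L),
                             decreasing = TRUE)]
    assignment <- rep(NA_character_, n)
    pool <- sample.int(n)  # random order, one stream
    for (cl in classes) {
      need <- target[[cl]]
      if (cl == "IC") next
      elig <- pool[is.na(assignment[pool]) &
                     introns$length[pool] >= class_min_len(cl, k = 4L)]
      if (length(elig) < need) {
        abort(sprintf(
          "cannot plant %d %s events: only %d introns long enough",
          need, cl, length(elig)))
      }
      assignment[elig[seq_len(need)]] <- cl
    }
    assignment[is.na(assignment)] <- "IC"
    introns$class <- assignment

    prof5 <- site_profile("five", ps$consensus_strength)
    prof3 <- site_profile("three", ps$consensus_strength)
    profb <- site_profile("branch", ps$consensus_strength)
    pw <- new_patchset(stats::setNames(Biostrings::width(sim$genome),
                                       names(sim$genome)))

    jrows <- vector("list", n)
    for (r in seq_len(n)) {
      it <- introns[r, ]
      L <- it$length; s <- it$start; e <- it$end; st <- it$strand
      cl <- it$class
      base <- tibble::tibble(
        event_id = it$intron_id, gene_id = it$gene_id, chrom = it$chrom,
        strand = st, class = cl, isoform = 1L, role = "original",
        tx_donor = 1L, tx_acc = L, branch_offset3 = it$branch_offset3)
      alts <- NULL
      mk_alt <- function(iso, a, acc, d3) tibble::tibble(
        event_id = it$intron_id, gene_id = it$gene_id, chrom = it$chrom,
        strand = st, class = cl, isoform = iso, role = "alt",
        tx_donor = a, tx_acc = acc, branch_offset3 = d3)
      if (cl == "A5SS") {
        a <- sample(10:min(40L, L - 35L), 1) + 1L  # alt intron starts here
        pw <- plant_donor(pw, it, a, prof5)
        alts <- mk_alt(2L, a, L, it$branch_offset3)
      } else if (cl == "A3SS") {
        b <- sample(25:min(45L, L - 35L), 1)
        d3 <- sample(11:18, 1)
        pw <- plant_acceptor(pw, it, L - b, d3, prof3, profb)
        alts <- mk_alt(2L, 1L, L - b, d3)
      } else if (cl == "A5SS_AND_A3SS") {
        a <- sample(10:min(30L, L - 60L), 1) + 1L
        b <- sample(25:min(40L, L - a - 34L), 1)
        d3 <- sample(11:18, 1)
        pw <- plant_donor(pw, it, a, prof5)
        pw <- plant_acceptor(pw, it, L - b, d3, prof3, profb)
        alts <- mk_alt(2L, a, L - b, d3)
      } else if (cl == "A5SS_OR_A3SS") {
        a <- sample(10:min(40L, L - 35L), 1) + 1L
        cc <- sample(15:24, 1)  # extension into the downstream exon
        pw <- plant_donor(pw, it, a, prof5)
        pw <- plant_acceptor(pw, it, L + cc, NA_integer_, prof3,
                                 profb, plant_branch = FALSE)
        # the original branch serves the alt junction: offset = cc + d3 <= 60
        alts <- mk_alt(2L, a, L + cc, it$branch_offset3 + cc)
      } else if (cl == "MA5SS") {
        kk <- min(4L, 2L + (L - 35L - 10L) %/% 13L)
        offs <- 10L + 13L * (seq_len(kk - 1L) - 1L) + 1L
        for (a in offs) pw <- plant_donor(pw, it, a, prof5)
        alts <- dplyr::bind_rows(purrr::imap(
          offs, function(a, i) mk_alt(i + 1L, a, L, it$branch_offset3)))
      } else if (cl == "MA3SS") {
        kk <- min(4L, 2L + (L - 35L - 25L) %/% 25L)
        offs <- 25L * seq_len(kk - 1L)
        d3s <- sample(11:18, kk - 1L, replace = TRUE)
        for (i in seq_along(offs)) {
          pw <- plant_acceptor(pw, it, L - offs[i], d3s[i],
                                   prof3, profb)
        }
        alts <- dplyr::bind_rows(purrr::imap(
          offs, function(b, i) mk_alt(i + 1L, 1L, L - b, d3s[i])))
      }
      jrows[[r]] <- dplyr::bind_rows(base, alts)
    }
    junctions <- dplyr::bind_rows(jrows)

    # enforcement pass: donor/acceptor cores can be clobbered by later
    # window patches, so re-write every junction's boundary dinucleotides
    junctions <- junctions %>%
      dplyr::left_join(introns %>%
                         dplyr::select("intron_id", i_start = "start",
                                       i_end = "end", "site_pair"),
                       by = c(event_id = "intron_id")) %>%
      dplyr::mutate(
        start = ifelse(.data$strand == "+",
                       .data$i_start + .data$tx_donor - 1L,
                       .data$i_end - .data$tx_acc + 1L),
        end = ifelse(.data$strand == "+",
                     .data$i_start + .data$tx_acc - 1L,
                     .data$i_end - .data$tx_donor + 1L)) %>%
      dplyr::mutate(start = as.integer(.data$start),
                    end = as.integer(.data$end))
    for (r in seq_len(nrow(junctions))) {
      j <- junctions[r, ]
      pair <- strsplit(j$site_pair, "-")[[1]]
      rd <- if (j$strand == "+") c(j$start, j$start + 1L) else
        c(j$end - 1L, j$end)
      pw <- patch_window(pw, j$chrom, rd[1], rd[2], pair[1], j$strand)
      ra <- if (j$strand == "+") c(j$end - 1L, j$end) else
        c(j$start, j$start + 1L)
      pw <- patch_window(pw, j$chrom, ra[1], ra[2], pair[2], j$strand)
    }
    genome <- basevec_to_genome(
      apply_patches(genome_to_basevec(sim$genome), pw))

    junctions$sj_id <- sprintf("%s.j%d", junctions$event_id,
                               junctions$isoform)

    # usage from the package's own splice-site scores of planted windows
    sim2 <- sim
    sim2$genome <- genome
    scores <- truth_junction_scores(sim2, junctions)
    junctions <- dplyr::left_join(junctions, scores, by = "sj_id")
    junctions <- junctions %>%
      dplyr::group_by(.data$event_id) %>%
      dplyr::mutate(usage = planted_usage(.data$class[1], .data$link_score,
                                          es$usage_link_beta)) %>%
      dplyr::ungroup()

    events <- junctions %>%
      dplyr::group_by(.data$event_id) %>%
      dplyr::summarise(gene_id = .data$gene_id[1], chrom = .data$chrom[1],
                       strand = .data$strand[1], class = .data$class[1],
                       n_isoforms = dplyr::n(),
                       delta_link_score =
                         if (dplyr::n() == 2)
                           .data$link_score[1] - .data$link_score[2]
                         else NA_real_,
                       .groups = "drop")
    irr <- rep(0, nrow(events))
    is_ir <- events$class == "IR"
    irr[is_ir] <- es$irr_distribution(sum(is_ir))
    events$planted_irr <- irr

    sim$genome <- genome
    sim$introns <- introns
    sim$junctions <- junctions %>%
      dplyr::select("sj_id", "event_id", "gene_id", "chrom", "strand",
                    "start", "end", "class", "isoform", "role",
                    "branch_offset3", "site_pair", "usage", "link_score")
    sim$events <- events
    sim$params$event_spec <- es
    sim
  })
}

plant_donor <- function(pw, it, a, prof5) {
  # alternative donor: alt intron begins at transcription position `a`
  w5 <- sample_window(prof5)
  substr(w5, 4, 5) <- "GT"
  r <- tx_range(it$start, it$end, it$strand, a - 3L, a + 9L)
  patch_window(pw, it$chrom, r[1], r[2], w5, it$strand)
}

plant_acceptor <- function(pw, it, acc_at, d3, prof3, profb,
                           plant_branch = TRUE) {
  w3 <- sample_window(prof3)
  substr(w3, 13, 14) <- "AG"
  r <- tx_range(it$start, it$end, it$strand, acc_at - 13L, acc_at + 3L)
  pw <- patch_window(pw, it$chrom, r[1], r[2], w3, it$strand)
  if (plant_branch) {
    wb <- sample_window(profb)
    bpos <- acc_at - d3
    rb <- tx_range(it$start, it$end, it$strand, bpos - 6L, bpos + 4L)
    pw <- patch_window(pw, it$chrom, rb[1], rb[2], wb, it$strand)
  }
  pw
}

# score planted junctions with matrices built from all planted windows;
# link score: 5'ss for A5SS family, 3'ss for A3SS family, sum for combined
truth_junction_scores <- function(sim, junctions) {
  sj <- tibble::tibble(
    sj_id = junctions$sj_id, chrom = junctions$chrom,
    strand = junctions$strand, intron_start = junctions$start,
    intron_end = junctions$end,
    branch_pos3 = junctions$branch_offset3)
  win <- extract_site_windows(sj, sim$genome,
                              branch_offset3 = sj$branch_pos3)
  mats <- build_matrices(win)
  scored <- score_junction_windows(win, mats)
  out <- dplyr::left_join(
    tibble::tibble(sj_id = junctions$sj_id, class = junctions$class),
    scored, by = "sj_id")
  out$link_score <- dplyr::case_when(
    out$class %in% c("A5SS", "MA5SS") ~ out$five_score,
    out$class %in% c("A3SS", "MA3SS") ~ out$three_score,
    out$class %in% c("A5SS_AND_A3SS", "A5SS_OR_A3SS") ~
      out$five_score + out$three_score,
    TRUE ~ 0)
  out$link_score[!is.finite(out$link_score)] <- 0
  out[, c("sj_id", "link_score")]
}

planted_usage <- function(class, link_score, beta) {
  k <- length(link_score)
  if (k == 1) return(1)
  if (k == 2) {
    u1 <- stats::plogis(beta * (link_score[1] - link_score[2]))
    return(c(u1, 1 - u1))
  }
  w <- exp(beta * (link_score - max(link_score)))
  w / sum(w)
}

# ---- sequencing simulation -------------------------------------------------

#' Simulate junction read counts and per-base coverage
#'
#' Per-sample cluster depth is drawn from an overdispersed (negative
#' binomial) distribution around `junction_depth_mean` and apportioned to
#' isoforms by planted usage. Exonic bases get Poisson coverage at the
#' cluster depth; intronic bases of retained introns get Poisson coverage
#' with mean planted IRR times the junction's per-sample support, so the
#' measured retention ratio is centred on the planted one. Optionally emits
#' minimal spliced SAM pairs (read length 75) consistent with the counts.
#'
#' @param sim a planted `splice_sim` (after [plant_events()]).
#' @param read_spec see [read_sim_spec()].
#' @return list with `counts` (tibble: chrom, intron_start, intron_end,
#'   strand, sample, reads, sj_id), `coverage` (list of RleList per
#'   sample), and `sam` (tibble of alignment records or NULL).
#' @export
simulate_sequencing <- function(sim, read_spec) {
  stopifnot(inherits(sim, "splice_sim"))
  if (is.null(sim$junctions)) abort("plant_events() must run first")
  rs <- read_spec
  with_stream(rs$seed, "sequencing", {
    samples <- paste0("s", seq_len(rs$n_samples))
    size <- if (rs$coverage_noise > 0) 1 / rs$coverage_noise else Inf
    jt <- sim$junctions
    ev_ids <- unique(jt$event_id)

    counts <- vector("list", length(ev_ids) * rs$n_samples)
    idx <- 1L
    support <- matrix(0L, nrow = nrow(jt), ncol = rs$n_samples,
                      dimnames = list(jt$sj_id, samples))
    for (ev in ev_ids) {
      rows <- which(jt$event_id == ev)
      usage <- jt$usage[rows]
      for (si in seq_len(rs$n_samples)) {
        total <- if (is.finite(size)) {
          stats::rnbinom(1, mu = rs$junction_depth_mean, size = size)
        } else stats::rpois(1, rs$junction_depth_mean)
        cts <- if (length(rows) == 1) total else
          as.integer(stats::rmultinom(1, total, usage))
        support[rows, si] <- cts
        counts[[idx]] <- tibble::tibble(
          sj_id = jt$sj_id[rows], sample = samples[si], reads = cts)
        idx <- idx + 1L
      }
    }
    counts <- dplyr::bind_rows(counts) %>%
      dplyr::left_join(jt %>% dplyr::select("sj_id", "chrom",
                                            intron_start = "start",
                                            intron_end = "end", "strand"),
                       by = "sj_id") %>%
      dplyr::select("chrom", "intron_start", "intron_end", "strand",
                    "sample", "reads", "sj_id")

    # per-sample coverage
    chrlen <- Biostrings::width(sim$genome)
    coverage <- lapply(seq_len(rs$n_samples), function(si) {
      cov <- lapply(chrlen, function(L) integer(L))
      names(cov) <- names(sim$genome)
      fill <- function(ch, s, e, lambda) {
        if (e < s || lambda <= 0) return()
        v <- stats::rpois(e - s + 1L, lambda)
        cov[[ch]][s:e] <<- cov[[ch]][s:e] + v
      }
      # exon coverage at cluster depth
      for (r in seq_len(nrow(sim$exons))) {
        x <- sim$exons[r, ]
        fill(x$chrom, x$start, x$end, rs$junction_depth_mean)
      }
      # retained-intron coverage: mean = planted IRR x per-sample support
      ir <- sim$events[sim$events$class == "IR", ]
      for (r in seq_len(nrow(ir))) {
        ev <- ir[r, ]
        j <- jt[jt$event_id == ev$event_id, ]
        fill(ev$chrom, j$start[1], j$end[1],
             ev$planted_irr * support[j$sj_id[1], si])
      }
      # alternative regions covered in proportion to isoform usage
      alt <- jt[jt$role == "alt", ]
      for (r in seq_len(nrow(alt))) {
        a <- alt[r, ]
        orig <- jt[jt$event_id == a$event_id & jt$role == "original", ][1, ]
        u <- a$usage * support[orig$sj_id, si] /
          max(1, sum(support[jt$event_id == a$event_id, si]))
        lam <- rs$junction_depth_mean * a$usage
        if (a$start > orig$start) {
          fill(a$chrom, orig$start, a$start - 1L, lam)
        }
        if (a$end < orig$end) fill(a$chrom, a$end + 1L, orig$end, lam)
      }
      methods::as(lapply(cov, S4Vectors::Rle), "SimpleRleList")
    })
    names(coverage) <- samples

    sam <- NULL
    if (isTRUE(rs$emit_sam)) {
      sam <- emit_spliced_sam(sim, counts)
    }
    list(counts = counts, coverage = coverage, sam = sam,
         support = support)
  })
}

# one spliced pair per counted junction read: mate1 spans the junction,
# mate2 is a plain 75M alignment downstream (transcription orientation is
# ignored for flags; the pipeline infers strand from splice dinucleotides)
emit_spliced_sam <- function(sim, counts) {
  chrlen <- Biostrings::width(sim$genome)
  names(chrlen) <- names(sim$genome)
  rl <- 75L
  cts <- counts[counts$reads > 0, , drop = FALSE]
  idx <- rep(seq_len(nrow(cts)), cts$reads)
  n <- length(idx)
  if (n == 0) return(NULL)
  s <- cts$intron_start[idx]; e <- cts$intron_end[idx]
  ch <- cts$chrom[idx]; L <- chrlen[ch]
  a <- sample(8:(rl - 8L), n, replace = TRUE)
  a <- ifelse(s - a < 1L, s - 1L, a)
  p1 <- s - a
  cig1 <- sprintf("%dM%dN%dM", a, e - s + 1L, rl - a)
  end1 <- e + (rl - a)
  p2 <- pmin(end1 + sample(5:120, n, replace = TRUE), L - rl)
  qname <- sprintf("%s.%s.r%06d", cts$sj_id[idx], cts$sample[idx],
                   seq_len(n))
  tibble::tibble(
    qname = rep(qname, each = 2L),
    flag = rep(c(99L, 147L), n),
    chrom = rep(ch, each = 2L),
    pos = as.integer(rbind(p1, p2)),
    mapq = 50L,
    cigar = as.vector(rbind(cig1, sprintf("%dM", rl))),
    mrnm = "=",
    mpos = as.integer(rbind(p2, p1)),
    tlen = 0L, seq = "*",
    sample = rep(cts$sample[idx], each = 2L))
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [generate_genome()], [plant_events()] and
#' [simulate_sequencing()].
#'
#' @inheritParams generate_genome
#' @inheritParams plant_events
#' @inheritParams simulate_sequencing
#' @export
simulate_splicing_dataset <- function(genome_spec = splicescape::genome_spec(),
                                      gene_spec = splicescape::gene_spec(),
                                      event_spec = splicescape::event_spec(),
                                      read_spec = splicescape::read_sim_spec()) {
  sim <- generate_genome(genome_spec, gene_spec)
  sim <- plant_events(sim, event_spec)
  seqd <- simulate_sequencing(sim, read_spec)
  c(list(sim = sim), seqd)
}

#' @export
print.splice_sim <- function(x, ...) {
  cat("<splice_sim>", length(x$genome), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$introns), "introns")
  if (!is.null(x$junctions)) {
    cat(",", nrow(x$junctions), "planted junctions")
  }
  cat("\n")
  invisible(x)
}
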