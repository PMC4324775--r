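#' Read and write pipeline file formats
#'
#' Thin wrappers over Biostrings / rtracklayer / Rsamtools so that every
#' coordinate conversion (1-based inclusive internally, 0-based half-open in
#' BED/bedGraph) happens in exactly one place.
#'
#' @param genome a named [Biostrings::DNAStringSet] of chromosomes.
#' @param path file path.
#' @name splicescape-io
NULL

#' @rdname splicescape-io
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' @rdname splicescape-io
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write truth-set gene models as GFF3
#'
#' Emits gene, exon and intron features (1-based inclusive, per GFF3).
#'
#' @param truth a `splice_sim` truth object (see [generate_genome()]).
#' @param path output path.
#' @export
write_truth_gff3 <- function(truth, path) {
  genes <- truth$genes
  exons <- truth$exons
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id
  )
  gr_e <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand, type = "exon",
    ID = paste0(exons$gene_id, ".e", exons$exon_rank),
    Parent = exons$gene_id
  )
  gr <- c(gr_g, gr_e)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname splicescape-io
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID %||% NA_character_),
    parent = vapply(as.list(gr$Parent %||% character(length(gr))),
                    function(p) if (length(p)) as.character(p[1]) else NA_character_,
                    character(1))
  )
}

#' Write / read per-base coverage as bedGraph
#'
#' Internal coverage is an [IRanges::RleList] keyed by chromosome (1-based);
#' bedGraph on disk is 0-based half-open.
#'
#' @param cov an RleList of integer per-base depth.
#' @param path file path.
#' @param genome optional genome used to recover chromosome lengths on read.
#' @export
write_coverage_bedgraph <- function(cov, path) {
  gr <- GenomicRanges::GRanges(cov)
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_coverage_bedgraph
#' @export
read_coverage_bedgraph <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         names(genome))
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)[
      match(GenomeInfoDb::seqlevels(gr), names(genome))]
  }
  GenomicRanges::coverage(gr, weight = "score")
}

#' Write / read the junction count table
#'
#' Columns: chrom, intron_start, intron_end, strand, sample, reads
#' (1-based inclusive intron coordinates).
#'
#' @param counts tibble of per-sample junction read counts.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts[, c("chrom", "intron_start", "intron_end",
                              "strand", "sample", "reads")], path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = "c", intron_start = "i", intron_end = "i",
                    strand = "c", sample = "c", reads = "i"))
}

#' Write junctions as 6-column BED (0-based half-open)
#'
#' @param sjs junction tibble.
#' @param path file path.
#' @export
write_junctions_bed <- function(sjs, path) {
  bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                 sjs$chrom, sjs$intron_start - 1L, sjs$intron_end,
                 sjs$sj_id, sjs$support_pooled, sjs$strand)
  writeLines(bed, path)
  invisible(path)
}

# ---- SAM ----

sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
}

#' Write a minimal SAM file of aligned read pairs
#'
#' One alignment line per mate; spliced alignments encode the intron as an
#' `N` (reference-skip) CIGAR operation. Sequences are emitted when present
#' so that overlap-consistency checks downstream can compare bases.
#'
#' @param records tibble with columns qname, flag, chrom, pos, mapq, cigar,
#'   mrnm, mpos, tlen, seq and (optionally) sample; one row per mate.
#' @param genome DNAStringSet used for the `@SQ` header.
#' @param path output path.
#' @export
write_sam <- function(records, genome, path) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*\tRG:Z:%s",
                   records$qname, records$flag, records$chrom, records$pos,
                   records$mapq %||% 50L, records$cigar,
                   records$mrnm %||% "=", records$mpos %||% 0L,
                   records$tlen %||% 0L, records$seq %||% "*",
                   records$sample %||% "s1")
  writeLines(c(sam_header(genome), lines), path)
  invisible(path)
}

#' Read spliced paired-end alignments from SAM
#'
#' Converts through BAM (Rsamtools) and expands CIGARs into aligned reference
#' blocks with GenomicAlignments; returns one row per alignment record.
#'
#' @param path SAM (or BAM) file path.
#' @return tibble: sample, qname, flag, chrom, pos, mapq, cigar, seq,
#'   first_mate, mate_strand, blocks (list of 2-column start/end matrices).
#' @export
read_sam_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "RG")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0) {
    return(tibble::tibble(sample = character(), qname = character(),
                          flag = integer(), chrom = character(),
                          pos = integer(), mapq = integer(),
                          cigar = character(), seq = character(),
                          first_mate = logical(), mate_strand = character(),
                          blocks = list()))
  }
  rg <- x$tag$RG %||% rep("s1", n)
  rg[is.na(rg)] <- "s1"
  ok <- !is.na(x$pos) & !is.na(x$cigar)
  blk <- vector("list", n)
  if (any(ok)) {
    br <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      x$cigar[ok], pos = x$pos[ok], ops = c("M", "=", "X"),
      reduce.ranges = TRUE)
    blk[ok] <- lapply(seq_along(br), function(i) {
      r <- br[[i]]
      cbind(start = IRanges::start(r), end = IRanges::end(r))
    })
  }
  tibble::tibble(
    sample = rg,
    qname = x$qname,
    flag = as.integer(x$flag),
    chrom = as.character(x$rname),
    pos = as.integer(x$pos),
    mapq = as.integer(x$mapq),
    cigar = as.character(x$cigar),
    seq = as.character(x$seq),
    first_mate = bitwAnd(as.integer(x$flag), 64L) > 0L,
    mate_strand = ifelse(bitwAnd(as.integer(x$flag), 16L) > 0L, "-", "+"),
    blocks = blk
  )
}

#' Write filtered pairs back to SAM
#'
#' @param pairs filtered pair tibble from [filter_pairs()].
#' @param genome DNAStringSet for the header.
#' @param path output path.
#' @export
write_pairs_sam <- function(pairs, genome, path) {
  rec_for <- function(blocks) {
    ops <- character(0)
    for (i in seq_len(nrow(blocks))) {
      if (i > 1) {
        gap <- blocks[i, 1] - blocks[i - 1, 2] - 1L
        ops <- c(ops, sprintf("%dN", gap))
      }
      ops <- c(ops, sprintf("%dM", blocks[i, 2] - blocks[i, 1] + 1L))
    }
    paste(ops, collapse = "")
  }
  rows <- purrr::pmap(pairs, function(pair_id, sample, chrom, blocks1,
                                      blocks2, ...) {
    tibble::tibble(
      qname = pair_id, sample = sample, chrom = chrom,
      flag = c(99L, 147L),
      pos = c(blocks1[1, 1], blocks2[1, 1]),
      mapq = 50L,
      cigar = c(rec_for(blocks1), rec_for(blocks2)),
      mrnm = "=", mpos = c(blocks2[1, 1], blocks1[1, 1]),
      tlen = 0L, seq = "*")
  })
  write_sam(dplyr::bind_rows(rows), genome, path)
}
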