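# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small planted dataset exercising every stage
small_dataset <- function() {
  memo("small", function() {
    sim <- generate_genome(
      genome_spec(n_chroms = 2, chrom_length = 150000, seed = 7),
      gene_spec(n_genes = 80))
    sim <- plant_events(sim, event_spec())
    sq <- simulate_sequencing(sim, read_sim_spec(junction_depth_mean = 50,
                                                 seed = 7))
    js <- junctions_from_counts(sq$counts, sim$genome)
    ann <- annotate_junctions(js)
    ref <- refine_junctions(ann, sim$genome)
    clu <- cluster_junctions(ref$junctions)
    res <- classify_clusters(clu$junctions, sq$coverage)
    list(sim = sim, sq = sq, junctions = clu$junctions, report = ref$report,
         events = res$events, ir = res$ir,
         n_mixed = clu$n_mixed_strand_excluded)
  })
}

# a one-chromosome genome built from an explicit sequence
toy_genome <- function(seq, name = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# junction tibble row constructor for hand-built cases
mk_sj <- function(chrom, start, end, strand = "+", support = 10L,
                  id = NULL, ...) {
  tibble::tibble(sj_id = id %||% sprintf("sj_%s_%d_%d", chrom, start, end),
                 chrom = chrom, strand = strand,
                 intron_start = as.integer(start),
                 intron_end = as.integer(end),
                 support_pooled = as.integer(support), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

irr_bin_for_test <- function(x) splicescape:::irr_bin(x)

# intron sequences of a truth set, in transcription orientation
slice_seq_for_test <- function(sim) {
  splicescape:::slice_seq(sim$genome, sim$introns$chrom, sim$introns$start,
                          sim$introns$end, sim$introns$strand)
}

# an RleList coverage track over one chromosome of given length
mk_coverage <- function(len, spans = list(), chrom = "chr1") {
  v <- integer(len)
  for (s in spans) v[s[1]:s[2]] <- s[3]
  methods::as(list(chr1 = S4Vectors::Rle(v)), "SimpleRleList")
}
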