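---
title: "Discovering alternative splicing in intron-dense fungal transcriptomes"
author: "splicescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering alternative splicing in intron-dense fungal transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Filamentous fungi have compact genomes with short introns (median around
72 bp) and, when deeply sequenced, show an alternative-splicing landscape
dominated by intron retention, with smaller contributions from alternative
donor (A5SS) and acceptor (A3SS) choice. Detecting these events from
paired-end RNA-seq requires a chain of small, rule-based decisions —
alignment filtering, junction correction, motif search, scoring,
clustering, classification — each of which is easy to get subtly wrong and
hard to validate on real data, where no truth is available. `splicescape`
implements that chain as composable table-in/table-out functions, and
pairs it with a seeded synthetic-data generator whose planted truth makes
every stage measurable.

## The pipeline model

### Alignment filtering

A pair is kept when it is uniquely mapped — operationalised as exactly one
alignment record per mate, since short-read aligners report a single best
placement for unique pairs and no mapping-quality cutoff is universally
comparable — both mates lie on one chromosome, and the interval between
the mates' facing ends is below 5 kb. Overlapping mates (negative
interval) are retained only when their alignments agree in the overlap:
identical aligned reference positions, and identical base calls where
sequence is available. Transcript strand is inferred from the splice
dinucleotides of reference skips (GT..AG, GC..AG, AT..AC forward; their
reverse complements imply the minus strand); pairs whose skips imply both
strands are rejected.

Two anchor corrections guard against alignment error at read ends:
terminal aligned blocks shorter than 5 bp are removed (iterated to a fixed
point, so the operation is idempotent), and when a candidate junction's
acceptor lies within 6 bp of a read's 5' end — or its donor within 6 bp of
the 3' end — the read bases falling inside the intron are trimmed,
provided the terminal anchor is longer than 12 bp. The ambiguous
"total length of the terminal anchor" clause is read as the length of the
terminal aligned block, and the rule is isolated in one function
(`trim_junction_proximal`) so the interpretation can be swapped.

### The junction catalog

Junctions are distinct (chromosome, strand, intron span) triples with
pooled support of at least two read pairs; a pair supports a junction once
even if both mates span it. Catalog refinement applies, in order:

1. junctions with no branch point anywhere in the intron are removed;
2. junctions whose branch point lies more than 60 bp from the 3'ss are
   removed;
3. same-length overlapping junction pairs whose starts differ by fewer
   than 10 bp are treated as alignment artefacts: the member with the
   lower donor-site score is deleted and its support added to the
   survivor. Ties on score are broken by higher pooled support, then by
   the 5'-most start, making the correction permutation-invariant.
   Transitive groups are resolved by keeping the single best member of
   each connected component;
4. junctions whose intron contains an N are excluded.

The filter report satisfies the identity
`n_final = n_input − n_no_branch − n_branch_too_far − n_overlap_corrected − n_n_excluded`
by construction, and total support is conserved through the correction.

### Branch points and polypyrimidine tracts

The branch search is hierarchical, on the DNA alphabet (U ≡ T): the
3'-most instance of the primary motif CURAY; failing that, the 3'-most
instance of the secondary motif; failing that, the 3'-most instance of the
degenerate family NURAY / YUNAY / YURAY-with-free-5th. The branch point is
the A at the fourth motif position. The search never consumes the final
two intron bases, so the acceptor AG cannot be claimed by a motif — a
biological sanity constraint the source methods leave implicit. The
secondary motif defaults to UURAY but is a plain IUPAC string argument
(`secondary_motif`), because the literature it derives from prints both
UURAY and UUARY; one argument change switches the convention.

A polypyrimidine tract is six consecutive non-adenine bases containing at
least three T. Among qualifying windows those with the maximal T count are
kept and the 3'-most is reported. The tract is assigned to the region 5'
of the branch point or between branch point and 3'ss by its own 3'-most
base; since the branch base is an A and tract windows contain none, a
window can never straddle the branch point, so the assignment is always
unambiguous.

### Scoring

Site windows are anchored in transcription orientation: 13 bases at the
donor (3 exonic + 10 intronic), 17 at the acceptor (14 intronic + 3
exonic), 11 around the branch A (6 upstream, the A, 4 downstream). Only
the branch window may extend past intron boundaries into flanking
sequence; introns shorter than a window's intronic span are flagged
unscorable for that window, as are windows running off a chromosome end.

Frequencies are plain counts over totals — no pseudocount. Building the
matrix from *all* catalogued junctions keeps zero frequencies rare; where
one occurs anyway the log-odds entry is a `-Inf` sentinel, and scores
hitting it propagate the sentinel rather than being silently patched,
so affected junctions drop out of downstream feature statistics visibly.
Scores are raw positional sums of base-2 log-odds against a uniform 0.25
background; no rescaling path exists anywhere in the package.

Matrices are built twice: once on the branch-filtered, pre-correction set
(these donor scores drive the overlap correction) and once on the final
corrected set (these are the reported scores). This two-pass scheme is the
only ordering consistent with using donor scores *during* correction while
still scoring the final catalog against matrices from all of its members.

### Classification and retention

Junction clusters are single-linkage components under "intron spans share
at least one base on the same chromosome" (adjacency is not overlap);
components containing both strands are excluded and tallied. For a
two-junction cluster, with donor and acceptor in transcription
orientation: shared acceptor → A5SS, shared donor → A3SS, strict nesting →
"A5SS and A3SS", staggered overlap → "A5SS or A3SS". For three or more: a
shared acceptor across all members is MA5SS(k), a shared donor MA3SS(k);
exactly three members, two of them disjoint and the third sharing its
donor with the upstream one and its acceptor with the downstream one, is
exon skipping; anything else is complex, encoded as
`n=<k>;A5SS=<a>;A3SS=<b>;AND=<c>;OR=<d>` from an all-pairs comparison.
Clusters larger than three that merely contain the skipping sub-pattern
stay complex: the three-junction definition is exact.

A single-junction cluster with any intronic base covered by at least one
read is a retained intron, otherwise constitutive. The intron retention
ratio is the median intronic per-base coverage divided by the junction's
pooled support; medians over an even number of bases are the mean of the
central pair. Bins are left-closed: [0, 0.01), [0.01, 0.1), [0.1, 1) and
[1, ∞) — the last because median intronic coverage can exceed junction
support. Retention uses pooled coverage and pooled support (one IRR per
intron); per-sample IRRs are emitted as extra columns when per-sample
coverage is supplied. The stringent "high coverage" class requires every
intronic base at depth ≥ 2. When no coverage input exists the pipeline
labels single-junction clusters `NOT_ASSESSED`, says so, and still
produces all multi-junction classification; the accounting summary is then
deliberately unavailable rather than silently wrong.

### Transcript models

Transcriptionally active regions are maximal runs longer than 35 bp with
every base at depth ≥ 4; read pairs with one mate in each of two regions
link them into transcript units, kept when their total region length
exceeds 150 bp and mean depth is at least 10. A unit's "length" is the sum
of its member-region widths (the source text does not distinguish covered
length from span; covered length is the conservative reading and the one
implemented).

Artificial reads span mate intervals: overlapping mates merge; intervals
without a catalogued junction are filled as exonic; an interval holding
exactly one junction embeds it as a skip when interval length minus
junction length is below 85 bp (the raw-gap reading of an ambiguous rule,
isolated in one predicate); anything else passes the mates through
unchanged. Models chain reads whose spans overlap *and* whose exon/intron
structure agrees in the shared region — contradictory junction content
blocks chaining, which prevents chimeric contigs and keeps an unspliced
stray read from poisoning the per-base support of a spliced model. Models
need 100 covered bases and depth ≥ 2 everywhere. Overlapping models merge
into loci, and loci at most 10 bp apart are linked; a separate
"link partial models within 30 bp inside one locus" rule in the source
text is unreachable under the overlap-closure definition of a locus and
is therefore not a distinct code path (a known ambiguity, recorded here).

ORF calls scan the spliced exon sequence in six frames — three when an
embedded junction fixes the strand — combining each start codon with the
nearest in-frame stop; the longest wins, coding means more than 30 aa, and
completeness requires both a start and a stop inside the model.

### Downstream statistics

Intron classes are IC (constitutive singleton), IR (retained singleton)
and IA−IR (member of any multi-junction cluster). Class comparisons use
the two-sided Mann-Whitney-Wilcoxon test: exact when both groups have at
most 20 observations and no ties, normal approximation with tie and
continuity correction otherwise; raw p-values are reported without
multiplicity correction, matching how such comparisons are conventionally
tabled in this literature. The isoform analysis computes per-sample and
pooled relative frequencies for every two-junction cluster, the score
difference appropriate to the type (donor score for A5SS, acceptor for
A3SS, their sum for nested/staggered events, which are pooled into one
"combined" regression since their regressor is the same), and fits
ordinary least squares of the natural-log frequency ratio on the score
difference. Clusters with a zero isoform count are excluded rather than
pseudocounted — exclusion adds no tuning constant, and the output metadata
says so (`zero_count_clusters = "excluded"`, `log_base = "natural"`; the
log base only affects the slope's units, never r²).

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates:

* a multi-chromosome background at configurable GC, with non-overlapping
  multi-exon genes on both strands;
* lognormal intron lengths (median 72 bp by default, truncated below
  30 bp so every intron can host a donor window, branch region and
  acceptor window), intron interiors at 49% GC;
* donor, acceptor and branch windows drawn from per-position probability
  profiles. `consensus_strength` blends the full-strength profiles toward
  uniform — except the donor/acceptor dinucleotides and the branch core
  CURAY, which are always emitted as valid instances (strength biases the
  R toward A and the Y toward C). A core that could degrade below the
  primary tier would make planted branch points unrecoverable by
  construction, which would confound generator noise with search defects.
  The acceptor region and the branch 3' flank emit adenine at only 2–3%,
  as real pyrimidine tracts do; this also keeps chance CURAY instances
  from appearing 3' of the planted core, so the planted branch stays the
  3'-most primary instance in at least 99% of introns at strength 0.95;
* noncanonical GC-AG (1.7%) and AT-AC (0.5%) boundary pairs at the
  observed fungal rates, configurable;
* every taxonomy class, planted by patching alternative donor/acceptor
  (and where needed branch) sites into or beside existing introns. The
  default class mix is the observed deep-RNA-seq cluster composition
  (71% retained, 24% constitutive, ~3.6% donor/acceptor pairs, the rest
  multi-site); planted retention ratios default to a lognormal solved
  from the observed bin fractions (a third below 0.01, two thirds below
  0.1);
* isoform usage drawn as logistic(β × Δscore), where Δscore is computed
  by scoring the planted windows with log-odds matrices built from all
  planted windows — the only self-consistent definition, since a
  splice-site "score" exists only relative to a matrix estimated from
  data. Site-profile degeneracy is moderate by design, so that typical
  Δscores land in the informative range of the logistic rather than its
  saturated tails;
* per-sample cluster depth from a negative binomial (variance
  μ + 0.1 μ²; pure Poisson understates RNA-seq dispersion) apportioned to
  isoforms multinomially, so per-isoform counts always sum to the cluster
  total; exonic Poisson coverage at the cluster depth; intronic Poisson
  coverage at planted IRR × per-sample support, centring the measured
  retention ratio on the planted one; and optional minimal spliced SAM
  pairs (read length 75, the intron encoded as a reference skip, no
  quality strings) consistent with the counts.

Each simulator stage draws from its own stream derived from (module name,
seed), so adding draws to one stage never perturbs another, and identical
specs with identical seeds give byte-identical FASTA/GFF3/TSV output.

What the generator does *not* emulate — and what green tests therefore do
not certify about real data: sequencing error and quality, adapter
contamination, multi-mapping and mappability structure, expression-level
variation between genes, paralogy, incomplete genome assemblies, and
library-preparation biases. Recovery rates measured here are upper bounds
specific to clean alignments.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere inside the package;
  conversion to 0-based half-open happens only in the BED/bedGraph
  readers and writers.
* All thresholds follow their stated strictness: interval < 5000, anchor
  ≥ 5, proximity trim needs anchor > 12, support ≥ 2, branch distance
  ≤ 60, overlap-correction start distance < 10, active regions > 35 bp at
  depth ≥ 4, units > 150 bp at mean ≥ 10, models ≥ 100 bases at depth
  ≥ 2, junction embedding < 85 bp, reference screen drops overlap > 10 bp
  (structural RNA at ≥ 1 bp), coding > 30 aa, locus linking ≤ 10 bp.
* Problem sizes used by the test suite and the acceptance script: oracle
  batches of 1000–2000 random instances per primitive; matrix round-trips
  at n = 10,000 windows; end-to-end recovery on ~300 genes / ~790 introns
  with 300+ planted alternative-donor events at per-sample depth 50 —
  large enough that the measured rates have small Monte-Carlo error,
  small enough to run comfortably on one CPU.

## Limitations

The pipeline detects junction-evidenced events only; it does not
reconstruct isoforms, quantify PSI, or test differential splicing between
samples. The uniquely-mapped rule discards multi-mapping rescue entirely.
The accounting summary requires coverage input; without it retention
simply is not assessed. Real-data catalogs will contain branch points
found at the degenerate tier and junctions removed by the 60 bp rule at
rates the generator's clean profiles do not reproduce.
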