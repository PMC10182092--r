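---
title: "Models and methods behind snrand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snrand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snrand)
```

# The chemistry being modelled

snrand implements the computational layer of a pre-indexed, random-primed
droplet single-nucleus total RNA-seq chemistry (snRandom-seq-style
libraries). The wet-lab design it mirrors: nuclei are split across `K`
reverse-transcription tubes whose random primers carry a tube-specific
**pre-index**; cDNA 3' ends receive a **poly(dA) tail**; nuclei are pooled
and co-encapsulated in droplets with hydrogel beads carrying **split-pool
barcodes** (three ligation rounds), whose poly(dT) primers anneal to the dA
tail and append the 30-nt cell barcode and 8-nt UMI. Read1 therefore reads
`barcode + UMI + poly(T) junction + insert`; Read2 reads
`pre-index + insert (cDNA orientation) + poly(A) read-through`.

Because random primers capture total RNA — including intronic pre-mRNA and
non-polyadenylated biotypes — the processing side must correct split-pool
barcodes, split intron/exon evidence, and quantify spliced/unspliced
molecules; the simulation side must generate libraries whose ground truth
exercises all of it.

# Barcode correction

The accepted barcode set is the Cartesian product of the three round
segment sets. `correct_barcodes()` exploits this: per-round segment
distances are computed exactly and combined over all error splits summing
to at most `d_max`, which is mathematically identical to an exhaustive
Hamming scan over the enumerated product (the test suite verifies exact
agreement on randomized whitelists, and the acceptance suite on a
2,000-barcode whitelist with 10^4 observations).

*Unique assignment* is read conservatively: a non-member observation is
corrected only when exactly one accepted barcode lies within `d_max`
substitutions; if two or more do — even when one is strictly nearer — it is
ambiguous and dropped. A `nearest` mode accepting a unique nearest
neighbour is available behind a flag. When the minimum pairwise whitelist
distance is at least `2 d_max + 1`, no observation with at most `d_max`
errors can be ambiguous or miscorrected; this guarantee is tested
constructively.

Defaults follow the assay constants: 30-nt barcode (three 10-nt segments —
the published material states only the 30-nt total, so segment lengths and
optional fixed linkers are configurable), 8-nt UMI, `d_max = 2`. The
pre-index length (6 nt) and its merge bound (`d_pre = 1`) are not stated in
the published text; both are configurable defaults.

## Homopolymer junctions

The dA-tail appears on Read1 as a poly(T) run after the UMI and on Read2 as
a trailing poly(A). Both are scanned greedily with an allowance of one
mismatch per 10 nt of run (`ceiling(L/10)` mismatches for a run of length
`L`), never ending a run on a mismatch. The Read1 junction requires a
minimum run of 6; Read2 tail trimming requires 4. These tolerances are our
choices, sized to the simulated substitution-error regime (0.5% per base);
neither is stated by the assay's published description. A junction run can
absorb template bases that genuinely start with T — an ambiguity inherent
to the chemistry, which is why the barcode and UMI (fixed offsets) never
depend on junction detection.

# The generative model

`simulate_library()` chains four seeded stages; a fixed seed reproduces the
library byte-for-byte.

**Annotation** (`simulate_annotation()`): one chromosome per species, genes
laid out without overlap, alternating exons and introns (0-based half-open
coordinates), eight biotype classes with the first genes cycling through
all classes so each is always present. Per-gene expression rates are Gamma
draws multiplied by a biotype factor (protein-coding 1, lncRNA 0.3, short
non-coding classes 0.05, mito/ribo 0.5) — nuclear libraries are dominated
by long, intron-rich transcripts, and this weighting, together with default
intron lengths of 2–4 kb against 150–400 nt exons, places the expected
intron:exon priming-site ratio of the default configuration near 3:1. The
expectation is computed from the annotation itself (rate-weighted intronic
length share times the unspliced fraction), and tests compare recovered
ratios against that configured expectation, not against any external
number.

**Expression** (`simulate_expression()`): molecules per nucleus are
Poisson (default mean 200); genes are drawn by rate within the nucleus's
own species only (barnyard construction); each molecule is unspliced with
probability `unspliced_fraction` (default 0.88, a nuclear-RNA-like value).

**Droplets** (`simulate_droplets()`): nuclei are assigned uniformly to `K`
tubes, then packed into droplets with truncated-Poisson(λ) occupancy
(conditioned on ≥ 1 nucleus; every droplet carries exactly one bead, as in
the source chemistry's imaging). Each droplet draws a distinct whitelist
barcode. A droplet with ≥ 2 nuclei is a *physical collision*; it becomes an
*observed doublet* only when at least two of its nuclei share a pre-index —
for pairs this happens with probability `1/K`, which is the entire point of
pre-indexing. The acceptance suite checks the measured thinning against the
analytic truncated-Poisson expectation for K ∈ {1, 4, 12}. λ defaults to
0.06 (≈ 3% physical collisions), chosen to reproduce the percent-level
collision regime of real droplet runs; the published text does not state
its λ or tube count.

**Reads** (`simulate_reads()`): priming sites are uniform along the
molecule (spliced transcript for mature mRNA, full gene body for pre-mRNA);
a configurable fraction of spliced molecules instead primes at the 3'
poly(A) terminus (the extra oligo(dT) primer in the RT mix; default 0.15,
matching the assay's slight 3' bias). Reverse transcription extends from
the priming site toward the 5' end over a log-normal fragment length whose
default mode sits in the 300–800 bp window. The truth table records each
read's genomic footprint as the whole fragment interval; for spliced
molecules this interval spans intervening introns, as an unspliced aligner
projection would. Substitution errors are applied uniformly at
`error_rate`; indels are excluded because correction is Hamming-based.
Quality strings are a constant Q37 placeholder — the pipeline never uses
qualities. Ambient reads (default 5% of the library) carry a valid bead
barcode drawn from a dedicated pool of otherwise-empty droplets plus a
random transcript from either species: they create the background shoulder
of the rank plot without contaminating true nuclei, so
`reads_in_cells = 1 - ambient share` holds exactly in truth.

**UMIs** are drawn from a distance-2 checksum code (7 random bases plus one
parity base) and kept distinct within each (cell, gene) group. Under ideal
molecular labelling this is what "distinct molecules" means; with raw
random 8-mers, pairs of molecules would land within one substitution of
each other at ~4 × 10⁻⁴ per pair and be conflated by any Hamming-based
deduplicator, making exact count recovery impossible even on error-free
data. The code costs 2 bits of UMI entropy (16,384 codewords) and leaves
the dedup logic fully exercised by sequencing errors.

# Quantification

Gene assignment is gene-body ("GeneFull"-like): a record overlapping
exactly one gene span is assigned to it; multi-gene overlaps are discarded
and counted; exon-only counting would discard most of an intron-rich
library's signal. A record is `exon` only when fully contained in exonic
sequence, `intron` when it overlaps any intron. Strand is ignored by
default — random-primed second-strand chemistry makes the strand of origin
ambiguous.

UMI collapse is *directional*: `v` merges into the more abundant `u` when
they differ by one substitution and `count(u) ≥ 2·count(v) − 1`, components
grown from the most abundant unvisited UMI with lexicographic tie-breaks,
so results are deterministic. The published pipeline does not state its
merge rule; directional is the established default for 8-nt UMIs, and an
exact-match mode is available. Tests compare every collapse against an
exhaustive adjacency-graph oracle.

Molecule layers follow read evidence: `spliced` when all reads of a
molecule are fully exonic, `unspliced` when any read overlaps an intron,
`ambiguous` otherwise; `total` is their elementwise sum on every output.
Note that with whole-fragment footprints, a spliced fragment spanning an
exon junction is projected across the intervening intron and therefore
counts as intron evidence; read-level intron:exon ratios measured this way
exceed the priming-site ratio (the configured ~3:1 law), which is why the
acceptance script reports both quantities separately.

# Nucleus calling

Barcodes are ranked by genes detected (UMIs optional), ties broken
lexicographically. On the smoothed log-log curve (running median, window
15), the chord joining the endpoints gates the call: the maximal signed
perpendicular distance above the chord must be a unique maximum with
relative prominence ≥ 0.05, otherwise the caller falls back to the
expected-cells quantile rule (threshold = 99th percentile of the top N
values, divided by 10) or raises a no-knee error for curves spanning less
than a decade. The threshold itself is placed at the top of the *steepest
descending segment* of the smoothed curve (slopes over a fixed 0.02-decade
window, restricted to the region with chord distance ≥ 25% of maximum,
then the largest single-step drop inside the steepest window). We found
that placing the threshold at the chord-distance maximum itself — the more
common "kneedle" reading — sits mid-plateau whenever the nucleus population
has realistic spread, cutting recall to ~0.77; the steep-slope placement
recovers 100% of true nuclei with zero ambient contamination across 20
seeds of the two-population benchmark, and is the direct concretization of
the rank-plot "significant steep slope" that motivates the method. Ties at
the threshold are included: deterministic supersets beat arbitrary
exclusion.

# QC metrics

* **Barnyard**: per-cell species specificity `max(a,b)/(a+b)`; a cell is a
  doublet when the minor-species share is ≥ `t_minor = 0.1`. The source
  experiments report specificities but no cutoff; 0.1 keeps true singlets
  (median specificity ≈ 0.99) far from the boundary and is configurable.
* **Gene-body coverage**: exonic parts of each alignment are projected onto
  spliced-transcript coordinates of genes at least 500 nt long, rescaled to
  100 strand-aware bins, and normalized to sum to one. Pure random priming
  yields near-uniform central coverage (taper only within a fragment length
  of the 3' end); pure oligo(dT) concentrates coverage in the terminal
  bins. The acceptance contrast uses long (≥ 6 kb spliced) genes so the
  taper stays confined to the outer bins.
* **Saturation**: alignments are subsampled without replacement at each
  fraction and the entire assignment/dedup/count pipeline re-runs; at
  `f = 1` the subsample is the identity permutation, so medians match the
  direct pipeline bit-for-bit. Monotonicity holds in expectation and is
  tested on averages over subsampling seeds.
* **Filtering**: excluded genes (mitochondrial/ribosomal lists emitted by
  the simulator) are removed first, then nuclei with fewer than 200
  detected genes, then genes detected in fewer than 3 nuclei — one pass, in
  that order. Removing rare genes can in principle push a nucleus back
  under the gene threshold, so idempotence is a property of realistic
  matrices rather than a theorem; it holds on the simulated libraries and
  is tested there.
* **Pseudobulk correlation**: counts-per-10k per cell, averaged per gene
  over cells, then `ln(x + 1)`; Pearson over genes detected in both
  matrices (error below 10 shared genes). The natural-log-plus-pseudocount
  transform follows the replicate-comparison convention of the assay's own
  analysis; the depth normalization (cp10k) is our documented choice, as
  the original normalization is not printed.

# Problem sizes and determinism

The packaged tests run the full pipeline on a 500-nucleus, ~2×10⁵-read
library (the lossless round-trip), droplet-only sweeps of 2,000 nuclei × 20
seeds for the thinning law, and 55,000-barcode rank curves × 20 seeds for
knee recovery — sizes chosen so the whole suite completes in a few minutes
on one CPU while keeping binomial standard errors small enough for 3·SE
bounds. Every stochastic stage takes an explicit seed, and
`simulate_library()` seeds once from its config, so libraries, FASTQ bytes
and all downstream results are exactly reproducible.

# Known limitations

* No indel errors, PCR chimeras, or base-quality error profiles; no FFPE
  degradation chemistry beyond the fragment-length and error-rate knobs.
* Alignment is not modelled: truth-mode records stand in for an external
  aligner, and SAM ingestion assumes ungapped single-block records.
  Junction-spanning spliced fragments are deliberately left as single
  genomic intervals (see Quantification).
* Passing tests on these synthetic libraries demonstrate the correctness of
  the processing algorithms under the generator's assumptions — uniform
  priming, independent substitution errors, species-exclusive expression —
  not the behaviour of any particular real library.
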