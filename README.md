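# snrand

Simulation, demultiplexing, quantification and QC for **pre-indexed,
random-primed droplet single-nucleus total RNA-seq** libraries
(snRandom-seq-style chemistry).

## The problem

Random-primed droplet snRNA-seq captures total nuclear RNA — intronic
pre-mRNA, lncRNAs, short non-coding classes — instead of only
polyadenylated mRNA, and suppresses droplet doublets by *pre-indexing*:
nuclei are reverse-transcribed in `K` separate tubes whose primers carry a
tube index before pooling, so two co-encapsulated nuclei are only
mistakenly merged when they also share a pre-index (a `1/K` thinning of the
collision rate). cDNAs are dA-tailed and barcoded in droplets by
split-pool bead barcodes (three ligation rounds, 30 nt) with an 8-nt UMI.

This package provides, for that chemistry:

* **chemistry** — read-layout declaration, split-pool whitelist
  construction/validation, and Hamming-bounded unique-assignment barcode
  correction (`read_structure()`, `build_whitelist()`,
  `correct_barcodes()`, `match_preindexes()`, `parse_read1()`);
* **simulate** — a fully seeded generative model of paired-end libraries
  with per-read ground truth: two-species barnyard mixtures, truncated-
  Poisson droplet co-encapsulation, pre-index tubes, uniform random priming
  vs 3'-anchored oligo(dT), dA-tail junctions, 300–800 bp fragments,
  substitution errors and ambient background (`simulate_library()` and its
  stages);
* **demux** — paired-FASTQ streaming, dA-tail trimming, barcode/pre-index
  correction, tagged-read emission and a partitioned run report
  (`demux_pair_stream()`, `trim_read2()`);
* **quantify** — gene-body assignment with exon/intron regions, directional
  UMI deduplication, and cell×gene matrices with
  spliced/unspliced/ambiguous layers in MatrixMarket form
  (`assign_features()`, `dedup_umis()`, `count_matrix()`,
  `write_matrix()`);
* **cellcall** — barcode-rank curves, knee detection with an
  expected-cells fallback, capture metrics (`rank_barcodes()`,
  `call_knee()`, `capture_metrics()`);
* **qc** — barnyard doublet/specificity reports, region fractions,
  100-bin gene-body coverage, biotype tallies, saturation by downsampling,
  matrix filtering (200-gene / 3-nucleus defaults, mito/ribo exclusion) and
  pseudobulk `ln(mean+1)` Pearson correlation (`barnyard()`,
  `genebody_coverage()`, `saturation()`, `filter_matrix()`,
  `pseudobulk_correlation()`).

The key quantities it computes: the per-cell species specificity
`s_c = max(u_A, u_B)/(u_A + u_B)` and doublet rate `D`; the corrected-
barcode identity `cell = preindex ⊕ barcode` under Hamming distance
`d ≤ d_max = 2`; UMI counts `n_{c,g}` after directional collapse
(`count(u) ≥ 2·count(v) − 1` at Hamming 1); and the knee threshold on the
log-log barcode-rank curve.

## Worked example

Simulate a 200-nucleus barnyard library, demultiplex it, quantify it, call
nuclei and run the species-mixing QC:

```r
library(snrand)

cfg <- library_config(n_nuclei_A = 100, n_nuclei_B = 100,
                      molecules_per_nucleus = 150, seed = 42)
wl  <- random_whitelist(sizes = c(24, 24, 24), n_preindex = 12, seed = 43)
ann <- simulate_annotation(100, seed = 44)
sim <- simulate_library(cfg, annotation = ann, whitelist = wl)
#> snrand_sim: 63397 read pairs from 200 nuclei in 193 droplets;
#>   33298 molecules ( 3170 ambient )

dx <- demux_pair_stream(sim$r1, sim$r2, sim$structure, wl, d_max = 2)
dx$report
#> demux_report:
#>   total             63397
#>   valid             63347 (99.92%; 8877 corrected)
#>   ambiguous             2
#>   no_match             48
#>   malformed             0

aln <- alignments_from_demux(dx$tagged, sim)   # aligner stand-in
cm  <- count_matrix(aln, ann)
#> count_matrix: 200 genes x 2823 cells; 33342 molecules
#>   ( 2359 spliced / 30983 unspliced / 0 ambiguous )

call <- call_knee(rank_barcodes(cm, metric = "genes"))
#> call_result: 198 barcodes called by knee at threshold 32
capture_metrics(call, truth_cells = unique(sim$nuclei$cell_id),
                read_cells = dx$tagged$cell_id)
#> $capture_rate   1
#> $reads_in_cells 0.9499897

barnyard(count_matrix(aln, ann, called_cells = call$called_cells))$summary
#> $doublet_rate          0.005050505
#> $median_specificity    A: 1, B: 1
```

Reading the numbers: 99.92% of read pairs carry a usable barcode (8,877 of
them repaired within two substitutions); 2,823 barcodes appear in the
matrix but the knee at 32 detected genes separates the 198 real nucleus
barcodes (two doublet pairs share a barcode and pre-index) from the ambient
shoulder; 95% of tagged reads sit in called nuclei — exactly the simulated
1 − ambient fraction; and one called barcode (0.5%) is a cross-species
doublet, with median species specificity 1.0 for both species.

A command-line dispatcher wrapping the same functions ships in
`inst/cli/snrand.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","snrand.R",package="snrand"))')" \
    validate-whitelist --rounds r1.txt,r2.txt,r3.txt --preindexes pre.txt
```

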