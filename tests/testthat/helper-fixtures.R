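# Shared fixtures, built once per test run (memoised).

.fx <- new.env(parent = emptyenv())

# Toy annotation with hand-placed genes for assignment tests.
# g1 (chrA, +): exons [100,200) [300,400), intron [200,300)
# g2 (chrA, +): single exon [1000,1200)
# g3 (chrA, +): single exon [1150,1300)  (overlaps g2 -> ambiguity cases)
# g4 (chrB, -): exons [500,700) [900,1100), intron [700,900)
manual_annotation <- function(seq_len_A = 2000L, seq_len_B = 1600L) {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4"),
    species = c("A", "A", "A", "B"),
    biotype = c("protein_coding", "lncRNA", "protein_coding",
                "protein_coding"),
    chrom = c("chrA", "chrA", "chrA", "chrB"),
    strand = c("+", "+", "+", "-"),
    start = c(100L, 1000L, 1150L, 500L),
    end = c(400L, 1200L, 1300L, 1100L),
    spliced_len = c(200L, 200L, 150L, 400L),
    unspliced_len = c(300L, 200L, 150L, 600L),
    rate = rep(1, 4))
  exons <- data.table::data.table(
    gene_id = c("g1", "g1", "g2", "g3", "g4", "g4"),
    chrom = c("chrA", "chrA", "chrA", "chrA", "chrB", "chrB"),
    strand = c("+", "+", "+", "+", "-", "-"),
    start = c(100L, 300L, 1000L, 1150L, 500L, 900L),
    end = c(200L, 400L, 1200L, 1300L, 700L, 1100L))
  introns <- data.table::data.table(
    gene_id = c("g1", "g4"),
    chrom = c("chrA", "chrB"),
    strand = c("+", "-"),
    start = c(200L, 700L),
    end = c(300L, 900L))
  set.seed(42)
  seqs <- Biostrings::DNAStringSet(c(
    chrA = paste(sample(c("A", "C", "G", "T"), seq_len_A, TRUE),
                 collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), seq_len_B, TRUE),
                 collapse = "")))
  snrand:::.index_annotation(genes, exons, introns, seqs)
}

# Error-free, ambient-free barnyard library (the lossless round-trip
# conditions): 500 nuclei, ~2e5 read pairs.
fx_roundtrip <- function() {
  if (is.null(.fx$rt)) {
    ann <- simulate_annotation(100L, seed = 11L)
    wl <- random_whitelist(sizes = c(24L, 24L, 24L), n_preindex = 4L,
                           seed = 12L)
    cfg <- library_config(n_nuclei_A = 250L, n_nuclei_B = 250L,
                          molecules_per_nucleus = 200,
                          reads_per_molecule = 2,
                          error_rate = 0, ambient_fraction = 0,
                          seed = 101L)
    sim <- simulate_library(cfg, annotation = ann, whitelist = wl)
    dx <- demux_pair_stream(sim$r1, sim$r2, sim$structure, wl)
    .fx$rt <- list(sim = sim, wl = wl, dx = dx)
  }
  .fx$rt
}

# Small noisy library (errors + ambient) for report/oracle tests.
fx_noisy <- function() {
  if (is.null(.fx$noisy)) {
    ann <- simulate_annotation(40L, seed = 21L)
    wl <- random_whitelist(sizes = c(12L, 12L, 12L), n_preindex = 4L,
                           min_dist = 1L, seed = 22L)
    cfg <- library_config(n_nuclei_A = 40L, n_nuclei_B = 40L,
                          molecules_per_nucleus = 60,
                          reads_per_molecule = 2,
                          error_rate = 0.01, ambient_fraction = 0.05,
                          ambient_barcodes = 300L, seed = 102L)
    sim <- simulate_library(cfg, annotation = ann, whitelist = wl)
    .fx$noisy <- list(sim = sim, wl = wl)
  }
  .fx$noisy
}
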