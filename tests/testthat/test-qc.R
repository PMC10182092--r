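# Helper: build a count_matrix directly from a dense total matrix.
dense_cm <- function(m, species = NULL, biotype = NULL) {
  genes <- data.table::data.table(
    gene_id = rownames(m),
    species = species %||% rep("A", nrow(m)),
    biotype = biotype %||% rep("protein_coding", nrow(m)))
  sp <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  zero <- sp * 0
  out <- list(layers = list(total = sp, spliced = sp, unspliced = zero,
                            ambiguous = zero),
              genes = genes, cells = colnames(m))
  class(out) <- "count_matrix"
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("barnyard specificity and doublet flags follow the definitions", {
  m <- rbind(gA1 = c(10, 5, 0), gA2 = c(10, 5, 0), gB1 = c(0, 10, 8))
  colnames(m) <- c("pureA", "mix", "pureB")
  cm <- dense_cm(m, species = c("A", "A", "B"))
  rep <- barnyard(cm, t_minor = 0.1)
  pc <- rep$per_cell
  expect_equal(pc[pc$cell_id == "pureA", specificity], 1)
  expect_false(pc[pc$cell_id == "pureA", is_doublet])
  expect_equal(pc[pc$cell_id == "mix", specificity], 0.5)
  expect_true(pc[pc$cell_id == "mix", is_doublet])
  expect_equal(rep$summary$doublet_rate, 1 / 3)
  expect_true(all(pc$specificity >= 0.5 & pc$specificity <= 1))
  # swapping species labels leaves the doublet rate invariant
  cm2 <- dense_cm(m, species = c("B", "B", "A"))
  expect_equal(barnyard(cm2, 0.1)$summary$doublet_rate,
               rep$summary$doublet_rate)
  # single-species matrix: undefined rate with a warning
  cm1 <- dense_cm(m[1:2, , drop = FALSE], species = c("A", "A"))
  expect_warning(r1 <- barnyard(cm1), "single-species")
  expect_true(is.na(r1$summary$doublet_rate))
})

test_that("pre-indexing thins observed doublets by 1/K", {
  ann <- simulate_annotation(5L, seed = 71L)
  wl <- random_whitelist(sizes = c(24L, 24L, 24L), n_preindex = 12L,
                         seed = 72L)
  lambda <- 0.0613  # physical collisions ~ 3% of occupied droplets
  rates <- sapply(c(1L, 10L), function(K) {
    obs <- 0L; phys <- 0L
    for (s in 1:8) {
      cfg <- library_config(n_nuclei_A = 1500L, n_nuclei_B = 1500L,
                            K = K, lambda = lambda,
                            molecules_per_nucleus = 1,
                            ambient_fraction = 0, seed = 1000L + s)
      set.seed(cfg$seed)
      pr <- simulate_expression(ann, cfg)
      dr <- simulate_droplets(pr, wl, cfg)
      obs <- obs + sum(dr$droplets$observed_doublet)
      phys <- phys + sum(dr$droplets$physical_collision)
    }
    c(obs = obs, phys = phys)
  })
  p1 <- unname(rates["obs", 1] / rates["phys", 1])
  p10 <- unname(rates["obs", 2] / rates["phys", 2])
  expect_equal(p1, 1)
  se <- sqrt(0.1 * 0.9 / rates["phys", 2])
  expect_lt(abs(p10 - 1 / 10), 3 * se + 0.01)
})

test_that("region fractions partition to 100 percent", {
  dt <- data.table::data.table(region = c(rep("exon", 3), rep("intron", 6),
                                          "intergenic"))
  rf <- region_fractions(dt)
  expect_equal(sum(rf), 100)
  expect_equal(unname(rf["exon"]), 30)
  expect_equal(unname(rf["intron"]), 60)
  all_ex <- data.table::data.table(region = rep("exon", 5))
  expect_equal(unname(region_fractions(all_ex)["exon"]), 100)
  expect_error(region_fractions(dt[0]), "no reads")
  # percentages sum to 100 on random inputs
  set.seed(73)
  for (i in 1:5) {
    r <- data.table::data.table(
      region = sample(c("exon", "intron", "intergenic"), 50, TRUE))
    expect_equal(sum(region_fractions(r)), 100)
  }
})

test_that("a single read covers exactly its footprint bins", {
  genes <- data.table::data.table(
    gene_id = "g1", species = "A", biotype = "protein_coding",
    chrom = "c1", strand = "+", start = 0L, end = 1000L,
    spliced_len = 1000L, unspliced_len = 1000L, rate = 1)
  exons <- data.table::data.table(gene_id = "g1", chrom = "c1",
                                  strand = "+", start = 0L, end = 1000L)
  introns <- exons[0]
  ann <- snrand:::.index_annotation(genes, exons, introns,
                                    Biostrings::DNAStringSet())
  aln <- data.table::data.table(read_id = "r1", chrom = "c1",
                                start = 200L, end = 400L,
                                cell_id = "c", umi = "AAAA")
  cov <- genebody_coverage(aln, ann, B = 10L)
  expect_equal(cov$coverage, c(0, 0, 0.5, 0.5, 0, 0, 0, 0, 0, 0))
  expect_equal(sum(cov$coverage), 1)
  # reversing the strand reverses the profile exactly
  genes_m <- data.table::copy(genes)[, strand := "-"]
  exons_m <- data.table::copy(exons)[, strand := "-"]
  ann_m <- snrand:::.index_annotation(genes_m, exons_m, introns,
                                      Biostrings::DNAStringSet())
  cov_m <- genebody_coverage(aln, ann_m, B = 10L)
  expect_equal(cov_m$coverage, rev(cov$coverage))
  # a gene below min_len is excluded
  expect_error(genebody_coverage(aln, ann, B = 10L, min_len = 2000L),
               "min_len")
})

test_that("coverage projects exonic parts onto spliced coordinates", {
  ann <- manual_annotation()
  # read across g1's intron: only its exonic halves contribute, mapped to
  # adjacent transcript positions
  aln <- data.table::data.table(read_id = "r1", chrom = "chrA",
                                start = 150L, end = 350L,
                                cell_id = "c", umi = "AAAA")
  cov <- genebody_coverage(aln, ann, B = 10L, min_len = 100L)
  expect_equal(sum(cov$coverage), 1)
  # transcript footprint is [50,100)+[0,50 of exon2] = tx [50,150) of 200
  expect_equal(cov$coverage,
               c(0, 0, 0.1, 0.2, 0.2, 0.2, 0.2, 0.1, 0, 0))
})

test_that("biotype tallies count detected genes and UMIs", {
  m <- rbind(g1 = c(0, 0), g2 = c(3, 1), g3 = c(0, 5), g4 = c(0, 0))
  colnames(m) <- c("c1", "c2")
  cm <- dense_cm(m, biotype = c("lncRNA", "lncRNA", "weird", "miRNA"))
  bt <- biotype_counts(cm)
  expect_equal(bt[biotype == "lncRNA", genes_detected], 1L)
  expect_equal(bt[biotype == "other", genes_detected], 1L)
  expect_equal(bt[biotype == "miRNA", genes_detected], 0L)
  expect_equal(sum(bt$umis), sum(m))
  expect_equal(sum(bt$genes_detected), sum(rowSums(m) > 0))
  # zero matrix
  cm0 <- dense_cm(m * 0, biotype = c("lncRNA", "lncRNA", "weird", "miRNA"))
  expect_equal(sum(biotype_counts(cm0)$genes_detected), 0L)
})

test_that("filter_matrix applies exclusions and thresholds in order", {
  set.seed(74)
  m <- matrix(rpois(50 * 20, 1), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("c%02d", 1:20)))
  # nucleus boundary: 199 detected genes removed, 200 kept
  big <- matrix(0, 250, 2, dimnames = list(sprintf("G%03d", 1:250),
                                           c("n199", "n200")))
  big[1:199, 1] <- 1
  big[1:200, 2] <- 1
  cmb <- dense_cm(big)
  fb <- filter_matrix(cmb, filter_config(min_genes_per_nucleus = 200L,
                                         min_nuclei_per_gene = 0L))
  expect_equal(fb$matrix$cells, "n200")
  expect_equal(unname(fb$report["nuclei_removed"]), 1)
  # gene boundary: detected in 2 nuclei removed, 3 kept
  gm <- matrix(0, 2, 3, dimnames = list(c("gene2", "gene3"),
                                        c("c1", "c2", "c3")))
  gm["gene2", 1:2] <- 1
  gm["gene3", 1:3] <- 1
  cmg <- dense_cm(gm)
  fg <- filter_matrix(cmg, filter_config(min_genes_per_nucleus = 0L,
                                         min_nuclei_per_gene = 3L))
  expect_equal(fg$matrix$genes$gene_id, "gene3")
  # exclusion lists removed first
  cme <- dense_cm(m)
  fe <- filter_matrix(cme, filter_config(0L, 0L,
                                         exclude_genes = c("g01", "g02")))
  expect_equal(unname(fe$report["genes_excluded"]), 2)
  expect_false(any(c("g01", "g02") %in% fe$matrix$genes$gene_id))
  # zero thresholds and no exclusions: identity
  f0 <- filter_matrix(cme, filter_config(0L, 0L))
  expect_equal(dim(f0$matrix$layers$total), dim(m))
  # filtering everything yields an empty matrix, not an error
  fx_all <- filter_matrix(cme, filter_config(10000L, 0L))
  expect_equal(length(fx_all$matrix$cells), 0L)
  # idempotence on this matrix
  cfg <- filter_config(min_genes_per_nucleus = 5L, min_nuclei_per_gene = 2L)
  once <- filter_matrix(cme, cfg)
  twice <- filter_matrix(once$matrix, cfg)
  expect_equal(as.matrix(twice$matrix$layers$total),
               as.matrix(once$matrix$layers$total))
})

test_that("pseudobulk correlation: identity gives r = 1, disjoint errors", {
  fx <- fx_noisy()
  cm <- truth_matrix(fx$sim)
  r <- pseudobulk_correlation(cm, cm)
  expect_equal(r$r, 1)
  expect_gte(r$n_genes, 10L)
  # disjoint detected gene sets: error path
  m1 <- rbind(g1 = c(5, 2), g2 = c(1, 1), g3 = c(0, 0), g4 = c(0, 0))
  m2 <- rbind(g1 = c(0, 0), g2 = c(0, 0), g3 = c(2, 2), g4 = c(1, 3))
  colnames(m1) <- colnames(m2) <- c("c1", "c2")
  expect_error(pseudobulk_correlation(dense_cm(m1), dense_cm(m2)),
               "fewer than 10")
})

test_that("saturation at f = 1 is bit-identical to the direct pipeline", {
  fx <- fx_noisy()
  sim <- fx$sim
  aln <- assign_features(truth_alignments(sim), sim$annotation)$assigned
  cells <- sort(unique(aln$cell_id))
  sat <- saturation(aln, sim$annotation, fractions = c(0.05, 0.5, 1),
                    seed = 7L, called_cells = cells)
  cm <- count_matrix(aln, sim$annotation, called_cells = cells)
  tot <- cm$layers$total
  expect_identical(sat[f == 1, median_genes],
                   median(Matrix::colSums(tot > 0)))
  expect_identical(sat[f == 1, median_umis], median(Matrix::colSums(tot)))
  expect_lt(sat[f == 0.05, median_genes], sat[f == 1, median_genes])
  expect_error(saturation(aln[0], sim$annotation), "no alignments")
})

test_that("exclusion lists cover mitochondrial and ribosomal genes", {
  ann <- simulate_annotation(50L, seed = 75L)
  ex <- exclusion_lists(ann)
  expect_setequal(unique(ann$genes[gene_id %in% ex, biotype]),
                  c("mito", "ribo"))
  expect_equal(length(ex),
               nrow(ann$genes[biotype %in% c("mito", "ribo")]))
})
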