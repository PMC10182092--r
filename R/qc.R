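# Library validation metrics: barnyard statistics, region fractions,
# gene-body coverage, biotype tallies, saturation, filtering, pseudobulk
# correlation.

#' Species-mixing (barnyard) report
#'
#' Splits each cell's UMIs by gene species, computes the per-cell species
#' specificity `s_c = max(umis_A, umis_B) / (umis_A + umis_B)`, and flags a
#' cell as a doublet when the minor-species fraction is at least `t_minor`.
#' The summary doublet rate `D` is doublets / cells with counts.
#'
#' @param cm A `count_matrix` whose genes carry a two-level `species` label.
#' @param t_minor Minor-species UMI fraction at or above which a cell is a
#'   doublet.
#' @return A `barnyard_report`: `per_cell` table (cell_id, umis_A, umis_B,
#'   specificity, majority species, is_doublet) and `summary` (doublet_rate,
#'   per-species median specificity, t_minor). With a single-species matrix,
#'   `doublet_rate` is `NA` with a warning.
#' @export
barnyard <- function(cm, t_minor = 0.1) {
  sp <- sort(unique(cm$genes$species))
  tot <- cm$layers$total
  if (length(sp) < 2L) {
    warning("single-species matrix: doublet rate undefined")
    uA <- Matrix::colSums(tot)
    per_cell <- data.table(cell_id = cm$cells, umis_A = as.numeric(uA),
                           umis_B = 0, specificity = 1,
                           majority = sp[1], is_doublet = FALSE)
    out <- list(per_cell = per_cell,
                summary = list(doublet_rate = NA_real_,
                               median_specificity = setNames(1, sp[1]),
                               t_minor = t_minor))
    class(out) <- "barnyard_report"
    return(out)
  }
  uA <- Matrix::colSums(tot[cm$genes$species == sp[1], , drop = FALSE])
  uB <- Matrix::colSums(tot[cm$genes$species == sp[2], , drop = FALSE])
  total <- uA + uB
  keep <- total > 0
  spec <- ifelse(keep, pmax(uA, uB) / total, NA_real_)
  minor <- ifelse(keep, pmin(uA, uB) / total, NA_real_)
  per_cell <- data.table(
    cell_id = cm$cells, umis_A = as.numeric(uA), umis_B = as.numeric(uB),
    specificity = as.numeric(spec),
    majority = ifelse(uA >= uB, sp[1], sp[2]),
    is_doublet = !is.na(minor) & minor >= t_minor)
  med <- vapply(sp, function(s) {
    v <- per_cell[majority == s & !is.na(specificity), specificity]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  out <- list(per_cell = per_cell,
              summary = list(
                doublet_rate = sum(per_cell$is_doublet) / sum(keep),
                median_specificity = med,
                t_minor = t_minor))
  class(out) <- "barnyard_report"
  out
}

#' @exportS3Method base::print
print.barnyard_report <- function(x, ...) {
  cat("barnyard_report:", nrow(x$per_cell), "cells; doublet rate",
      format(x$summary$doublet_rate, digits = 3), "\n")
  invisible(x)
}

#' Read fractions by genomic region
#'
#' Percentages of exon, intron and intergenic reads; always partitions to
#' 100 over the counted reads.
#'
#' @param x An assignment report from [assign_features()] (named counts with
#'   `exon`, `intron`), or a table of tagged alignments with a `region`
#'   column.
#' @return Named numeric vector: percentages `exon`, `intron`, `intergenic`.
#' @export
region_fractions <- function(x) {
  if (is.numeric(x) && all(c("exon", "intron") %in% names(x))) {
    counts <- c(exon = unname(x["exon"]), intron = unname(x["intron"]),
                intergenic = unname(x["intergenic"]) +
                  unname(x[["intergenic_region"]] %||% 0))
  } else {
    dt <- as.data.table(x)
    stopifnot("region" %in% names(dt))
    counts <- c(exon = dt[region == "exon", .N],
                intron = dt[region == "intron", .N],
                intergenic = dt[region == "intergenic", .N])
  }
  total <- sum(counts)
  if (total == 0) stop("no reads to compute region fractions from")
  100 * counts / total
}

#' Gene-body coverage profile
#'
#' For every gene with spliced length at least `min_len`, projects the
#' exonic part of each assigned alignment onto spliced-transcript
#' coordinates, rescales to `B` bins from 5' to 3' (strand-aware), and
#' accumulates fractional bin overlaps. The profile is normalized to sum
#' to 1.
#'
#' @param alignments Alignment records (assigned via [assign_features()]
#'   first when `gene_id` is absent).
#' @param annotation A `toy_annotation`.
#' @param B Number of bins.
#' @param min_len Minimum spliced length of qualifying genes (nt).
#' @return A `coverage_profile`: list with `coverage` (length-`B` numeric
#'   summing to 1), `B`, `n_transcripts`.
#' @export
genebody_coverage <- function(alignments, annotation, B = 100L,
                              min_len = 500L) {
  aln <- as.data.table(alignments)
  if (!"gene_id" %in% names(aln)) {
    aln <- assign_features(aln, annotation)$assigned
  }
  qual <- annotation$genes[spliced_len >= min_len,
                           .(gene_id, spliced_len)]
  if (!nrow(qual)) stop("no transcript with spliced length >= min_len")
  aln <- aln[!is.na(gene_id)][qual, on = "gene_id", nomatch = NULL]
  ex <- annotation$exons[, .(gene_id, ex_start = start, ex_end = end,
                             tx_off, bstart, bend, strand)]
  # exon pieces overlapped by each alignment, in genomic coordinates
  pieces <- ex[aln, on = "gene_id", allow.cartesian = TRUE, nomatch = NULL]
  pieces <- pieces[pmax(start, ex_start) < pmin(end, ex_end)]
  if (!nrow(pieces)) stop("no exonic coverage on qualifying transcripts")
  pieces[, `:=`(ov_s = pmax(start, ex_start), ov_e = pmin(end, ex_end))]
  # genomic -> transcript coordinates, strand-aware
  pieces[, `:=`(
    t1 = fifelse(strand == "+", tx_off + (ov_s - ex_start),
                 tx_off + (ex_end - ov_e)),
    t2 = fifelse(strand == "+", tx_off + (ov_e - ex_start),
                 tx_off + (ex_end - ov_s)))]
  # scale to bin units
  pieces[, `:=`(a = t1 * B / spliced_len, b = t2 * B / spliced_len)]
  k1 <- pmax(0L, pmin(B - 1L, as.integer(floor(pieces$a))))
  k2 <- pmax(0L, pmin(B - 1L, as.integer(ceiling(pieces$b)) - 1L))
  nb <- k2 - k1 + 1L
  ks <- sequence(nb) - 1L + rep(k1, nb)
  aa <- rep(pieces$a, nb)
  bb <- rep(pieces$b, nb)
  contrib <- pmin(bb, ks + 1) - pmax(aa, ks)
  contrib[contrib < 0] <- 0
  cov <- numeric(B)
  agg <- rowsum(contrib, ks)
  cov[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  out <- list(coverage = cov / sum(cov), B = B,
              n_transcripts = length(unique(pieces$gene_id)))
  class(out) <- "coverage_profile"
  out
}

#' @exportS3Method base::print
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$B, "bins over", x$n_transcripts,
      "transcripts; 5'/3' decile means",
      format(mean(x$coverage[seq_len(x$B %/% 10)]), digits = 3), "/",
      format(mean(x$coverage[(x$B - x$B %/% 10 + 1):x$B]), digits = 3),
      "\n")
  invisible(x)
}

#' Detected genes and UMIs per RNA biotype
#'
#' A gene is detected when its total count is positive. Unknown biotype
#' labels are tallied under `other`.
#' @param cm A `count_matrix`.
#' @return `data.table(biotype, genes_detected, umis)`.
#' @export
biotype_counts <- function(cm) {
  bt <- cm$genes$biotype
  bt[!bt %in% BIOTYPES] <- "other"
  tot <- cm$layers$total
  dt <- data.table(biotype = bt,
                   detected = Matrix::rowSums(tot) > 0,
                   umis = Matrix::rowSums(tot))
  out <- dt[, .(genes_detected = sum(detected), umis = sum(umis)),
            by = biotype]
  setorder(out, biotype)
  out
}

#' Sequencing-saturation curve by downsampling
#'
#' Subsamples the tagged alignments without replacement at each fraction
#' (seeded), re-runs gene assignment, UMI collapse and counting, and records
#' the median genes and UMIs per called cell. At `f = 1` the subsample is
#' the full input, so the medians equal the direct pipeline's exactly.
#'
#' @param alignments Tagged alignment records.
#' @param annotation A `toy_annotation`.
#' @param fractions Sorted downsampling fractions in (0, 1].
#' @param seed Seed for the subsampling draws.
#' @param called_cells Cells over which medians are taken; defaults to all
#'   cells present in the full data. Cells with no remaining reads count as
#'   zero.
#' @param umi_mode Passed to [count_matrix()].
#' @return A `saturation_curve`: `data.table(f, median_genes, median_umis)`
#'   plus the seed as an attribute.
#' @export
saturation <- function(alignments, annotation, fractions = c(0.1, 0.25,
                                                             0.5, 0.75, 1),
                       seed = 1L, called_cells = NULL,
                       umi_mode = "directional") {
  aln <- as.data.table(alignments)
  if (!nrow(aln)) stop("no alignments to downsample")
  stopifnot(!is.unsorted(fractions), all(fractions > 0), all(fractions <= 1))
  if (!all(c("gene_id", "region") %in% names(aln))) {
    aln <- assign_features(aln, annotation)$assigned
  }
  if (is.null(called_cells)) called_cells <- sort(unique(aln$cell_id))
  set.seed(seed)
  res <- lapply(fractions, function(f) {
    idx <- sort(sample.int(nrow(aln), round(f * nrow(aln))))
    cm <- count_matrix(aln[idx], annotation, called_cells = called_cells,
                       umi_mode = umi_mode)
    tot <- cm$layers$total
    data.table(f = f,
               median_genes = median(Matrix::colSums(tot > 0)),
               median_umis = median(Matrix::colSums(tot)))
  })
  out <- rbindlist(res)
  setattr(out, "seed", seed)
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Matrix filtering configuration
#'
#' Defaults follow the standard post-quantification filter: nuclei with
#' fewer than 200 detected genes and genes detected in fewer than three
#' nuclei are removed, after dropping mitochondrial and ribosomal genes.
#' @param min_genes_per_nucleus Minimum detected genes to keep a nucleus.
#' @param min_nuclei_per_gene Minimum nuclei a gene must be detected in.
#' @param exclude_genes Character vector of gene ids (e.g. mitochondrial and
#'   ribosomal RNAs) removed before thresholding.
#' @export
filter_config <- function(min_genes_per_nucleus = 200L,
                          min_nuclei_per_gene = 3L,
                          exclude_genes = character()) {
  stopifnot(min_genes_per_nucleus >= 0L, min_nuclei_per_gene >= 0L)
  out <- list(min_genes_per_nucleus = as.integer(min_genes_per_nucleus),
              min_nuclei_per_gene = as.integer(min_nuclei_per_gene),
              exclude_genes = exclude_genes)
  class(out) <- "filter_config"
  out
}

#' Mitochondrial/ribosomal exclusion lists from a toy annotation
#' @param annotation A `toy_annotation`.
#' @return Character vector of gene ids with biotype `mito` or `ribo`.
#' @export
exclusion_lists <- function(annotation) {
  annotation$genes[biotype %in% c("mito", "ribo"), gene_id]
}

#' Filter a count matrix
#'
#' Single pass in a fixed order: excluded genes are removed first, then
#' nuclei with fewer than `min_genes_per_nucleus` detected genes, then genes
#' detected in fewer than `min_nuclei_per_gene` of the remaining nuclei.
#' Filtering everything yields an empty matrix with an explicit report, not
#' an error.
#'
#' @param cm A `count_matrix`.
#' @param config A [filter_config()].
#' @return List with `matrix` (filtered `count_matrix`) and `report` (named
#'   counts of removals per class).
#' @export
filter_matrix <- function(cm, config = filter_config()) {
  tot <- cm$layers$total
  excl <- cm$genes$gene_id %in% config$exclude_genes
  keep_g <- !excl
  tot1 <- tot[keep_g, , drop = FALSE]
  genes_det <- Matrix::colSums(tot1 > 0)
  keep_c <- genes_det >= config$min_genes_per_nucleus
  tot2 <- tot1[, keep_c, drop = FALSE]
  nuclei_det <- Matrix::rowSums(tot2 > 0)
  keep_g2 <- nuclei_det >= config$min_nuclei_per_gene
  sel_g <- which(keep_g)[keep_g2]
  sel_c <- which(keep_c)
  layers <- lapply(cm$layers, function(m) m[sel_g, sel_c, drop = FALSE])
  out <- list(layers = layers, genes = cm$genes[sel_g],
              cells = cm$cells[sel_c])
  class(out) <- "count_matrix"
  report <- c(genes_excluded = sum(excl),
              nuclei_removed = sum(!keep_c),
              genes_low_detection = sum(!keep_g2),
              genes_kept = length(sel_g),
              nuclei_kept = length(sel_c))
  list(matrix = out, report = report)
}

#' Pseudobulk replicate correlation
#'
#' Depth-normalizes each cell to counts-per-10k, averages over cells per
#' gene, transforms with the natural logarithm of the average expression
#' with one added pseudocount, and returns the Pearson correlation over the
#' genes detected in both matrices. Fewer than 10 shared detected genes is
#' an error.
#'
#' @param cmA,cmB Two `count_matrix` objects.
#' @return List with `r`, `n_genes`, and the paired gene table
#'   (`gene_id`, `lnA`, `lnB`).
#' @export
pseudobulk_correlation <- function(cmA, cmB) {
  avg <- function(cm) {
    tot <- cm$layers$total
    depth <- Matrix::colSums(tot)
    keep <- depth > 0
    if (!any(keep)) stop("matrix has no counts")
    norm <- tot[, keep, drop = FALSE] %*%
      Matrix::Diagonal(x = 1e4 / depth[keep])
    setNames(as.numeric(Matrix::rowSums(norm)) / sum(keep),
             cm$genes$gene_id)
  }
  mA <- avg(cmA); mB <- avg(cmB)
  shared <- intersect(names(mA)[mA > 0], names(mB)[mB > 0])
  if (length(shared) < 10L)
    stop("fewer than 10 genes detected in both matrices")
  lnA <- log(mA[shared] + 1)
  lnB <- log(mB[shared] + 1)
  list(r = cor(lnA, lnB), n_genes = length(shared),
       table = data.table(gene_id = shared, lnA = unname(lnA),
                          lnB = unname(lnB)))
}
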