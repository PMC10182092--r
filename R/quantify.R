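# Gene/region assignment, directional UMI deduplication and layered
# cell-by-gene count matrices.

.ann_granges <- function(annotation) {
  g <- annotation$genes
  genes_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), gene_id = g$gene_id)
  ex <- annotation$exons
  exons_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end)))
  intr <- annotation$introns
  introns_gr <- if (nrow(intr)) {
    GenomicRanges::GRanges(intr$chrom,
                           IRanges::IRanges(intr$start + 1L, intr$end))
  } else GenomicRanges::GRanges()
  list(genes = genes_gr, exons = exons_gr, introns = introns_gr)
}

#' Assign alignment records to genes and regions
#'
#' Gene-body assignment: a record overlapping exactly one gene span is
#' assigned to that gene; records overlapping two or more gene bodies are
#' discarded as ambiguous (counted); records overlapping none are
#' intergenic. The region is `exon` when the alignment interval is fully
#' contained in exonic sequence, `intron` when it overlaps any intronic
#' sequence, and `intergenic` otherwise. Strand is ignored (random-primed
#' second-strand chemistry makes the strand of origin ambiguous).
#' Coordinates are 0-based half-open.
#'
#' @param alignments `data.table`/data.frame with `read_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and any tag columns (`cell_id`,
#'   `umi`) to carry through.
#' @param annotation A `toy_annotation`.
#' @return List with `assigned` (input rows plus `gene_id`, `region`;
#'   multi-gene rows dropped) and `report` (named counts: assigned,
#'   ambiguous_gene, intergenic, missing_chrom, plus exon/intron/intergenic
#'   region tallies over gene-assigned reads).
#' @export
assign_features <- function(alignments, annotation) {
  aln <- as.data.table(alignments)
  stopifnot(all(c("chrom", "start", "end") %in% names(aln)),
            all(aln$start < aln$end))
  grs <- .ann_granges(annotation)
  known <- aln$chrom %in% unique(annotation$genes$chrom)
  missing_chrom <- sum(!known)
  if (missing_chrom > 0L)
    warning(missing_chrom, " records on chromosomes absent from annotation")
  reads_gr <- GenomicRanges::GRanges(
    ifelse(known, aln$chrom, "__absent__"),
    IRanges::IRanges(aln$start + 1L, aln$end))
  # suppress seqlevel-mismatch chatter for reads on unknown chromosomes
  nhits <- suppressWarnings(
    GenomicRanges::countOverlaps(reads_gr, grs$genes))
  fo <- suppressWarnings(GenomicRanges::findOverlaps(reads_gr, grs$genes))
  one <- which(nhits == 1L)
  gene_of <- rep(NA_character_, nrow(aln))
  first_hit <- S4Vectors::queryHits(fo)
  sel <- !duplicated(first_hit)
  gene_of[first_hit[sel]] <-
    grs$genes$gene_id[S4Vectors::subjectHits(fo)[sel]]
  gene_of[nhits != 1L] <- NA_character_

  region <- rep("intergenic", nrow(aln))
  assigned_idx <- which(nhits == 1L)
  if (length(assigned_idx)) {
    sub <- reads_gr[assigned_idx]
    # exonic containment: summed exonic overlap equals the read width
    ov <- GenomicRanges::findOverlaps(sub, grs$exons)
    ovw <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(sub)[S4Vectors::queryHits(ov)],
      IRanges::ranges(grs$exons)[S4Vectors::subjectHits(ov)]))
    exw <- rep(0L, length(sub))
    if (length(ov)) {
      agg <- rowsum(ovw, S4Vectors::queryHits(ov))
      exw[as.integer(rownames(agg))] <- agg[, 1]
    }
    in_exon <- exw == GenomicRanges::width(sub)
    in_intron <- IRanges::overlapsAny(sub, grs$introns)
    region[assigned_idx[in_exon]] <- "exon"
    region[assigned_idx[!in_exon & in_intron]] <- "intron"
  }

  aln[, `:=`(gene_id = gene_of, region = region)]
  ambiguous <- sum(nhits >= 2L)
  out <- aln[nhits < 2L]
  report <- c(
    total = nrow(aln),
    assigned = sum(!is.na(out$gene_id)),
    ambiguous_gene = ambiguous,
    intergenic = sum(is.na(out$gene_id)),
    missing_chrom = missing_chrom,
    exon = sum(out$region == "exon" & !is.na(out$gene_id)),
    intron = sum(out$region == "intron" & !is.na(out$gene_id)),
    intergenic_region = sum(out$region == "intergenic" &
                              !is.na(out$gene_id)))
  list(assigned = out, report = report)
}

#' Assign a single alignment record
#'
#' Scalar wrapper around [assign_features()].
#' @param rec One-row data.frame/list with `chrom`, `start`, `end`.
#' @param annotation A `toy_annotation`.
#' @return List with `gene_id` (`NA` for intergenic or multi-gene), `region`.
#' @export
assign_feature <- function(rec, annotation) {
  r <- assign_features(as.data.table(rec)[, .(read_id = "r", chrom, start,
                                              end)], annotation)
  if (!nrow(r$assigned)) return(list(gene_id = NA_character_,
                                     region = "ambiguous"))
  list(gene_id = r$assigned$gene_id[1], region = r$assigned$region[1])
}

# Directional single-link UMI clustering within one group.
# Returns the representative UMI for each distinct input UMI.
.umi_cluster_group <- function(umis, counts, mode) {
  k <- length(umis)
  if (k == 1L) return(setNames(umis, umis))
  if (mode == "exact") return(setNames(umis, umis))
  ord <- order(-counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  w <- nchar(umis[1])
  m <- .seq_mat(umis, w)
  rep_of <- rep(NA_character_, k)
  visited <- rep(FALSE, k)
  for (i in seq_len(k)) {
    if (visited[i]) next
    # BFS over directional edges u -> v: d(u,v) == 1 and cnt(u) >= 2 cnt(v) - 1
    comp <- i
    visited[i] <- TRUE
    frontier <- i
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        cand <- which(!visited)
        if (!length(cand)) break
        d <- colSums(m[, cand, drop = FALSE] != m[, u])
        hit <- cand[d == 1L & counts[u] >= 2L * counts[cand] - 1L]
        if (length(hit)) {
          visited[hit] <- TRUE
          nxt <- c(nxt, hit)
          comp <- c(comp, hit)
        }
      }
      frontier <- nxt
    }
    rep_of[comp] <- umis[i]
  }
  setNames(rep_of, umis)
}

#' Cluster UMIs within one (cell, gene) group
#'
#' Directional single-link collapse: a UMI `v` merges into a more abundant
#' UMI `u` when they differ by one substitution and
#' `count(u) >= 2 * count(v) - 1`; components are grown from the most
#' abundant unvisited UMI (ties broken lexicographically), so the result is
#' deterministic. `mode = "exact"` disables merging.
#'
#' @param umis Character vector of UMIs, one per read.
#' @param mode `"directional"` (default) or `"exact"`.
#' @return Character vector, same length as `umis`: the representative
#'   (molecule) UMI of each read.
#' @export
umi_clusters <- function(umis, mode = c("directional", "exact")) {
  mode <- match.arg(mode)
  if (!length(umis)) return(character())
  tab <- table(umis)
  map <- .umi_cluster_group(names(tab), as.integer(tab), mode)
  unname(map[umis])
}

#' Count molecules in a UMI group
#'
#' Number of surviving representatives after directional collapse.
#' @inheritParams umi_clusters
#' @return Integer molecule count (0 for an empty group).
#' @export
dedup_umis <- function(umis, mode = c("directional", "exact")) {
  mode <- match.arg(mode)
  if (!length(umis)) return(0L)
  length(unique(umi_clusters(umis, mode)))
}

# counts: data.table(cell_id, gene_id, spliced, unspliced, ambiguous)
.build_count_matrix <- function(counts, annotation, cells = NULL) {
  genes <- annotation$genes[, .(gene_id, species, biotype)]
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
  if (is.null(cells)) {
    cells <- sort(unique(counts$cell_id))
  } else {
    counts <- counts[cell_id %in% cells]
  }
  gi <- match(counts$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("counts refer to genes absent from annotation")
  ci <- match(counts$cell_id, cells)
  mk <- function(x) {
    keep <- x > 0L
    Matrix::sparseMatrix(i = gi[keep], j = ci[keep], x = as.numeric(x[keep]),
                         dims = c(nrow(genes), length(cells)),
                         dimnames = list(genes$gene_id, cells))
  }
  layers <- list(spliced = mk(counts$spliced),
                 unspliced = mk(counts$unspliced),
                 ambiguous = mk(counts$ambiguous))
  layers <- c(list(total = layers$spliced + layers$unspliced +
                     layers$ambiguous), layers)
  out <- list(layers = layers, genes = genes, cells = cells)
  class(out) <- "count_matrix"
  out
}

#' Build a layered cell-by-gene UMI count matrix
#'
#' Groups tagged alignments by (cell, gene), collapses UMIs with the
#' directional rule, and classifies each molecule: `spliced` when all of its
#' reads are fully exonic, `unspliced` when any read overlaps an intron, and
#' `ambiguous` otherwise (single-read molecules are never ambiguous in
#' practice since a fully exonic read is spliced and an intron-overlapping
#' one is unspliced). The `total` layer is the elementwise sum of the other
#' three. Genes are rows (all annotation genes, detected or not); cells are
#' columns.
#'
#' @param alignments Tagged alignment records (`cell_id`, `umi`, `chrom`,
#'   `start`, `end`); if `gene_id`/`region` are absent, [assign_features()]
#'   is run first.
#' @param annotation A `toy_annotation`.
#' @param called_cells Optional cell subset/ordering to restrict to.
#' @param umi_mode `"directional"` or `"exact"`.
#' @return A `count_matrix`: list with `layers` (total, spliced, unspliced,
#'   ambiguous sparse matrices), `genes` (with species/biotype metadata),
#'   `cells`.
#' @export
count_matrix <- function(alignments, annotation, called_cells = NULL,
                         umi_mode = c("directional", "exact")) {
  umi_mode <- match.arg(umi_mode)
  aln <- as.data.table(alignments)
  if (!all(c("gene_id", "region") %in% names(aln))) {
    aln <- assign_features(aln, annotation)$assigned
  }
  stopifnot(all(c("cell_id", "umi") %in% names(aln)))
  aln <- aln[!is.na(gene_id)]
  if (!is.null(called_cells)) aln <- aln[cell_id %in% called_cells]
  if (!nrow(aln)) {
    return(.build_count_matrix(
      data.table(cell_id = character(), gene_id = character(),
                 spliced = integer(), unspliced = integer(),
                 ambiguous = integer()),
      annotation, called_cells))
  }
  aln[, rep_umi := umi_clusters(umi, umi_mode), by = .(cell_id, gene_id)]
  mols <- aln[, .(all_exon = all(region == "exon"),
                  any_intron = any(region == "intron")),
              by = .(cell_id, gene_id, rep_umi)]
  mols[, layer := fifelse(all_exon, "spliced",
                          fifelse(any_intron, "unspliced", "ambiguous"))]
  counts <- dcast(mols[, .N, by = .(cell_id, gene_id, layer)],
                  cell_id + gene_id ~ layer, value.var = "N", fill = 0L)
  for (col in c("spliced", "unspliced", "ambiguous")) {
    if (!col %in% names(counts)) counts[, (col) := 0L]
  }
  .build_count_matrix(counts, annotation, called_cells)
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$genes), "genes x", length(x$cells), "cells;",
      sum(x$layers$total), "molecules (",
      sum(x$layers$spliced), "spliced /", sum(x$layers$unspliced),
      "unspliced /", sum(x$layers$ambiguous), "ambiguous )\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) c(nrow(x$genes), length(x$cells))

#' Write a count matrix as MatrixMarket + sidecars
#'
#' Writes `barcodes.tsv`, `features.tsv` (gene_id, species, biotype) and one
#' `matrix_<layer>.mtx` per layer into `dir`.
#' @param cm A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @export
write_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(cm$cells, file.path(dir, "barcodes.tsv"))
  fwrite(cm$genes, file.path(dir, "features.tsv"), sep = "\t")
  for (ly in names(cm$layers)) {
    Matrix::writeMM(cm$layers[[ly]],
                    file.path(dir, paste0("matrix_", ly, ".mtx")))
  }
  invisible(dir)
}

#' Read a count matrix written by [write_matrix()]
#' @param dir Directory containing the files.
#' @return A `count_matrix`.
#' @export
read_matrix <- function(dir) {
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- fread(file.path(dir, "features.tsv"))
  layer_files <- list.files(dir, pattern = "^matrix_.*\\.mtx$")
  layers <- list()
  for (f in layer_files) {
    ly <- sub("^matrix_(.*)\\.mtx$", "\\1", f)
    m <- as(Matrix::readMM(file.path(dir, f)), "CsparseMatrix") * 1
    if (nrow(m) != nrow(genes) || ncol(m) != length(cells))
      stop("dimension mismatch between ", f, " and sidecar files")
    dimnames(m) <- list(genes$gene_id, cells)
    layers[[ly]] <- m
  }
  need <- c("total", "spliced", "unspliced", "ambiguous")
  if (!all(need %in% names(layers)))
    stop("missing layer files: ", paste(setdiff(need, names(layers)),
                                        collapse = ", "))
  out <- list(layers = layers[need], genes = genes, cells = cells)
  class(out) <- "count_matrix"
  out
}

#' Read tagged alignment records from SAM/BAM
#'
#' Ingests ungapped records (single-M cigars, as written by
#' [write_alignments_sam()]) with CB/UB tags via Rsamtools, converting to
#' 0-based half-open coordinates.
#' @param path SAM or BAM file.
#' @return `data.table(read_id, chrom, start, end, strand, cell_id, umi)`.
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM input")
  if (grepl("\\.sam$", path)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand"),
    tag = c("CB", "UB")))[[1]]
  data.table(read_id = b$qname,
             chrom = as.character(b$rname),
             start = b$pos - 1L,
             end = b$pos - 1L + b$qwidth,
             strand = as.character(b$strand),
             cell_id = b$tag$CB,
             umi = b$tag$UB)
}

#' Write tagged alignment records as SAM text
#'
#' Emits unmapped-quality-agnostic ungapped records (cigar `<len>M`, flag
#' 0/16 by strand) with CB/UB tags, suitable for [read_alignments_sam()].
#' @param alignments Records with `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `cell_id`, `umi`.
#' @param path Output `.sam` path.
#' @param chrom_lens Named integer vector of chromosome lengths for the
#'   header.
#' @export
write_alignments_sam <- function(alignments, path, chrom_lens) {
  aln <- as.data.table(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens),
                   as.integer(chrom_lens)))
  w <- aln$end - aln$start
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tCB:Z:%s\tUB:Z:%s",
    aln$read_id, ifelse(aln$strand == "-", 16L, 0L), aln$chrom,
    aln$start + 1L, w, strrep("N", w), aln$cell_id, aln$umi)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
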