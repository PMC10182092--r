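# File interfaces: FASTQ, whitelist text files, GTF-lite annotation,
# reference FASTA, YAML configs, library export.

#' Read a FASTQ file
#'
#' Returns a named character vector of sequences (names = record ids, first
#' whitespace-delimited token retained with any comment). Gzip handled
#' transparently.
#' @param path FASTQ path (.fastq or .fastq.gz).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write a FASTQ file with constant qualities
#'
#' The pipeline never consumes base qualities; records are written with a
#' constant Q37 ('F') quality string.
#' @param seqs Named character vector (names = read ids).
#' @param path Output path; `.gz` suffix compresses.
#' @export
write_fastq <- function(seqs, path) {
  s <- Biostrings::DNAStringSet(unname(seqs))
  names(s) <- names(seqs)
  q <- Biostrings::BStringSet(strrep("F", nchar(seqs)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

.read_segment_file <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read a split-pool whitelist from text files
#'
#' Each file holds one segment per line; `#` starts a comment. Supply one
#' file per ligation round (preferred) or a single combined file of full
#' barcodes split by `segment_lens`.
#' @param round_files Character vector of per-round files, or one combined
#'   file.
#' @param preindex_file Optional pre-index file.
#' @param segment_lens Segment lengths used to split a combined file.
#' @return A `barcode_whitelist`.
#' @export
read_whitelist <- function(round_files, preindex_file = NULL,
                           segment_lens = c(10L, 10L, 10L)) {
  pres <- if (!is.null(preindex_file)) .read_segment_file(preindex_file)
    else character()
  if (length(round_files) == 1L) {
    full <- .read_segment_file(round_files)
    if (all(nchar(full) == sum(segment_lens))) {
      pos <- cumsum(c(1L, segment_lens))
      rounds <- lapply(seq_along(segment_lens), function(i) {
        unique(substr(full, pos[i], pos[i + 1L] - 1L))
      })
      return(build_whitelist(rounds, pres))
    }
    return(build_whitelist(list(full), pres))
  }
  build_whitelist(lapply(round_files, .read_segment_file), pres)
}

#' Write whitelist round files
#' @param whitelist A `barcode_whitelist`.
#' @param dir Output directory (round1.txt, round2.txt, ..., preindexes.txt).
#' @export
write_whitelist <- function(whitelist, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(whitelist$rounds)) {
    writeLines(whitelist$rounds[[r]],
               file.path(dir, sprintf("round%d.txt", r)))
  }
  if (length(whitelist$preindexes))
    writeLines(whitelist$preindexes, file.path(dir, "preindexes.txt"))
  invisible(dir)
}

#' Write a toy annotation as GTF-lite TSV
#'
#' One row per feature (`gene`, `exon`, `intron`) with 0-based half-open
#' coordinates and gene metadata columns.
#' @param annotation A `toy_annotation`.
#' @param path Output TSV path.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes[, .(feature = "gene", gene_id, chrom, start, end,
                            strand, species, biotype, rate)]
  e <- annotation$exons[, .(feature = "exon", gene_id, chrom, start, end,
                            strand, species = NA_character_,
                            biotype = NA_character_, rate = NA_real_)]
  i <- annotation$introns[, .(feature = "intron", gene_id, chrom, start,
                              end, strand, species = NA_character_,
                              biotype = NA_character_, rate = NA_real_)]
  fwrite(rbind(g, e, i), path, sep = "\t")
  invisible(path)
}

#' Read a GTF-lite annotation written by [write_annotation()]
#'
#' @param path TSV path.
#' @param fasta Optional reference FASTA to attach chromosome sequences
#'   (required for read simulation, not for quantification).
#' @return A `toy_annotation`.
#' @export
read_annotation <- function(path, fasta = NULL) {
  dt <- fread(path)
  genes <- dt[feature == "gene", .(gene_id, species, biotype, chrom,
                                   strand, start, end, rate)]
  ex <- dt[feature == "exon", .(gene_id, chrom, strand, start, end)]
  intr <- dt[feature == "intron", .(gene_id, chrom, strand, start, end)]
  sl <- ex[, .(spliced_len = sum(end - start)), by = gene_id]
  genes <- sl[genes, on = "gene_id"]
  genes[, unspliced_len := end - start]
  setcolorder(genes, c("gene_id", "species", "biotype", "chrom", "strand",
                       "start", "end", "spliced_len", "unspliced_len",
                       "rate"))
  seqs <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else
    Biostrings::DNAStringSet()
  if (length(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  .index_annotation(genes, ex, intr, seqs)
}

#' Write the reference FASTA of a toy annotation
#' @param annotation A `toy_annotation`.
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(annotation, path) {
  Biostrings::writeXStringSet(annotation$seqs, path)
  invisible(path)
}

#' Read/write a read-structure or library config as YAML
#' @param x A `read_structure` or `library_config`.
#' @param path YAML path.
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(c(list(.class = class(x)[1]), unclass(x)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class %||% "list"
  x$.class <- NULL
  if (cls == "read_structure") {
    do.call(read_structure, x)
  } else if (cls == "library_config") {
    do.call(library_config, x)
  } else x
}

#' Export a simulated library to disk
#'
#' Writes R1/R2 FASTQ, truth tables (reads, molecules, nuclei, droplets) as
#' TSV, the annotation (GTF-lite + reference FASTA), the whitelist round
#' files and a YAML echo of the configuration.
#' @param sim A `snrand_sim`.
#' @param dir Output directory.
#' @param gzip Compress the FASTQ files.
#' @export
write_library <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  write_fastq(sim$r1, file.path(dir, paste0("R1", ext)))
  write_fastq(sim$r2, file.path(dir, paste0("R2", ext)))
  fwrite(sim$reads, file.path(dir, "truth_reads.tsv"), sep = "\t")
  fwrite(sim$molecules, file.path(dir, "truth_molecules.tsv"), sep = "\t")
  fwrite(sim$nuclei, file.path(dir, "truth_nuclei.tsv"), sep = "\t")
  fwrite(sim$droplets, file.path(dir, "truth_droplets.tsv"), sep = "\t")
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_reference_fasta(sim$annotation, file.path(dir, "reference.fa"))
  if (!is.null(sim$whitelist))
    write_whitelist(sim$whitelist, file.path(dir, "whitelist"))
  write_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
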