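# Paired-FASTQ demultiplexing: trimming, barcode/pre-index correction,
# tagged-read emission and run report.

#' Trim Read2: split off the pre-index and the dA-tail read-through
#'
#' Removes the first `preindex_len` bases (returned separately) and trims a
#' trailing homopolymer run (dA-tail read-through, >= 4 bases) from the 3'
#' end, with the same per-10-nt mismatch tolerance as the Read1 junction.
#' Reads shorter than the pre-index are flagged `malformed` (counted, not an
#' error).
#'
#' @param seq Character vector of Read2 sequences.
#' @param structure A [read_structure()].
#' @return `data.table` with columns `preindex`, `insert`, `malformed`.
#' @export
trim_read2 <- function(seq, structure) {
  p <- structure$preindex_len
  n <- length(seq)
  malformed <- nchar(seq) < p
  out <- data.table(preindex = NA_character_, insert = NA_character_,
                    malformed = malformed)
  ok <- which(!malformed)
  if (!length(ok)) return(out)
  s <- seq[ok]
  pre <- if (p > 0L) substr(s, 1L, p) else ""
  rest <- substr(s, p + 1L, nchar(s))
  run <- .scan_run(.reverse_strings(rest), structure$r2_tail_trim,
                   structure$junction_tol_per10)
  run[run < 4L] <- 0L
  out$preindex[ok] <- pre
  out$insert[ok] <- substr(rest, 1L, nchar(rest) - run)
  out
}

#' Demultiplex a paired-end library
#'
#' Consumes paired Read1/Read2 records (FASTQ paths or named sequence
#' vectors, paired positionally with id-prefix verification), parses the
#' Read1 layout, corrects the cell barcode against the whitelist (Hamming
#' distance at most `d_max`, unique assignment) and the Read2 pre-index
#' (distance at most `d_pre`), and emits one tagged read per accepted pair
#' plus a run report whose rejection categories partition the input.
#'
#' A read is emitted only when its barcode is exact/corrected and its
#' pre-index is exact/corrected (or pre-indexing is disabled). Ambiguous
#' barcodes or pre-indexes are counted as `reads_ambiguous`; unmatched ones
#' as `reads_no_match`; structurally unusable reads (too short, failed
#' linker) as `reads_malformed`.
#'
#' @param r1,r2 FASTQ file paths, or named character vectors of sequences
#'   (names are read ids).
#' @param structure A [read_structure()].
#' @param whitelist A `barcode_whitelist`.
#' @param d_max Maximum barcode merge distance.
#' @param d_pre Maximum pre-index merge distance.
#' @param mode Correction mode, see [correct_barcodes()].
#' @param keep_rejected Optional path; when given, rejected read ids and
#'   their category are written there as TSV.
#' @return List with `tagged` (`data.table`: read_id, cell_id, umi, insert2,
#'   insert1, barcode_status, preindex_status, junction_ok) and `report`
#'   (a `demux_report`).
#' @export
demux_pair_stream <- function(r1, r2, structure, whitelist,
                              d_max = 2L, d_pre = 1L,
                              mode = c("unique", "nearest"),
                              keep_rejected = NULL) {
  mode <- match.arg(mode)
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) {
    r1 <- read_fastq(r1)
  }
  if (is.character(r2) && length(r2) == 1L && file.exists(r2)) {
    r2 <- read_fastq(r2)
  }
  if (length(r1) != length(r2))
    stop("R1 and R2 record counts differ (truncated input?)")
  ids1 <- sub("[/ ].*$", "", names(r1) %||% as.character(seq_along(r1)))
  ids2 <- sub("[/ ].*$", "", names(r2) %||% as.character(seq_along(r2)))
  if (!identical(ids1, ids2))
    stop("R1/R2 read ids do not pair up (corrupt pairing)")
  n <- length(r1)

  p1 <- parse_read1(unname(r1), structure)
  t2 <- trim_read2(unname(r2), structure)
  malformed <- p1$malformed | t2$malformed
  usable <- which(!malformed)

  bc <- correct_barcodes(p1$barcode[usable], whitelist, d_max, mode)
  pre <- match_preindexes(t2$preindex[usable], whitelist, d_pre, mode)

  bc_ok <- bc$status %in% c("exact", "corrected")
  pre_ok <- pre$status %in% c("exact", "corrected", "disabled")
  valid <- bc_ok & pre_ok
  ambiguous <- !valid & (bc$status == "ambiguous" |
                           (bc_ok & pre$status == "ambiguous"))
  no_match <- !valid & !ambiguous

  keep <- usable[valid]
  tagged <- data.table(
    read_id = ids1[keep],
    cell_id = paste0(pre$preindex[valid], bc$barcode[valid]),
    umi = p1$umi[keep],
    insert2 = t2$insert[keep],
    insert1 = p1$insert[keep],
    barcode_status = bc$status[valid],
    preindex_status = pre$status[valid],
    junction_ok = p1$junction_ok[keep])

  report <- list(
    reads_total = n,
    reads_valid_barcode = sum(valid),
    reads_corrected = sum(valid & bc$status == "corrected"),
    reads_ambiguous = sum(ambiguous),
    reads_no_match = sum(no_match),
    reads_malformed = sum(malformed),
    reads_preindex_corrected = sum(valid & pre$status == "corrected"),
    valid_barcode_rate = if (n > 0L) sum(valid) / n else NA_real_)
  class(report) <- "demux_report"

  if (!is.null(keep_rejected)) {
    cat_all <- rep("malformed", n)
    cat_all[usable] <- ifelse(valid, "valid",
                              ifelse(ambiguous, "ambiguous", "no_match"))
    rej <- data.table(read_id = ids1, category = cat_all)[category != "valid"]
    fwrite(rej, keep_rejected, sep = "\t")
  }
  list(tagged = tagged, report = report)
}

#' @exportS3Method base::print
print.demux_report <- function(x, ...) {
  cat("demux_report:\n")
  cat(sprintf("  total        %10d\n", x$reads_total))
  cat(sprintf("  valid        %10d (%.2f%%; %d corrected)\n",
              x$reads_valid_barcode, 100 * x$valid_barcode_rate,
              x$reads_corrected))
  cat(sprintf("  ambiguous    %10d\n", x$reads_ambiguous))
  cat(sprintf("  no_match     %10d\n", x$reads_no_match))
  cat(sprintf("  malformed    %10d\n", x$reads_malformed))
  invisible(x)
}

#' Write a demultiplexing report as JSON
#' @param report A `demux_report`.
#' @param path Output path.
#' @export
write_demux_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write tagged reads as headered TSV
#' @param tagged Tagged-read table from [demux_pair_stream()].
#' @param path Output path.
#' @export
write_tagged_reads <- function(tagged, path) {
  fwrite(tagged, path, sep = "\t")
  invisible(path)
}
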