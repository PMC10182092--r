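# Barcode ranking, knee detection and nucleus-calling metrics.

#' Rank barcodes by a per-barcode metric
#'
#' Orders barcodes from largest to smallest genes-detected (default) or UMI
#' total; ties are broken lexicographically by barcode so the order is
#' deterministic.
#'
#' @param x A `count_matrix`, or a named numeric vector of per-barcode
#'   tallies.
#' @param metric `"genes"` (genes detected per barcode) or `"umis"`.
#' @return A `rank_curve`: `data.table(barcode, value, rank)` with `value`
#'   non-increasing along `rank`.
#' @export
rank_barcodes <- function(x, metric = c("genes", "umis")) {
  metric <- match.arg(metric)
  if (inherits(x, "count_matrix")) {
    tot <- x$layers$total
    v <- if (metric == "genes") Matrix::colSums(tot > 0) else
      Matrix::colSums(tot)
    v <- setNames(as.numeric(v), x$cells)
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    v <- x
  }
  if (!length(v)) stop("no barcodes to rank")
  ord <- order(-v, names(v))
  out <- data.table(barcode = names(v)[ord], value = as.numeric(v[ord]))
  out[, rank_ := .I]
  setnames(out, "rank_", "rank")
  class(out) <- c("rank_curve", class(out))
  out
}

.no_knee <- function(msg) {
  stop(errorCondition(paste0(msg, "; supply expected_cells to use the ",
                             "quantile fallback"),
                      class = c("snrand_no_knee", "error")))
}

#' Call nuclei from the knee of the barcode-rank curve
#'
#' Smooths log10(value) against log10(rank) with a fixed-width running
#' median, then places the knee at the rank maximizing the (signed,
#' above-chord) perpendicular distance to the chord joining the curve's
#' endpoints. The threshold is the raw metric value at the knee rank; all
#' barcodes at or above it are called (ties included). When the distance
#' profile has no unique maximum exceeding a relative prominence of
#' `prominence` (fraction of the curve's log-range), the method falls back
#' to the `expected_cells` rule: threshold = (99th percentile of the top
#' `expected_cells` values) / 10. Curves spanning less than one decade raise
#' a no-knee error.
#'
#' @param curve A `rank_curve` from [rank_barcodes()].
#' @param window Running-median window (points, odd).
#' @param prominence Minimum relative prominence of the knee.
#' @param expected_cells Optional expected nucleus count for the fallback.
#' @return A `call_result`: list with `called_cells`, `threshold_value`,
#'   `method` ("knee" or "expected_cells") and `diagnostics`.
#' @export
call_knee <- function(curve, window = 15L, prominence = 0.05,
                      expected_cells = NULL) {
  curve <- as.data.table(curve)
  pos <- curve[value > 0]
  if (nrow(pos) < 10L)
    .no_knee("fewer than 10 barcodes with positive counts")
  if (max(pos$value) / min(pos$value) < 10)
    .no_knee("barcode-rank curve spans less than one decade (flat curve)")
  x <- log10(pos$rank)
  y <- log10(pos$value)
  k <- min(window, nrow(pos))
  if (k %% 2L == 0L) k <- k - 1L
  ys <- runmed(y, k)
  x1 <- x[1]; y1 <- ys[1]
  x2 <- x[length(x)]; y2 <- ys[length(ys)]
  # signed perpendicular distance above the chord
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  d <- ((ys - y1) * dx - (x - x1) * dy) / len
  rel <- max(d) / max(diff(range(ys)), .Machine$double.eps)
  unique_max <- sum(d == max(d)) == 1L
  fallback <- function(reason) {
    if (is.null(expected_cells))
      .no_knee(reason)
    ncand <- min(expected_cells, nrow(pos))
    robust_max <- quantile(pos$value[seq_len(ncand)], 0.99, names = FALSE)
    thr <- robust_max / 10
    list(thr = thr, method = "expected_cells",
         diag = list(reason = reason, robust_max = robust_max,
                     expected_cells = expected_cells))
  }
  if (rel < prominence || !unique_max) {
    fb <- fallback(sprintf(
      "no unique knee with relative prominence >= %.2f", prominence))
    thr <- fb$thr; method <- fb$method; diag <- fb$diag
  } else {
    # The prominent shoulder confirmed, place the threshold at the top of
    # the steepest descending segment of the smoothed curve (the cliff that
    # separates nuclei from ambient background). The chord-distance maximum
    # itself sits mid-plateau whenever the nucleus population has spread,
    # so it gates the call but does not place it.
    n <- length(x)
    dx_win <- 0.02  # slope window in log10-rank decades
    iend <- findInterval(x + dx_win, x) + 1L
    iend <- pmin(pmax(iend, seq_len(n) + 1L), n)
    slope <- (ys[iend] - ys) / pmax(x[iend] - x, .Machine$double.eps)
    slope[iend <= seq_len(n)] <- 0
    # the knee must sit where the curve still stands clear of the chord
    slope[d < 0.25 * max(d)] <- 0
    idx <- which.min(slope)
    # inside the steepest window, sit on the cliff edge itself: the largest
    # single-step drop of the smoothed curve
    j1 <- iend[idx]
    if (j1 > idx) {
      drops <- -diff(ys[idx:j1])
      idx <- idx + which.max(drops) - 1L
    }
    thr <- pos$value[idx]
    method <- "knee"
    diag <- list(knee_rank = pos$rank[idx], prominence = rel,
                 steepest_slope = min(slope), window = k)
  }
  called <- curve[value >= thr, barcode]
  out <- list(called_cells = called, threshold_value = thr,
              method = method, diagnostics = diag)
  class(out) <- "call_result"
  out
}

#' @exportS3Method base::print
print.call_result <- function(x, ...) {
  cat("call_result:", length(x$called_cells), "barcodes called by",
      x$method, "at threshold", x$threshold_value, "\n")
  invisible(x)
}

#' Capture metrics for a called nucleus set
#'
#' `capture_rate` is the fraction of true nuclei whose cell id was called;
#' `reads_in_cells` is the fraction of valid-barcode reads carried by called
#' barcodes. Either side may be omitted, giving a partial report with
#' explicit `NA`s.
#'
#' @param call A `call_result` (or character vector of called barcodes).
#' @param truth_cells Character vector of true nucleus cell ids (simulation
#'   truth), or `NULL`.
#' @param read_cells Character vector: the cell id of every valid-barcode
#'   read (e.g. `tagged$cell_id`), or `NULL`.
#' @return List with `capture_rate`, `reads_in_cells`, `n_called`,
#'   `n_truth`.
#' @export
capture_metrics <- function(call, truth_cells = NULL, read_cells = NULL) {
  called <- if (inherits(call, "call_result")) call$called_cells else call
  capture_rate <- if (!is.null(truth_cells)) {
    truth <- unique(truth_cells)
    length(intersect(called, truth)) / length(truth)
  } else NA_real_
  reads_in_cells <- if (!is.null(read_cells)) {
    mean(read_cells %in% called)
  } else NA_real_
  list(capture_rate = capture_rate, reads_in_cells = reads_in_cells,
       n_called = length(called),
       n_truth = if (is.null(truth_cells)) NA_integer_ else
         length(unique(truth_cells)))
}
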