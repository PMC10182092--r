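# Read architecture, split-pool whitelists and Hamming-bounded barcode
# correction.

#' Declare the paired-end read layout
#'
#' Describes where the cell barcode, UMI, dA-tail junction and pre-index sit
#' on Read1/Read2. Defaults follow the assay's published constants: a 30-nt
#' cell barcode assembled from three 10-nt split-pool segments, an 8-nt UMI,
#' a poly(T) junction on Read1 left by the dA-tailing step, and a 6-nt
#' pre-index at the start of Read2.
#'
#' @param barcode_len Total cell-barcode length in nucleotides.
#' @param barcode_segment_lens Integer vector of per-round segment lengths;
#'   must sum to `barcode_len`.
#' @param linker_seqs Optional fixed linker sequences between consecutive
#'   segments (`length(barcode_segment_lens) - 1` strings), or `NULL`.
#' @param umi_len UMI length in nucleotides.
#' @param r1_junction_base Homopolymer base expected after the UMI on Read1
#'   (the read-through of the dA tail, sequenced as T).
#' @param junction_min_run Minimum run length for the junction to be called.
#' @param junction_tol_per10 Allowed mismatches per 10 nt of run.
#' @param preindex_len Pre-index length at position 0 of Read2; 0 disables
#'   pre-indexing.
#' @param r2_tail_trim Homopolymer base trimmed from the 3' end of Read2
#'   (dA-tail read-through).
#' @return An object of class `read_structure`.
#' @export
read_structure <- function(barcode_len = 30L,
                           barcode_segment_lens = c(10L, 10L, 10L),
                           linker_seqs = NULL,
                           umi_len = 8L,
                           r1_junction_base = "T",
                           junction_min_run = 6L,
                           junction_tol_per10 = 1L,
                           preindex_len = 6L,
                           r2_tail_trim = "A") {
  barcode_len <- as.integer(barcode_len)
  barcode_segment_lens <- as.integer(barcode_segment_lens)
  umi_len <- as.integer(umi_len)
  preindex_len <- as.integer(preindex_len)
  if (any(barcode_segment_lens <= 0L))
    stop("all barcode segment lengths must be > 0")
  if (sum(barcode_segment_lens) != barcode_len)
    stop("barcode_segment_lens must sum to barcode_len")
  if (umi_len <= 0L) stop("umi_len must be > 0")
  if (preindex_len < 0L) stop("preindex_len must be >= 0")
  if (!is.null(linker_seqs)) {
    if (length(linker_seqs) != length(barcode_segment_lens) - 1L)
      stop("need one linker per junction between segments")
    if (!.is_dna(linker_seqs)) stop("linker sequences must be ACGT")
  }
  structure(list(
    barcode_len = barcode_len,
    barcode_segment_lens = barcode_segment_lens,
    linker_seqs = linker_seqs,
    umi_len = umi_len,
    r1_junction_base = r1_junction_base,
    junction_min_run = as.integer(junction_min_run),
    junction_tol_per10 = as.integer(junction_tol_per10),
    preindex_len = preindex_len,
    r2_tail_trim = r2_tail_trim
  ), class = "read_structure")
}

#' @exportS3Method base::print
print.read_structure <- function(x, ...) {
  cat("read_structure:\n")
  cat("  Read1: [", paste(x$barcode_segment_lens, collapse = "+"),
      "nt barcode]",
      if (!is.null(x$linker_seqs)) "(with linkers)" else "",
      "+", x$umi_len, "nt UMI +", x$r1_junction_base, "run >=",
      x$junction_min_run, "\n")
  cat("  Read2: [", x$preindex_len, "nt pre-index ] + insert, 3' ",
      x$r2_tail_trim, "-tail trimmed\n", sep = "")
  invisible(x)
}

# Read1 layout offsets: list of per-segment start positions, umi start,
# scan start (all 1-based).
.r1_layout <- function(structure) {
  segs <- structure$barcode_segment_lens
  link_lens <- if (is.null(structure$linker_seqs)) {
    rep(0L, length(segs) - 1L)
  } else nchar(structure$linker_seqs)
  seg_start <- integer(length(segs))
  pos <- 1L
  link_start <- integer(length(link_lens))
  for (i in seq_along(segs)) {
    seg_start[i] <- pos
    pos <- pos + segs[i]
    if (i < length(segs)) {
      link_start[i] <- pos
      pos <- pos + link_lens[i]
    }
  }
  list(seg_start = seg_start, seg_len = segs,
       link_start = link_start, link_len = link_lens,
       umi_start = pos, scan_start = pos + structure$umi_len)
}

#' Build a split-pool barcode whitelist
#'
#' The accepted barcode set is the Cartesian product of the per-round segment
#' sets (three rounds of split-and-pool ligation by default). The minimum
#' pairwise Hamming distance over the accepted set is computed by brute force
#' for small products; for larger products it equals the minimum within-round
#' segment distance, which is exact for product-structured whitelists because
#' the closest pair of accepted barcodes always differs in a single round.
#'
#' @param round_sets List of character vectors, one per ligation round; equal
#'   string length within a round, DNA alphabet, no duplicates.
#' @param preindexes Character vector of pre-index (RT tube) sequences.
#' @return An object of class `barcode_whitelist`.
#' @export
build_whitelist <- function(round_sets, preindexes = character()) {
  if (!is.list(round_sets) || length(round_sets) < 1L)
    stop("round_sets must be a non-empty list of character vectors")
  for (r in seq_along(round_sets)) {
    seg <- round_sets[[r]]
    if (length(seg) == 0L) stop("round ", r, " is empty")
    if (length(unique(nchar(seg))) != 1L)
      stop("round ", r, ": segments must have equal length")
    if (!.is_dna(seg))
      stop("round ", r, ": non-ACGT character in segment set")
    if (anyDuplicated(seg))
      stop("round ", r, ": duplicate segment within a round")
  }
  seg_lens <- vapply(round_sets, function(s) nchar(s[1]), integer(1))
  sizes <- lengths(round_sets)
  total <- prod(sizes)
  if (length(preindexes)) {
    if (length(unique(nchar(preindexes))) != 1L)
      stop("preindexes must have equal length")
    if (!.is_dna(preindexes)) stop("non-ACGT character in preindexes")
    if (anyDuplicated(preindexes)) stop("duplicate preindex")
  }
  wl <- structure(list(
    rounds = round_sets,
    seg_lens = seg_lens,
    barcode_len = sum(seg_lens),
    preindexes = preindexes,
    accepted = NULL,
    min_pairwise_dist = NA_integer_
  ), class = "barcode_whitelist")
  if (total <= 1e5) wl$accepted <- accepted_barcodes(wl)
  wl$min_pairwise_dist <- .wl_min_dist(wl)
  wl
}

#' Number of accepted barcodes in a whitelist
#' @param whitelist A `barcode_whitelist`.
#' @export
whitelist_size <- function(whitelist) {
  prod(lengths(whitelist$rounds))
}

#' Materialize the accepted barcode set
#'
#' Enumerates the full product of round segments. Order is round-1-fastest,
#' matching [barcode_at()].
#' @param whitelist A `barcode_whitelist`.
#' @export
accepted_barcodes <- function(whitelist) {
  if (!is.null(whitelist$accepted)) return(whitelist$accepted)
  idx <- lapply(lengths(whitelist$rounds), seq_len)
  grid <- do.call(expand.grid, idx)  # first factor varies fastest
  parts <- lapply(seq_along(whitelist$rounds), function(r) {
    whitelist$rounds[[r]][grid[[r]]]
  })
  do.call(paste0, parts)
}

#' Barcode at a given whitelist index
#'
#' Index 1..whitelist_size, decomposed round-1-fastest; consistent with the
#' enumeration order of [accepted_barcodes()].
#' @param whitelist A `barcode_whitelist`.
#' @param idx Integer vector of indices.
#' @export
barcode_at <- function(whitelist, idx) {
  sizes <- lengths(whitelist$rounds)
  stopifnot(all(idx >= 1L), all(idx <= prod(sizes)))
  rest <- idx - 1L
  parts <- vector("list", length(sizes))
  for (r in seq_along(sizes)) {
    parts[[r]] <- whitelist$rounds[[r]][(rest %% sizes[r]) + 1L]
    rest <- rest %/% sizes[r]
  }
  do.call(paste0, parts)
}

# Min pairwise Hamming distance within one set of equal-length strings.
.set_min_dist <- function(set) {
  n <- length(set)
  if (n < 2L) return(nchar(set[1]))
  w <- nchar(set[1])
  m <- .seq_mat(set, w)
  best <- w
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, (i + 1L):n, drop = FALSE] != m[, i])
    best <- min(best, min(d))
    if (best == 0L) break
  }
  as.integer(best)
}

.wl_min_dist <- function(wl, brute_limit = 4000L) {
  total <- whitelist_size(wl)
  if (total < 2L) return(as.integer(wl$barcode_len))
  if (total <= brute_limit) {
    .set_min_dist(accepted_barcodes(wl))
  } else {
    # exact for product whitelists: nearest accepted pair differs in one round
    min(vapply(wl$rounds, .set_min_dist, integer(1)))
  }
}

#' @exportS3Method base::print
print.barcode_whitelist <- function(x, ...) {
  cat("barcode_whitelist:", paste(lengths(x$rounds), collapse = " x "),
      "segments =", whitelist_size(x), "accepted barcodes of length",
      x$barcode_len, "nt\n")
  cat("  min pairwise Hamming distance:", x$min_pairwise_dist, "\n")
  cat("  pre-indexes:", length(x$preindexes), "\n")
  invisible(x)
}

# Unique-assignment Hamming correction against a flat set of equal-length
# strings. Returns data.table(status, match, distance).
.correct_in_set <- function(observed, set, d_max, mode = c("unique", "nearest")) {
  mode <- match.arg(mode)
  n <- length(observed)
  out <- data.table(status = rep("no_match", n),
                    match = NA_character_,
                    distance = NA_integer_)
  if (n == 0L || length(set) == 0L) return(out)
  w <- nchar(set[1])
  ok <- which(nchar(observed) == w)
  if (!length(ok)) return(out)
  m <- .seq_mat(observed[ok], w)
  sm <- .seq_mat(set, w)
  d_max <- min(d_max, w)
  nt <- d_max + 1L
  cnt <- matrix(0L, length(ok), nt)
  ids <- matrix(0L, length(ok), nt)
  for (j in seq_along(set)) {
    d <- colSums(m != sm[, j])
    for (t in 0:d_max) {
      sel <- d == t
      if (any(sel)) {
        cnt[sel, t + 1L] <- cnt[sel, t + 1L] + 1L
        ids[sel, t + 1L] <- j
      }
    }
  }
  status <- rep("no_match", length(ok))
  match_id <- rep(NA_integer_, length(ok))
  dist <- rep(NA_integer_, length(ok))
  exact <- cnt[, 1L] == 1L
  status[exact] <- "exact"
  match_id[exact] <- ids[exact, 1L]
  dist[exact] <- 0L
  rest <- which(!exact)
  if (length(rest)) {
    if (mode == "unique") {
      total <- rowSums(cnt[rest, , drop = FALSE])
      uni <- total == 1L
      amb <- total >= 2L
      if (any(uni)) {
        rs <- rest[uni]
        tcol <- max.col(cnt[rs, , drop = FALSE], ties.method = "first")
        status[rs] <- "corrected"
        dist[rs] <- tcol - 1L
        match_id[rs] <- ids[cbind(seq_len(nrow(ids))[rs], tcol)]
      }
      status[rest[amb]] <- "ambiguous"
    } else {
      cr <- cnt[rest, , drop = FALSE]
      has <- cr > 0L
      any_hit <- rowSums(has) > 0L
      if (any(any_hit)) {
        rh <- which(any_hit)
        first_t <- max.col(has[rh, , drop = FALSE], ties.method = "first")
        n_at <- cr[cbind(rh, first_t)]
        uni <- n_at == 1L
        rs <- rest[rh[uni]]
        if (length(rs)) {
          tc <- first_t[uni]
          status[rs] <- "corrected"
          dist[rs] <- tc - 1L
          match_id[rs] <- ids[cbind(rs, tc)]
        }
        status[rest[rh[!uni]]] <- "ambiguous"
      }
    }
  }
  out$status[ok] <- status
  out$match[ok] <- ifelse(is.na(match_id), NA_character_, set[match_id])
  out$distance[ok] <- dist
  out
}

#' Vectorized whitelist barcode correction
#'
#' Corrects observed barcodes against the accepted set using the product
#' structure of the split-pool whitelist: per-round segment distances are
#' computed exactly and combined, which is equivalent to (and tested against)
#' an exhaustive Hamming scan over the enumerated accepted set. An observed
#' barcode that is itself accepted is `exact`; otherwise, in the default
#' `unique` mode it is `corrected` only when exactly one accepted barcode
#' lies within `d_max` substitutions, `ambiguous` when two or more do
#' (even if one is strictly nearer), and `no_match` otherwise. The
#' `nearest` mode instead accepts a unique nearest neighbour within `d_max`.
#'
#' @param observed Character vector of observed barcode sequences.
#' @param whitelist A `barcode_whitelist`.
#' @param d_max Maximum merge distance (substitutions).
#' @param mode `"unique"` (default, conservative) or `"nearest"`.
#' @return `data.table` with columns `status`
#'   (exact/corrected/ambiguous/no_match), `barcode`, `distance`,
#'   `malformed` (length mismatch; such reads are `no_match`, not errors).
#' @export
correct_barcodes <- function(observed, whitelist, d_max = 2L,
                             mode = c("unique", "nearest")) {
  mode <- match.arg(mode)
  n <- length(observed)
  L <- whitelist$barcode_len
  out <- data.table(status = rep("no_match", n),
                    barcode = NA_character_,
                    distance = NA_integer_,
                    malformed = nchar(observed) != L)
  ok <- which(!out$malformed)
  if (!length(ok)) return(out)
  rounds <- whitelist$rounds
  R <- length(rounds)
  seg_lens <- whitelist$seg_lens
  d_max <- as.integer(d_max)
  nt <- d_max + 1L
  nok <- length(ok)

  cnts <- vector("list", R)
  ids <- vector("list", R)
  pos <- 1L
  for (r in seq_len(R)) {
    seg_obs <- substr(observed[ok], pos, pos + seg_lens[r] - 1L)
    pos <- pos + seg_lens[r]
    m <- .seq_mat(seg_obs, seg_lens[r])
    sm <- .seq_mat(rounds[[r]], seg_lens[r])
    cnt <- matrix(0L, nok, nt)
    id <- matrix(0L, nok, nt)
    tmax <- min(d_max, seg_lens[r])
    for (j in seq_along(rounds[[r]])) {
      d <- colSums(m != sm[, j])
      for (t in 0:tmax) {
        sel <- d == t
        if (any(sel)) {
          cnt[sel, t + 1L] <- cnt[sel, t + 1L] + 1L
          id[sel, t + 1L] <- j
        }
      }
    }
    cnts[[r]] <- cnt
    ids[[r]] <- id
  }

  # enumerate per-round error-split tuples with total <= d_max
  tuples <- as.matrix(do.call(expand.grid, rep(list(0:d_max), R)))
  tuples <- tuples[rowSums(tuples) <= d_max, , drop = FALSE]
  tsum <- rowSums(tuples)
  ord <- order(tsum)
  tuples <- tuples[ord, , drop = FALSE]
  tsum <- tsum[ord]
  Tn <- nrow(tuples)

  combo <- matrix(1, nok, Tn)
  for (k in seq_len(Tn)) {
    for (r in seq_len(R)) combo[, k] <- combo[, k] * cnts[[r]][, tuples[k, r] + 1L]
  }

  exact <- combo[, 1L] == 1L  # tuple (0,...,0) is first after ordering
  status <- rep("no_match", nok)
  dist <- rep(NA_integer_, nok)
  win <- rep(NA_integer_, nok)  # winning tuple index
  status[exact] <- "exact"
  dist[exact] <- 0L
  win[exact] <- 1L

  rest <- which(!exact)
  if (length(rest)) {
    cr <- combo[rest, , drop = FALSE]
    if (mode == "unique") {
      total <- rowSums(cr)
      uni <- total == 1L
      status[rest[total >= 2L]] <- "ambiguous"
      if (any(uni)) {
        ru <- rest[uni]
        wc <- max.col(cr[uni, , drop = FALSE], ties.method = "first")
        status[ru] <- "corrected"
        dist[ru] <- as.integer(tsum[wc])
        win[ru] <- wc
      }
    } else {
      dmat <- matrix(rep(tsum, each = length(rest)), nrow = length(rest))
      dmat[cr == 0] <- Inf
      dstar <- do.call(pmin, as.data.frame(dmat))
      hit <- is.finite(dstar)
      if (any(hit)) {
        at <- rowSums(cr * (dmat == dstar))
        uni <- hit & at == 1L
        status[rest[hit & at >= 2L]] <- "ambiguous"
        if (any(uni)) {
          ru <- rest[uni]
          wc <- max.col((cr * (dmat == dstar))[uni, , drop = FALSE],
                        ties.method = "first")
          status[ru] <- "corrected"
          dist[ru] <- as.integer(dstar[uni])
          win[ru] <- wc
        }
      }
    }
  }

  matched <- which(!is.na(win))
  if (length(matched)) {
    parts <- vector("list", R)
    for (r in seq_len(R)) {
      tcol <- tuples[win[matched], r] + 1L
      seg_id <- ids[[r]][cbind(matched, tcol)]
      parts[[r]] <- rounds[[r]][seg_id]
    }
    out$barcode[ok[matched]] <- do.call(paste0, parts)
  }
  out$status[ok] <- status
  out$distance[ok] <- dist
  out
}

#' Correct a single observed barcode
#'
#' Scalar wrapper around [correct_barcodes()].
#' @inheritParams correct_barcodes
#' @param observed A single observed barcode string.
#' @return A `correction_result`: list with `status`, `accepted_barcode`,
#'   `distance`.
#' @export
correct_barcode <- function(observed, whitelist, d_max = 2L,
                            mode = c("unique", "nearest")) {
  stopifnot(length(observed) == 1L)
  r <- correct_barcodes(observed, whitelist, d_max, mode)
  structure(list(status = r$status, accepted_barcode = r$barcode,
                 distance = r$distance, malformed = r$malformed),
            class = "correction_result")
}

#' @exportS3Method base::print
print.correction_result <- function(x, ...) {
  cat("correction_result:", x$status,
      if (!is.na(x$accepted_barcode)) paste0("-> ", x$accepted_barcode),
      if (!is.na(x$distance)) paste0("(d=", x$distance, ")"), "\n")
  invisible(x)
}

#' Vectorized pre-index matching
#'
#' Unique-assignment correction of observed pre-index sequences against the
#' whitelist's RT-tube set, with the same semantics as [correct_barcodes()]
#' at merge distance `d_pre`. When pre-indexing is disabled (no preindexes /
#' `preindex_len == 0`), every read is assigned the empty pre-index.
#'
#' @param observed Character vector of observed pre-index sequences.
#' @param whitelist A `barcode_whitelist` carrying `preindexes`.
#' @param d_pre Maximum merge distance.
#' @inheritParams correct_barcodes
#' @return `data.table` with `status` (exact/corrected/ambiguous/no_match/
#'   disabled) and `preindex`.
#' @export
match_preindexes <- function(observed, whitelist, d_pre = 1L,
                             mode = c("unique", "nearest")) {
  mode <- match.arg(mode)
  n <- length(observed)
  if (!length(whitelist$preindexes)) {
    return(data.table(status = rep("disabled", n), preindex = ""))
  }
  r <- .correct_in_set(observed, whitelist$preindexes, d_pre, mode)
  data.table(status = r$status, preindex = r$match, distance = r$distance)
}

#' Match a single pre-index
#' @inheritParams match_preindexes
#' @param observed A single observed pre-index string.
#' @export
match_preindex <- function(observed, whitelist, d_pre = 1L,
                           mode = c("unique", "nearest")) {
  stopifnot(length(observed) == 1L)
  r <- match_preindexes(observed, whitelist, d_pre, mode)
  structure(list(status = r$status, preindex = r$preindex,
                 distance = if ("distance" %in% names(r)) r$distance else 0L),
            class = "correction_result")
}

#' Parse Read1 into barcode, UMI, junction flag and insert
#'
#' Slices the cell barcode and UMI by the declared layout (verifying linkers
#' within one mismatch each, when declared), then looks for the poly(T)
#' junction left by dA-tailing: a run of at least `junction_min_run`
#' `r1_junction_base` characters, tolerating `junction_tol_per10` mismatches
#' per 10 nt of run. The insert is everything after the run. Reads shorter
#' than barcode + linkers + UMI are flagged `malformed` (counted, not an
#' error).
#'
#' @param seq Character vector of Read1 sequences.
#' @param structure A [read_structure()].
#' @return `data.table` with columns `barcode`, `umi`, `junction_ok`,
#'   `insert`, `malformed`.
#' @export
parse_read1 <- function(seq, structure) {
  lay <- .r1_layout(structure)
  n <- length(seq)
  min_len <- lay$scan_start - 1L
  malformed <- nchar(seq) < min_len
  out <- data.table(barcode = NA_character_, umi = NA_character_,
                    junction_ok = FALSE, insert = NA_character_,
                    malformed = malformed)
  ok <- which(!malformed)
  if (!length(ok)) return(out)
  s <- seq[ok]
  parts <- vector("list", length(lay$seg_len))
  for (i in seq_along(lay$seg_len)) {
    parts[[i]] <- substr(s, lay$seg_start[i],
                         lay$seg_start[i] + lay$seg_len[i] - 1L)
  }
  bc <- do.call(paste0, parts)
  # linker verification: <=1 mismatch per declared linker
  if (!is.null(structure$linker_seqs)) {
    bad <- rep(FALSE, length(s))
    for (i in seq_along(structure$linker_seqs)) {
      lk <- structure$linker_seqs[i]
      w <- nchar(lk)
      obs <- substr(s, lay$link_start[i], lay$link_start[i] + w - 1L)
      mm <- colSums(.seq_mat(obs, w) != strsplit(lk, "", fixed = TRUE)[[1]])
      bad <- bad | mm > 1L
    }
    if (any(bad)) {
      out$malformed[ok[bad]] <- TRUE
      keep <- !bad
      ok <- ok[keep]
      if (!length(ok)) return(out)
      s <- s[keep]
      bc <- bc[keep]
    }
  }
  umi <- substr(s, lay$umi_start, lay$umi_start + structure$umi_len - 1L)
  rest <- substr(s, lay$scan_start, nchar(s))
  run <- .scan_run(rest, structure$r1_junction_base,
                   structure$junction_tol_per10)
  out$barcode[ok] <- bc
  out$umi[ok] <- umi
  out$junction_ok[ok] <- run >= structure$junction_min_run
  out$insert[ok] <- substr(rest, run + 1L, nchar(rest))
  out
}
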