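# Low-level fixed-width sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Split equal-width strings into a width x n character matrix.
.seq_mat <- function(x, width) {
  if (length(x) == 0L) return(matrix(character(), nrow = width, ncol = 0L))
  stopifnot(all(nchar(x) == width))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = width)
}

.is_dna <- function(x) {
  !any(grepl("[^ACGT]", x))
}

# Hamming distance between two equal-length strings (or elementwise over
# two equal-length vectors).
hamming <- function(a, b) {
  stopifnot(length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# Greedy homopolymer-run scan with a per-10-nt mismatch allowance.
# Returns, for each string, the length of the leading run of `base`
# tolerating ceiling(i/10) * tol_per10 mismatches among the first i
# characters; the run never ends on a mismatch.
.scan_run <- function(x, base, tol_per10 = 1L, max_scan = 100L) {
  n <- length(x)
  if (n == 0L) return(integer())
  W <- min(max(nchar(x), 0L), max_scan)
  if (W == 0L) return(integer(n))
  xp <- substr(x, 1L, W)
  fmt <- paste0("%-", W, "s")
  xp <- sprintf(fmt, xp)
  m <- matrix(unlist(strsplit(xp, "", fixed = TRUE), use.names = FALSE),
              nrow = W)
  acc <- integer(n)
  ok <- rep(TRUE, n)
  run <- integer(n)
  for (i in seq_len(W)) {
    isb <- m[i, ] == base
    acc <- acc + !isb
    ok <- ok & (acc <= ceiling(i / 10) * tol_per10)
    hit <- ok & isb
    if (any(hit)) run[hit] <- i
  }
  run
}

.reverse_strings <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

.revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA strings.
random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

.paste_mat_rows <- function(m) {
  # m: width x n character matrix -> n strings
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
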