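# Independent brute-force oracles used to check the package's optimized
# implementations.

# Exhaustive Hamming scan of each observed barcode against the full accepted
# set. Unique-assignment semantics: exact on membership; corrected iff
# exactly one accepted barcode lies within d_max; ambiguous for >= 2;
# no_match otherwise.
brute_correct <- function(observed, accepted, d_max = 2L) {
  w <- nchar(accepted[1])
  n <- length(observed)
  status <- rep("no_match", n)
  barcode <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  ok <- which(nchar(observed) == w)
  if (!length(ok)) {
    return(data.frame(status, barcode, distance, stringsAsFactors = FALSE))
  }
  m <- matrix(unlist(strsplit(observed[ok], "", fixed = TRUE)), nrow = w)
  am <- matrix(unlist(strsplit(accepted, "", fixed = TRUE)), nrow = w)
  n_within <- integer(length(ok))
  hit_id <- integer(length(ok))
  hit_d <- rep(NA_integer_, length(ok))
  is_member <- logical(length(ok))
  for (j in seq_along(accepted)) {
    d <- colSums(m != am[, j])
    is_member <- is_member | d == 0L
    within <- d <= d_max
    upd <- within & n_within == 0L
    hit_id[upd] <- j
    hit_d[upd] <- d[upd]
    n_within <- n_within + within
  }
  st <- ifelse(is_member, "exact",
               ifelse(n_within == 1L, "corrected",
                      ifelse(n_within >= 2L, "ambiguous", "no_match")))
  status[ok] <- st
  sel <- st %in% c("exact", "corrected")
  # for exact, re-find the member itself
  for (i in which(st == "exact")) {
    d <- colSums(am != m[, i])
    hit_id[i] <- which(d == 0L)[1]
    hit_d[i] <- 0L
  }
  barcode[ok][sel] <- accepted[hit_id[sel]]
  distance[ok][sel] <- hit_d[sel]
  data.frame(status, barcode, distance, stringsAsFactors = FALSE)
}

# Naive directional UMI dedup: full pairwise adjacency among distinct UMIs
# (d == 1 and count(u) >= 2*count(v) - 1), components grown by reachability
# from nodes in (-count, lexicographic) order.
naive_dedup <- function(umis) {
  if (!length(umis)) return(list(count = 0L, rep = character()))
  tab <- sort(table(umis), decreasing = TRUE)
  us <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, us)
  us <- us[ord]; cnt <- cnt[ord]
  k <- length(us)
  dmat <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        dmat[i, j] <- sum(strsplit(us[i], "")[[1]] != strsplit(us[j], "")[[1]])
      }
    }
  }
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && dmat[i, j] == 1L && cnt[i] >= 2L * cnt[j] - 1L) {
        adj[i, j] <- TRUE
      }
    }
  }
  assigned <- rep(NA_character_, k)
  for (i in seq_len(k)) {
    if (!is.na(assigned[i])) next
    # reachable set from i through unassigned nodes
    comp <- i
    repeat {
      nxt <- setdiff(which(is.na(assigned) &
                             apply(adj[comp, , drop = FALSE], 2, any)), comp)
      if (!length(nxt)) break
      comp <- c(comp, nxt)
      assigned[nxt] <- us[i]
    }
    assigned[comp] <- us[i]
  }
  list(count = length(unique(assigned)),
       rep = setNames(assigned, us))
}

# All-pairs minimum Hamming distance of a string set.
brute_min_dist <- function(set) {
  n <- length(set)
  w <- nchar(set[1])
  m <- matrix(unlist(strsplit(set, "", fixed = TRUE)), nrow = w)
  best <- w
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, (i + 1L):n, drop = FALSE] != m[, i])
    best <- min(best, d)
  }
  best
}

# Inject k substitution errors at distinct positions.
perturb <- function(x, k) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}
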