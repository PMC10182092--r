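test_that("read_structure validates its layout invariants", {
  st <- read_structure()
  expect_s3_class(st, "read_structure")
  expect_equal(st$barcode_len, 30L)
  expect_equal(sum(st$barcode_segment_lens), st$barcode_len)
  expect_equal(st$umi_len, 8L)
  expect_equal(st$preindex_len, 6L)
  expect_error(read_structure(barcode_segment_lens = c(10L, 10L)),
               "sum to barcode_len")
  expect_error(read_structure(umi_len = 0L), "umi_len")
  expect_error(read_structure(barcode_segment_lens = c(30L, 0L, 0L)),
               "> 0")
  expect_error(read_structure(preindex_len = -1L), "preindex_len")
})

test_that("build_whitelist enumerates the product and validates inputs", {
  wl <- build_whitelist(list(c("AAAA", "CCCC"), c("GGGG", "TTTT"),
                             c("ACGT", "TGCA")))
  expect_equal(whitelist_size(wl), 8)
  expect_equal(length(accepted_barcodes(wl)), 8L)
  expect_false(anyDuplicated(accepted_barcodes(wl)) > 0)
  expect_true(all(nchar(accepted_barcodes(wl)) == wl$barcode_len))
  # 96^3 product reported without materialization limits
  big <- build_whitelist(lapply(1:3, function(i) {
    unique(random_dna(200, 10))[1:96]
  }))
  expect_equal(whitelist_size(big), 96^3)
  # barcode_at agrees with the enumeration order
  acc <- accepted_barcodes(wl)
  expect_equal(barcode_at(wl, seq_len(8L)), acc)
  expect_error(build_whitelist(list(c("AANA"), c("CCCC"), c("GGGG"))),
               "non-ACGT")
  expect_error(build_whitelist(list(c("AAAA", "AAAA"), c("CCCC"),
                                    c("GGGG"))), "duplicate")
})

test_that("min pairwise distance matches the brute-force oracle", {
  set.seed(5)
  wl <- random_whitelist(sizes = c(3L, 3L, 3L), seg_len = 6L,
                         min_dist = 3L, n_preindex = 0L)
  expect_equal(wl$min_pairwise_dist, brute_min_dist(accepted_barcodes(wl)))
  expect_gte(wl$min_pairwise_dist, 3L)
  # per-round minima of 3 propagate to the product
  r <- list(c("AAAAAA", "TTTAAA"), c("CCCCCC", "GGGCCC"),
            c("GGGGGG", "AAAGGG"))
  wl2 <- build_whitelist(r)
  expect_equal(wl2$min_pairwise_dist, 3L)
  expect_equal(brute_min_dist(accepted_barcodes(wl2)), 3L)
})

test_that("correct_barcode handles exact, bounded and out-of-range errors", {
  set.seed(7)
  wl <- random_whitelist(sizes = c(8L, 8L, 8L), seg_len = 10L,
                         min_dist = 7L, n_preindex = 0L)
  bc <- accepted_barcodes(wl)[5]
  r <- correct_barcode(bc, wl)
  expect_equal(r$status, "exact")
  expect_equal(r$accepted_barcode, bc)
  expect_equal(r$distance, 0L)
  # two substitutions: unique neighbour at the published merge bound
  obs2 <- perturb(bc, 2L)
  r2 <- correct_barcode(obs2, wl, d_max = 2L)
  expect_equal(r2$status, "corrected")
  expect_equal(r2$accepted_barcode, bc)
  expect_equal(r2$distance, 2L)
  # three substitutions exceed the bound (min pairwise distance >= 7 keeps
  # other accepted barcodes out of range)
  obs3 <- perturb(bc, 3L)
  r3 <- correct_barcode(obs3, wl, d_max = 2L)
  expect_equal(r3$status, "no_match")
  # malformed length is a counted no_match, not an exception
  rl <- correct_barcode(substr(bc, 1, 10), wl)
  expect_equal(rl$status, "no_match")
  expect_true(rl$malformed)
})

test_that("ambiguity is rejected conservatively; nearest mode is optional", {
  # two accepted barcodes, Hamming 2 apart in round 1
  wl <- build_whitelist(list(c("AAAAAAAAAA", "AACCAAAAAA"),
                             c("GGGGGGGGGG"), c("TTTTTTTTTT")))
  # observed sits 1 from the first and 1 from the second
  obs <- paste0("AACAAAAAAA", "GGGGGGGGGG", "TTTTTTTTTT")
  r <- correct_barcode(obs, wl, d_max = 2L)
  expect_equal(r$status, "ambiguous")
  # nearer-but-not-unique within d_max is still ambiguous in unique mode
  wl2 <- build_whitelist(list(c("AAAAAAAAAA", "AACCAAAAAA"),
                              c("GGGGGGGGGG"), c("TTTTTTTTTT")))
  obs2 <- paste0("AACCAAAAAC", "GGGGGGGGGG", "TTTTTTTTTT") # d=1 and d=3
  r2u <- correct_barcode(obs2, wl2, d_max = 2L)
  r2n <- correct_barcode(obs2, wl2, d_max = 2L, mode = "nearest")
  expect_equal(r2u$status, "corrected") # second lies at d=3, outside d_max
  obs3 <- paste0("AACAAAAAAA", "GGGGGGGGGG", "TTTTTTTTTG") # 2 vs 2
  r3u <- correct_barcode(obs3, wl2, d_max = 2L)
  expect_equal(r3u$status, "ambiguous")
  r3n <- correct_barcode(obs3, wl2, d_max = 2L, mode = "nearest")
  expect_equal(r3n$status, "ambiguous") # tied at the same distance
  # d=1 vs d=2: unique mode rejects, nearest mode takes the nearer one
  obs4 <- paste0("AAGAAAAAAA", "GGGGGGGGGG", "TTTTTTTTTT")
  expect_equal(correct_barcode(obs4, wl2, d_max = 2L)$status, "ambiguous")
  r4n <- correct_barcode(obs4, wl2, d_max = 2L, mode = "nearest")
  expect_equal(r4n$status, "corrected")
  expect_equal(r4n$accepted_barcode,
               paste0("AAAAAAAAAA", "GGGGGGGGGG", "TTTTTTTTTT"))
  expect_equal(r4n$distance, 1L)
})

test_that("correction agrees exactly with the exhaustive Hamming oracle", {
  set.seed(13)
  wl <- random_whitelist(sizes = c(10L, 10L, 10L), seg_len = 10L,
                         min_dist = 1L, n_preindex = 0L)
  acc <- accepted_barcodes(wl)
  n <- 2000L
  obs <- character(n)
  src <- sample(acc, n, replace = TRUE)
  nerr <- sample(0:4, n, replace = TRUE)
  for (i in seq_len(n)) {
    obs[i] <- if (nerr[i] == 0L) src[i] else perturb(src[i], nerr[i])
  }
  obs[sample.int(n, 200L)] <- random_dna(200L, 30L)
  got <- correct_barcodes(obs, wl, d_max = 2L)
  want <- brute_correct(obs, acc, d_max = 2L)
  expect_identical(got$status, want$status)
  expect_identical(got$barcode, want$barcode)
  expect_identical(as.integer(got$distance), as.integer(want$distance))
})

test_that("min distance >= 2*d_max+1 guarantees error-free correction", {
  set.seed(17)
  wl <- random_whitelist(sizes = c(12L, 12L, 12L), seg_len = 10L,
                         min_dist = 5L, n_preindex = 0L)
  expect_gte(wl$min_pairwise_dist, 5L)
  d_max <- 2L
  truth <- sample(accepted_barcodes(wl), 200L, replace = TRUE)
  k <- sample(0:d_max, 200L, replace = TRUE)
  for (i in seq_along(truth)) {
    obs <- if (k[i] == 0L) truth[i] else perturb(truth[i], k[i])
    r <- correct_barcode(obs, wl, d_max = d_max)
    expect_true(r$status %in% c("exact", "corrected"))
    expect_equal(r$accepted_barcode, truth[i])
    expect_equal(r$distance, k[i])
  }
})

test_that("match_preindex corrects within bound and rejects ties", {
  wl <- build_whitelist(list(c("AAAAAAAAAA"), c("CCCCCCCCCC"),
                             c("GGGGGGGGGG")),
                        preindexes = c("AAAAAA", "CCAAAA", "GGGGGG"))
  expect_equal(match_preindex("AAAAAA", wl)$status, "exact")
  r <- match_preindex("AAAAAG", wl, d_pre = 1L)
  expect_equal(r$status, "corrected")
  expect_equal(r$preindex, "AAAAAA")
  # equidistant between two preindexes: rejected, never assigned
  tie <- match_preindex("ACAAAA", wl, d_pre = 1L)
  expect_equal(tie$status, "ambiguous")
  # brute-force confirmation of the tie
  d <- sapply(wl$preindexes, function(p) hamming("ACAAAA", p))
  expect_equal(sort(d)[1:2], c(1, 1), ignore_attr = TRUE)
  # disabled pre-indexing yields the empty pre-index
  wl0 <- build_whitelist(list(c("AAAAAAAAAA"), c("CCCCCCCCCC"),
                              c("GGGGGGGGGG")))
  expect_equal(match_preindex("AAAAAA", wl0)$status, "disabled")
  expect_equal(match_preindex("AAAAAA", wl0)$preindex, "")
})

test_that("parse_read1 slices layout and detects the dA-tail junction", {
  st <- read_structure()
  bc <- strrep("ACGTA", 6) # 30 nt
  umi <- "ACGTACGT"
  cdna <- "GACCTGATCGGCATCAG"
  seq <- paste0(bc, umi, strrep("T", 12), cdna)
  p <- parse_read1(seq, st)
  expect_equal(p$barcode, bc)
  expect_equal(p$umi, umi)
  expect_true(p$junction_ok)
  expect_equal(p$insert, cdna)
  # boundary: exactly barcode+UMI -> empty insert, junction not found
  p0 <- parse_read1(paste0(bc, umi), st)
  expect_false(p0$malformed)
  expect_equal(p0$insert, "")
  expect_false(p0$junction_ok)
  # one mismatch inside a 10-nt run is tolerated
  p1 <- parse_read1(paste0(bc, umi, "TTTTGTTTTT", "CAGCAGGACA"), st)
  expect_true(p1$junction_ok)
  expect_equal(p1$insert, "CAGCAGGACA")
  # too-short reads are structural rejects, flagged not thrown
  ps <- parse_read1(substr(seq, 1, 20), st)
  expect_true(ps$malformed)
})

test_that("declared linkers are verified within one mismatch", {
  st <- read_structure(linker_seqs = c("ACGT", "TGCA"))
  bc <- strrep("GATCA", 6)
  segs <- substring(bc, c(1, 11, 21), c(10, 20, 30))
  umi <- "AAGGTTCC"
  seq <- paste0(segs[1], "ACGT", segs[2], "TGCA", segs[3], umi,
                strrep("T", 8), "CCGGA")
  p <- parse_read1(seq, st)
  expect_equal(p$barcode, bc)
  expect_equal(p$umi, umi)
  # one mismatch in a linker is fine, two are a structural reject
  seq1 <- sub("ACGT", "ACTT", seq, fixed = TRUE)
  expect_false(parse_read1(seq1, st)$malformed)
  seq2 <- sub("ACGT", "AATT", seq, fixed = TRUE)
  expect_true(parse_read1(seq2, st)$malformed)
})

test_that("parse_read1 recovers truth for all error-free simulated reads", {
  fx <- fx_noisy() # reuse annotation/whitelist, fresh error-free reads
  cfg <- library_config(n_nuclei_A = 20L, n_nuclei_B = 20L,
                        molecules_per_nucleus = 30,
                        reads_per_molecule = 1.5,
                        error_rate = 0, ambient_fraction = 0, seed = 103L)
  sim <- simulate_library(cfg, annotation = fx$sim$annotation,
                          whitelist = fx$wl)
  p <- parse_read1(unname(sim$r1), sim$structure)
  truth <- sim$reads
  expect_false(any(p$malformed))
  expect_equal(p$barcode,
               substr(truth$cell_id_truth, 7L, nchar(truth$cell_id_truth)))
  expect_equal(p$umi, truth$umi_truth)
  expect_true(all(p$junction_ok))
})
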