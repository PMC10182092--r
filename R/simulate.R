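# Generative model of pre-indexed random-primed droplet snRNA-seq libraries
# with full per-read ground truth.

BIOTYPES <- c("protein_coding", "lncRNA", "snoRNA", "snRNA", "miRNA",
              "miscRNA", "mito", "ribo")
SHORT_BIOTYPES <- c("snoRNA", "snRNA", "miRNA", "miscRNA", "mito")

.default_biotype_weights <- c(protein_coding = 0.50, lncRNA = 0.18,
                              snoRNA = 0.07, snRNA = 0.07, miRNA = 0.06,
                              miscRNA = 0.04, mito = 0.04, ribo = 0.04)

#' Library simulation parameters
#'
#' Collects the knobs of the generative model. Defaults emulate the regimes
#' of a two-species (barnyard) validation library: sub-percent observed
#' doublets via pre-indexing, intron-rich random priming with a modest
#' oligo(dT) fraction, fragment sizes peaking between 300 and 800 bp, and a
#' small ambient background.
#'
#' @param n_nuclei_A,n_nuclei_B Nuclei per species.
#' @param K Number of pre-index reverse-transcription tubes.
#' @param lambda Mean nuclei per droplet (Poisson co-encapsulation rate).
#' @param molecules_per_nucleus Mean captured molecules per nucleus (Poisson).
#' @param reads_per_molecule Mean reads per molecule (1 + Poisson duplication).
#' @param unspliced_fraction Probability a captured molecule is unspliced
#'   pre-mRNA (nuclear RNA is mostly nascent; the default, together with the
#'   default gene architecture, puts the expected intron:exon read ratio
#'   near 3:1).
#' @param oligodT_fraction Fraction of spliced molecules primed at the
#'   3' poly(A) end instead of uniformly (the assay adds oligo(dT) primers on
#'   top of random primers, giving a slight 3' bias).
#' @param fragment_meanlog,fragment_sdlog Log-normal fragment length
#'   parameters; defaults put the mode in the 300-800 bp window.
#' @param dA_tail_mean Mean dA-tail length (geometric above the junction
#'   minimum run, so every tail is detectable).
#' @param error_rate Per-base substitution sequencing error rate.
#' @param ambient_fraction Fraction of all reads that are ambient background
#'   (valid bead barcode from an otherwise empty droplet, random transcript).
#' @param ambient_barcodes Number of empty-droplet bead barcodes available to
#'   ambient reads.
#' @param read1_len,read2_len Read lengths.
#' @param seed Integer seed fixing every draw of the simulation.
#' @return An object of class `library_config`.
#' @export
library_config <- function(n_nuclei_A = 250L, n_nuclei_B = 250L,
                           K = 4L, lambda = 0.06,
                           molecules_per_nucleus = 200,
                           reads_per_molecule = 2,
                           unspliced_fraction = 0.88,
                           oligodT_fraction = 0.15,
                           fragment_meanlog = log(500),
                           fragment_sdlog = 0.35,
                           dA_tail_mean = 12,
                           error_rate = 0.005,
                           ambient_fraction = 0.05,
                           ambient_barcodes = 2000L,
                           read1_len = 150L,
                           read2_len = 150L,
                           seed = 1L) {
  cfg <- list(n_nuclei_A = as.integer(n_nuclei_A),
              n_nuclei_B = as.integer(n_nuclei_B),
              K = as.integer(K), lambda = lambda,
              molecules_per_nucleus = molecules_per_nucleus,
              reads_per_molecule = reads_per_molecule,
              unspliced_fraction = unspliced_fraction,
              oligodT_fraction = oligodT_fraction,
              fragment_meanlog = fragment_meanlog,
              fragment_sdlog = fragment_sdlog,
              dA_tail_mean = dA_tail_mean,
              error_rate = error_rate,
              ambient_fraction = ambient_fraction,
              ambient_barcodes = as.integer(ambient_barcodes),
              read1_len = as.integer(read1_len),
              read2_len = as.integer(read2_len),
              seed = as.integer(seed))
  probs <- c(unspliced_fraction = unspliced_fraction,
             oligodT_fraction = oligodT_fraction,
             error_rate = error_rate,
             ambient_fraction = ambient_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (lambda <= 0) stop("lambda must be > 0")
  if (ambient_fraction >= 1) stop("ambient_fraction must be < 1")
  if (reads_per_molecule < 1) stop("reads_per_molecule must be >= 1")
  if (cfg$K < 1L) stop("K must be >= 1")
  structure(cfg, class = "library_config")
}

#' Simulate a toy two-species annotation
#'
#' Lays out non-overlapping genes along one chromosome per species, with
#' alternating exon/intron structure (0-based half-open coordinates),
#' random strands, a configurable biotype mix (the first genes of each
#' species cycle through all requested biotypes so every class is present),
#' per-gene Gamma expression rates, and random chromosome sequence.
#'
#' @param n_genes_per_species Genes per species (>= 1).
#' @param seed Optional seed; fixed seeds give byte-identical annotations.
#' @param biotype_weights Named sampling weights over the biotype classes.
#' @param n_exons Range of exon counts for multi-exon biotypes.
#' @param exon_len,intron_len,short_len,gap_len Length ranges (nt) for exons,
#'   introns, single-exon short ncRNAs, and intergenic gaps.
#' @param rate_shape Gamma shape for per-gene expression rates.
#' @param biotype_rate_factor Named multipliers on expression rates per
#'   biotype: nuclear libraries are dominated by intron-rich protein-coding
#'   transcripts, with short non-coding classes contributing few molecules.
#'   Together with the intron lengths this sets the expected intron:exon
#'   read ratio of the default configuration near 3:1.
#' @return An object of class `toy_annotation` with elements `genes`,
#'   `exons`, `introns` (data.tables) and `seqs` (a `DNAStringSet`).
#' @export
simulate_annotation <- function(n_genes_per_species = 100L, seed = NULL,
                                biotype_weights = NULL,
                                n_exons = c(3L, 8L),
                                exon_len = c(150L, 400L),
                                intron_len = c(2000L, 4000L),
                                short_len = c(80L, 300L),
                                gap_len = c(200L, 1000L),
                                rate_shape = 0.6,
                                biotype_rate_factor = c(
                                  protein_coding = 1, lncRNA = 0.3,
                                  snoRNA = 0.05, snRNA = 0.05, miRNA = 0.05,
                                  miscRNA = 0.05, mito = 0.5, ribo = 0.5)) {
  if (n_genes_per_species < 1L) stop("need at least one gene per species")
  if (!is.null(seed)) set.seed(seed)
  w <- biotype_weights %||% .default_biotype_weights
  stopifnot(all(names(w) %in% BIOTYPES), all(w >= 0), sum(w) > 0)
  genes_l <- list(); exons_l <- list(); introns_l <- list()
  seqs <- list()
  rint <- function(n, range) {
    as.integer(floor(runif(n, range[1], range[2] + 1)))
  }
  for (sp in c("A", "B")) {
    chrom <- paste0("chr", sp)
    n <- as.integer(n_genes_per_species)
    bts <- names(w)[((seq_len(n) - 1L) %% length(w)) + 1L]
    if (n > length(w)) {
      bts[(length(w) + 1L):n] <-
        sample(names(w), n - length(w), replace = TRUE, prob = w)
    }
    cursor <- 0L
    for (i in seq_len(n)) {
      cursor <- cursor + rint(1L, gap_len)
      bt <- bts[i]
      if (bt %in% SHORT_BIOTYPES) {
        if (bt == "mito") {
          ex_lens <- rint(1L, c(300L, 1200L))
        } else {
          ex_lens <- rint(1L, short_len)
        }
        in_lens <- integer()
      } else {
        ne <- rint(1L, n_exons)
        ex_lens <- rint(ne, exon_len)
        in_lens <- rint(ne - 1L, intron_len)
      }
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("g%s%04d", sp, i)
      rel <- 0L
      ex_rs <- integer(length(ex_lens)); ex_re <- integer(length(ex_lens))
      in_rs <- integer(length(in_lens)); in_re <- integer(length(in_lens))
      for (k in seq_along(ex_lens)) {
        ex_rs[k] <- rel; rel <- rel + ex_lens[k]; ex_re[k] <- rel
        if (k <= length(in_lens)) {
          in_rs[k] <- rel; rel <- rel + in_lens[k]; in_re[k] <- rel
        }
      }
      span <- rel
      gstart <- cursor
      genes_l[[length(genes_l) + 1L]] <- data.table(
        gene_id = gid, species = sp, biotype = bt, chrom = chrom,
        strand = strand, start = gstart, end = gstart + span,
        spliced_len = sum(ex_lens), unspliced_len = span,
        rate = (rgamma(1L, shape = rate_shape, rate = 1) + 1e-4) *
          (if (bt %in% names(biotype_rate_factor))
            biotype_rate_factor[[bt]] else 1))
      exons_l[[length(exons_l) + 1L]] <- data.table(
        gene_id = gid, chrom = chrom, strand = strand,
        start = gstart + ex_rs, end = gstart + ex_re)
      if (length(in_lens)) {
        introns_l[[length(introns_l) + 1L]] <- data.table(
          gene_id = gid, chrom = chrom, strand = strand,
          start = gstart + in_rs, end = gstart + in_re)
      }
      cursor <- gstart + span
    }
    cursor <- cursor + rint(1L, gap_len)
    seqs[[chrom]] <- paste(sample(DNA_BASES, cursor, replace = TRUE),
                           collapse = "")
  }
  genes <- rbindlist(genes_l)
  exons <- rbindlist(exons_l)
  introns <- if (length(introns_l)) rbindlist(introns_l) else
    data.table(gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer())
  .index_annotation(genes, exons, introns,
                    Biostrings::DNAStringSet(unlist(seqs)))
}

# Attach gene-body (5'->3') and spliced-transcript offsets to exon/intron
# tables and assemble the toy_annotation object.
.index_annotation <- function(genes, exons, introns, seqs) {
  setDT(genes); setDT(exons); setDT(introns)
  gidx <- genes[, .(gene_id, gstart = start, gend = end, gstrand = strand)]
  add_body <- function(dt) {
    if (!nrow(dt)) {
      dt[, `:=`(bstart = integer(), bend = integer())]
      return(dt)
    }
    dt <- gidx[dt, on = "gene_id"]
    dt[, `:=`(
      bstart = fifelse(gstrand == "+", start - gstart, gend - end),
      bend = fifelse(gstrand == "+", end - gstart, gend - start))]
    dt[, c("gstart", "gend", "gstrand") := NULL]
    dt
  }
  exons <- add_body(exons)
  introns <- add_body(introns)
  setorder(exons, gene_id, bstart)
  exons[, tx_off := cumsum(c(0L, head(bend - bstart, -1L))), by = gene_id]
  exons[, tx_end := tx_off + (bend - bstart)]
  structure(list(genes = genes, exons = exons, introns = introns,
                 seqs = seqs),
            class = "toy_annotation")
}

#' @exportS3Method base::print
print.toy_annotation <- function(x, ...) {
  cat("toy_annotation:", nrow(x$genes), "genes on",
      length(x$seqs), "chromosomes;",
      nrow(x$exons), "exons,", nrow(x$introns), "introns\n")
  invisible(x)
}

#' Check toy-annotation invariants
#'
#' Exons and introns of each gene must tile the gene span without overlap,
#' and spliced lengths must equal summed exon lengths. Stops on violation.
#' @param annotation A `toy_annotation`.
#' @export
validate_annotation <- function(annotation) {
  g <- annotation$genes
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids")
  feats <- rbind(annotation$exons[, .(gene_id, start, end)],
                 annotation$introns[, .(gene_id, start, end)])
  setorder(feats, gene_id, start)
  bad <- feats[, any(start[-1] != head(end, -1L)), by = gene_id][V1 == TRUE]
  if (nrow(bad)) stop("exons/introns do not tile gene span: ",
                      paste(bad$gene_id, collapse = ", "))
  sl <- annotation$exons[, .(sl = sum(end - start)), by = gene_id]
  chk <- g[sl, on = "gene_id"][spliced_len != sl]
  if (nrow(chk)) stop("spliced_len mismatch")
  invisible(TRUE)
}

#' Random split-pool whitelist
#'
#' Draws per-round segment sets (and pre-indexes) of random DNA, greedily
#' enforcing a minimum within-round pairwise Hamming distance so that
#' bounded-error correction is well-posed.
#'
#' @param sizes Segments per ligation round.
#' @param seg_len Segment length (nt).
#' @param n_preindex Number of pre-index (RT tube) sequences.
#' @param preindex_len Pre-index length (nt).
#' @param min_dist Minimum pairwise Hamming distance within each round.
#' @param preindex_min_dist Minimum pairwise distance within the pre-index
#'   set (kept feasible for short pre-indexes).
#' @param seed Optional seed.
#' @return A `barcode_whitelist`.
#' @export
random_whitelist <- function(sizes = c(24L, 24L, 24L), seg_len = 10L,
                             n_preindex = 8L, preindex_len = 6L,
                             min_dist = 3L, preindex_min_dist = 3L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_set <- function(n, len, dmin) {
    chosen <- character(0)
    mat <- NULL
    tries <- 0L
    while (length(chosen) < n) {
      cand <- random_dna(1L, len)
      tries <- tries + 1L
      if (tries > 1000L * n) stop("cannot satisfy min_dist; reduce it")
      if (length(chosen)) {
        d <- colSums(mat != strsplit(cand, "", fixed = TRUE)[[1]])
        if (min(d) < dmin) next
      }
      chosen <- c(chosen, cand)
      mat <- .seq_mat(chosen, len)
    }
    chosen
  }
  rounds <- lapply(sizes, draw_set, len = seg_len, dmin = min_dist)
  pres <- if (n_preindex > 0L && preindex_len > 0L) {
    draw_set(n_preindex, preindex_len,
             min(preindex_min_dist, preindex_len))
  } else character()
  build_whitelist(rounds, pres)
}

#' Simulate per-nucleus expression profiles
#'
#' Each nucleus of a species expresses only that species' genes
#' (species-exclusive barnyard construction). The number of captured
#' molecules per nucleus is Poisson; genes are drawn proportionally to their
#' Gamma rates (a Gamma-Poisson mixture across genes); each molecule is
#' unspliced pre-mRNA with probability `unspliced_fraction`.
#'
#' @param annotation A `toy_annotation`.
#' @param config A [library_config()].
#' @param seed Optional seed (the top-level [simulate_library()] seeds once).
#' @return `sim_profiles`: list with `nuclei` (nucleus_id, species) and
#'   `molecules` (nucleus_id, gene_id, unspliced).
#' @export
simulate_expression <- function(annotation, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nA <- config$n_nuclei_A; nB <- config$n_nuclei_B
  nuclei <- data.table(
    nucleus_id = sprintf("n%05d", seq_len(nA + nB)),
    species = rep(c("A", "B"), c(nA, nB)))
  mols <- list()
  for (sp in c("A", "B")) {
    nuc <- nuclei[species == sp]
    if (!nrow(nuc)) next
    g <- annotation$genes[species == sp]
    M <- rpois(nrow(nuc), config$molecules_per_nucleus)
    total <- sum(M)
    if (total == 0L) next
    mols[[sp]] <- data.table(
      nucleus_id = rep(nuc$nucleus_id, M),
      gene_id = sample(g$gene_id, total, replace = TRUE,
                       prob = g$rate / sum(g$rate)),
      unspliced = runif(total) < config$unspliced_fraction)
  }
  molecules <- rbindlist(mols)
  structure(list(nuclei = nuclei, molecules = molecules),
            class = "sim_profiles")
}

# Truncated-Poisson (>=1) droplet occupancies.
.rtpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  qpois(runif(n, p0, 1), lambda)
}

#' Assign nuclei to pre-index tubes and droplets
#'
#' Nuclei are split uniformly across `K` reverse-transcription tubes (each
#' tube's primers carry one pre-index), pooled, and co-encapsulated with
#' bead barcodes: occupied-droplet sizes are Poisson(`lambda`) conditioned
#' on at least one nucleus, and each droplet draws a distinct bead barcode
#' from the whitelist. A droplet is a physical collision when it holds two
#' or more nuclei, and an observed doublet only when at least two of its
#' nuclei share a pre-index — the 1/K thinning that motivates pre-indexing.
#'
#' @param profiles Output of [simulate_expression()].
#' @param whitelist A `barcode_whitelist` with at least `K` preindexes and
#'   more accepted barcodes than droplets.
#' @param config A [library_config()].
#' @param seed Optional seed.
#' @return `sim_droplets`: list with augmented `nuclei`, `droplets`,
#'   `ambient_pool` (empty-droplet barcodes), `preindexes`.
#' @export
simulate_droplets <- function(profiles, whitelist, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nuclei <- copy(profiles$nuclei)
  n <- nrow(nuclei)
  K <- config$K
  if (length(whitelist$preindexes) < K)
    stop("whitelist has fewer preindexes than K tubes")
  pres <- whitelist$preindexes[seq_len(K)]
  tube <- sample.int(K, n, replace = TRUE)
  lambda <- config$lambda
  ebar <- lambda / (1 - exp(-lambda))
  sizes <- .rtpois(ceiling(n / ebar * 1.2) + 16L, lambda)
  while (sum(sizes) < n) sizes <- c(sizes, .rtpois(64L, lambda))
  cs <- cumsum(sizes)
  D <- which(cs >= n)[1]
  sizes <- sizes[seq_len(D)]
  sizes[D] <- n - (cs[D] - sizes[D])
  n_amb <- if (config$ambient_fraction > 0) config$ambient_barcodes else 0L
  if (D + n_amb > whitelist_size(whitelist))
    stop("whitelist smaller than required droplet + ambient barcode count")
  bead_idx <- sample.int(whitelist_size(whitelist), D + n_amb)
  bead_bc <- barcode_at(whitelist, bead_idx[seq_len(D)])
  ambient_pool <- if (n_amb > 0L) {
    barcode_at(whitelist, bead_idx[(D + 1L):(D + n_amb)])
  } else character()
  droplet <- integer(n)
  droplet[sample.int(n)] <- rep(seq_len(D), sizes)
  nuclei[, `:=`(tube = tube,
                preindex = pres[tube],
                droplet_id = droplet,
                barcode = bead_bc[droplet])]
  nuclei[, cell_id := paste0(preindex, barcode)]
  droplets <- nuclei[, .(
    n_nuclei = .N,
    physical_collision = .N >= 2L,
    observed_doublet = anyDuplicated(preindex) > 0L,
    barcode = barcode[1]), by = droplet_id]
  structure(list(nuclei = nuclei, droplets = droplets,
                 ambient_pool = ambient_pool, preindexes = pres),
            class = "sim_droplets")
}

# UMIs from a Hamming-distance-2 checksum code: L-1 random bases plus one
# parity base, so distinct codewords never sit within one substitution of
# each other (ideal molecular labelling; see the methods vignette).
.draw_umis <- function(n, len) {
  if (n == 0L) return(character())
  stopifnot(len >= 2L)
  m <- matrix(sample(0:3, n * (len - 1L), replace = TRUE), nrow = len - 1L)
  chk <- colSums(m) %% 4L
  codes <- rbind(m, chk)
  mode(codes) <- "integer"
  .paste_mat_rows(matrix(DNA_BASES[codes + 1L], nrow = len))
}

# Per-gene sense sequences: spliced transcript and unspliced gene body.
.gene_sequences <- function(annotation) {
  g <- annotation$genes
  ex <- annotation$exons
  body <- character(nrow(g)); tx <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    s <- Biostrings::subseq(annotation$seqs[[g$chrom[i]]],
                            g$start[i] + 1L, g$end[i])
    if (g$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    body[i] <- as.character(s)
    exi <- ex[gene_id == g$gene_id[i]][order(tx_off)]
    tx[i] <- paste(substring(body[i], exi$bstart + 1L, exi$bend),
                   collapse = "")
  }
  list(body = setNames(body, g$gene_id), tx = setNames(tx, g$gene_id))
}

# Map spliced-transcript coordinates to genomic positions.
.tx_to_genome <- function(exons, gene_id_vec, t_vec) {
  q <- data.table(gene_id = gene_id_vec, t = t_vec, i = seq_along(t_vec))
  exi <- exons[, .(gene_id, tx_lo = tx_off, tx_hi = tx_end,
                   start, end, strand, off = tx_off)]
  hit <- exi[q, on = .(gene_id, tx_lo <= t, tx_hi > t), mult = "first",
             .(i = i.i, g = fifelse(strand == "+",
                                    start + (i.t - off),
                                    end - 1L - (i.t - off)))]
  setorder(hit, i)
  if (anyNA(hit$g)) stop("transcript coordinate outside exons")
  hit$g
}

#' Simulate paired-end reads with ground truth
#'
#' Converts molecules into sequenced read pairs following the chemistry:
#' random priming is uniform along the molecule (spliced transcript for
#' mature mRNA, full gene body for pre-mRNA), the oligo(dT) fraction primes
#' at the 3' terminus of spliced transcripts, and reverse transcription
#' extends from the priming site toward the 5' end over a log-normal
#' fragment length. Read1 carries barcode + UMI + the poly(T) read-through
#' of the dA tail + proximal insert bases; Read2 carries the pre-index, the
#' insert (cDNA orientation) and any dA-tail read-through as trailing A's.
#' Substitution errors are applied uniformly; ambient reads (a configurable
#' fraction) carry valid bead barcodes from otherwise empty droplets and a
#' random transcript from either species.
#'
#' @param annotation A `toy_annotation`.
#' @param profiles Output of [simulate_expression()].
#' @param droplets Output of [simulate_droplets()].
#' @param structure A [read_structure()].
#' @param config A [library_config()].
#' @param seed Optional seed.
#' @return `snrand_sim`: list with `r1`, `r2` (named sequence vectors),
#'   `reads` (per-read truth), `molecules` (per-molecule truth), `nuclei`,
#'   `droplets`, plus the annotation/whitelist/structure/config used.
#' @export
simulate_reads <- function(annotation, profiles, droplets, structure,
                           config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (structure$preindex_len > 0L &&
      any(nchar(droplets$preindexes) != structure$preindex_len))
    stop("preindex length of whitelist does not match read structure")
  min_insert <- structure$preindex_len + 1L
  if (config$read2_len < min_insert)
    stop("read2_len shorter than structural minimum")
  lay <- .r1_layout(structure)
  if (config$read1_len < lay$scan_start - 1L)
    stop("read1_len shorter than structural minimum")

  mol <- copy(profiles$molecules)
  nuc <- droplets$nuclei[, .(nucleus_id, droplet_id, cell_id, preindex,
                             barcode)]
  mol <- nuc[mol, on = "nucleus_id"]
  mol[, is_ambient := FALSE]
  mol[, n_reads := 1L + rpois(.N, max(config$reads_per_molecule - 1, 0))]

  # ambient molecules: one read each, empty-droplet bead barcodes
  n_real <- sum(mol$n_reads)
  a <- config$ambient_fraction
  n_amb <- if (a > 0) round(a / (1 - a) * n_real) else 0L
  if (n_amb > 0L) {
    if (!length(droplets$ambient_pool))
      stop("ambient_fraction > 0 but no ambient barcode pool")
    g <- annotation$genes
    amb_bc <- sample(droplets$ambient_pool, n_amb, replace = TRUE)
    amb_pre <- sample(droplets$preindexes, n_amb, replace = TRUE)
    amb <- data.table(
      nucleus_id = NA_character_,
      droplet_id = NA_integer_,
      cell_id = paste0(amb_pre, amb_bc),
      preindex = amb_pre, barcode = amb_bc,
      gene_id = sample(g$gene_id, n_amb, replace = TRUE,
                       prob = g$rate / sum(g$rate)),
      unspliced = runif(n_amb) < config$unspliced_fraction,
      is_ambient = TRUE, n_reads = 1L)
    mol <- rbind(mol, amb, use.names = TRUE)
  }
  M <- nrow(mol)
  mol[, mol_id := seq_len(M)]

  # distinct checksum-code UMIs within each (cell, gene) group
  mol[, umi := .draw_umis(M, structure$umi_len)]
  repeat {
    dup <- mol[, .I[duplicated(umi)], by = .(cell_id, gene_id)]$V1
    if (!length(dup)) break
    mol[dup, umi := .draw_umis(length(dup), structure$umi_len)]
  }

  gi <- annotation$genes[, .(gene_id, chrom, strand, gstart = start,
                             gend = end, spliced_len, unspliced_len)]
  mol <- gi[mol, on = "gene_id"]
  mol[, L := fifelse(unspliced, unspliced_len, spliced_len)]

  # priming site and fragment (RT extends from the site toward the 5' end)
  F_len <- pmax(50L, as.integer(round(
    rlnorm(M, config$fragment_meanlog, config$fragment_sdlog))))
  is_dT <- !mol$unspliced & (runif(M) < config$oligodT_fraction)
  s <- as.integer(floor(runif(M) * mol$L))
  s[s >= mol$L] <- mol$L[s >= mol$L] - 1L
  s[is_dT] <- mol$L[is_dT] - 1L
  mol[, `:=`(site = s, frag_end = s + 1L,
             frag_start = pmax(0L, s + 1L - F_len),
             oligodT = is_dT)]

  # region of the priming site (molecule coordinates)
  mol[, region := "exon"]
  un <- which(mol$unspliced)
  if (length(un)) {
    q <- mol[un, .(gene_id, site)]
    exb <- annotation$exons[, .(gene_id, bstart, bend)]
    hit <- exb[q, on = .(gene_id, bstart <= site, bend > site),
               mult = "first", which = TRUE]
    mol$region[un][is.na(hit)] <- "intron"
  }

  # genomic footprint of the fragment
  mol[, `:=`(aln_start = NA_integer_, aln_end = NA_integer_)]
  un <- mol$unspliced
  mol[un & strand == "+", `:=`(aln_start = gstart + frag_start,
                               aln_end = gstart + frag_end)]
  mol[un & strand == "-", `:=`(aln_start = gend - frag_end,
                               aln_end = gend - frag_start)]
  sp <- which(!un)
  if (length(sp)) {
    g1 <- .tx_to_genome(annotation$exons, mol$gene_id[sp],
                        mol$frag_start[sp])
    g2 <- .tx_to_genome(annotation$exons, mol$gene_id[sp],
                        mol$frag_end[sp] - 1L)
    mol$aln_start[sp] <- pmin(g1, g2)
    mol$aln_end[sp] <- pmax(g1, g2) + 1L
  }

  # fragment sequence (sense, 5'->3' of the molecule)
  seqs <- .gene_sequences(annotation)
  src <- fifelse(mol$unspliced, seqs$body[mol$gene_id],
                 seqs$tx[mol$gene_id])
  frag_seq <- substring(src, mol$frag_start + 1L, mol$frag_end)

  # dA tail per molecule (always at least the junction minimum run)
  jmin <- structure$junction_min_run
  extra <- max(config$dA_tail_mean - jmin, 0.5)
  tail_len <- jmin + rgeom(M, prob = 1 / (1 + extra))

  # expand molecules to reads
  ridx <- rep(seq_len(M), mol$n_reads)
  nr <- length(ridx)
  ord <- sample.int(nr)  # shuffle library order
  ridx <- ridx[ord]
  read_id <- sprintf("r%07d", seq_len(nr))

  bc_part <- .bc_with_linkers(mol$barcode[ridx], structure)
  tails <- tail_len[ridx]
  frag_r <- frag_seq[ridx]
  prefix_len <- lay$scan_start - 1L
  avail1 <- pmax(0L, config$read1_len - prefix_len - tails)
  r1 <- paste0(bc_part, mol$umi[ridx],
               strrep(structure$r1_junction_base, tails),
               substr(frag_r, 1L, avail1))
  rc <- .revcomp(frag_r)
  core <- substr(rc, 1L, config$read2_len - structure$preindex_len)
  room <- config$read2_len - structure$preindex_len - nchar(core)
  pre_part <- if (structure$preindex_len > 0L) mol$preindex[ridx] else ""
  r2 <- paste0(pre_part, core,
               strrep(structure$r2_tail_trim, pmin(tails, room)))
  if (config$error_rate > 0) {
    r1 <- .add_errors(r1, config$error_rate)
    r2 <- .add_errors(r2, config$error_rate)
  }
  names(r1) <- read_id
  names(r2) <- read_id

  reads <- data.table(
    read_id = read_id,
    mol_id = mol$mol_id[ridx],
    droplet_id = mol$droplet_id[ridx],
    nucleus_id = mol$nucleus_id[ridx],
    cell_id_truth = mol$cell_id[ridx],
    gene_id = mol$gene_id[ridx],
    region = mol$region[ridx],
    spliced_flag = !mol$unspliced[ridx],
    umi_truth = mol$umi[ridx],
    chrom = mol$chrom[ridx],
    aln_start = mol$aln_start[ridx],
    aln_end = mol$aln_end[ridx],
    strand = mol$strand[ridx],
    priming_site = mol$site[ridx],
    oligodT = mol$oligodT[ridx],
    is_ambient = mol$is_ambient[ridx])

  molecules <- mol[, .(mol_id, cell_id, nucleus_id, gene_id, umi,
                       spliced_flag = !unspliced, region, n_reads,
                       is_ambient)]
  out <- list(r1 = r1, r2 = r2, reads = reads, molecules = molecules,
              nuclei = droplets$nuclei, droplets = droplets$droplets,
              ambient_pool = droplets$ambient_pool,
              annotation = annotation, structure = structure,
              config = config)
  class(out) <- "snrand_sim"
  out
}

.bc_with_linkers <- function(bc, structure) {
  if (is.null(structure$linker_seqs)) return(bc)
  segs <- structure$barcode_segment_lens
  pos <- cumsum(c(1L, segs))
  parts <- list()
  for (i in seq_along(segs)) {
    parts[[length(parts) + 1L]] <- substr(bc, pos[i], pos[i + 1L] - 1L)
    if (i < length(segs))
      parts[[length(parts) + 1L]] <- structure$linker_seqs[i]
  }
  do.call(paste0, parts)
}

# Uniform substitution errors; substituted base is one of the other three.
.add_errors <- function(seqs, e) {
  nch <- nchar(seqs)
  nerr <- rbinom(length(seqs), nch, e)
  idx <- which(nerr > 0L)
  if (!length(idx)) return(seqs)
  split <- strsplit(seqs[idx], "", fixed = TRUE)
  for (k in seq_along(idx)) {
    ch <- split[[k]]
    pos <- sample.int(length(ch), nerr[idx[k]])
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    split[[k]] <- ch
  }
  seqs[idx] <- vapply(split, paste, "", collapse = "")
  seqs
}

#' @exportS3Method base::print
print.snrand_sim <- function(x, ...) {
  cat("snrand_sim:", length(x$r1), "read pairs from",
      nrow(x$nuclei), "nuclei in", nrow(x$droplets), "droplets;",
      nrow(x$molecules), "molecules (",
      sum(x$molecules$is_ambient), "ambient )\n")
  invisible(x)
}

#' Simulate a complete library
#'
#' Seeds the generator once from `config$seed` and chains
#' [simulate_annotation()] (unless one is supplied), [random_whitelist()]
#' (unless supplied), [simulate_expression()], [simulate_droplets()] and
#' [simulate_reads()]. Fixed seeds give byte-identical libraries.
#'
#' @param config A [library_config()].
#' @param annotation Optional `toy_annotation`.
#' @param whitelist Optional `barcode_whitelist`.
#' @param structure A [read_structure()].
#' @param n_genes_per_species Passed to [simulate_annotation()] when
#'   `annotation` is NULL.
#' @return A `snrand_sim` (see [simulate_reads()]).
#' @export
simulate_library <- function(config = library_config(),
                             annotation = NULL, whitelist = NULL,
                             structure = read_structure(),
                             n_genes_per_species = 100L) {
  set.seed(config$seed)
  if (is.null(annotation))
    annotation <- simulate_annotation(n_genes_per_species)
  if (is.null(whitelist))
    whitelist <- random_whitelist(n_preindex = max(config$K, 2L),
                                  preindex_len = structure$preindex_len)
  profiles <- simulate_expression(annotation, config)
  droplets <- simulate_droplets(profiles, whitelist, config)
  sim <- simulate_reads(annotation, profiles, droplets, structure, config)
  sim$whitelist <- whitelist
  sim
}

#' Truth-mode alignment records from a simulation
#'
#' One record per read with its true genomic footprint and true cell/UMI
#' tags; stands in for an external aligner's output on error-free data.
#' @param sim A `snrand_sim`.
#' @return `data.table(read_id, chrom, start, end, strand, cell_id, umi)`.
#' @export
truth_alignments <- function(sim) {
  sim$reads[, .(read_id, chrom, start = aln_start, end = aln_end, strand,
                cell_id = cell_id_truth, umi = umi_truth)]
}

#' Alignment records for demultiplexed reads
#'
#' Joins the demultiplexer's tagged reads with the simulator's true
#' genomic coordinates by read id (the aligner stand-in for simulated data).
#' @param tagged Tagged reads from [demux_pair_stream()].
#' @param sim The `snrand_sim` the reads came from.
#' @export
alignments_from_demux <- function(tagged, sim) {
  coords <- sim$reads[, .(read_id, chrom, start = aln_start,
                          end = aln_end, strand)]
  out <- coords[tagged[, .(read_id, cell_id, umi)], on = "read_id",
                nomatch = NULL]
  out[, .(read_id, chrom, start, end, strand, cell_id, umi)]
}

#' True molecule count matrix
#'
#' Builds the cell-by-gene matrix implied by the simulator's molecule table
#' (the ground truth a lossless pipeline must reproduce). Layers reflect the
#' molecules' true spliced/unspliced status; ambient molecules are counted
#' under their bead barcodes.
#' @param sim A `snrand_sim`.
#' @param cells Optional cell ordering/subset.
#' @export
truth_matrix <- function(sim, cells = NULL) {
  counts <- sim$molecules[, .(total = .N,
                              spliced = sum(spliced_flag),
                              unspliced = sum(!spliced_flag)),
                          by = .(cell_id, gene_id)]
  .build_count_matrix(counts[, .(cell_id, gene_id, spliced, unspliced,
                                 ambiguous = 0L)],
                      sim$annotation, cells)
}
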