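# Synthetic-data generators.  Every downstream stage of the pipeline is
# verified against data produced here with known ground truth: planted
# occupancy changes, a known global ChIP scaling with a spike-in reference
# epigenome, known new/old histone fractions with planted barcode
# duplicates, and negative-binomial stranded counts with planted
# differential expression.

#' Canonical TSS-relative occupancy profile
#'
#' A stylized yeast promoter: uniform occupancy far upstream, a
#' nucleosome-depleted region just upstream of the TSS, and phased
#' nucleosomes (repeat length 165 bp, +1 dyad near +74) decaying into the
#' gene body.  Used as the WT sampling weight for fragment simulation.
#'
#' @param spec a [window_spec()].
#' @return positive numeric vector of per-window weights.
#' @export
baseline_occupancy_profile <- function(spec = window_spec()) {
  x <- window_midpoints(spec)
  w <- numeric(length(x))
  upstream <- x < -200
  ndr <- x >= -200 & x < -20
  body <- x >= -20
  w[upstream] <- 1
  w[ndr] <- 0.3
  w[body] <- 1 + 0.6 * cos(2 * pi * (x[body] - 74) / 165) * exp(-x[body] / 700)
  w
}

#' Ground truth for the synthetic experiment
#'
#' Bundles every planted parameter the pipeline is later asked to recover.
#' `occupancy_delta` is a genes x windows matrix of log2 occupancy changes
#' (mutant relative to WT; 0 = no change).  `scaling_factor` is the true
#' global ChIP signal level of the condition relative to a reference
#' condition with level 1.  `new_fraction` is the genes x windows matrix of
#' new-histone fractions f, so the expected Flag:V5 ratio is f / (1 - f).
#'
#' @param annotation gene annotation data.frame.
#' @param spec a [window_spec()].
#' @param occupancy_delta NULL (no change) or genes x windows matrix of
#'   log2 fold changes.
#' @param scaling_factor true global ChIP scaling (> 0).
#' @param orthologous_fraction fraction of spike-in reads aligning to both
#'   genomes, in [0, 1).
#' @param mixing_ratio target:reference chromatin mixing in the input
#'   (default 2, i.e. 40e7 : 20e7 cells).
#' @param promoter_new_fraction,body_new_fraction new-histone fraction f in
#'   promoter windows (oriented midpoint in [-300, 0)) and gene-body
#'   windows (>= 0); upstream windows get the body value.
#' @param de_table NULL or data.frame with `gene_id`, `strand_class`
#'   (`sense`/`antisense`) and `log2fc` for planted DE genes; (gene,
#'   strand_class) pairs must be unique.
#' @param seed integer seed recorded with the truth.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(annotation, spec = window_spec(),
                            occupancy_delta = NULL,
                            scaling_factor = 1,
                            orthologous_fraction = 0.05,
                            mixing_ratio = 2,
                            promoter_new_fraction = 0.5,
                            body_new_fraction = 0.5,
                            de_table = NULL,
                            seed = 1L) {
  validate_annotation(annotation)
  check_scalar_number(scaling_factor, "scaling_factor", lower = 0, strict_lower = TRUE)
  check_fraction(orthologous_fraction, "orthologous_fraction")
  if (orthologous_fraction >= 1) cq_stop("orthologous_fraction must be < 1")
  check_scalar_number(mixing_ratio, "mixing_ratio", lower = 0, strict_lower = TRUE)
  check_fraction(promoter_new_fraction, "promoter_new_fraction")
  check_fraction(body_new_fraction, "body_new_fraction")
  n <- nrow(annotation)
  if (is.null(occupancy_delta)) {
    occupancy_delta <- matrix(0, n, spec$n_windows)
  }
  stopifnot(is.matrix(occupancy_delta),
            nrow(occupancy_delta) == n,
            ncol(occupancy_delta) == spec$n_windows)
  rownames(occupancy_delta) <- annotation$gene_id
  x <- window_midpoints(spec)
  f_row <- ifelse(x >= -300 & x < 0, promoter_new_fraction, body_new_fraction)
  new_fraction <- matrix(rep(f_row, each = n), n, spec$n_windows,
                         dimnames = list(annotation$gene_id, NULL))
  if (!is.null(de_table)) {
    stopifnot(all(c("gene_id", "strand_class", "log2fc") %in% names(de_table)))
    if (!all(de_table$gene_id %in% annotation$gene_id)) {
      cq_stop("de_table references unknown gene(s)")
    }
    if (anyDuplicated(de_table[, c("gene_id", "strand_class")])) {
      cq_stop("planted DE sets must be disjoint per (gene, strand_class)")
    }
  }
  structure(list(annotation = annotation, window_spec = spec,
                 occupancy_delta = occupancy_delta,
                 scaling_factor = scaling_factor,
                 orthologous_fraction = orthologous_fraction,
                 mixing_ratio = mixing_ratio,
                 new_fraction = new_fraction,
                 de_table = de_table,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# sample n positions (0-based) from the gene-window weight matrix plus a
# uniform genomic background; returns data.frame(pos, chrom, gene, window)
.sample_window_positions <- function(truth, chrom_sizes, n, weights,
                                     background = 0.1) {
  ann <- truth$annotation
  spec <- truth$window_spec
  bnd <- .window_bounds(ann, spec)
  ok <- matrix(TRUE, nrow(ann), spec$n_windows)
  for (g in seq_len(nrow(ann))) {
    len <- chrom_sizes[[ann$chrom[g]]]
    ok[g, ] <- bnd$lo[g, ] >= 0L & bnd$hi[g, ] <= len
  }
  w <- weights * ok
  slots <- which(w > 0)
  slot_w <- w[slots]
  n_bg <- rbinom(1L, n, background)
  n_fg <- n - n_bg
  out_chrom <- character(n)
  out_pos <- integer(n)
  if (n_fg > 0L) {
    pick <- sample(slots, n_fg, replace = TRUE, prob = slot_w)
    g <- (pick - 1L) %% nrow(ann) + 1L
    wi <- (pick - 1L) %/% nrow(ann) + 1L
    lo <- bnd$lo[cbind(g, wi)]
    hi <- bnd$hi[cbind(g, wi)]
    out_pos[seq_len(n_fg)] <- lo + floor(runif(n_fg) * (hi - lo))
    out_chrom[seq_len(n_fg)] <- ann$chrom[g]
  }
  if (n_bg > 0L) {
    chroms <- sample(names(chrom_sizes), n_bg, replace = TRUE,
                     prob = as.numeric(chrom_sizes))
    out_chrom[n_fg + seq_len(n_bg)] <- chroms
    out_pos[n_fg + seq_len(n_bg)] <-
      floor(runif(n_bg) * as.numeric(chrom_sizes[chroms]))
  }
  gene <- rep(NA_integer_, n); win <- rep(NA_integer_, n)
  if (n_fg > 0L) { gene[seq_len(n_fg)] <- g; win[seq_len(n_fg)] <- wi }
  data.frame(chrom = out_chrom, pos = out_pos, gene = gene, window = win,
             stringsAsFactors = FALSE)
}

# genome-wide per-base new-histone fraction: window values from the truth
# matrix, 0.5 outside all TSS windows; later genes overwrite earlier ones in
# the rare case of overlapping window regions
.new_fraction_map <- function(truth, chrom_sizes) {
  ann <- truth$annotation
  spec <- truth$window_spec
  bnd <- .window_bounds(ann, spec)
  fmap <- lapply(names(chrom_sizes),
                 function(chrom) rep(0.5, chrom_sizes[[chrom]]))
  names(fmap) <- names(chrom_sizes)
  for (g in seq_len(nrow(ann))) {
    chrom <- ann$chrom[g]
    len <- chrom_sizes[[chrom]]
    for (i in seq_len(spec$n_windows)) {
      lo <- max(bnd$lo[g, i], 0L); hi <- min(bnd$hi[g, i], len)
      if (lo < hi) fmap[[chrom]][(lo + 1L):hi] <- truth$new_fraction[g, i]
    }
  }
  fmap
}

# mapq mix: mostly unique alignments, a tail below the q13 filter
.sample_mapq <- function(n) {
  sample(c(60L, 30L, 3L), n, replace = TRUE, prob = c(0.9, 0.05, 0.05))
}

#' Simulate mononucleosome fragments with planted occupancy changes
#'
#' Dyad centres are drawn from the canonical occupancy profile (WT) or from
#' the profile multiplied by `2^occupancy_delta` (mutant), plus a uniform
#' genomic background.  Each fragment is 148 bp; records carry the 5'
#' position of a random strand so that [extend_and_pile()] with
#' `extension = 148` reconstructs the fragment.
#'
#' @param annotation gene annotation data.frame.
#' @param truth a [synthetic_truth()].
#' @param chrom_sizes named integer vector.
#' @param n_fragments number of fragments (> 0).
#' @param condition `"WT"` or `"mutant"`.
#' @param seed integer RNG seed.
#' @param background fraction of background (non-positioned) fragments.
#' @return alignment record data.frame.
#' @export
simulate_mnase_fragments <- function(annotation, truth, chrom_sizes,
                                     n_fragments, condition = c("WT", "mutant"),
                                     seed = 1L, background = 0.1) {
  condition <- match.arg(condition)
  check_scalar_number(n_fragments, "n_fragments", lower = 1)
  stopifnot(inherits(truth, "synthetic_truth"))
  n_fragments <- as.integer(n_fragments)
  spec <- truth$window_spec
  base <- matrix(rep(baseline_occupancy_profile(spec), each = nrow(annotation)),
                 nrow(annotation), spec$n_windows)
  weights <- if (condition == "WT") base else base * 2^truth$occupancy_delta
  half <- 74L  # fragments are 148 bp around the dyad
  with_seed(seed, {
    dyads <- .sample_window_positions(truth, chrom_sizes, n_fragments,
                                      weights, background)
    strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
    len <- as.numeric(chrom_sizes[dyads$chrom])
    start <- ifelse(strand == "+", dyads$pos - half, dyads$pos + half - 1L)
    start <- pmin(pmax(start, 0L), len - 1L)
    data.frame(chrom = dyads$chrom, start = as.integer(start), strand = strand,
               mapq = .sample_mapq(n_fragments),
               read_id = sprintf("mnase_%s_%07d", condition, seq_len(n_fragments)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a two-species spike-in ChIP/input read pair
#'
#' The input library mixes target and reference chromatin at
#' `mixing_ratio : 1`.  In the ChIP library the target pull-down is scaled
#' by the condition's true global signal level `scaling_factor` while the
#' reference pull-down is constant, so read-depth (RPM) normalization of the
#' target coverage alone cannot see the global change but the calibration
#' factor recovers it.  A fraction `orthologous_fraction` of reads is
#' pre-labelled `orthologous` (they would align to both genomes) and is
#' excluded from calibration tallies downstream.
#'
#' @param annotation gene annotation data.frame (target genome).
#' @param truth a [synthetic_truth()] (fields `scaling_factor`,
#'   `mixing_ratio`, `orthologous_fraction`).
#' @param chrom_sizes target genome chromosome sizes.
#' @param n_reads_chip,n_reads_input library sizes.
#' @param seed integer RNG seed.
#' @param ref_chrom,ref_length name and length of the single reference
#'   genome chromosome.
#' @return list with `chip` and `input` alignment record data.frames, each
#'   with a `species` column.
#' @export
simulate_spikein_chip <- function(annotation, truth, chrom_sizes,
                                  n_reads_chip = 1e5, n_reads_input = 1e5,
                                  seed = 1L, ref_chrom = "refI",
                                  ref_length = 5e4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_scalar_number(n_reads_chip, "n_reads_chip", lower = 1)
  check_scalar_number(n_reads_input, "n_reads_input", lower = 1)
  m <- truth$mixing_ratio
  s <- truth$scaling_factor
  o <- truth$orthologous_fraction
  spec <- truth$window_spec
  base <- matrix(rep(baseline_occupancy_profile(spec), each = nrow(annotation)),
                 nrow(annotation), spec$n_windows)
  make_lib <- function(n_reads, p_target, shaped, prefix) {
    n_reads <- as.integer(n_reads)
    is_target <- runif(n_reads) < p_target
    n_t <- sum(is_target)
    species <- ifelse(is_target, "target", "reference")
    species[runif(n_reads) < o] <- "orthologous"
    chrom <- character(n_reads); pos <- integer(n_reads)
    # orthologous reads are placed on the target genome; they are excluded
    # from every tally so their position is irrelevant
    tgt <- is_target | species == "orthologous"
    n_tgt <- sum(tgt)
    if (n_tgt) {
      if (shaped) {
        smp <- .sample_window_positions(truth, chrom_sizes, n_tgt, base,
                                        background = 0.2)
        chrom[tgt] <- smp$chrom; pos[tgt] <- smp$pos
      } else {
        ch <- sample(names(chrom_sizes), n_tgt, replace = TRUE,
                     prob = as.numeric(chrom_sizes))
        chrom[tgt] <- ch
        pos[tgt] <- floor(runif(n_tgt) * as.numeric(chrom_sizes[ch]))
      }
    }
    n_ref <- n_reads - n_tgt
    if (n_ref) {
      chrom[!tgt] <- ref_chrom
      pos[!tgt] <- floor(runif(n_ref) * ref_length)
    }
    data.frame(chrom = chrom, start = pos,
               strand = sample(c("+", "-"), n_reads, replace = TRUE),
               mapq = .sample_mapq(n_reads),
               species = species,
               read_id = sprintf("%s_%07d", prefix, seq_len(n_reads)),
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    chip <- make_lib(n_reads_chip, p_target = m * s / (m * s + 1),
                     shaped = TRUE, prefix = "chip")
    input <- make_lib(n_reads_input, p_target = m / (m + 1),
                      shaped = FALSE, prefix = "input")
    list(chip = chip, input = input)
  })
}

#' Simulate barcoded RITE / ChIP-nexus reads with planted duplicates
#'
#' Read 5' positions follow the canonical occupancy profile; each read is
#' tagged Flag (new histone) with the window's planted new-histone fraction
#' f, else V5 (old histone), so the expected Flag:V5 ratio per window is
#' f / (1 - f).  Each read's raw sequence carries a 6 bp random barcode and
#' a 4 bp fixed barcode in front of the insert.  A `dup_rate` fraction of
#' the reads are exact coordinate-and-barcode copies of another read,
#' recorded in the truth table; distinct reads are guaranteed to differ in
#' (chrom, strand, position, barcode), so barcode-aware deduplication must
#' remove exactly the planted copies.
#'
#' @param annotation gene annotation data.frame.
#' @param truth a [synthetic_truth()].
#' @param chrom_sizes named integer vector.
#' @param n_reads total reads including duplicates.
#' @param dup_rate fraction of reads that are planted duplicates, in [0, 1).
#' @param seed integer RNG seed.
#' @param fixed_barcode the 4-base fixed barcode sequence.
#' @param background fraction of background reads (new fraction 0.5).
#' @return list with `fastq` (raw reads), `alignments` (records with
#'   `barcode` and `tag` columns) and `truth` (per-read table incl.
#'   `is_duplicate` and `dup_group`, plus `n_duplicates`).
#' @export
simulate_rite_reads <- function(annotation, truth, chrom_sizes, n_reads,
                                dup_rate = 0, seed = 1L,
                                fixed_barcode = "CTGA", background = 0.1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_scalar_number(n_reads, "n_reads", lower = 1)
  check_fraction(dup_rate, "dup_rate")
  if (dup_rate >= 1) cq_stop("dup_rate must be < 1")
  if (!is.character(fixed_barcode) || length(fixed_barcode) != 1L ||
      nchar(fixed_barcode) != 4L || !grepl("^[ACGT]+$", fixed_barcode)) {
    cq_stop("fixed_barcode must be a 4-base string over A/C/G/T")
  }
  n_reads <- as.integer(n_reads)
  spec <- truth$window_spec
  base <- matrix(rep(baseline_occupancy_profile(spec), each = nrow(annotation)),
                 nrow(annotation), spec$n_windows)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    n_dup <- as.integer(round(n_reads * dup_rate))
    n_unique <- n_reads - n_dup
    smp <- .sample_window_positions(truth, chrom_sizes, n_unique, base,
                                    background)
    strand <- sample(c("+", "-"), n_unique, replace = TRUE)
    # the new-histone fraction is a property of the locus: look it up from
    # the window containing the read position (0.5 outside all windows)
    fmap <- .new_fraction_map(truth, chrom_sizes)
    f <- vapply(seq_len(n_unique), function(i) {
      fmap[[smp$chrom[i]]][smp$pos[i] + 1L]
    }, numeric(1))
    tag <- ifelse(runif(n_unique) < f, "Flag", "V5")
    barcode <- vapply(seq_len(n_unique), function(i) {
      paste(sample(bases, 6L, replace = TRUE), collapse = "")
    }, character(1))
    # guarantee distinct (chrom, strand, pos, barcode) for non-duplicates
    key <- paste(smp$chrom, strand, smp$pos, barcode)
    while (anyDuplicated(key)) {
      clash <- which(duplicated(key))
      barcode[clash] <- vapply(clash, function(i) {
        paste(sample(bases, 6L, replace = TRUE), collapse = "")
      }, character(1))
      key <- paste(smp$chrom, strand, smp$pos, barcode)
    }
    src <- if (n_dup > 0L) sample.int(n_unique, n_dup, replace = TRUE) else integer()
    idx <- c(seq_len(n_unique), src)
    is_dup <- c(rep(FALSE, n_unique), rep(TRUE, n_dup))
    mapq <- .sample_mapq(n_reads)
    # a duplicate never outranks its source, so the source is the survivor
    if (n_dup > 0L) mapq[n_unique + seq_len(n_dup)] <- pmin(
      mapq[n_unique + seq_len(n_dup)], mapq[src])
    read_id <- sprintf("rite_%07d", seq_len(n_reads))
    aln <- data.frame(chrom = smp$chrom[idx], start = smp$pos[idx],
                      strand = strand[idx], mapq = mapq,
                      barcode = barcode[idx], tag = tag[idx],
                      read_id = read_id, stringsAsFactors = FALSE)
    insert <- vapply(seq_len(n_reads), function(i) {
      paste(sample(bases, 40L, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- paste0(aln$barcode, fixed_barcode, insert)
    fastq <- data.frame(read_id = read_id, sequence = seqs,
                        quality = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    truth_tab <- data.frame(read_id = read_id, chrom = aln$chrom,
                            start = aln$start, strand = aln$strand,
                            barcode = aln$barcode, tag = aln$tag,
                            is_duplicate = is_dup,
                            dup_group = c(seq_len(n_unique), src),
                            stringsAsFactors = FALSE)
    list(fastq = fastq, alignments = aln,
         truth = list(reads = truth_tab, n_duplicates = n_dup,
                      seed = as.integer(seed)))
  })
}

#' Simulate stranded negative-binomial count matrices
#'
#' Gene-level sense and antisense counts for WT and mutant, drawn
#' negative-binomial with a common `dispersion` and mild library-size
#' variation.  Sense baseline means follow the gene's transcription-rate
#' class (10 / 40 / 120 / 400 / 1200 expected counts for the five classes,
#' with log-normal jitter); antisense means are low (median 5) and
#' rate-independent.
#' Genes in `truth$de_table` get their mutant mean multiplied by
#' `2^log2fc` on the stated strand class; all other genes share means
#' across conditions.
#'
#' @param annotation gene annotation data.frame.
#' @param truth a [synthetic_truth()] (field `de_table`).
#' @param n_replicates replicates per condition (>= 2).
#' @param dispersion NB dispersion alpha (> 0; variance mu + alpha mu^2).
#' @param seed integer RNG seed.
#' @return nested list `sense`/`antisense`, each with `wt` and `mut`
#'   genes x replicates integer matrices.
#' @export
simulate_stranded_counts <- function(annotation, truth, n_replicates = 3L,
                                     dispersion = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_scalar_number(n_replicates, "n_replicates", lower = 2)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0) {
    cq_stop("dispersion must be a positive number")
  }
  n_replicates <- as.integer(n_replicates)
  ann <- annotation
  n <- nrow(ann)
  size <- 1 / dispersion
  rate_mu <- c("<1" = 10, "1-3.9" = 40, "4-15.9" = 120,
               "16-50" = 400, ">50" = 1200)
  mu0 <- if ("rate_class" %in% names(ann)) {
    unname(rate_mu[ann$rate_class])
  } else rep(100, n)
  mu0[is.na(mu0)] <- 100
  with_seed(seed, {
    base_sense <- mu0 * exp(rnorm(n, 0, 0.3))
    base_anti <- exp(rnorm(n, log(5), 1))
    lfc <- function(strand_class) {
      out <- numeric(n)
      de <- truth$de_table
      if (!is.null(de)) {
        de <- de[de$strand_class == strand_class, , drop = FALSE]
        out[match(de$gene_id, ann$gene_id)] <- de$log2fc
      }
      out
    }
    depth <- function() exp(rnorm(n_replicates, 0, 0.1))
    draw <- function(mu, cond) {
      d <- depth()
      m <- vapply(seq_len(n_replicates), function(j) {
        rnbinom(n, size = size, mu = mu * d[j])
      }, numeric(n))
      dimnames(m) <- list(ann$gene_id, paste0(cond, "_", seq_len(n_replicates)))
      m
    }
    list(
      sense = list(wt = draw(base_sense, "WT"),
                   mut = draw(base_sense * 2^lfc("sense"), "mut")),
      antisense = list(wt = draw(base_anti, "WT"),
                       mut = draw(base_anti * 2^lfc("antisense"), "mut"))
    )
  })
}
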