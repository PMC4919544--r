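# Reference-epigenome (spike-in) calibration of ChIP coverage.
#
# A defined quantity of a second species' chromatin (the reference
# epigenome) is mixed into every sample before immunoprecipitation.  Reads
# are then attributable to the target genome ("target"), the reference
# genome ("reference"), or both ("orthologous"; excluded from all tallies).
# The ratio of non-orthologous read counts defines a calibration factor that
# rescales read-depth-normalized coverage onto a common absolute scale,
# exposing global signal changes that per-library RPM normalization hides.

#' Calibration counts: the four non-orthologous read tallies
#'
#' @param chip_sc,chip_cg,input_sc,input_cg read counts for the ChIP and
#'   input libraries on the target (`sc`) and reference (`cg`) genomes,
#'   orthologous reads excluded.  All four must be positive.
#' @return an object of class `calibration_counts`.
#' @export
calibration_counts <- function(chip_sc, chip_cg, input_sc, input_cg) {
  counts <- c(chip_sc = as.numeric(chip_sc), chip_cg = as.numeric(chip_cg),
              input_sc = as.numeric(input_sc), input_cg = as.numeric(input_cg))
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    cq_stop("all four calibration counts must be positive (got %s)",
            paste(sprintf("%s=%g", names(counts), counts), collapse = ", "))
  }
  structure(as.list(counts), class = "calibration_counts")
}

#' Tally non-orthologous reads by species for a ChIP/input pair
#'
#' Every record must carry a `species` label in `target`, `reference` or
#' `orthologous`.  Orthologous reads (aligning to both genomes) are excluded
#' from both the target and the reference tally.
#'
#' @param chip_records,input_records alignment record data.frames with a
#'   `species` column.
#' @return a [calibration_counts()] object.
#' @export
partition_species <- function(chip_records, input_records) {
  tally <- function(records, role) {
    sp <- records$species
    if (is.null(sp) || anyNA(sp)) {
      cq_stop("%s records lack a species label", role)
    }
    bad <- setdiff(unique(sp), c("target", "reference", "orthologous"))
    if (length(bad)) cq_stop("unknown species label(s) in %s records: %s",
                             role, paste(bad, collapse = ", "))
    c(sum(sp == "target"), sum(sp == "reference"))
  }
  chip <- tally(chip_records, "ChIP")
  input <- tally(input_records, "input")
  calibration_counts(chip_sc = chip[1], chip_cg = chip[2],
                     input_sc = input[1], input_cg = input[2])
}

#' The spike-in calibration factor
#'
#' Computes `(input_cg * chip_sc) / (input_sc * chip_cg)`: the ChIP
#' target:reference alignment ratio divided by the input target:reference
#' ratio.  The input ratio fixes the mixing proportion of the two
#' epigenomes, so the factor isolates how efficiently target chromatin was
#' immunoprecipitated relative to the constant reference.  It is invariant
#' to multiplying all four counts by a constant (sequencing depth).
#'
#' @param counts a [calibration_counts()] object.
#' @return positive scalar calibration factor.
#' @export
calibration_factor <- function(counts) {
  stopifnot(inherits(counts, "calibration_counts"))
  (counts$input_cg * counts$chip_sc) / (counts$input_sc * counts$chip_cg)
}

#' Rescale an RPM track by a calibration factor
#'
#' @param track an rpm-normalized [coverage_track()].
#' @param factor positive calibration factor from [calibration_factor()].
#' @return the track with every bin multiplied by `factor` and
#'   `normalization = "calibrated"`.
#' @export
calibrate_track <- function(track, factor) {
  stopifnot(inherits(track, "coverage_track"))
  check_scalar_number(factor, "factor", lower = 0, strict_lower = TRUE)
  if (track$normalization != "rpm") {
    cq_stop("calibrate_track expects an rpm-normalized track (got %s)",
            track$normalization)
  }
  track$values <- lapply(track$values, function(v) v * factor)
  track$normalization <- "calibrated"
  track
}

#' Fold-enrichment track with zero substitution
#'
#' Per-bin ratio chip / control after replacing zero bins in either track by
#' 1, a value well below the genomic mean, so the ratio is always defined.
#'
#' @param chip,control [coverage_track()]s with identical bins.
#' @return a `coverage_track` of per-bin fold enrichment.
#' @export
fold_enrichment <- function(chip, control) {
  stopifnot(inherits(chip, "coverage_track"), inherits(control, "coverage_track"))
  if (!same_bins(chip, control)) cq_stop("tracks have mismatched chromosomes/bins")
  out <- chip
  out$values <- Map(function(num, den) {
    num[num == 0] <- 1
    den[den == 0] <- 1
    num / den
  }, chip$values, control$values)
  out$total_reads <- NA_real_
  out
}

#' Bidirectional Poisson q-value signal
#'
#' For each bin, tests the observed ChIP count against a Poisson expectation
#' `lambda` from the control in both directions: enrichment
#' (upper tail, `P(X >= obs)`) and depletion (lower tail, `P(X <= obs)`).
#' Each direction's p-values are converted to q-values by Benjamini-Hochberg
#' over all bins, and per bin the direction with the larger `-log10(q)` is
#' reported (ties break to `enriched`).
#'
#' @param chip_counts non-negative integer ChIP counts per bin.
#' @param lambda_control positive Poisson expectations per bin (control
#'   signal scaled to the ChIP depth, zero-substituted upstream).
#' @return data.frame with `p_enriched`, `p_depleted`, `q_enriched`,
#'   `q_depleted`, `neglog10_q`, `direction`.
#' @export
bidirectional_q <- function(chip_counts, lambda_control) {
  if (length(chip_counts) != length(lambda_control)) {
    cq_stop("chip_counts and lambda_control differ in length")
  }
  if (any(chip_counts < 0)) cq_stop("negative counts are not allowed")
  if (any(lambda_control <= 0)) {
    cq_stop("lambda_control must be positive everywhere (apply zero substitution first)")
  }
  p_enr <- ppois(chip_counts - 1, lambda_control, lower.tail = FALSE)
  p_dep <- ppois(chip_counts, lambda_control, lower.tail = TRUE)
  q_enr <- p.adjust(p_enr, method = "BH")
  q_dep <- p.adjust(p_dep, method = "BH")
  enriched <- q_enr <= q_dep   # ties -> enriched
  data.frame(
    p_enriched = p_enr, p_depleted = p_dep,
    q_enriched = q_enr, q_depleted = q_dep,
    neglog10_q = -log10(ifelse(enriched, q_enr, q_dep)),
    direction = ifelse(enriched, "enriched", "depleted"),
    stringsAsFactors = FALSE
  )
}
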