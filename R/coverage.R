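# Coverage tracks: fragment extension and pile-up, read-depth normalization,
# difference maps and replicate correlation.
#
# Alignment records are data.frames in the package's BED-derived dialect:
# columns `chrom`, `start` (0-based 5' position of the read: leftmost base for
# `+` reads, rightmost base for `-` reads), `strand`, `mapq`, and optionally
# `species`, `barcode`, `read_id`.

#' Construct a coverage track
#'
#' A coverage track holds one numeric vector per chromosome (per-base when
#' `bin_size = 1`, otherwise per-bin averages; the last bin may cover fewer
#' bases), together with its normalization state (`"raw"`, `"rpm"` or
#' `"calibrated"`) and the number of reads it was built from.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param bin_size bin width in bp; 1 means per-base.
#' @param normalization one of `"raw"`, `"rpm"`, `"calibrated"`.
#' @param total_reads number of reads the track was piled from.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(values, chrom_sizes, bin_size = 1L,
                           normalization = "raw", total_reads = 0L) {
  if (!is.list(values) || is.null(names(values))) {
    cq_stop("`values` must be a named list of numeric vectors")
  }
  normalization <- match.arg(normalization, c("raw", "rpm", "calibrated"))
  check_scalar_number(bin_size, "bin_size", lower = 1)
  for (chrom in names(values)) {
    if (!chrom %in% names(chrom_sizes)) {
      cq_stop("chromosome '%s' missing from chrom_sizes", chrom)
    }
    expect_len <- ceiling(chrom_sizes[[chrom]] / bin_size)
    if (length(values[[chrom]]) != expect_len) {
      cq_stop("track vector for '%s' has length %d, expected %d",
              chrom, length(values[[chrom]]), expect_len)
    }
  }
  structure(list(values = values,
                 chrom_sizes = chrom_sizes[names(values)],
                 bin_size = as.integer(bin_size),
                 normalization = normalization,
                 total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), bin_size=%d, %s, %g reads\n",
              length(x$values), x$bin_size, x$normalization, x$total_reads))
  invisible(x)
}

# all bin values of a track as one numeric vector (chromosome order preserved)
track_values <- function(track) unlist(track$values, use.names = FALSE)

same_bins <- function(a, b) {
  identical(names(a$values), names(b$values)) &&
    a$bin_size == b$bin_size &&
    all(lengths(a$values) == lengths(b$values))
}

#' Filter alignment records on mapping quality
#'
#' Keeps exactly the records with `mapq >= min_mapq` (the default 13 is the
#' conventional novoalign/MAQ threshold for confidently mapped reads), in
#' their original order.
#'
#' @param records alignment record data.frame with a `mapq` column.
#' @param min_mapq minimum mapping quality to keep (inclusive).
#' @return the filtered data.frame.
#' @export
mapq_filter <- function(records, min_mapq = 13) {
  check_scalar_number(min_mapq, "min_mapq", lower = 0)
  if (!"mapq" %in% names(records)) cq_stop("records lack a `mapq` column")
  records[records$mapq >= min_mapq, , drop = FALSE]
}

#' Extend reads to fragments and pile up coverage
#'
#' Each read is extended to `extension` bp in its 3' direction from its 5'
#' position: a `+` read at 5' position s covers `[s, s + extension)`, a `-`
#' read covers `(s - extension, s]`.  Fragments are clipped at chromosome
#' edges.  Per-base coverage is the number of extended fragments overlapping
#' each base; with `bin_size > 1` bases are averaged within bins.
#'
#' @param records alignment record data.frame (`chrom`, `start`, `strand`).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param extension fragment length in bp (148 for mononucleosomes, 200 for
#'   standard ChIP).
#' @param bin_size bin width in bp.
#' @return a `raw` [coverage_track()] with `total_reads = nrow(records)`.
#' @export
extend_and_pile <- function(records, chrom_sizes, extension, bin_size = 1L) {
  check_scalar_number(extension, "extension", lower = 1)
  check_scalar_number(bin_size, "bin_size", lower = 1)
  extension <- as.integer(extension)
  bad_chrom <- setdiff(unique(records$chrom), names(chrom_sizes))
  if (length(bad_chrom)) {
    cq_stop("record(s) on unknown chromosome(s): %s",
            paste(bad_chrom, collapse = ", "))
  }
  values <- vector("list", length(chrom_sizes))
  names(values) <- names(chrom_sizes)
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    idx <- which(records$chrom == chrom)
    if (length(idx)) {
      s <- records$start[idx]
      out <- s < 0 | s >= len
      if (any(out)) {
        i <- idx[which(out)[1]]
        id <- if ("read_id" %in% names(records)) records$read_id[i] else
          sprintf("row %d", i)
        cq_stop("record %s at %s:%d lies outside chromosome bounds [0,%d)",
                id, chrom, records$start[i], len)
      }
      plus <- records$strand[idx] == "+"
      frag_start <- ifelse(plus, s, s - extension + 1L)
      frag_end <- ifelse(plus, s + extension, s + 1L)       # half-open
      frag_start <- pmax(frag_start, 0L)
      frag_end <- pmin(frag_end, len)
      d <- numeric(len + 1L)
      tab_s <- tabulate(frag_start + 1L, nbins = len)
      tab_e <- tabulate(frag_end + 1L, nbins = len + 1L)
      d[seq_len(len)] <- tab_s
      d <- d - tab_e
      cov <- cumsum(d[seq_len(len)])
    } else {
      cov <- numeric(len)
    }
    if (bin_size > 1L) {
      grp <- (seq_len(len) - 1L) %/% as.integer(bin_size)
      sums <- rowsum(cov, grp)
      counts <- tabulate(grp + 1L)
      cov <- as.numeric(sums / counts)
    }
    values[[chrom]] <- cov
  }
  coverage_track(values, chrom_sizes, bin_size = bin_size,
                 normalization = "raw", total_reads = nrow(records))
}

#' Normalize a coverage track to reads per million
#'
#' Scales every bin by `1e6 / total_reads` so tracks from libraries of
#' different depth are comparable.
#'
#' @param track a raw [coverage_track()].
#' @return the track with `normalization = "rpm"`.
#' @export
rpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(track$total_reads) || track$total_reads <= 0) {
    cq_stop("cannot RPM-normalize a track with total_reads = 0")
  }
  f <- 1e6 / track$total_reads
  track$values <- lapply(track$values, function(v) v * f)
  track$normalization <- "rpm"
  track
}

#' Subtract a wild-type track from a mutant track
#'
#' Produces the signed difference map (mutant minus WT) used to visualize
#' gains and losses of nucleosome occupancy.  Both tracks must share bins and
#' a depth-comparable normalization (`rpm` or `calibrated`).
#'
#' @param mutant,wt [coverage_track()]s with identical bins.
#' @return a signed `coverage_track` of per-bin differences.
#' @export
difference_track <- function(mutant, wt) {
  stopifnot(inherits(mutant, "coverage_track"), inherits(wt, "coverage_track"))
  if (!same_bins(mutant, wt)) cq_stop("tracks have mismatched chromosomes/bins")
  if (mutant$normalization != wt$normalization) {
    cq_stop("tracks have different normalization (%s vs %s)",
            mutant$normalization, wt$normalization)
  }
  if (mutant$normalization == "raw") {
    cq_stop("difference maps require depth-normalized (rpm/calibrated) tracks")
  }
  out <- mutant
  out$values <- Map(`-`, mutant$values, wt$values)
  out$total_reads <- NA_real_
  out
}

#' Pearson correlation between two replicate tracks
#'
#' Used to decide whether biological replicates are similar enough to merge;
#' the conventional threshold (not enforced here) is r >= 0.8.
#'
#' @param a,b [coverage_track()]s with identical bins.
#' @return Pearson r over all bins.
#' @export
replicate_pearson <- function(a, b) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"))
  if (!same_bins(a, b)) cq_stop("tracks have mismatched chromosomes/bins")
  va <- track_values(a)
  vb <- track_values(b)
  if (length(va) < 2L) cq_stop("need at least 2 bins")
  if (sd(va) == 0 || sd(vb) == 0) {
    cq_stop("Pearson r undefined: a track has zero variance")
  }
  cor(va, vb, method = "pearson")
}
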