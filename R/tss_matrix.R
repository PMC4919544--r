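# TSS-relative window matrices: signal mapped into fixed windows around each
# gene's transcription start site, oriented so that window 1 is always the
# most upstream regardless of strand, with windows overlapping neighbouring
# genes masked out.

#' Window specification for TSS-relative matrices
#'
#' Defines `2 * span / width` half-open windows covering `[-span, +span)`
#' around the TSS in gene orientation.  The defaults (span 800 bp, width
#' 20 bp) give exactly 80 windows.
#'
#' @param span half-width of the region around the TSS, in bp.
#' @param width window width in bp; must divide `span`.
#' @return a `window_spec` list with `span`, `width`, `n_windows`.
#' @export
window_spec <- function(span = 800L, width = 20L) {
  check_scalar_number(span, "span", lower = 1)
  check_scalar_number(width, "width", lower = 1)
  if (span %% width != 0) cq_stop("span (%d) must be divisible by width (%d)",
                                  span, width)
  structure(list(span = as.integer(span), width = as.integer(width),
                 n_windows = as.integer(2L * span / width)),
            class = "window_spec")
}

# oriented window midpoints, used as column labels (-790 ... +790 at defaults)
window_midpoints <- function(spec) {
  -spec$span + (seq_len(spec$n_windows) - 1L) * spec$width + spec$width / 2
}

#' Construct a TSS matrix object
#'
#' @param values genes x windows numeric matrix; masked cells are NA.
#' @param mask logical matrix, TRUE where the window is excluded.
#' @param spec the [window_spec()] the matrix was computed under.
#' @return an object of class `tss_matrix`.
#' @export
tss_matrix <- function(values, mask, spec) {
  stopifnot(is.matrix(values), is.matrix(mask),
            all(dim(values) == dim(mask)), inherits(spec, "window_spec"))
  if (ncol(values) != spec$n_windows) {
    cq_stop("matrix has %d columns but the window spec defines %d windows",
            ncol(values), spec$n_windows)
  }
  values[mask] <- NA_real_
  colnames(values) <- colnames(mask) <- as.character(window_midpoints(spec))
  structure(list(gene_ids = rownames(values), values = values, mask = mask,
                 window_spec = spec),
            class = "tss_matrix")
}

#' @export
print.tss_matrix <- function(x, ...) {
  cat(sprintf("<tss_matrix> %d genes x %d windows (width %d bp), %.1f%% masked\n",
              nrow(x$values), ncol(x$values), x$window_spec$width,
              100 * mean(x$mask)))
  invisible(x)
}

congruent_tss_matrices <- function(a, b) {
  identical(a$gene_ids, b$gene_ids) &&
    identical(unclass(a$window_spec), unclass(b$window_spec)) &&
    identical(a$mask, b$mask)
}

# per-chromosome cumulative sums used for O(1) interval means/sums
.track_cumsums <- function(track) {
  lapply(track$values, function(v) {
    if (track$bin_size > 1L) v <- rep(v, each = track$bin_size)
    cumsum(as.numeric(v))
  })
}

# genomic half-open window boundaries for every (gene, window) pair, oriented:
# window i covers offsets [-span + (i-1)w, -span + i*w) in gene direction
.window_bounds <- function(annotation, spec) {
  tss <- tss_positions(annotation)
  n <- nrow(annotation)
  w <- spec$width
  offs_lo <- -spec$span + (seq_len(spec$n_windows) - 1L) * w
  plus <- annotation$strand == "+"
  lo <- matrix(NA_integer_, n, spec$n_windows)
  hi <- matrix(NA_integer_, n, spec$n_windows)
  for (i in seq_len(spec$n_windows)) {
    # + strand: [TSS + off, TSS + off + w) ; - strand mirrored around the TSS
    lo[plus, i] <- tss[plus] + offs_lo[i]
    hi[plus, i] <- tss[plus] + offs_lo[i] + w
    lo[!plus, i] <- tss[!plus] - offs_lo[i] - w + 1L
    hi[!plus, i] <- tss[!plus] - offs_lo[i] + 1L
  }
  list(lo = lo, hi = hi)
}

#' Map a coverage track into TSS-relative windows
#'
#' For every gene the mean coverage is computed in `n_windows` half-open
#' windows spanning `[-span, +span)` around its TSS, oriented along the gene
#' (window 1 is always the most upstream window).  A window is masked when it
#' overlaps any base of a different gene's body, or when it extends beyond
#' the chromosome ends.
#'
#' @param track a [coverage_track()]; per-base, or binned with `bin_size`
#'   dividing the window width.
#' @param annotation gene annotation data.frame.
#' @param spec a [window_spec()].
#' @return a [tss_matrix()] with one row per annotated gene.
#' @export
tss_window_matrix <- function(track, annotation, spec = window_spec()) {
  stopifnot(inherits(track, "coverage_track"))
  validate_annotation(annotation)
  if (track$bin_size > 1L && spec$width %% track$bin_size != 0) {
    cq_stop("track bin_size (%d) must divide window width (%d)",
            track$bin_size, spec$width)
  }
  n <- nrow(annotation)
  cums <- .track_cumsums(track)
  bnd <- .window_bounds(annotation, spec)
  values <- matrix(NA_real_, n, spec$n_windows)
  mask <- matrix(TRUE, n, spec$n_windows)
  rownames(values) <- rownames(mask) <- annotation$gene_id

  # per-chromosome cumulative gene-body base counts (with multiplicity), to
  # detect overlap of a window with any gene other than its anchor
  body_cum <- list()
  for (chrom in unique(annotation$chrom)) {
    len <- track$chrom_sizes[[chrom]]
    if (is.null(len)) cq_stop("annotation chromosome '%s' absent from track", chrom)
    d <- numeric(len + 1L)
    rows <- which(annotation$chrom == chrom)
    for (r in rows) {
      s <- max(annotation$start[r], 0L); e <- min(annotation$end[r], len)
      if (s < e) { d[s + 1L] <- d[s + 1L] + 1; d[e + 1L] <- d[e + 1L] - 1 }
    }
    body_cum[[chrom]] <- cumsum(cumsum(d[seq_len(len)]))  # cum of per-base counts
  }

  interval_sum <- function(cum, lo, hi) {
    # sum over 0-based half-open [lo, hi) of the per-base vector behind `cum`
    (if (hi >= 1L) cum[hi] else 0) - (if (lo >= 1L) cum[lo] else 0)
  }

  for (g in seq_len(n)) {
    chrom <- annotation$chrom[g]
    len <- track$chrom_sizes[[chrom]]
    cum <- cums[[chrom]]
    bcum <- body_cum[[chrom]]
    gs <- annotation$start[g]; ge <- annotation$end[g]
    for (i in seq_len(spec$n_windows)) {
      lo <- bnd$lo[g, i]; hi <- bnd$hi[g, i]
      if (lo < 0L || hi > len) next                      # off-edge: stays masked
      own <- max(0L, min(hi, ge) - max(lo, gs))          # overlap with anchor body
      other <- interval_sum(bcum, lo, hi) - own
      if (other > 0) next                                # neighbouring gene: masked
      mask[g, i] <- FALSE
      values[g, i] <- interval_sum(cum, lo, hi) / (hi - lo)
    }
  }
  tss_matrix(values, mask, spec)
}

#' Mean signal profile over a gene set
#'
#' Per-window arithmetic mean across the given genes, ignoring masked cells;
#' windows masked in every selected gene come back as NA.
#'
#' @param matrix a [tss_matrix()].
#' @param gene_set character vector of gene ids (subset of the matrix rows).
#' @return numeric vector of length `n_windows`, named by window midpoint.
#' @export
mean_profile <- function(matrix, gene_set = matrix$gene_ids) {
  stopifnot(inherits(matrix, "tss_matrix"))
  if (length(gene_set) == 0L) cq_stop("gene_set is empty")
  missing <- setdiff(gene_set, matrix$gene_ids)
  if (length(missing)) cq_stop("gene(s) not in matrix: %s",
                               paste(head(missing, 5), collapse = ", "))
  sub <- matrix$values[match(gene_set, matrix$gene_ids), , drop = FALSE]
  out <- colMeans(sub, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Write a TSS matrix as TSV (gene ids as row labels, window midpoints as
#' column labels)
#'
#' @param matrix a [tss_matrix()].
#' @param file output path.
#' @export
write_tss_matrix <- function(matrix, file) {
  stopifnot(inherits(matrix, "tss_matrix"))
  dt <- data.table::as.data.table(matrix$values, keep.rownames = "gene_id")
  data.table::fwrite(dt, file, sep = "\t", na = "NA")
  invisible(file)
}
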