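# RITE histone-turnover statistics: new (Flag) vs old (V5) histone H3 ChIP
# signal in TSS-relative windows, and a repeated-measures test for
# WT-vs-mutant differences per gene group.

# per-base track of read 5'-position counts, optionally RPM-scaled
.five_prime_track <- function(records, chrom_sizes, rpm = TRUE) {
  values <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    s <- records$start[records$chrom == chrom]
    if (any(s < 0 | s >= len)) cq_stop("read 5' position outside chromosome '%s'", chrom)
    as.numeric(tabulate(s + 1L, nbins = len))
  })
  names(values) <- names(chrom_sizes)
  tr <- coverage_track(values, chrom_sizes, bin_size = 1L,
                       normalization = "raw", total_reads = nrow(records))
  if (rpm) rpm_normalize(tr) else tr
}

#' Per-window depth-normalized tag counts around TSSs
#'
#' Sums RPM-normalized read counts (each read assigned to the window
#' containing its 5' position) in TSS-relative windows for the new-histone
#' (Flag) and old-histone (V5) ChIP libraries, with the same
#' neighbouring-gene masking as [tss_window_matrix()].
#'
#' @param flag_records,v5_records mapq-filtered, deduplicated alignment
#'   record data.frames.
#' @param annotation gene annotation data.frame (non-empty).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param spec a [window_spec()].
#' @param depth `"common"` (default) scales both libraries by the combined
#'   read total, preserving the Flag:V5 odds the turnover ratio estimates
#'   (both tags are ChIPed from the same material); `"library"` scales each
#'   by its own total; `"raw"` leaves plain counts.
#' @return list with `flag` and `v5`, each a [tss_matrix()] of per-window
#'   RPM sums.
#' @export
window_tag_counts <- function(flag_records, v5_records, annotation,
                              chrom_sizes, spec = window_spec(),
                              depth = c("common", "library", "raw")) {
  depth <- match.arg(depth)
  validate_annotation(annotation)
  if (nrow(annotation) == 0L) cq_stop("annotation is empty")
  n_total <- nrow(flag_records) + nrow(v5_records)
  one <- function(records) {
    tr <- .five_prime_track(records, chrom_sizes, rpm = FALSE)
    if (depth != "raw") {
      tr$total_reads <- if (depth == "common") n_total else nrow(records)
      tr <- rpm_normalize(tr)
    }
    m <- tss_window_matrix(tr, annotation, spec)
    # window mean of a 5'-count track times window width = per-window sum
    m$values <- m$values * spec$width
    m
  }
  list(flag = one(flag_records), v5 = one(v5_records))
}

#' Per-window turnover ratio (new / old histone)
#'
#' Cell-wise `(flag + pseudocount) / (v5 + pseudocount)` over congruent
#' matrices.  For a region where a fraction `f` of histones are new, the
#' ratio estimates `f / (1 - f)`.  The pseudocount (default 1 normalized
#' count) keeps ratios finite in sparse windows.
#'
#' @param flag_matrix,v5_matrix congruent [tss_matrix()] objects (same
#'   genes, windows, masks) from [window_tag_counts()].
#' @param pseudocount positive value added to both numerator and denominator.
#' @return a [tss_matrix()] of ratios.
#' @export
turnover_ratio <- function(flag_matrix, v5_matrix, pseudocount = 1) {
  stopifnot(inherits(flag_matrix, "tss_matrix"), inherits(v5_matrix, "tss_matrix"))
  check_scalar_number(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  if (!congruent_tss_matrices(flag_matrix, v5_matrix)) {
    cq_stop("flag and v5 matrices are not congruent (genes/windows/masks differ)")
  }
  out <- flag_matrix
  out$values <- (flag_matrix$values + pseudocount) /
    (v5_matrix$values + pseudocount)
  out$values[out$mask] <- NA_real_
  out
}

#' Repeated-measures test for a turnover difference between conditions
#'
#' For each window the group-mean turnover is computed over `gene_group` in
#' both conditions; windows are then treated as matched subjects with
#' condition as the repeated factor.  With two conditions this reduces to
#' the paired t-test on the per-window differences d(w) = mutant - WT, and
#' F = t^2 on (1, W - 1) degrees of freedom, where W is the number of
#' windows with usable data in both conditions.
#'
#' @param wt_ratios,mut_ratios [tss_matrix()] ratio matrices for the two
#'   conditions (same window spec).
#' @param gene_group character vector of gene ids to aggregate over.
#' @return list with `F`, `p` (two-sided), `df`, `n_windows`, `mean_diff`.
#' @export
group_rm_anova <- function(wt_ratios, mut_ratios, gene_group) {
  if (length(gene_group) == 0L) cq_stop("gene_group is empty")
  m_wt <- mean_profile(wt_ratios, gene_group)
  m_mut <- mean_profile(mut_ratios, gene_group)
  d <- m_mut - m_wt
  d <- d[is.finite(d)]
  w <- length(d)
  if (w < 3L) cq_stop("need >= 3 windows with data in both conditions (got %d)", w)
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(F = 0, p = 1, df = c(1L, w - 1L),
                                 n_windows = w, mean_diff = 0))
    return(list(F = Inf, p = .Machine$double.xmin, df = c(1L, w - 1L),
                n_windows = w, mean_diff = mean(d)))
  }
  tstat <- mean(d) / (s / sqrt(w))
  Fstat <- tstat^2
  p <- pf(Fstat, 1, w - 1L, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(F = Fstat, p = p, df = c(1L, w - 1L), n_windows = w, mean_diff = mean(d))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    cq_stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Group-level turnover analysis table
#'
#' Runs [group_rm_anova()] for each named gene group and converts the
#' p-values to q-values across groups.
#'
#' @param wt_ratios,mut_ratios ratio matrices from [turnover_ratio()].
#' @param gene_groups named list of gene-id character vectors (for example
#'   all genes, co-up-regulated genes, Ribi genes).
#' @return data.frame with `group`, `F`, `p`, `q`, `n_genes`, `n_windows`.
#' @export
turnover_analysis <- function(wt_ratios, mut_ratios, gene_groups) {
  stopifnot(is.list(gene_groups), !is.null(names(gene_groups)))
  rows <- lapply(names(gene_groups), function(nm) {
    res <- group_rm_anova(wt_ratios, mut_ratios, gene_groups[[nm]])
    data.frame(group = nm, F = res$F, p = res$p,
               n_genes = length(gene_groups[[nm]]),
               n_windows = res$n_windows, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_qvalues(out$p)
  out[, c("group", "F", "p", "q", "n_genes", "n_windows")]
}
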