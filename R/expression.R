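# Strand-specific expression: sense/antisense counting, a documented
# negative-binomial differential-expression test, the threshold filter, and
# the 2^-ddCt qPCR fold change.

#' Strand-specific sense/antisense read counting
#'
#' Assigns each read (by its 5' position) to every gene body containing it
#' and classifies it as sense or antisense.  Under the dUTP-style
#' `"reverse"` orientation (the default) a read is sense for a gene when its
#' strand is opposite the gene's strand; `"forward"` inverts the convention.
#' Reads overlapping several genes count once for each (set
#' `multi = "exclusive"` to drop them instead).
#'
#' @param records alignment record data.frame with `chrom`, `start`,
#'   `strand`.
#' @param annotation gene annotation data.frame.
#' @param orientation `"reverse"` (dUTP) or `"forward"`.
#' @param multi `"all"` (count for every overlapped gene) or `"exclusive"`.
#' @return list with integer vectors `sense` and `antisense`, named by
#'   gene_id, plus `multi_gene_reads` (how many reads hit more than one
#'   gene).
#' @export
count_stranded <- function(records, annotation,
                           orientation = c("reverse", "forward"),
                           multi = c("all", "exclusive")) {
  orientation <- match.arg(orientation)
  multi <- match.arg(multi)
  validate_annotation(annotation)
  if (is.null(records$strand) || anyNA(records$strand) ||
      !all(records$strand %in% c("+", "-"))) {
    cq_stop("records must carry a '+'/'-' strand")
  }
  n_genes <- nrow(annotation)
  sense <- setNames(integer(n_genes), annotation$gene_id)
  antisense <- sense
  hits_per_read <- integer(nrow(records))
  hit_list <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    idx <- which(records$chrom == annotation$chrom[g] &
                   records$start >= annotation$start[g] &
                   records$start < annotation$end[g])
    hit_list[[g]] <- idx
    hits_per_read[idx] <- hits_per_read[idx] + 1L
  }
  for (g in seq_len(n_genes)) {
    idx <- hit_list[[g]]
    if (multi == "exclusive") idx <- idx[hits_per_read[idx] == 1L]
    if (!length(idx)) next
    opposite <- records$strand[idx] != annotation$strand[g]
    is_sense <- if (orientation == "reverse") opposite else !opposite
    sense[g] <- sum(is_sense)
    antisense[g] <- sum(!is_sense)
  }
  list(sense = sense, antisense = antisense,
       multi_gene_reads = sum(hits_per_read > 1L))
}

# DESeq-style median-of-ratios size factors over a combined count matrix
median_of_ratios <- function(counts) {
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) cq_stop("no gene has non-zero counts in every sample")
  apply(counts[usable, , drop = FALSE], 2L, function(k) {
    exp(median(log(k) - log_geo[usable]))
  })
}

#' Negative-binomial differential-expression test
#'
#' A documented replacement for a full DESeq analysis, keeping the parts the
#' thresholds depend on: median-of-ratios library normalization; per-gene
#' method-of-moments NB dispersion, shrunk toward a genome-wide common
#' dispersion with `prior_df` prior degrees of freedom; and a Wald test on
#' the log2 ratio of normalized condition means (pseudocount 0.5), referred
#' to a moderated t distribution with the pooled residual df plus
#' `prior_df` degrees of freedom, matching the information the dispersion
#' shrinkage adds.
#'
#' @param counts_wt,counts_mut integer matrices (genes x replicates) with
#'   identical rownames; at least 2 replicates each.
#' @param prior_df prior degrees of freedom for dispersion shrinkage.
#' @return data.frame with `gene_id`, `base_mean`, `log2fc`, `p`.
#' @export
nb_de_test <- function(counts_wt, counts_mut, prior_df = 50) {
  stopifnot(is.matrix(counts_wt), is.matrix(counts_mut),
            nrow(counts_wt) == nrow(counts_mut))
  n_wt <- ncol(counts_wt); n_mut <- ncol(counts_mut)
  if (n_wt < 2L || n_mut < 2L) cq_stop("need >= 2 replicates per condition")
  if (all(colSums(counts_wt) == 0) || all(colSums(counts_mut) == 0)) {
    cq_stop("a condition has all-zero libraries")
  }
  counts <- cbind(counts_wt, counts_mut)
  sf <- median_of_ratios(counts)
  sf_wt <- sf[seq_len(n_wt)]; sf_mut <- sf[n_wt + seq_len(n_mut)]
  q_wt <- sweep(counts_wt, 2L, sf_wt, "/")
  q_mut <- sweep(counts_mut, 2L, sf_mut, "/")
  mu_wt <- rowMeans(q_wt); mu_mut <- rowMeans(q_mut)
  xi_wt <- mean(1 / sf_wt); xi_mut <- mean(1 / sf_mut)

  # method-of-moments dispersion: Var(k/s) = mu/s + alpha mu^2
  var_wt <- apply(q_wt, 1L, var); var_mut <- apply(q_mut, 1L, var)
  df_wt <- n_wt - 1L; df_mut <- n_mut - 1L
  alpha_c <- function(v, mu, xi) ifelse(mu > 0, (v - mu * xi) / mu^2, NA_real_)
  a_raw <- (df_wt * alpha_c(var_wt, mu_wt, xi_wt) +
              df_mut * alpha_c(var_mut, mu_mut, xi_mut)) / (df_wt + df_mut)
  a_raw <- pmax(a_raw, 0)
  expressed <- mu_wt + mu_mut > 1
  # common dispersion by an unbiased ratio estimator: E[v - mu*xi] =
  # alpha*mu^2, so sum the numerators and denominators across genes (a
  # trimmed mean of per-gene MoM values is biased ~20% low at n = 3)
  num <- (df_wt * (var_wt - mu_wt * xi_wt) +
            df_mut * (var_mut - mu_mut * xi_mut))[expressed]
  den <- (df_wt * mu_wt^2 + df_mut * mu_mut^2)[expressed]
  a_prior <- if (length(den) && sum(den) > 0) {
    max(sum(num, na.rm = TRUE) / sum(den), 1e-8)
  } else 0.01
  d <- df_wt + df_mut
  alpha <- ifelse(is.finite(a_raw),
                  (d * a_raw + prior_df * a_prior) / (d + prior_df),
                  a_prior)

  pc <- 0.5
  lfc <- log2((mu_mut + pc) / (mu_wt + pc))
  # delta-method variance of log normalized means, NB sampling model
  v_ln <- function(mu, xi, n) (xi / pmax(mu, pc) + alpha) / n
  se_ln <- sqrt(v_ln(mu_wt, xi_wt, n_wt) + v_ln(mu_mut, xi_mut, n_mut))
  z <- (log(mu_mut + pc) - log(mu_wt + pc)) / se_ln
  # moderated reference: shrinkage adds prior_df effective df to the
  # residual df (plain t(d) is badly conservative, normal anti-conservative)
  p <- 2 * pt(-abs(z), df = d + prior_df)
  p[mu_wt + mu_mut == 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(gene_id = rownames(counts_wt) %||% as.character(seq_len(nrow(counts_wt))),
             base_mean = (mu_wt + mu_mut) / 2,
             log2fc = lfc, p = p, stringsAsFactors = FALSE)
}

#' Apply the differential-expression thresholds
#'
#' A gene is `up` when its FDR is strictly below `fdr_threshold` and its
#' log2 fold change is at least `lfc_threshold` (0.585, i.e. 1.5-fold);
#' `down` symmetrically with `log2fc <= -lfc_threshold`; otherwise `ns`.
#' FDR is computed by [bh_qvalues()] when not already present.
#'
#' @param results data.frame from [nb_de_test()] (columns `log2fc`, `p`,
#'   optionally `fdr`).
#' @param fdr_threshold FDR cutoff (exclusive).
#' @param lfc_threshold absolute log2 fold-change cutoff (inclusive).
#' @return the data.frame with `fdr` and `status` columns added.
#' @export
threshold_filter <- function(results, fdr_threshold = 0.05,
                             lfc_threshold = 0.585) {
  stopifnot(all(c("log2fc", "p") %in% names(results)))
  if (!"fdr" %in% names(results)) results$fdr <- bh_qvalues(results$p)
  up <- results$fdr < fdr_threshold & results$log2fc >= lfc_threshold
  down <- results$fdr < fdr_threshold & results$log2fc <= -lfc_threshold
  results$status <- ifelse(up, "up", ifelse(down, "down", "ns"))
  results
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each strain;
#' `ddCt = dCt_mutant - dCt_wt`; the fold change relative to WT is
#' `2^-ddCt`.
#'
#' @param ct_target_wt,ct_ref_wt,ct_target_mut,ct_ref_mut Ct values
#'   (cycles, > 0) for the target and reference transcript in each strain.
#' @return positive fold change of the target transcript in the mutant
#'   relative to WT.
#' @export
ddct_fold_change <- function(ct_target_wt, ct_ref_wt,
                             ct_target_mut, ct_ref_mut) {
  cts <- c(ct_target_wt = ct_target_wt, ct_ref_wt = ct_ref_wt,
           ct_target_mut = ct_target_mut, ct_ref_mut = ct_ref_mut)
  if (length(cts) != 4L || anyNA(cts) || any(!is.finite(cts)) || any(cts <= 0)) {
    cq_stop("all four Ct values must be present, finite and positive")
  }
  dct_wt <- ct_target_wt - ct_ref_wt
  dct_mut <- ct_target_mut - ct_ref_mut
  2^(-(dct_mut - dct_wt))
}
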