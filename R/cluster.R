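# k-means clustering of TSS-relative occupancy-change matrices and
# hypergeometric gene-set intersection statistics.

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance to the nearest chosen centre
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' Cluster genes by their TSS-relative signal profiles
#'
#' Euclidean k-means (k-means++ seeding, best of `n_init` restarts by total
#' within-cluster sum of squares) on the rows of a [tss_matrix()], as used
#' to sort occupancy-change maps into six categories.  Genes with more than
#' `max_masked` masked windows are dropped; remaining masked cells are
#' imputed with the gene's row mean.  Cluster labels are renumbered
#' deterministically by decreasing cluster size (ties by decreasing centroid
#' norm), so a fixed seed gives an identical assignment.
#'
#' @param delta_matrix a [tss_matrix()] (typically mutant-minus-WT
#'   occupancy) or a plain numeric matrix with gene ids as rownames.
#' @param k number of clusters (default 6).
#' @param seed integer RNG seed.
#' @param n_init number of k-means++ restarts (default 20).
#' @param max_masked maximum tolerated fraction of masked windows per gene.
#' @param standardize if TRUE, rows are z-scored before clustering (default
#'   FALSE: raw values, matching the visual semantics of the heat maps).
#' @return object of class `cluster_assignment`: list with `assignment`
#'   (named integer vector), `centroids` (k x n_windows), `withinss`,
#'   `dropped` (gene ids removed by the mask rule), `seed`, `n_init`.
#' @export
kmeans_clusters <- function(delta_matrix, k = 6L, seed = 1L, n_init = 20L,
                            max_masked = 0.5, standardize = FALSE) {
  check_scalar_number(k, "k", lower = 1)
  check_scalar_number(n_init, "n_init", lower = 1)
  if (inherits(delta_matrix, "tss_matrix")) {
    vals <- delta_matrix$values
    mask_frac <- rowMeans(delta_matrix$mask)
  } else {
    stopifnot(is.matrix(delta_matrix), !is.null(rownames(delta_matrix)))
    vals <- delta_matrix
    mask_frac <- rowMeans(is.na(vals))
  }
  keep <- mask_frac <= max_masked
  dropped <- rownames(vals)[!keep]
  x <- vals[keep, , drop = FALSE]
  # impute residual masked cells with the gene's own mean
  row_mean <- rowMeans(x, na.rm = TRUE)
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx)) x[na_idx] <- row_mean[na_idx[, 1L]]
  if (standardize) {
    s <- apply(x, 1L, sd)
    s[s == 0] <- 1
    x <- (x - rowMeans(x)) / s
  }
  if (nrow(x) < k) cq_stop("only %d usable genes for k = %d clusters", nrow(x), k)
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      centers <- .kmeanspp_centers(x, k)
      km <- suppressWarnings(kmeans(x, centers = centers, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  # deterministic renumbering: big clusters first, ties by centroid norm
  size <- fit$size
  norm <- sqrt(rowSums(fit$centers^2))
  new_order <- order(-size, -norm)
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k)
  assignment <- setNames(relabel[fit$cluster], rownames(x))
  centroids <- fit$centers[new_order, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(assignment = assignment, centroids = centroids,
                 withinss = fit$tot.withinss, dropped = dropped,
                 seed = seed, n_init = n_init, k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d genes in %d clusters (sizes %s), %d dropped\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment, x$k), collapse = "/"),
              length(x$dropped)))
  invisible(x)
}

#' Upper-tail hypergeometric intersection p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` are
#' annotated.
#'
#' @param N universe size.
#' @param K number of annotated genes in the universe.
#' @param n number of genes drawn (e.g. a cluster or DE set).
#' @param k observed overlap.
#' @return `P(X >= k)` under Hypergeometric(N, K, n).
#' @export
hypergeom_p <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || K > N || n > N || k > min(K, n) || k < max(0, n + K - N)) {
    cq_stop("inconsistent hypergeometric sizes (N=%g, K=%g, n=%g, k=%g)",
            N, K, n, k)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Intersect clusters with transcription-rate classes
#'
#' One upper-tail hypergeometric test per (cluster, rate class) pair.  The
#' universe is the set of clustered genes that carry a rate class; the rate
#' classes must partition that universe.
#'
#' @param clusters a `cluster_assignment` from [kmeans_clusters()].
#' @param annotation gene annotation data.frame with a `rate_class` column.
#' @return data.frame with `cluster`, `rate_class`, `cluster_size`,
#'   `class_size`, `overlap`, `p`.
#' @export
rate_class_table <- function(clusters, annotation) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  validate_annotation(annotation)
  if (!"rate_class" %in% names(annotation)) cq_stop("annotation lacks rate_class")
  rc <- setNames(annotation$rate_class, annotation$gene_id)
  genes <- names(clusters$assignment)
  genes <- genes[!is.na(rc[genes])]
  N <- length(genes)
  if (N == 0L) cq_stop("no clustered gene carries a rate class")
  cls <- rc[genes]
  memb <- clusters$assignment[genes]
  out <- expand.grid(cluster = seq_len(clusters$k),
                     rate_class = RATE_CLASSES,
                     stringsAsFactors = FALSE)
  out$cluster_size <- tabulate(memb, clusters$k)[out$cluster]
  out$class_size <- vapply(out$rate_class, function(cl) sum(cls == cl), 0L)
  out$overlap <- mapply(function(cu, cl) sum(memb == cu & cls == cl),
                        out$cluster, out$rate_class)
  out$p <- mapply(function(K, n, k) hypergeom_p(N, K, n, k),
                  out$class_size, out$cluster_size, out$overlap)
  out
}

#' Exact Venn partition of gene sets
#'
#' Set algebra over any number of named gene sets on a shared universe:
#' pairwise-disjoint membership regions, the common intersection, and the
#' genes unique to each set.
#'
#' @param sets named list of character vectors (e.g. up-regulated genes per
#'   strain).
#' @param universe optional character vector; every set must be a subset.
#' @return list with `regions` (named by membership pattern such as
#'   `"setA&setB"`), `common` (intersection of all sets) and `unique`
#'   (per-set exclusive genes).
#' @export
venn_sets <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 2L)
  sets <- lapply(sets, unique)
  if (!is.null(universe)) {
    for (nm in names(sets)) {
      out_of <- setdiff(sets[[nm]], universe)
      if (length(out_of)) cq_stop("set '%s' has %d gene(s) outside the universe",
                                  nm, length(out_of))
    }
  }
  all_genes <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  regions <- split(all_genes, pattern)
  common <- Reduce(intersect, sets)
  uniq <- lapply(names(sets), function(nm) {
    setdiff(sets[[nm]], unique(unlist(sets[setdiff(names(sets), nm)],
                                      use.names = FALSE)))
  })
  names(uniq) <- names(sets)
  list(regions = regions, common = common, unique = uniq)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments; 1 means identical
#' partitions, 0 the expectation under random labelling.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) cq_stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
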