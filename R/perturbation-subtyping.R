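#' Edge-perturbation subtyping of disease samples
#'
#' Bulk expression is reduced, per sample, to within-sample gene ranks;
#' each ligand-receptor edge becomes rank(ligand) - rank(receptor); the
#' same quantity on the mean normal expression ranking is the reference;
#' the perturbation matrix is the disease edge matrix minus the reference.
#' Disease samples are then partitioned by subsampled PAM consensus
#' clustering with K chosen from the relative change in area under the
#' consensus CDF.
#'
#' @name perturbation_subtyping
NULL

#' Within-sample rank transform
#'
#' Restricts the expression matrix to `gene_subset` and converts each
#' sample (column) to ranks 1..G, ascending, average ranks for ties.
#' Invariant to any strictly increasing per-sample transform.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param gene_subset genes to keep (default all); a requested gene
#'   missing from the matrix is an error naming it.
#' @return genes x samples matrix of ranks.
#' @export
rank_transform <- function(expr, gene_subset = rownames(expr)) {
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing))
    stopf("gene(s) missing from expression matrix: %s",
          paste(missing, collapse = ", "))
  x <- expr[gene_subset, , drop = FALSE]
  apply(x, 2, rank, ties.method = "average")
}

#' Ligand-receptor edge matrix
#'
#' `value(edge, sample) = rank(ligand) - rank(receptor)` within each
#' sample.
#'
#' @param ranks genes x samples rank matrix from [rank_transform()].
#' @param edges data.frame with columns `ligand`, `receptor` (single
#'   genes; expand complexes with [expand_pair_edges()] first).
#' @return edges x samples matrix, rownames `"ligand>receptor"`.
#' @export
edge_matrix <- function(ranks, edges) {
  missing <- setdiff(unique(c(edges$ligand, edges$receptor)),
                     rownames(ranks))
  if (length(missing))
    stopf("edge gene(s) missing from rank matrix: %s",
          paste(missing, collapse = ", "))
  out <- ranks[edges$ligand, , drop = FALSE] -
    ranks[edges$receptor, , drop = FALSE]
  rownames(out) <- paste(edges$ligand, edges$receptor, sep = ">")
  out
}

#' Normal-reference edge vector
#'
#' Genes are ranked by their mean expression across all normal samples;
#' edge values are computed on that single ranking.
#'
#' @param normal_expr genes x normal-samples matrix (>= 1 column).
#' @param edges as in [edge_matrix()].
#' @return Named numeric vector, one value per edge.
#' @export
reference_edges <- function(normal_expr, edges) {
  if (is.null(dim(normal_expr)) || ncol(normal_expr) == 0)
    stopf("need at least one normal sample")
  mean_expr <- matrix(rowMeans(normal_expr), ncol = 1,
                      dimnames = list(rownames(normal_expr), "ref"))
  drop(edge_matrix(rank_transform(mean_expr), edges))
}

#' Perturbation matrix
#'
#' Disease edge matrix minus the normal reference vector, columnwise. A
#' disease sample whose gene ranking equals the reference ranking yields
#' an all-zero column.
#'
#' @param disease_edges edges x disease-samples matrix from
#'   [edge_matrix()].
#' @param reference vector from [reference_edges()] over the same edges.
#' @return edges x disease-samples matrix.
#' @export
perturbation <- function(disease_edges, reference) {
  if (!identical(rownames(disease_edges), names(reference)))
    stopf("edge universes of disease matrix and reference differ")
  sweep(disease_edges, 1, reference, "-")
}

#' Full perturbation matrix from bulk expression
#'
#' Convenience wrapper: rank-transforms disease and normal expression over
#' the edge genes and returns the perturbation matrix.
#'
#' @param expr genes x samples matrix.
#' @param labels data.frame with columns `sample`, `status`
#'   (`"normal"` / `"disease"`).
#' @param edges data.frame with columns `ligand`, `receptor`.
#' @return edges x disease-samples perturbation matrix. Invariant to any
#'   strictly increasing per-sample transform of the disease samples;
#'   the reference ranking is defined on the mean normal expression
#'   profile, so transforms that reorder normal means would move it.
#' @export
perturbation_from_bulk <- function(expr, labels, edges) {
  genes <- unique(c(edges$ligand, edges$receptor))
  normal <- expr[, labels$sample[labels$status == "normal"], drop = FALSE]
  disease <- expr[, labels$sample[labels$status == "disease"], drop = FALSE]
  ref <- reference_edges(normal[genes, , drop = FALSE], edges)
  de <- edge_matrix(rank_transform(disease, genes), edges)
  perturbation(de, ref)
}

#' PAM k-medoids with randomized restarts
#'
#' Partitioning around medoids (BUILD + SWAP) with `nstart` random
#' restarts; plain single-start BUILD + SWAP is a local search over
#' one-medoid swaps and can miss the global optimum even on a handful of
#' samples, while a few random restarts reliably reach it.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param k number of clusters.
#' @param nstart random restarts (default 5).
#' @return List with `labels` (integer vector), `medoids` (indices) and
#'   `cost` (total distance to closest medoid).
#' @export
pam_kmedoids <- function(d, k, nstart = 5) {
  d <- stats::as.dist(d)
  fit <- cluster::pam(d, k, medoids = "random", nstart = nstart)
  dm <- as.matrix(d)
  list(labels = as.integer(fit$clustering),
       medoids = as.integer(fit$id.med),
       cost = pam_cost(dm, fit$id.med))
}

#' Total PAM assignment cost
#'
#' Sum over samples of the distance to the closest medoid — the objective
#' PAM minimizes; exposed so small instances can be checked against the
#' exhaustive-search optimum.
#'
#' @param dmat symmetric distance matrix.
#' @param medoids medoid indices.
#' @return Numeric cost.
#' @export
pam_cost <- function(dmat, medoids) {
  sum(apply(dmat[, medoids, drop = FALSE], 1, min))
}

#' Subsampled PAM consensus clustering with CDF delta-area K selection
#'
#' For each of `reps` repetitions, `p_sample` of the samples and
#' `p_feature` of the edges are drawn without replacement and PAM
#' (k-medoids, Euclidean distance on the subsampled columns) is run for
#' every K in `k_range`. The consensus matrix entry (i, j) is the
#' co-cluster count over the co-sampled count. A(K) is the area under the
#' empirical CDF of the off-diagonal consensus values; the relative delta
#' area is `delta(2) = A(2)` and `delta(K) = (A(K) - A(K-1)) / A(K-1)`;
#' the chosen K is the largest K whose delta area still exceeds
#' `delta_floor` (the point where the area change slows down). Final
#' labels come from PAM on `1 - consensus` at the chosen K.
#'
#' @param P edges x samples perturbation matrix (>= max(k_range) + 1
#'   samples).
#' @param k_range candidate cluster numbers (default 2:6).
#' @param reps subsampling repetitions (default 1000).
#' @param p_sample,p_feature subsampling proportions (default 0.8, 0.8).
#' @param delta_floor relative delta-area floor for K selection
#'   (default 0.1).
#' @param seed master seed; per-rep seeds are derived from it.
#' @return Object of class `consensus_result`: list with `consensus`
#'   (named list of per-K matrices), `area`, `delta`, `k` (chosen),
#'   `labels` (named integer vector at chosen K), `k_range`.
#' @export
consensus_cluster <- function(P, k_range = 2:6, reps = 1000,
                              p_sample = 0.8, p_feature = 0.8,
                              delta_floor = 0.1, seed = 1L) {
  n <- ncol(P)
  if (n < max(k_range) + 1)
    stopf("need at least %d samples for k up to %d",
          max(k_range) + 1, max(k_range))
  n_sub <- floor(p_sample * n)
  f_sub <- max(1, floor(p_feature * nrow(P)))
  co_sampled <- matrix(0, n, n)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- paste0("K", k_range)
  for (r in seq_len(reps)) {
    with_seed((seed + r) %% 2147483647, {
      samp <- sort(sample.int(n, n_sub))
      feat <- sort(sample.int(nrow(P), f_sub))
      dmat <- dist(t(P[feat, samp, drop = FALSE]))
      co_sampled[samp, samp] <- co_sampled[samp, samp] + 1
      for (ki in seq_along(k_range)) {
        cl <- pam_kmedoids(dmat, k_range[ki])$labels
        same <- outer(cl, cl, "==") * 1
        co_cluster[[ki]][samp, samp] <- co_cluster[[ki]][samp, samp] + same
      }
    })
  }
  if (any(co_sampled[upper.tri(co_sampled)] == 0))
    stopf(paste("some sample pair was never co-sampled;",
                "raise reps or p_sample"))
  consensus <- lapply(co_cluster, function(cc) {
    m <- cc / pmax(co_sampled, 1)
    diag(m) <- 1
    dimnames(m) <- list(colnames(P), colnames(P))
    m
  })
  area <- vapply(consensus, function(m) cdf_area(m[upper.tri(m)]), 0)
  delta <- numeric(length(k_range))
  delta[1] <- area[1]
  if (length(k_range) > 1)
    delta[-1] <- diff(area) / area[-length(area)]
  names(area) <- names(delta) <- names(consensus)
  above <- which(delta > delta_floor)
  k <- if (length(above)) k_range[max(above)] else k_range[1]
  final <- with_seed(seed,
    pam_kmedoids(as.dist(1 - consensus[[paste0("K", k)]]), k)$labels)
  labels <- setNames(final, colnames(P))
  structure(list(consensus = consensus, area = area, delta = delta,
                 k = k, labels = labels, k_range = k_range),
            class = "consensus_result")
}

# Area under the empirical CDF of consensus values over [0, 1]
# (trapezoid-free form: sum over sorted unique values of
# (x_{i+1} - x_i) * CDF(x_i), anchored at 0 and 1).
cdf_area <- function(v) {
  x <- sort(unique(c(0, v, 1)))
  cdf <- ecdf(v)
  sum(diff(x) * cdf(x[-length(x)]))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result over K = %s; chosen K = %d\n",
              paste(range(x$k_range), collapse = ".."), x$k))
  print(round(rbind(area = x$area, delta = x$delta), 4))
  cat("cluster sizes at chosen K:\n")
  print(table(x$labels))
  invisible(x)
}

#' Per-subtype mean perturbation per edge
#'
#' @param P edges x samples perturbation matrix.
#' @param labels cluster labels (named as columns of `P`).
#' @return edges x subtypes matrix of mean perturbations.
#' @export
subtype_edge_means <- function(P, labels) {
  labs <- sort(unique(labels))
  vapply(labs, function(l)
    rowMeans(P[, names(labels)[labels == l], drop = FALSE]),
    numeric(nrow(P)))
}
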