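#' Quality control, normalization, feature selection and clustering
#'
#' Standard single-cell preprocessing: mitochondrial-fraction cell filter,
#' log-normalization to a fixed per-cell total, variance-stabilized highly
#' variable gene selection, PCA + shared-nearest-neighbor graph clustering,
#' and marker-overlap cell-type annotation.
#'
#' @name sc_preprocess
NULL

#' Filter cells by mitochondrial content
#'
#' Removes cells whose mitochondrial fraction (mito counts / total counts)
#' is strictly greater than `max_mito`; a cell at exactly the threshold is
#' kept. Cells with zero total counts are removed and reported (their
#' fraction is undefined). Order of surviving cells is preserved. The
#' filter is idempotent.
#'
#' @param m a [cell_matrix()] holding raw counts with mito flags set.
#' @param max_mito fraction threshold (default 0.20).
#' @return Filtered [cell_matrix()]; number of removed cells in
#'   `attr(, "n_removed")`.
#' @export
filter_cells <- function(m, max_mito = 0.20) {
  if (is.null(m$counts)) stopf("filter_cells needs raw counts")
  total <- Matrix::colSums(m$counts)
  zero <- total == 0
  if (any(zero))
    message(sprintf("removing %d cell(s) with zero total counts", sum(zero)))
  mito_counts <- if (any(m$gene_meta$mito))
    Matrix::colSums(m$counts[m$gene_meta$mito, , drop = FALSE])
  else rep(0, ncol(m$counts))
  frac <- ifelse(zero, NA_real_, mito_counts / total)
  keep <- !zero & frac <= max_mito
  out <- subset_cells(m, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Log-normalize counts to a fixed per-cell total
#'
#' `value = ln(1 + count / cell_total * scale_factor)`, so each cell's
#' back-transformed total `sum(exp(value) - 1)` equals `scale_factor`.
#' Invariant to per-cell library-size rescaling.
#'
#' @param m a [cell_matrix()] with raw counts and no zero-total cells
#'   (run [filter_cells()] first).
#' @param scale_factor target per-cell total (default 10000).
#' @return The [cell_matrix()] with `values` filled in.
#' @export
normalize_log <- function(m, scale_factor = 10000) {
  if (is.null(m$counts)) stopf("normalize_log needs raw counts")
  if (any(m$counts < 0)) stopf("negative values in count matrix")
  total <- Matrix::colSums(m$counts)
  if (any(total == 0)) stopf("zero-total cell present; run filter_cells first")
  m$values <- log1p(m$counts %*% Matrix::Diagonal(x = scale_factor / total))
  dimnames(m$values) <- dimnames(m$counts)
  m
}

#' Select highly variable genes (vst-style standardized variance)
#'
#' Per gene, a loess trend of log10 variance on log10 mean (over raw
#' counts) predicts the expected variance; counts are standardized with the
#' observed mean and trend-predicted standard deviation, clipped at
#' `sqrt(n_cells)`, and genes are ranked by the variance of the clipped
#' standardized values. Ties break lexicographically by gene id.
#'
#' @param m a [cell_matrix()] with raw counts.
#' @param n number of genes to return (default 2000). If `n` exceeds the
#'   gene count, all genes are returned with a warning.
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return Character vector of gene ids, highest standardized variance
#'   first.
#' @export
select_hvg <- function(m, n = 2000, loess_span = 0.3) {
  counts <- as.matrix(m$counts)
  if (n > nrow(counts)) {
    warnf("n = %d exceeds %d genes; returning all", n, nrow(counts))
    n <- nrow(counts)
  }
  mu <- rowMeans(counts)
  v <- apply(counts, 1, var)
  sv <- numeric(nrow(counts))
  fit_idx <- v > 0 & mu > 0
  if (sum(fit_idx) >= 4) {
    fit <- stats::loess(log10(v[fit_idx]) ~ log10(mu[fit_idx]),
                        span = loess_span, degree = 2)
    exp_sd <- sqrt(10^predict(fit, log10(mu[fit_idx])))
    clip <- sqrt(ncol(counts))
    z <- (counts[fit_idx, , drop = FALSE] - mu[fit_idx]) / exp_sd
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    sv[fit_idx] <- apply(z, 1, var)
  } else {
    sv[fit_idx] <- v[fit_idx]
  }
  ord <- order(-sv, rownames(counts))
  rownames(counts)[ord][seq_len(n)]
}

#' PCA + SNN graph clustering
#'
#' Scales the given genes, runs PCA, builds a shared-nearest-neighbor graph
#' (Jaccard overlap of k-nearest-neighbor sets in PC space, pruned below
#' 1/15), and applies Louvain modularity community detection at the given
#' resolution. Labels are contiguous integers from 0.
#'
#' @param m a normalized [cell_matrix()].
#' @param genes genes to use (e.g. from [select_hvg()]); default all.
#' @param n_pcs number of principal components (default 20).
#' @param k_neighbors neighbors for the SNN graph (default 20).
#' @param resolution Louvain resolution (default 0.8).
#' @param seed RNG seed for community detection.
#' @return Integer vector of cluster labels, one per cell.
#' @export
embed_cluster <- function(m, genes = NULL, n_pcs = 20, k_neighbors = 20,
                          resolution = 0.8, seed = 1L) {
  if (is.null(m$values)) stopf("embed_cluster needs a normalized matrix")
  x <- as.matrix(m$values)
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  n_cells <- ncol(x)
  if (n_pcs >= min(nrow(x), n_cells))
    stopf("n_pcs = %d must be below min(genes, cells) = %d",
          n_pcs, min(nrow(x), n_cells))
  gm <- rowMeans(x)               # per-gene z-scores across cells;
  gs <- apply(x, 1, sd)           # constant genes carry no signal
  gs[gs == 0] <- 1
  xs <- (x - gm) / gs
  pcs <- prcomp(t(xs), center = FALSE, scale. = FALSE,
                rank. = n_pcs)$x
  k <- min(k_neighbors, n_cells - 1)
  d <- as.matrix(dist(pcs))
  if (max(d) == 0) return(rep(0L, n_cells))  # all cells identical
  knn <- apply(d, 1, function(row) order(row)[2:(k + 1)])  # k x n
  # SNN edge weight: Jaccard overlap of neighbor sets (self included),
  # pruned below 1/15 as is conventional for SNN graphs.
  nb <- lapply(seq_len(n_cells), function(i) c(i, knn[, i]))
  adj <- matrix(0, n_cells, n_cells)
  for (i in seq_len(n_cells)) {
    cand <- unique(unlist(nb[nb[[i]]]))
    for (j in cand[cand > i]) {
      shared <- length(intersect(nb[[i]], nb[[j]]))
      jac <- shared / (2 * (k + 1) - shared)
      if (jac >= 1 / 15) adj[i, j] <- adj[j, i] <- jac
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  labels <- as.integer(igraph::membership(comm))
  match(labels, sort(unique(labels))) - 1L
}

#' Annotate clusters against a marker database
#'
#' Per cluster, candidate markers are genes with Wilcoxon rank-sum
#' p < `alpha` (cluster vs rest, on normalized values) and natural-log
#' fold-change > `min_lfc` (Seurat-style `ln(mean(expm1) + 1)` ratio). The
#' cluster is assigned the cell type with the largest overlap between its
#' candidate markers and that type's marker list; ties go to the larger
#' mean log fold-change over the overlapping markers; a cluster with zero
#' overlap for every type becomes `"other cells"`. Only genes present in
#' the marker database are tested — genes outside it cannot contribute to
#' any overlap, so the restriction is exact.
#'
#' @param m a normalized [cell_matrix()].
#' @param labels integer cluster labels from [embed_cluster()].
#' @param markers named list, cell type -> marker gene symbols.
#' @param min_lfc log fold-change threshold (default 0.25).
#' @param alpha Wilcoxon significance threshold (default 0.05).
#' @return List with `cluster_type` (named vector, cluster -> type) and
#'   `cell_type` (vector per cell); also written into `m$cell_meta` of the
#'   returned `matrix` element.
#' @export
annotate_clusters <- function(m, labels, markers, min_lfc = 0.25,
                              alpha = 0.05) {
  if (is.null(m$values)) stopf("annotate_clusters needs normalized values")
  if (length(labels) != ncol(m$values))
    stopf("labels length %d != %d cells", length(labels), ncol(m$values))
  db_genes <- intersect(unique(unlist(markers)), gene_ids(m))
  x <- as.matrix(m$values[db_genes, , drop = FALSE])
  clusters <- sort(unique(labels))
  cluster_type <- setNames(character(length(clusters)),
                           as.character(clusters))
  for (cl in clusters) {
    in_cl <- labels == cl
    if (!any(in_cl)) stopf("empty cluster %s", cl)
    if (all(in_cl)) {
      # single cluster: no "rest" to test against, no candidate markers
      cluster_type[as.character(cl)] <- "other cells"
      next
    }
    lfc <- log(rowMeans(expm1(x[, in_cl, drop = FALSE])) + 1) -
      log(rowMeans(expm1(x[, !in_cl, drop = FALSE])) + 1)
    pvals <- vapply(db_genes, function(g) {
      a <- x[g, in_cl]; b <- x[g, !in_cl]
      if (all(a == a[1]) && all(b == a[1])) return(1)
      suppressWarnings(wilcox.test(a, b)$p.value)
    }, 0)
    cand <- db_genes[pvals < alpha & lfc > min_lfc]
    overlap <- vapply(markers, function(mk) length(intersect(cand, mk)), 0L)
    if (all(overlap == 0)) {
      cluster_type[as.character(cl)] <- "other cells"
      next
    }
    best <- which(overlap == max(overlap))
    if (length(best) > 1) {
      mean_lfc <- vapply(best, function(b)
        mean(lfc[intersect(cand, markers[[b]])]), 0)
      best <- best[which.max(mean_lfc)]
    }
    cluster_type[as.character(cl)] <- names(markers)[best]
  }
  cell_type <- unname(cluster_type[as.character(labels)])
  m$cell_meta$cluster <- labels
  m$cell_meta$cell_type <- cell_type
  list(cluster_type = cluster_type, cell_type = cell_type, matrix = m)
}

#' Read a marker table (TSV with columns cell_type, gene)
#'
#' @param path TSV path.
#' @return Named list, cell type -> marker genes.
#' @export
read_marker_db <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(tab)))
    stopf("%s must have columns 'cell_type' and 'gene'", path)
  split(tab$gene, tab$cell_type)
}
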