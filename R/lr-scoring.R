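#' Four ligand-receptor scoring schemes
#'
#' For one annotated sub-dataset, four independent scorers produce raw
#' scores over all (pair, sender type, receiver type) triples from shared
#' per-cell-type expression profiles. The four formulas cover the main
#' families of published communication scores: a Hill (mass-action,
#' half-saturating) score on robust trimean summaries, a regularized
#' square-root product, a min-max-scaled product, and an expression-gated
#' product that emits no entry when either gene fails its detection gate.
#'
#' @name lr_scoring
NULL

#' Per-cell-type expression profiles
#'
#' Computes, per annotated cell type and gene: mean normalized expression,
#' Tukey trimean, and detection fraction (share of cells with count > 0),
#' plus per-type cell counts and the global mean of the normalized matrix.
#' Cells annotated `"other cells"` are excluded from scoring; a type with
#' fewer than 3 cells is excluded with a warning.
#'
#' @param m a normalized, annotated [cell_matrix()] (run
#'   [annotate_clusters()] first).
#' @param min_cells minimum cells for a type to be profiled (default 3).
#' @return Object of class `cell_type_profile`: list with matrices `mean`,
#'   `trimean`, `detect` (genes x types), vector `n_cells`, scalar `mu`.
#' @export
build_profiles <- function(m, min_cells = 3) {
  if (is.null(m$values)) stopf("build_profiles needs normalized values")
  if (is.null(m$cell_meta$cell_type))
    stopf("matrix is not annotated; run annotate_clusters first")
  keep <- m$cell_meta$cell_type != "other cells"
  m2 <- subset_cells(m, which(keep))
  tys <- sort(unique(m2$cell_meta$cell_type))
  n_cells <- vapply(tys, function(ty) sum(m2$cell_meta$cell_type == ty), 0L)
  small <- n_cells < min_cells
  if (any(small)) {
    warnf("excluding type(s) with < %d cells: %s", min_cells,
          paste(tys[small], collapse = ", "))
    tys <- tys[!small]
    n_cells <- n_cells[!small]
  }
  if (length(tys) == 0) stopf("no cell type with >= %d cells", min_cells)
  vals <- as.matrix(m2$values)
  detect_src <- if (!is.null(m2$counts)) as.matrix(m2$counts) else vals
  G <- nrow(vals)
  mk <- function() matrix(0, G, length(tys),
                          dimnames = list(rownames(vals), tys))
  mean_m <- mk(); tri_m <- mk(); det_m <- mk()
  for (ty in tys) {
    idx <- m2$cell_meta$cell_type == ty
    mean_m[, ty] <- rowMeans(vals[, idx, drop = FALSE])
    tri_m[, ty] <- apply(vals[, idx, drop = FALSE], 1, trimean)
    det_m[, ty] <- rowMeans(detect_src[, idx, drop = FALSE] > 0)
  }
  in_types <- m2$cell_meta$cell_type %in% tys
  structure(list(mean = mean_m, trimean = tri_m, detect = det_m,
                 n_cells = setNames(n_cells, tys),
                 mu = mean(vals[, in_types, drop = FALSE]),
                 types = tys),
            class = "cell_type_profile")
}

#' @export
print.cell_type_profile <- function(x, ...) {
  cat(sprintf("cell_type_profile: %d genes, %d types (mu = %.3f)\n",
              nrow(x$mean), length(x$types), x$mu))
  print(x$n_cells)
  invisible(x)
}

# Complex-aggregated expression of each pair side in each type, from a
# genes x types summary matrix. Genes absent from the matrix count as
# zero-expressed. Returns a pairs x types matrix.
side_expression <- function(summary_mat, units_list) {
  res <- vapply(seq_len(ncol(summary_mat)), function(j) {
    col <- summary_mat[, j]
    vapply(units_list, function(u) {
      v <- ifelse(u %in% rownames(summary_mat), col[u], 0)
      complex_expression(unname(v))
    }, 0)
  }, numeric(length(units_list)))
  matrix(res, nrow = length(units_list), ncol = ncol(summary_mat))
}

score_skeleton <- function(pairs, types, method) {
  grid <- expand.grid(sender = types, receiver = types,
                      stringsAsFactors = FALSE)
  data.frame(method = method,
             pair_id = rep(vapply(pairs, `[[`, "", "pair_id"),
                           each = nrow(grid)),
             sender = rep(grid$sender, length(pairs)),
             receiver = rep(grid$receiver, length(pairs)),
             score = NA_real_, stringsAsFactors = FALSE)
}

# Shared driver: given pairs x types matrices L (ligand summary) and R
# (receptor summary), fill score = f(l, r) over all triples.
score_product_grid <- function(pairs, types, method, L, R, f) {
  out <- score_skeleton(pairs, types, method)
  n_t <- length(types)
  grid <- expand.grid(s = seq_len(n_t), r = seq_len(n_t))
  for (i in seq_along(pairs)) {
    rows <- (i - 1) * nrow(grid) + seq_len(nrow(grid))
    out$score[rows] <- f(L[i, grid$s], R[i, grid$r])
  }
  out
}

#' Hill mass-action score on trimean summaries
#'
#' `score = l * r / (0.5 + l * r)` with `l`, `r` the Tukey trimean of the
#' (complex-aggregated) ligand in the sender and receptor in the receiver.
#' Saturates at 1; half-saturation at `l * r = 0.5`.
#'
#' @param p a [build_profiles()] result.
#' @param pairs list of [lr_pair()].
#' @return Long data.frame: method, pair_id, sender, receiver, score.
#' @export
score_hill <- function(p, pairs) {
  L <- (side_expression(p$trimean,
                                 lapply(pairs, `[[`, "ligand_units")))
  R <- (side_expression(p$trimean,
                                 lapply(pairs, `[[`, "receptor_units")))
  score_product_grid(pairs, p$types, "hill", L, R,
                     function(l, r) l * r / (0.5 + l * r))
}

#' Regularized square-root product score
#'
#' `score = sqrt(l * r) / (mu + sqrt(l * r))` with `l`, `r` mean
#' expressions and `mu` the global mean of the normalized matrix.
#'
#' @inheritParams score_hill
#' @return Long data.frame as in [score_hill()].
#' @export
score_regularized <- function(p, pairs) {
  if (p$mu <= 0) stopf("global mean is zero; matrix is all-zero")
  L <- (side_expression(p$mean,
                                 lapply(pairs, `[[`, "ligand_units")))
  R <- (side_expression(p$mean,
                                 lapply(pairs, `[[`, "receptor_units")))
  mu <- p$mu
  score_product_grid(pairs, p$types, "regularized", L, R,
                     function(l, r) sqrt(l * r) / (mu + sqrt(l * r)))
}

# Min-max scale each gene's mean across types to [0, 10]; a constant
# nonzero gene maps to 10 everywhere, a constant zero gene to 0.
scale_across_types <- function(mean_mat) {
  t(apply(mean_mat, 1, function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) {
      if (rng[2] > 0) rep(10, length(x)) else rep(0, length(x))
    } else (x - rng[1]) / (rng[2] - rng[1]) * 10
  }))
}

#' Scaled-product score
#'
#' Each gene's mean expression is min-max scaled to `[0, 10]` across cell
#' types; the score is the product of the (complex-aggregated) scaled
#' ligand and receptor values, in `[0, 100]`.
#'
#' @inheritParams score_hill
#' @return Long data.frame as in [score_hill()].
#' @export
score_product <- function(p, pairs) {
  scaled <- scale_across_types(p$mean)
  dimnames(scaled) <- dimnames(p$mean)
  L <- (side_expression(scaled,
                                 lapply(pairs, `[[`, "ligand_units")))
  R <- (side_expression(scaled,
                                 lapply(pairs, `[[`, "receptor_units")))
  score_product_grid(pairs, p$types, "product", L, R,
                     function(l, r) l * r)
}

#' Expression-gated product score
#'
#' A gene passes its gate in a type iff its detection fraction is at least
#' `min_detect` and its mean there exceeds its across-type mean. The score
#' is `mean_l * mean_r` when the ligand passes in the sender and the
#' receptor in the receiver (every complex subunit must pass); otherwise no
#' entry is emitted — absence, not zero, which is what triggers downstream
#' zero-imputation.
#'
#' @inheritParams score_hill
#' @param min_detect detection-fraction gate (default 0.10).
#' @return Long data.frame as in [score_hill()]; rows only for passing
#'   triples.
#' @export
score_gated <- function(p, pairs, min_detect = 0.10) {
  across <- rowMeans(p$mean)
  pass <- p$detect >= min_detect & p$mean > across
  unit_pass <- function(units_list) {
    vapply(seq_along(p$types), function(j) {
      vapply(units_list, function(u) {
        u_in <- u %in% rownames(pass)
        all(u_in) && all(pass[u, j])
      }, TRUE)
    }, logical(length(units_list)))
  }
  lp <- matrix(unit_pass(lapply(pairs, `[[`, "ligand_units")),
               nrow = length(pairs))
  rp <- matrix(unit_pass(lapply(pairs, `[[`, "receptor_units")),
               nrow = length(pairs))
  L <- (side_expression(p$mean,
                                 lapply(pairs, `[[`, "ligand_units")))
  R <- (side_expression(p$mean,
                                 lapply(pairs, `[[`, "receptor_units")))
  out <- score_product_grid(pairs, p$types, "gated", L, R,
                            function(l, r) l * r)
  n_t <- length(p$types)
  grid <- expand.grid(s = seq_len(n_t), r = seq_len(n_t))
  keep <- logical(nrow(out))
  for (i in seq_along(pairs)) {
    rows <- (i - 1) * nrow(grid) + seq_len(nrow(grid))
    keep[rows] <- lp[i, grid$s] & rp[i, grid$r]
  }
  out[keep, , drop = FALSE]
}

#' Run all four scorers on one sub-dataset
#'
#' @param m a normalized, annotated [cell_matrix()].
#' @param pairs list of [lr_pair()].
#' @param min_detect detection gate for [score_gated()].
#' @return Named list of four long score tables
#'   (`hill`, `regularized`, `product`, `gated`).
#' @export
score_all_methods <- function(m, pairs, min_detect = 0.10) {
  p <- build_profiles(m)
  list(hill = score_hill(p, pairs),
       regularized = score_regularized(p, pairs),
       product = score_product(p, pairs),
       gated = score_gated(p, pairs, min_detect = min_detect))
}
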