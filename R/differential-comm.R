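#' Condition-specific communication calling
#'
#' Compares ISIscores between two groups of sub-datasets (e.g. disease vs
#' normal, male vs female) per (pair, sender, receiver) key with a
#' two-sided Wilcoxon rank-sum test, and calls a key condition-specific
#' when p < alpha and the log2 mean-ISIscore ratio clears a strict cutoff.
#'
#' @name differential_comm
NULL

# Wilcoxon rank-sum p-value with the sampling policy used throughout:
# exact for small groups (<= 25 per side), normal approximation with
# continuity correction otherwise. Ties block wilcox.test's exact path,
# so small tied problems are handled by exact permutation over all
# C(n+m, n) group assignments of the average ranks.
wilcox_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  small <- n <= 25 && m <= 25
  ties <- anyDuplicated(c(a, b)) > 0
  if (small && !ties)
    return(suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = TRUE)$p.value))
  if (small && ties && choose(n + m, n) <= 2e4) {
    r <- rank(c(a, b))
    ew <- n * (n + m + 1) / 2
    w_obs <- sum(r[seq_len(n)])
    ws <- utils::combn(n + m, n, function(idx) sum(r[idx]))
    return(mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9))
  }
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided",
                exact = FALSE, correct = TRUE)$p.value)
}

# Per-cell fallback samples for one key in one group: per sender cell, the
# complex-aggregated ligand value times the receiver-type mean receptor
# value, so shifts on either side move the cross-group ranks.
fallback_samples <- function(m, pair, sender, receiver) {
  vals <- m$values
  ct <- m$cell_meta$cell_type
  sender_cells <- which(ct == sender)
  receiver_cells <- which(ct == receiver)
  if (!length(sender_cells) || !length(receiver_cells)) return(numeric())
  gene_val <- function(units, cells) {
    present <- units %in% rownames(vals)
    if (!all(present)) return(matrix(0, length(units), length(cells)))
    as.matrix(vals[units, cells, drop = FALSE])
  }
  lig <- gene_val(pair$ligand_units, sender_cells)
  lig_cell <- apply(lig, 2, complex_expression)
  rec_mean <- vapply(seq_along(pair$receptor_units), function(i)
    mean(gene_val(pair$receptor_units[i], receiver_cells)), 0)
  lig_cell * complex_expression(rec_mean)
}

#' Compare communication between two condition groups
#'
#' Keys are first pruned to those with a positive ISIscore somewhere in the
#' union of both groups. When both groups contain at least
#' `min_subdatasets` sub-datasets, the Wilcoxon samples per key are the
#' per-sub-dataset ISIscores (a key absent from a table scores 0, its
#' imputed value). Otherwise — e.g. a single sub-dataset per condition —
#' the samples fall back to per-cell ligand x receptor expression products
#' over the sender/receiver cells, which requires the annotated matrices
#' `cells_a` / `cells_b`.
#'
#' @param group_a,group_b lists of `isi_table` objects (>= 1 each).
#' @param pairs list of [lr_pair()]; needed for the per-cell fallback.
#' @param cells_a,cells_b lists of normalized annotated [cell_matrix()]
#'   objects backing each group (fallback path only).
#' @param alpha significance threshold (default 0.05).
#' @param log2_cut strict log2 ratio cutoff (default 3).
#' @param eps pseudocount for the log ratio (default 1e-3).
#' @param min_subdatasets sub-datasets per group required for the
#'   group-level sampling unit (default 3).
#' @return data.frame of class `diff_result`: pair_id, sender, receiver,
#'   mean_a, mean_b, p, p_bh, log2_ratio, call, sampling_unit. `p_bh` is a
#'   Benjamini-Hochberg column emitted for reference; calls use raw p.
#' @export
compare_conditions <- function(group_a, group_b, pairs = NULL,
                               cells_a = NULL, cells_b = NULL,
                               alpha = 0.05, log2_cut = 3, eps = 1e-3,
                               min_subdatasets = 3) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stopf("each group needs at least one sub-dataset ISI table")
  pruned <- prune_all_zero(c(group_a, group_b))
  keys <- pruned$keys
  group_level <- length(group_a) >= min_subdatasets &&
    length(group_b) >= min_subdatasets
  if (!group_level && (is.null(cells_a) || is.null(cells_b) ||
                       is.null(pairs)))
    stopf(paste("fewer than %d sub-datasets per group: per-cell fallback",
                "requires pairs, cells_a and cells_b"), min_subdatasets)

  key_scores <- function(tables, key_df) {
    kk <- isi_key(key_df)
    sapply(tables, function(t) {
      s <- rep(0, nrow(key_df))          # absent key = imputed zero
      idx <- match(isi_key(t), kk)
      ok <- !is.na(idx)
      s[idx[ok]] <- t$isiscore[ok]
      s
    })
  }
  sa <- matrix(key_scores(group_a, keys), nrow = nrow(keys))
  sb <- matrix(key_scores(group_b, keys), nrow = nrow(keys))

  pair_by_id <- if (!is.null(pairs))
    setNames(pairs, vapply(pairs, `[[`, "", "pair_id"))
  out <- keys
  out$mean_a <- rowMeans(sa)
  out$mean_b <- rowMeans(sb)
  out$p <- NA_real_
  for (i in seq_len(nrow(keys))) {
    if (group_level) {
      out$p[i] <- wilcox_p(sa[i, ], sb[i, ])
    } else {
      pr <- pair_by_id[[keys$pair_id[i]]]
      va <- unlist(lapply(cells_a, fallback_samples, pair = pr,
                          sender = keys$sender[i],
                          receiver = keys$receiver[i]))
      vb <- unlist(lapply(cells_b, fallback_samples, pair = pr,
                          sender = keys$sender[i],
                          receiver = keys$receiver[i]))
      out$p[i] <- if (length(va) && length(vb)) wilcox_p(va, vb) else 1
    }
  }
  out$p_bh <- p.adjust(out$p, method = "BH")
  out$log2_ratio <- log2((out$mean_a + eps) / (out$mean_b + eps))
  out$call <- ifelse(out$p < alpha & out$log2_ratio > log2_cut, "A-specific",
              ifelse(out$p < alpha & out$log2_ratio < -log2_cut,
                     "B-specific", "not-specific"))
  out$sampling_unit <- if (group_level) "subdataset" else "cell"
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Extract condition-specific pair sets
#'
#' Strict inequalities on both criteria: p < `alpha` and |log2 ratio|
#' > `log2_cut` (recomputed from the means with pseudocount `eps`, so the
#' thresholds can be varied after [compare_conditions()]).
#'
#' @param d a `diff_result` table.
#' @param alpha,log2_cut,eps thresholds as in [compare_conditions()].
#' @return List with data.frames `a_specific` and `b_specific`.
#' @export
call_specific <- function(d, alpha = 0.05, log2_cut = 3, eps = 1e-3) {
  lr <- log2((d$mean_a + eps) / (d$mean_b + eps))
  list(a_specific = d[d$p < alpha & lr > log2_cut, , drop = FALSE],
       b_specific = d[d$p < alpha & lr < -log2_cut, , drop = FALSE])
}

#' Flatten specific pairs to a unique gene list
#'
#' All ligand and receptor subunits of the given calls, deduplicated and
#' sorted — the communication gene set fed to the disease classifier.
#'
#' @param specific data.frame with a `pair_id` column (e.g. one element of
#'   [call_specific()]).
#' @return Sorted character vector of gene symbols.
#' @export
collect_marker_genes <- function(specific) {
  if (nrow(specific) == 0) return(character())
  genes <- unlist(lapply(unique(specific$pair_id), function(id) {
    p <- parse_pair_id(id)
    c(p$ligand_units, p$receptor_units)
  }))
  sort(unique(genes))
}
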