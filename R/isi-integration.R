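#' ISIscore integration across the four scoring methods
#'
#' Per sub-dataset, each method's raw scores are min-max normalized to
#' `[0, 1]` over its present entries; the ISIscore of a (pair, sender,
#' receiver) triple is the arithmetic mean of the four normalized
#' components, with 0 imputed for entries absent from a method.
#'
#' @name isi_integration
NULL

isi_key <- function(df) paste(df$pair_id, df$sender, df$receiver, sep = "\r")

#' Min-max normalize one method score table
#'
#' `(x - min) / (max - min)` over all present entries of one method in one
#' sub-dataset. Degenerate cases: all entries equal and positive -> 1;
#' all zero -> 0. Absent entries stay absent (imputation happens at
#' integration). Adding a constant to every raw score leaves the output
#' unchanged.
#'
#' @param t long score table (columns method, pair_id, sender, receiver,
#'   score) from one scorer.
#' @return The table with `score` replaced by its normalized value.
#' @export
normalize_scores <- function(t) {
  if (nrow(t) == 0) {
    warnf("empty score table")
    return(t)
  }
  rng <- range(t$score)
  t$score <- if (rng[2] > rng[1]) (t$score - rng[1]) / (rng[2] - rng[1])
  else if (rng[2] > 0) rep(1, nrow(t))
  else rep(0, nrow(t))
  t
}

#' Integrate four normalized method tables into an ISI table
#'
#' Takes the union of (pair, sender, receiver) keys over the four methods;
#' a key missing from a method contributes 0 for that component; the
#' ISIscore is the mean of the four components. Symmetric in the methods.
#'
#' @param tables named list of exactly four normalized score tables
#'   (from [normalize_scores()]), one per method.
#' @param subdataset_id id string recorded on the result.
#' @param condition named list/vector of condition labels (disease, sex,
#'   region) recorded on the result.
#' @return data.frame of class `isi_table`: pair_id, sender, receiver,
#'   isiscore, and one `comp_<method>` column per method; attributes
#'   `subdataset_id` and `condition`.
#' @export
compute_isiscore <- function(tables, subdataset_id = "subdataset",
                             condition = list()) {
  if (length(tables) != 4)
    stopf("expected exactly 4 method tables, got %d", length(tables))
  methods <- vapply(tables, function(t)
    if (nrow(t)) t$method[1] else "gated", "")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- methods
  keys <- unique(do.call(rbind, lapply(tables, function(t)
    t[c("pair_id", "sender", "receiver")])))
  rownames(keys) <- NULL
  comp <- matrix(0, nrow(keys), 4,
                 dimnames = list(NULL, paste0("comp_", names(tables))))
  kk <- isi_key(keys)
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    if (nrow(t) == 0) next
    tk <- isi_key(t)
    if (anyDuplicated(tk))
      stopf("duplicate (pair, sender, receiver) keys within method '%s'",
            names(tables)[j])
    idx <- match(tk, kk)
    comp[idx, j] <- t$score
  }
  out <- cbind(keys,
               data.frame(isiscore = rowMeans(comp)),
               as.data.frame(comp))
  attr(out, "subdataset_id") <- subdataset_id
  attr(out, "condition") <- as.list(condition)
  class(out) <- c("isi_table", "data.frame")
  out
}

#' Score one sub-dataset end to end
#'
#' Runs the four scorers, normalizes each, and integrates into an ISI
#' table.
#'
#' @param m a normalized, annotated [cell_matrix()].
#' @param pairs list of [lr_pair()].
#' @param subdataset_id,condition recorded on the result (condition
#'   defaults to this sub-dataset's metadata labels).
#' @return An `isi_table` (see [compute_isiscore()]).
#' @export
isi_for_subdataset <- function(m, pairs, subdataset_id = NULL,
                               condition = NULL) {
  if (is.null(condition))
    condition <- as.list(m$cell_meta[1, c("disease", "sex", "region")])
  if (is.null(subdataset_id))
    subdataset_id <- paste(m$cell_meta$sample[1],
                           paste(unlist(condition), collapse = "-"),
                           sep = "-")
  raw <- score_all_methods(m, pairs)
  compute_isiscore(lapply(raw, normalize_scores),
                   subdataset_id = subdataset_id, condition = condition)
}

#' Remove keys whose ISIscore is zero in every table
#'
#' A (pair, sender, receiver) key is kept iff its ISIscore is positive in
#' at least one of the given tables.
#'
#' @param tables list of `isi_table` objects (>= 1).
#' @return List with `tables` (pruned, attributes preserved) and `keys`
#'   (data.frame of kept keys).
#' @export
prune_all_zero <- function(tables) {
  if (length(tables) == 0) stopf("need at least one ISI table")
  all_keys <- unique(do.call(rbind, lapply(tables, function(t)
    t[c("pair_id", "sender", "receiver")])))
  rownames(all_keys) <- NULL
  kk <- isi_key(all_keys)
  pos <- rep(FALSE, length(kk))
  for (t in tables) {
    idx <- match(isi_key(t), kk)
    pos[idx[t$isiscore > 0]] <- TRUE
  }
  kept <- all_keys[pos, , drop = FALSE]
  kept_k <- kk[pos]
  pruned <- lapply(tables, function(t) {
    out <- t[isi_key(t) %in% kept_k, , drop = FALSE]
    attr(out, "subdataset_id") <- attr(t, "subdataset_id")
    attr(out, "condition") <- attr(t, "condition")
    out
  })
  list(tables = pruned, keys = kept)
}

#' Summarize communication per sender-receiver cell pair
#'
#' For each (sender, receiver) cell of the directed communication grid,
#' the sum of ISIscores and the count of pairs with nonzero ISIscore (as
#' displayed on communication dot plots).
#'
#' @param t an `isi_table`.
#' @param types cell-type universe defining the grid (default the types
#'   observed in `t`); 6 types give the 36 directed communications.
#' @return data.frame: sender, receiver, isiscore_sum, n_pairs.
#' @export
summarize_communication <- function(t, types = NULL) {
  if (is.null(types)) types <- sort(unique(c(t$sender, t$receiver)))
  grid <- expand.grid(sender = types, receiver = types,
                      stringsAsFactors = FALSE)
  grid$isiscore_sum <- 0
  grid$n_pairs <- 0L
  gk <- paste(grid$sender, grid$receiver, sep = "\r")
  tk <- paste(t$sender, t$receiver, sep = "\r")
  sums <- tapply(t$isiscore, tk, sum)
  cnts <- tapply(t$isiscore > 0, tk, sum)
  idx <- match(names(sums), gk)
  ok <- !is.na(idx)
  grid$isiscore_sum[idx[ok]] <- unname(sums[ok])
  grid$n_pairs[idx[ok]] <- as.integer(unname(cnts[ok]))
  grid
}

#' Write an ISI table as long TSV
#'
#' Columns: subdataset_id, disease, sex, region, pair_id, sender,
#' receiver, isiscore and the four component columns.
#'
#' @param t an `isi_table`.
#' @param path output TSV path.
#' @export
write_isi_table <- function(t, path) {
  cond <- attr(t, "condition")
  meta <- data.frame(
    subdataset_id = attr(t, "subdataset_id") %||% "subdataset",
    disease = cond$disease %||% "unknown",
    sex = cond$sex %||% "unknown",
    region = cond$region %||% "unknown")
  out <- cbind(meta[rep(1, nrow(t)), , drop = FALSE], as.data.frame(t))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
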