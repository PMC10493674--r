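#' Sub-dataset partitioning and pipeline orchestration
#'
#' A sub-dataset is the set of cells of one dataset sharing a combination
#' of condition labels (disease, sex, brain region); it is the unit on
#' which communication is scored. `run_pipeline()` drives the stages
#' end-to-end from a YAML config on synthetic data.
#'
#' @name workflow
NULL

#' Partition a dataset into condition sub-datasets
#'
#' One sub-dataset per observed combination of the requested metadata
#' fields; cells partition exactly (disjoint, exhaustive) before the
#' size filter. Combinations with fewer than `min_cells` cells are
#' dropped with a warning. The sub-dataset id is
#' `"<sample>-<value1>[-<value2>...]"`.
#'
#' @param m a [cell_matrix()].
#' @param by character vector of metadata fields (subset of `sample`,
#'   `disease`, `sex`, `region`, ...); empty vector returns the input as
#'   a single sub-dataset.
#' @param min_cells minimum sub-dataset size (default 50).
#' @param dataset_id id prefix (default the first `sample` value).
#' @return Named list of [cell_matrix()] objects; each carries its
#'   `subdataset_id` and `condition` as attributes.
#' @export
partition_subdatasets <- function(m, by = c("disease"), min_cells = 50,
                                  dataset_id = NULL) {
  if (is.null(dataset_id)) dataset_id <- as.character(m$cell_meta$sample[1])
  unknown <- setdiff(by, names(m$cell_meta))
  if (length(unknown))
    stopf("unknown metadata field(s): %s", paste(unknown, collapse = ", "))
  if (length(by) == 0) {
    out <- list(m)
    names(out) <- dataset_id
    attr(out[[1]], "subdataset_id") <- dataset_id
    return(out)
  }
  key <- do.call(paste, c(m$cell_meta[by], list(sep = "-")))
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < min_cells) {
      warnf("dropping sub-dataset %s-%s with %d < %d cells",
            dataset_id, k, length(idx), min_cells)
      next
    }
    sub <- subset_cells(m, idx)
    id <- paste(dataset_id, k, sep = "-")
    attr(sub, "subdataset_id") <- id
    attr(sub, "condition") <- as.list(sub$cell_meta[1, by, drop = FALSE])
    out[[id]] <- sub
  }
  out
}

# Preprocess one raw sub-dataset up to annotated profiles.
preprocess_subdataset <- function(m, markers, max_mito = 0.20,
                                  n_hvg = 2000, n_pcs = 20,
                                  k_neighbors = 20, resolution = 0.8,
                                  seed = 1L) {
  m <- filter_cells(m, max_mito = max_mito)
  m <- normalize_log(m)
  hvg <- select_hvg(m, n = min(n_hvg, nrow(m$counts)))
  labels <- embed_cluster(m, genes = hvg,
                          n_pcs = min(n_pcs, length(hvg) - 1,
                                      ncol(m$counts) - 1),
                          k_neighbors = k_neighbors,
                          resolution = resolution, seed = seed)
  annotate_clusters(m, labels, markers)$matrix
}

#' Run the communication pipeline from a YAML config
#'
#' Stages, in order: simulate (synthetic single-cell sub-datasets and a
#' bulk cohort), preprocess + partition, score + integrate (ISI tables),
#' diff (condition-specific calls), subtype (consensus clustering on the
#' perturbation matrix), predict (communication-gene classifier). Every
#' stage writes its outputs under `out_dir` and is recorded, with
#' parameters and seeds, in `manifest.json`. Reruns with the same config
#' are identical for all deterministic stages.
#'
#' Config keys (flat YAML): `out_dir`, `seed`, and optional overrides
#' `n_cells_per_type`, `n_genes`, `n_subdatasets_per_group`,
#' `signal_fold`, `n_planted`, `reps`, `k_max`, `lr_database`
#' (TSV path; default the shipped synthetic fixture).
#'
#' @param config_path YAML file path.
#' @return Invisibly, the manifest list. Nonzero-status errors propagate
#'   as R errors after the failing stage is logged.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  for (key in c("out_dir", "seed"))
    if (is.null(cfg[[key]])) stopf("config is missing required key '%s'", key)
  defaults <- list(n_cells_per_type = 60, n_genes = 220,
                   n_subdatasets_per_group = 4, signal_fold = 8,
                   n_planted = 6, reps = 100, k_max = 5,
                   lr_database = system.file("extdata",
                                             "lr_pairs_synthetic.tsv",
                                             package = "braincomm"))
  for (key in names(defaults))
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages = list())
  log_stage <- function(name, files, params = list()) {
    manifest$stages[[name]] <<- list(files = files, params = params)
    message(sprintf("[%s] %s done (%s)", format(Sys.time(), "%H:%M:%S"),
                    name, paste(basename(files), collapse = ", ")))
  }

  pairs <- load_lr_database(cfg$lr_database)
  scenario <- communication_scenario(
    pairs, n_planted = cfg$n_planted, signal_fold = cfg$signal_fold,
    n_cells_per_type = cfg$n_cells_per_type, n_genes = cfg$n_genes,
    seed = cfg$seed)

  # simulate + preprocess + score each sub-dataset
  groups <- list(A = list(), B = list())
  for (g in c("A", "B")) {
    for (i in seq_len(cfg$n_subdatasets_per_group)) {
      cm <- simulate_condition_subdataset(scenario, group = g, index = i)
      ann <- preprocess_subdataset(cm, scenario$markers, seed = cfg$seed)
      groups[[g]][[i]] <- isi_for_subdataset(ann, scenario$pairs)
      f <- file.path(cfg$out_dir,
                     sprintf("isi_%s.tsv", attr(groups[[g]][[i]],
                                                "subdataset_id")))
      write_isi_table(groups[[g]][[i]], f)
    }
  }
  log_stage("score_integrate",
            file.path(cfg$out_dir,
                      vapply(unlist(groups, recursive = FALSE),
                             function(t) sprintf("isi_%s.tsv",
                                                 attr(t, "subdataset_id")),
                             "")),
            params = list(seed = cfg$seed))

  diff <- compare_conditions(groups$A, groups$B, pairs = scenario$pairs)
  diff_file <- file.path(cfg$out_dir, "diff_calls.tsv")
  write.table(as.data.frame(diff), diff_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("diff", diff_file,
            params = list(alpha = 0.05, log2_cut = 3))
  specific <- call_specific(diff)$a_specific

  # bulk subtyping + prediction on the same pair universe
  bulk_cfg <- bulk_sim_config(seed = cfg$seed)
  bulk <- simulate_bulk(bulk_cfg, pairs)
  write_bulk_dataset(bulk, file.path(cfg$out_dir, "bulk"))
  P <- perturbation_from_bulk(bulk$expr, bulk$labels, bulk$edges)
  cons <- consensus_cluster(P, k_range = 2:cfg$k_max, reps = cfg$reps,
                            seed = cfg$seed)
  write.table(data.frame(sample = names(cons$labels),
                         subtype = cons$labels),
              file.path(cfg$out_dir, "subtypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("subtype",
            file.path(cfg$out_dir, c("bulk/expr.tsv", "bulk/labels.tsv",
                                     "subtypes.tsv")),
            params = list(reps = cfg$reps, k = cons$k, seed = cfg$seed))

  genes <- if (nrow(specific) > 0) collect_marker_genes(specific)
  else unique(c(bulk$edges$ligand, bulk$edges$receptor))
  genes <- intersect(genes, rownames(bulk$expr))
  report <- train_evaluate(bulk$expr, bulk$labels$status, genes,
                           seed = cfg$seed)
  write_prediction_report(report, file.path(cfg$out_dir, "prediction"))
  log_stage("predict",
            file.path(cfg$out_dir,
                      c("prediction/report.json",
                        "prediction/probabilities.tsv")),
            params = list(auc = report$auc, seed = cfg$seed))

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Build a two-condition communication scenario
#'
#' Sets up a [sim_config()] whose planted pairs are elevated under
#' condition `"A"` only, using the first `n_planted` single-gene-capable
#' pairs remapped onto the synthetic gene universe, with senders and
#' receivers cycling over the six brain types.
#'
#' @param pairs list of [lr_pair()] (used for counting; planted genes are
#'   drawn from the generator's own `GENE` universe).
#' @param n_planted number of planted pairs.
#' @param signal_fold elevation of planted genes under condition A.
#' @param n_cells_per_type,n_genes,seed forwarded to [sim_config()].
#' @return List with `config`, `pairs` (planted + background pairs over
#'   the synthetic universe), `planted` (data.frame), `markers`.
#' @export
communication_scenario <- function(pairs, n_planted = 6, signal_fold = 8,
                                   n_cells_per_type = 60, n_genes = 220,
                                   seed = 1L) {
  types <- brain_cell_types()
  n_bg <- max(20, length(pairs))
  gene_pool <- sprintf("GENE%04d", seq_len(2 * (n_planted + n_bg)))
  lig <- gene_pool[seq(1, by = 2, length.out = n_planted + n_bg)]
  rec <- gene_pool[seq(2, by = 2, length.out = n_planted + n_bg)]
  planted <- data.frame(
    ligand = lig[seq_len(n_planted)], receptor = rec[seq_len(n_planted)],
    sender = types[(seq_len(n_planted) - 1) %% 6 + 1],
    receiver = types[seq_len(n_planted) %% 6 + 1],
    condition = "A", signal_fold = signal_fold,
    stringsAsFactors = FALSE)
  # gene universe must hold markers + mito + planted/background pairs +
  # the per-type program blocks without collision
  n_needed <- length(gene_pool) + 30 + 10 + 6 * 25 + 10
  config <- sim_config(
    n_cells_per_type = n_cells_per_type,
    n_genes = max(n_genes, n_needed),
    planted_pairs = planted, lr_genes = c(lig, rec), seed = seed)
  all_pairs <- Map(lr_pair, lig, rec)
  list(config = config, pairs = unname(all_pairs), planted = planted,
       markers = config$markers)
}

#' Simulate one sub-dataset of a two-condition scenario
#'
#' @param scenario a [communication_scenario()].
#' @param group `"A"` (planted signal active) or `"B"`.
#' @param index sub-dataset index within the group (drives the sample id,
#'   hence the noise seed).
#' @return A [cell_matrix()].
#' @export
simulate_condition_subdataset <- function(scenario, group, index) {
  simulate_sc(scenario$config,
              condition_labels = list(
                sample = sprintf("%s%02d", group, index),
                disease = group))
}
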