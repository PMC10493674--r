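# Shared fixture builders. Everything is generated in code; no files.

# 5-cell count matrix with mito fractions {0, 0.10, 0.20, 0.21, 0.50}
# over one mito and one nuclear gene (100 counts per cell).
mito_fixture <- function() {
  counts <- rbind(
    `MT-1` = c(0, 10, 20, 21, 50),
    NUC1   = c(100, 90, 80, 79, 50))
  colnames(counts) <- paste0("c", 1:5)
  cell_matrix(counts, data.frame(sample = "S"))
}

# Minimal hand-built cell_type_profile for direct scorer formula checks.
fake_profile <- function(mean_mat, trimean_mat = mean_mat,
                         detect_mat = (mean_mat > 0) * 1, mu = 1) {
  structure(list(mean = mean_mat, trimean = trimean_mat,
                 detect = detect_mat,
                 n_cells = setNames(rep(10L, ncol(mean_mat)),
                                    colnames(mean_mat)),
                 mu = mu, types = colnames(mean_mat)),
            class = "cell_type_profile")
}

# Hand-built ISI table: df has pair_id, sender, receiver, isiscore.
make_isi <- function(df, id = "sub", condition = list(disease = "x")) {
  attr(df, "subdataset_id") <- id
  attr(df, "condition") <- condition
  class(df) <- c("isi_table", "data.frame")
  df
}

# One-key ISI tables holding given scores, for Wilcoxon-path tests.
isi_group <- function(scores, prefix = "g") {
  lapply(seq_along(scores), function(i)
    make_isi(data.frame(pair_id = "L_R", sender = "neurons",
                        receiver = "microglia", isiscore = scores[i]),
             id = paste0(prefix, i)))
}

# Small two-condition scenario shared by differential tests.
test_scenario <- function(signal_fold, seed, n_cells_per_type = 60) {
  pairs <- load_lr_database(system.file("extdata",
                                        "lr_pairs_synthetic.tsv",
                                        package = "braincomm"))
  communication_scenario(pairs, n_planted = 6, signal_fold = signal_fold,
                         n_cells_per_type = n_cells_per_type, seed = seed)
}

# Simulate + preprocess one sub-dataset with truth annotation (skips
# clustering so downstream stages can be studied in isolation).
scenario_isi <- function(scenario, group, index) {
  cm <- simulate_condition_subdataset(scenario, group, index)
  isi_for_subdataset(annotate_truth(normalize_log(filter_cells(cm))),
                     scenario$pairs)
}

planted_keys <- function(scenario) {
  paste(paste0(scenario$planted$ligand, "_", scenario$planted$receptor),
        scenario$planted$sender, scenario$planted$receiver)
}

diff_keys <- function(d) paste(d$pair_id, d$sender, d$receiver)

# Exhaustive-enumeration oracle for the two-sided Wilcoxon rank-sum
# p-value: distribution of the group-A rank sum over all C(N, n)
# assignments, p = share of assignments at least as extreme (about the
# null mean) as observed.
enumerate_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  ew <- n * (length(pooled) + 1) / 2
  ws <- apply(utils::combn(length(pooled), n), 2,
              function(idx) sum(r[idx]))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}
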