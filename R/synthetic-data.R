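#' Synthetic single-cell and bulk data with planted ground truth
#'
#' The generator emulates the statistical structure this pipeline consumes:
#' negative-binomial counts with heterogeneous per-gene baseline means, six
#' brain cell types with elevated canonical markers, a configurable fraction
#' of high-mitochondrial-content cells, condition-dependent elevation of
#' planted ligand/receptor genes in chosen sender/receiver types, and bulk
#' matrices with planted subtype-specific ligand-vs-receptor rank reversals.
#'
#' @name synthetic_data
NULL

#' The six brain cell types used throughout
#' @export
brain_cell_types <- function() {
  c("astrocytes", "endothelial cells", "microglia",
    "neurons", "OPC", "oligodendrocytes")
}

#' Canonical marker genes per brain cell type
#'
#' Five markers per type (e.g. astrocytes: GFAP; endothelial cells: CLDN5;
#' microglia: CX3CR1, CSF1R; neurons: SLC17A7; OPC: PDGFRA;
#' oligodendrocytes: MAG, OLIG2). The synthetic generator names its marker
#' genes with these symbols so annotation can be exercised end to end.
#'
#' @return Named list, cell type -> character vector of gene symbols.
#' @export
brain_marker_db <- function() {
  list(
    "astrocytes"        = c("GFAP", "AQP4", "SLC1A2", "ALDH1L1", "GJA1"),
    "endothelial cells" = c("CLDN5", "FLT1", "PECAM1", "VWF", "A2M"),
    "microglia"         = c("CX3CR1", "CSF1R", "P2RY12", "AIF1", "TMEM119"),
    "neurons"           = c("SLC17A7", "SNAP25", "RBFOX3", "SYT1", "GAD1"),
    "OPC"               = c("PDGFRA", "CSPG4", "OLIG1", "VCAN", "LHFPL3"),
    "oligodendrocytes"  = c("MAG", "OLIG2", "MBP", "MOG", "PLP1")
  )
}

#' Single-cell simulation configuration
#'
#' @param n_cells_per_type cells simulated per cell type.
#' @param cell_types character vector of distinct type names (default the
#'   six brain types).
#' @param n_genes total genes, including markers and mitochondrial genes.
#' @param n_mito_genes number of mitochondrial genes (named `MT-1`, ...).
#' @param nb_mean baseline negative-binomial mean; per-gene baselines are
#'   drawn log-normally around it so expression spans a realistic dynamic
#'   range; marker, program and planted genes sit exactly at `nb_mean`.
#' @param gene_mean_sdlog log-scale spread of the per-gene baseline means
#'   (default 1; 0 pins every baseline to `nb_mean`).
#' @param nb_dispersion NB size parameter; variance = mean + mean^2 / size.
#'   The default 2 corresponds to a squared biological coefficient of
#'   variation of 0.5, typical of UMI counts.
#' @param marker_fold fold elevation (>= 1) of a type's markers and program
#'   genes in own type.
#' @param n_program_genes besides its named markers, each type elevates a
#'   disjoint block of this many "program" genes (default 25), emulating
#'   the broad transcriptional programs that make real cell types
#'   separable; program genes are the last filler genes of the universe,
#'   so they never collide with planted communication genes (which should
#'   use low-numbered `GENE` ids).
#' @param planted_pairs data.frame with columns `ligand`, `receptor`,
#'   `sender`, `receiver`, `condition`, `signal_fold`: under a sub-dataset
#'   whose labels include `condition`, the ligand mean is multiplied by
#'   `signal_fold` in sender cells and the receptor mean in receiver cells.
#' @param mito_high_fraction fraction of cells simulated with expected
#'   mitochondrial content above 20%.
#' @param lr_genes genes given a cell-type-structured baseline, emulating
#'   how real ligands and receptors are expressed in specific "home"
#'   types: mean `nb_mean / 4` off-home and `lr_home_fold` times that in
#'   the gene's home type (assigned deterministically from the gene name,
#'   never a type where the gene carries a planted signal). Defaults to
#'   all planted ligand/receptor genes.
#' @param lr_home_fold home-type elevation of `lr_genes` (default 8).
#' @param markers named list type -> marker symbols (default
#'   [brain_marker_db()], truncated to `cell_types`).
#' @param seed integer master seed; gene baselines depend only on it, count
#'   noise also on the sample id, so sub-datasets share structure but not
#'   noise.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_type = 100,
                       cell_types = brain_cell_types(),
                       n_genes = 300,
                       n_mito_genes = 10,
                       nb_mean = 0.5,
                       nb_dispersion = 2,
                       gene_mean_sdlog = 1,
                       marker_fold = 4,
                       n_program_genes = 25,
                       planted_pairs = NULL,
                       mito_high_fraction = 0,
                       lr_genes = NULL,
                       lr_home_fold = 8,
                       markers = NULL,
                       seed = 1L) {
  if (anyDuplicated(cell_types)) stopf("cell_types has duplicates")
  if (n_cells_per_type < 1 || n_genes < 1 || n_mito_genes < 0)
    stopf("counts must be positive")
  if (nb_mean <= 0 || nb_dispersion <= 0) stopf("NB parameters must be > 0")
  if (gene_mean_sdlog < 0) stopf("gene_mean_sdlog must be nonnegative")
  if (marker_fold < 1) stopf("marker_fold must be >= 1")
  if (mito_high_fraction < 0 || mito_high_fraction > 1)
    stopf("mito_high_fraction must lie in [0,1]")
  if (is.null(markers)) markers <- brain_marker_db()[
    intersect(names(brain_marker_db()), cell_types)]
  if (!is.null(planted_pairs)) {
    need <- c("ligand", "receptor", "sender", "receiver",
              "condition", "signal_fold")
    if (!all(need %in% names(planted_pairs)))
      stopf("planted_pairs needs columns %s", paste(need, collapse = ", "))
    if (any(planted_pairs$signal_fold < 1))
      stopf("all signal_fold values must be >= 1")
    if (!all(planted_pairs$sender %in% cell_types) ||
        !all(planted_pairs$receiver %in% cell_types))
      stopf("planted sender/receiver must be known cell types")
  }
  n_marker <- length(unlist(markers))
  n_fill <- n_genes - n_marker - n_mito_genes
  if (n_fill < length(cell_types) * n_program_genes + 1)
    stopf(paste("n_genes too small: %d markers + %d mito + %d program",
                "genes leave no filler"),
          n_marker, n_mito_genes, length(cell_types) * n_program_genes)
  structure(list(n_cells_per_type = as.integer(n_cells_per_type),
                 cell_types = cell_types, n_genes = as.integer(n_genes),
                 n_mito_genes = as.integer(n_mito_genes), nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion,
                 gene_mean_sdlog = gene_mean_sdlog,
                 marker_fold = marker_fold,
                 n_program_genes = as.integer(n_program_genes),
                 planted_pairs = planted_pairs,
                 mito_high_fraction = mito_high_fraction,
                 lr_genes = unique(c(lr_genes,
                                     planted_pairs$ligand,
                                     planted_pairs$receptor)),
                 lr_home_fold = lr_home_fold,
                 markers = markers, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic gene universe: markers, filler genes, mito genes.
sim_gene_universe <- function(config) {
  marker_genes <- unlist(config$markers, use.names = FALSE)
  n_fill <- config$n_genes - length(marker_genes) - config$n_mito_genes
  fill <- sprintf("GENE%04d", seq_len(n_fill))
  mito <- if (config$n_mito_genes > 0)
    paste0("MT-", seq_len(config$n_mito_genes)) else character()
  c(marker_genes, fill, mito)
}

# Per-type program gene blocks: disjoint slices off the tail of the
# filler range, so low-numbered GENE ids stay free for planted pairs.
sim_program_genes <- function(config) {
  genes <- sim_gene_universe(config)
  fill <- grep("^GENE", genes, value = TRUE)
  np <- config$n_program_genes
  if (np == 0) return(setNames(rep(list(character()), length(config$cell_types)),
                               config$cell_types))
  tail_fill <- fill[(length(fill) - np * length(config$cell_types) + 1):
                      length(fill)]
  setNames(split(tail_fill, rep(seq_along(config$cell_types), each = np)),
           config$cell_types)
}

# Small deterministic string hash (< 2^31) for per-sample noise seeds.
str_seed <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

#' Simulate one single-cell sub-dataset
#'
#' Draws genes x cells negative-binomial counts under a [sim_config()].
#' Marker genes are elevated `marker_fold`-fold in their own type; planted
#' ligand/receptor genes are elevated `signal_fold`-fold in sender/receiver
#' cells when one of this sub-dataset's condition labels equals the pair's
#' `condition`; mitochondrial gene means are inflated for a
#' `mito_high_fraction` share of cells so their expected mito content is 35%
#' (5% otherwise). Fully reproducible: gene baselines depend only on
#' `config$seed`; sampling noise also on the sample id.
#'
#' @param config a [sim_config()].
#' @param condition_labels named list/vector with entries `sample`,
#'   `disease`, `sex`, `region` (missing entries default to `"unknown"`).
#' @return A [cell_matrix()] with raw counts; the simulation truth (true
#'   type per cell, high-mito cells, planted table) in `attr(, "truth")`.
#' @export
simulate_sc <- function(config, condition_labels = list()) {
  labels <- list(sample = "S1", disease = "unknown",
                 sex = "unknown", region = "unknown")
  labels[names(condition_labels)] <- condition_labels
  genes <- sim_gene_universe(config)
  pp <- config$planted_pairs
  programs <- sim_program_genes(config)
  if (!is.null(pp)) {
    missing <- setdiff(unique(c(pp$ligand, pp$receptor)), genes)
    if (length(missing))
      stopf("planted gene(s) not in gene universe: %s",
            paste(missing, collapse = ", "))
    clash <- intersect(unique(c(pp$ligand, pp$receptor)),
                       unlist(programs))
    if (length(clash))
      stopf("planted gene(s) collide with program-gene block: %s",
            paste(clash, collapse = ", "))
  }

  types <- rep(config$cell_types, each = config$n_cells_per_type)
  n_cells <- length(types)
  marker_genes <- unlist(config$markers, use.names = FALSE)
  mito <- grepl("^MT-", genes)
  special <- genes %in% c(marker_genes, unlist(programs)) |
    genes %in% c(pp$ligand, pp$receptor)

  lr_set <- intersect(config$lr_genes, genes)
  bad_lr <- setdiff(config$lr_genes, genes)
  if (length(bad_lr))
    stopf("lr_gene(s) not in gene universe: %s",
          paste(bad_lr, collapse = ", "))

  # structural layer: shared across sub-datasets from the same config
  structural <- with_seed(config$seed, {
    base <- rlnorm(length(genes), meanlog = log(config$nb_mean),
                   sdlog = config$gene_mean_sdlog)
    base[special] <- config$nb_mean
    base[mito] <- config$nb_mean / 2
    base[genes %in% lr_set] <- config$nb_mean / 4
    base
  })

  # deterministic home type per ligand/receptor gene, avoiding any type
  # where the gene carries a planted signal
  home_of <- setNames(integer(0), character(0))
  if (length(lr_set)) {
    n_ty <- length(config$cell_types)
    home_of <- setNames((vapply(lr_set, str_seed, 0L) %% n_ty) + 1L, lr_set)
    if (!is.null(pp)) {
      for (g in lr_set) {
        sig_ty <- unique(c(pp$sender[pp$ligand == g],
                           pp$receiver[pp$receptor == g]))
        sig_idx <- match(sig_ty, config$cell_types)
        while (home_of[g] %in% sig_idx)
          home_of[g] <- home_of[g] %% n_ty + 1L
      }
    }
  }

  mu <- matrix(structural, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, NULL))
  for (ty in names(config$markers)) {
    sig <- c(config$markers[[ty]], programs[[ty]])
    mu[sig, types == ty] <- mu[sig, types == ty] * config$marker_fold
  }
  for (g in names(home_of)) {
    ty <- config$cell_types[home_of[g]]
    mu[g, types == ty] <- mu[g, types == ty] * config$lr_home_fold
  }
  if (!is.null(pp)) {
    active <- pp$condition %in% unlist(labels)
    for (i in which(active)) {
      mu[pp$ligand[i], types == pp$sender[i]] <-
        mu[pp$ligand[i], types == pp$sender[i]] * pp$signal_fold[i]
      mu[pp$receptor[i], types == pp$receiver[i]] <-
        mu[pp$receptor[i], types == pp$receiver[i]] * pp$signal_fold[i]
    }
  }

  noise_seed <- (config$seed + str_seed(labels$sample)) %% 2147483647
  out <- with_seed(noise_seed, {
    high <- rep(FALSE, n_cells)
    n_high <- round(config$mito_high_fraction * n_cells)
    if (n_high > 0) high[sample.int(n_cells, n_high)] <- TRUE
    if (any(mito)) {
      nonmito_total <- Matrix::colSums(mu[!mito, , drop = FALSE])
      frac <- ifelse(high, 0.35, 0.05)
      target <- frac / (1 - frac) * nonmito_total
      mu[mito, ] <- matrix(rep(target / sum(mito), each = sum(mito)),
                           nrow = sum(mito))
    }
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = config$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    list(counts = counts, high = high)
  })

  colnames(out$counts) <- sprintf("%s_c%05d", labels$sample, seq_len(n_cells))
  meta <- data.frame(sample = labels$sample, disease = labels$disease,
                     sex = labels$sex, region = labels$region,
                     stringsAsFactors = FALSE)
  meta <- meta[rep(1, n_cells), , drop = FALSE]
  m <- cell_matrix(methods::as(out$counts, "CsparseMatrix"), meta,
                   gene_meta = data.frame(mito = mito))
  attr(m, "truth") <- list(cell_type = types, high_mito = out$high,
                           planted = pp, markers = config$markers,
                           programs = programs,
                           lr_home = if (length(home_of))
                             setNames(config$cell_types[home_of],
                                      names(home_of)))
  m
}

#' Annotate a simulated matrix with its ground-truth cell types
#'
#' Copies the generator's true cell-type assignment into
#' `cell_meta$cell_type`, bypassing clustering — useful when a downstream
#' stage is studied in isolation.
#'
#' @param m a [cell_matrix()] from [simulate_sc()].
#' @return The matrix with `cell_type` metadata set.
#' @export
annotate_truth <- function(m) {
  truth <- attr(m, "truth")
  if (is.null(truth)) stopf("matrix carries no simulation truth")
  m$cell_meta$cell_type <- truth$cell_type
  m
}

#' Bulk simulation configuration
#'
#' @param n_normal,n_disease sample counts; `n_disease >= n_subtypes`.
#' @param n_subtypes planted disease subtypes.
#' @param edges_per_subtype ligand-receptor pairs whose ligand/receptor
#'   ordering each subtype inverts.
#' @param rank_shift additive log2-scale shift: each subtype's ligands are
#'   lowered and receptors raised by this amount relative to baseline.
#' @param noise_sd per-entry Gaussian noise on the log2 scale.
#' @param n_background extra background genes providing ranking context.
#' @param seed integer seed.
#' @return Object of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_normal = 20, n_disease = 80, n_subtypes = 4,
                            edges_per_subtype = 10, rank_shift = 4,
                            noise_sd = 0.5, n_background = 100, seed = 1L) {
  if (n_disease < n_subtypes) stopf("n_disease must be >= n_subtypes")
  if (edges_per_subtype < 1) stopf("edges_per_subtype must be >= 1")
  if (rank_shift < 0 || noise_sd < 0) stopf("shift/noise must be nonnegative")
  structure(list(n_normal = as.integer(n_normal),
                 n_disease = as.integer(n_disease),
                 n_subtypes = as.integer(n_subtypes),
                 edges_per_subtype = as.integer(edges_per_subtype),
                 rank_shift = rank_shift, noise_sd = noise_sd,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate a bulk expression dataset with planted disease subtypes
#'
#' Normal samples share one log2-scale baseline profile plus Gaussian noise.
#' Each of the `n_subtypes` disease subtypes takes `edges_per_subtype`
#' consecutive pairs from `pairs` (complexes expanded to subunit-level
#' edges) and inverts their ligand-vs-receptor ordering: ligand genes are
#' lowered and receptor genes raised by `rank_shift` on the log2 scale.
#' A gene claimed by two subtypes' edge sets is an allocation error.
#'
#' @param config a [bulk_sim_config()].
#' @param pairs list of [lr_pair()]; at least
#'   `n_subtypes * edges_per_subtype` of them.
#' @return List with `expr` (genes x samples, log2 scale), `labels`
#'   (data.frame sample/status), `subtype` (named vector, disease samples),
#'   `edges` (data.frame ligand/receptor/subtype).
#' @export
simulate_bulk <- function(config, pairs) {
  need <- config$n_subtypes * config$edges_per_subtype
  if (length(pairs) < need)
    stopf("need at least %d pairs for %d subtypes x %d edges",
          need, config$n_subtypes, config$edges_per_subtype)
  alloc <- split(pairs[seq_len(need)],
                 rep(seq_len(config$n_subtypes),
                     each = config$edges_per_subtype))
  edges <- do.call(rbind, lapply(seq_along(alloc), function(k) {
    e <- expand_pair_edges(alloc[[k]])
    e$subtype <- k
    e
  }))
  shifted_genes <- c(edges$ligand, edges$receptor)
  if (anyDuplicated(unique(data.frame(g = shifted_genes,
                                      s = rep(edges$subtype, 2)))$g))
    stopf("overlapping edge allocation: a gene is claimed by two subtypes")

  genes <- c(unique(c(edges$ligand, edges$receptor)),
             sprintf("BG%04d", seq_len(config$n_background)))
  with_seed(config$seed, {
    baseline <- rnorm(length(genes), mean = 8, sd = 2)
    names(baseline) <- genes
    n_tot <- config$n_normal + config$n_disease
    expr <- matrix(baseline, nrow = length(genes), ncol = n_tot,
                   dimnames = list(genes, c(
                     sprintf("N%03d", seq_len(config$n_normal)),
                     sprintf("D%03d", seq_len(config$n_disease)))))
    subtype <- rep(seq_len(config$n_subtypes),
                   length.out = config$n_disease)
    for (j in seq_len(config$n_disease)) {
      e <- edges[edges$subtype == subtype[j], ]
      col <- config$n_normal + j
      expr[unique(e$ligand), col] <-
        expr[unique(e$ligand), col] - config$rank_shift
      expr[unique(e$receptor), col] <-
        expr[unique(e$receptor), col] + config$rank_shift
    }
    expr <- expr + matrix(rnorm(length(expr), sd = config$noise_sd),
                          nrow = nrow(expr))
    labels <- data.frame(
      sample = colnames(expr),
      status = rep(c("normal", "disease"),
                   c(config$n_normal, config$n_disease)),
      stringsAsFactors = FALSE)
    names(subtype) <- colnames(expr)[labels$status == "disease"]
    list(expr = expr, labels = labels, subtype = subtype,
         edges = edges[c("ligand", "receptor", "subtype")])
  })
}

#' Expand ligand-receptor pairs to single-gene edges
#'
#' Complex subunits are expanded into all (ligand gene, receptor gene)
#' combinations; duplicates removed.
#'
#' @param pairs list of [lr_pair()].
#' @return data.frame with columns `ligand`, `receptor`, `pair_id`.
#' @export
expand_pair_edges <- function(pairs) {
  out <- do.call(rbind, lapply(pairs, function(p) {
    g <- expand.grid(ligand = p$ligand_units, receptor = p$receptor_units,
                     stringsAsFactors = FALSE)
    g$pair_id <- p$pair_id
    g
  }))
  out[!duplicated(out[c("ligand", "receptor")]), , drop = FALSE]
}

#' Write a bulk dataset as TSV
#'
#' @param bulk result of [simulate_bulk()] (or any list with `expr` and
#'   `labels`).
#' @param dir output directory; writes `expr.tsv` and `labels.tsv`.
#' @export
write_bulk_dataset <- function(bulk, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(gene = rownames(bulk$expr), bulk$expr,
                         check.names = FALSE),
              file.path(dir, "expr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bulk$labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
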