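test_that("mito filter keeps cells at or below 20% and is idempotent", {
  m <- mito_fixture()   # fractions 0, .10, .20, .21, .50
  f <- filter_cells(m)
  expect_equal(ncol(f$counts), 3)
  expect_equal(colnames(f$counts), c("c1", "c2", "c3"))
  expect_equal(attr(f, "n_removed"), 2)
  # idempotent
  f2 <- filter_cells(f)
  expect_equal(as.matrix(f2$counts), as.matrix(f$counts))

  # no flagged mito genes: everything kept
  m0 <- m
  m0$gene_meta$mito <- FALSE
  expect_equal(ncol(filter_cells(m0)$counts), 5)

  # zero-total cell is removed with a message
  counts <- cbind(a = c(1, 1), b = c(0, 0))
  rownames(counts) <- c("G1", "G2")
  mz <- cell_matrix(counts, data.frame(sample = "S"))
  expect_message(fz <- filter_cells(mz), "zero total")
  expect_equal(colnames(fz$counts), "a")
})

test_that("log-normalization scales every cell to the target total", {
  counts <- cbind(a = c(1, 1, 0))
  rownames(counts) <- c("G1", "G2", "G3")
  m <- normalize_log(cell_matrix(counts, data.frame(sample = "S")))
  expect_equal(as.numeric(m$values[1:2, 1]),
               rep(log(1 + 5000), 2))
  expect_equal(as.numeric(m$values[3, 1]), 0)   # all-zero gene stays zero

  # back-transform property on a random matrix
  set.seed(8)
  counts <- matrix(rpois(600, 3), 30, 20,
                   dimnames = list(sprintf("G%02d", 1:30),
                                   sprintf("c%02d", 1:20)))
  counts[1, ] <- pmax(counts[1, ], 1)    # no zero-total cells
  m <- normalize_log(cell_matrix(counts, data.frame(sample = "S")))
  totals <- Matrix::colSums(expm1(m$values))
  expect_true(all(abs(totals - 10000) < 1e-6))

  # library-size invariance: scaling one cell's counts changes nothing
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7L
  m2 <- normalize_log(cell_matrix(scaled, data.frame(sample = "S")))
  expect_equal(as.numeric(m2$values[, 3]), as.numeric(m$values[, 3]))
})

test_that("variable-gene selection ranks planted dispersion first", {
  set.seed(5)
  n_flat <- 200
  flat_mu <- exp(runif(n_flat, log(0.5), log(8)))   # spread of means
  counts <- matrix(rnbinom(n_flat * 100, mu = flat_mu, size = 50),
                   n_flat, 100)
  hot <- matrix(rnbinom(20 * 100, mu = 2, size = 0.05), 20, 100)
  counts <- rbind(counts, hot)
  rownames(counts) <- c(sprintf("FLAT%03d", 1:n_flat),
                        sprintf("HOT%02d", 1:20))
  colnames(counts) <- sprintf("c%03d", 1:100)
  counts[1, ] <- pmax(counts[1, ], 1)
  m <- normalize_log(cell_matrix(counts, data.frame(sample = "S")))
  top50 <- select_hvg(m, 50)
  expect_equal(sum(grepl("^HOT", top50)), 20)

  # constant gene is never selected while any gene varies
  counts2 <- rbind(CONST = rep(5L, 100), counts)
  m2 <- normalize_log(cell_matrix(counts2, data.frame(sample = "S")))
  expect_false("CONST" %in% select_hvg(m2, 100))

  # n beyond the gene count returns everything with a warning
  expect_warning(all_g <- select_hvg(m, 10000), "returning all")
  expect_setequal(all_g, rownames(counts))
})

test_that("clustering separates planted populations", {
  # two well-separated populations -> exactly 2 clusters, perfect ARI
  set.seed(2)
  mu <- matrix(0.2, 40, 120)
  mu[1:20, 1:60] <- 4
  mu[21:40, 61:120] <- 4
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 5),
                   nrow(mu), dimnames = list(sprintf("G%02d", 1:40),
                                             sprintf("c%03d", 1:120)))
  counts[1, ] <- pmax(counts[1, ], 1)
  m <- normalize_log(cell_matrix(counts, data.frame(sample = "S")))
  cl <- embed_cluster(m, n_pcs = 10, seed = 1)
  truth <- rep(c(1, 2), each = 60)
  expect_equal(length(unique(cl)), 2)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1)

  # all cells identical -> a single cluster
  const <- matrix(3L, 20, 30, dimnames = list(sprintf("G%02d", 1:20),
                                              sprintf("c%02d", 1:30)))
  mc <- normalize_log(cell_matrix(const, data.frame(sample = "S")))
  expect_equal(length(unique(embed_cluster(mc, n_pcs = 5, seed = 1))), 1)

  expect_error(embed_cluster(mc, n_pcs = 50, seed = 1), "n_pcs")
})

test_that("six planted brain cell types are recovered and annotated", {
  cfg <- sim_config(n_cells_per_type = 60, n_genes = 350, seed = 7)
  m <- simulate_sc(cfg, list(sample = "S1", disease = "AD"))
  truth <- attr(m, "truth")$cell_type
  mn <- normalize_log(filter_cells(m))
  hvg <- select_hvg(mn, 200)
  cl <- embed_cluster(mn, genes = hvg, n_pcs = 20, seed = 1)
  expect_gte(mclust::adjustedRandIndex(cl, truth), 0.95)

  ann <- annotate_clusters(mn, cl, brain_marker_db())
  # every cluster maps to the type that dominates it
  for (k in sort(unique(cl))) {
    dominant <- names(which.max(table(truth[cl == k])))
    expect_equal(unname(ann$cluster_type[as.character(k)]), dominant)
  }
  expect_equal(sort(unique(ann$cell_type)), sort(brain_cell_types()))
})

test_that("annotation falls back to 'other cells' without marker signal", {
  set.seed(31)
  genes <- c("GFAP", "CLDN5", "OTHER1", "OTHER2")
  counts <- matrix(rpois(4 * 60, 1), 4, 60,
                   dimnames = list(genes, sprintf("c%02d", 1:60)))
  counts["GFAP", 1:30] <- rpois(30, 20)        # cluster 0 = astrocytes
  counts[1, ] <- pmax(counts[1, ], 1)
  m <- normalize_log(cell_matrix(counts, data.frame(sample = "S")))
  labels <- rep(c(0L, 1L), each = 30)
  ann <- annotate_clusters(m, labels, brain_marker_db())
  expect_equal(unname(ann$cluster_type["0"]), "astrocytes")
  expect_equal(unname(ann$cluster_type["1"]), "other cells")

  expect_error(annotate_clusters(m, rep(0L, 60),
                                 brain_marker_db(), alpha = 0),
               NA)   # degenerate thresholds still run
})

test_that("marker table fixture round-trips into a marker db", {
  db <- read_marker_db(system.file("extdata", "brain_markers.tsv",
                                   package = "braincomm"))
  expect_setequal(names(db), brain_cell_types())
  expect_true("GFAP" %in% db$astrocytes)
  expect_true("CLDN5" %in% db[["endothelial cells"]])
})
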