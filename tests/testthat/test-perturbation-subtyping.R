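toy_edges <- data.frame(ligand = c("gB", "gA"), receptor = c("gC", "gB"))

test_that("rank transform uses average ranks and rejects missing genes", {
  expr <- cbind(s1 = c(0.1, 5.0, 3.0), s2 = c(2, 2, 5))
  rownames(expr) <- c("gA", "gB", "gC")
  r <- rank_transform(expr)
  expect_equal(unname(r[, "s1"]), c(1, 3, 2))
  expect_equal(unname(r[, "s2"]), c(1.5, 1.5, 3))
  expect_error(rank_transform(expr, c("gA", "gZ")), "gZ")

  # rank invariance under any strictly increasing transform
  expect_equal(rank_transform(exp(expr)), r)
  expect_equal(rank_transform(expr * 100 - 3), r)
})

test_that("edge values are antisymmetric rank differences", {
  ranks <- cbind(s1 = c(3, 1, 2))
  rownames(ranks) <- c("gA", "gB", "gC")
  e <- edge_matrix(ranks, data.frame(ligand = "gA", receptor = "gB"))
  expect_equal(unname(e[1, 1]), 2)
  e_rev <- edge_matrix(ranks, data.frame(ligand = "gB", receptor = "gA"))
  expect_equal(unname(e_rev[1, 1]), -2)
  # tied genes give a zero edge
  ranks2 <- cbind(s1 = c(1.5, 1.5, 3))
  rownames(ranks2) <- rownames(ranks)
  expect_equal(unname(edge_matrix(ranks2, data.frame(ligand = "gA",
                                                     receptor = "gB"))[1, 1]),
               0)
})

test_that("normal reference ranks mean expression across samples", {
  # means {gA: 1, gB: 4, gC: 2}; edge (gB, gC) -> rank 3 - rank 2 = 1
  normal <- cbind(n1 = c(1, 4, 2), n2 = c(1, 4, 2))
  rownames(normal) <- c("gA", "gB", "gC")
  ref <- reference_edges(normal, data.frame(ligand = "gB",
                                            receptor = "gC"))
  expect_equal(unname(ref), 1)

  # single normal sample: reference equals that sample's edge column
  one <- normal[, 1, drop = FALSE]
  r1 <- reference_edges(one, toy_edges)
  e1 <- edge_matrix(rank_transform(one), toy_edges)
  expect_equal(unname(r1), unname(e1[, 1]))
  expect_error(reference_edges(normal[, 0], toy_edges), "normal sample")
})

test_that("perturbation vanishes for reference-identical rankings", {
  normal <- cbind(n1 = c(1, 4, 2))
  rownames(normal) <- c("gA", "gB", "gC")
  ref <- reference_edges(normal, toy_edges)
  # disease sample with the same ordering (different scale)
  disease <- cbind(d1 = c(10, 40, 20), d2 = c(40, 10, 20))
  rownames(disease) <- rownames(normal)
  P <- perturbation(edge_matrix(rank_transform(disease), toy_edges), ref)
  expect_true(all(P[, "d1"] == 0))
  expect_false(all(P[, "d2"] == 0))
  bad <- edge_matrix(rank_transform(disease),
                     data.frame(ligand = "gA", receptor = "gC"))
  expect_error(perturbation(bad, ref), "edge universes")
})

test_that("the perturbation matrix is rank-invariant end to end", {
  pairs <- load_lr_database(system.file("extdata",
                                        "lr_pairs_synthetic.tsv",
                                        package = "braincomm"))
  b <- simulate_bulk(bulk_sim_config(n_normal = 6, n_disease = 10,
                                     n_subtypes = 2, edges_per_subtype = 4,
                                     seed = 5), pairs)
  P1 <- perturbation_from_bulk(b$expr, b$labels, b$edges)
  # strictly increasing per-sample transforms of the disease samples
  # (the normal reference is defined on the mean normal profile)
  tr <- b$expr
  dis <- b$labels$sample[b$labels$status == "disease"]
  tr[, dis[1:5]] <- exp(tr[, dis[1:5]])
  tr[, dis[6:10]] <- tr[, dis[6:10]]^3 + 10
  P2 <- perturbation_from_bulk(tr, b$labels, b$edges)
  expect_identical(P1, P2)
})

test_that("PAM with restarts reaches the exhaustive medoid optimum", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    fit <- pam_kmedoids(d, 2)
    combs <- utils::combn(n, 2)
    best <- min(apply(combs, 2, function(mds) pam_cost(d, mds)))
    expect_equal(fit$cost, best, tolerance = 1e-9)
  }
})

test_that("consensus clustering recovers planted subtypes and K", {
  pairs <- load_lr_database(system.file("extdata",
                                        "lr_pairs_synthetic.tsv",
                                        package = "braincomm"))
  b <- simulate_bulk(bulk_sim_config(n_normal = 20, n_disease = 80,
                                     n_subtypes = 4, edges_per_subtype = 10,
                                     rank_shift = 4, noise_sd = 0.5,
                                     seed = 3), pairs)
  P <- perturbation_from_bulk(b$expr, b$labels, b$edges)
  cons <- consensus_cluster(P, k_range = 2:6, reps = 100, seed = 3)
  expect_equal(cons$k, 4)
  expect_equal(mclust::adjustedRandIndex(cons$labels,
                                         b$subtype[names(cons$labels)]), 1)

  # determinism under a fixed seed
  cons2 <- consensus_cluster(P, k_range = 2:6, reps = 100, seed = 3)
  expect_identical(cons, cons2)

  # consensus matrices are symmetric with unit diagonal in [0, 1]
  for (cm in cons$consensus) {
    expect_equal(cm, t(cm))
    expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
    expect_true(all(cm >= 0 & cm <= 1))
  }
  # delta-area definition: delta(2) = A(2), relative changes after
  expect_equal(unname(cons$delta[1]), unname(cons$area[1]))
  expect_equal(unname(cons$delta[3]),
               unname((cons$area[3] - cons$area[2]) / cons$area[2]))
})

test_that("two point-mass groups yield a binary consensus at K = 2", {
  P <- cbind(matrix(0, 8, 10), matrix(10, 8, 10))
  colnames(P) <- sprintf("s%02d", 1:20)
  rownames(P) <- sprintf("e%02d", 1:8)
  P <- P + matrix(rnorm(length(P), sd = 1e-6), nrow(P))  # break exact ties
  cons <- consensus_cluster(P, k_range = 2:3, reps = 60, seed = 1)
  off <- cons$consensus$K2[upper.tri(cons$consensus$K2)]
  expect_true(all(off %in% c(0, 1)))
  k2 <- pam_kmedoids(as.dist(1 - cons$consensus$K2), 2)$labels
  expect_equal(mclust::adjustedRandIndex(k2, rep(1:2, each = 10)), 1)
})

test_that("per-subtype mean perturbations isolate each planted edge set", {
  pairs <- load_lr_database(system.file("extdata",
                                        "lr_pairs_synthetic.tsv",
                                        package = "braincomm"))
  b <- simulate_bulk(bulk_sim_config(n_normal = 10, n_disease = 40,
                                     n_subtypes = 2, edges_per_subtype = 5,
                                     rank_shift = 5, noise_sd = 0.2,
                                     seed = 9), pairs)
  P <- perturbation_from_bulk(b$expr, b$labels, b$edges)
  em <- subtype_edge_means(P, b$subtype)
  own1 <- rownames(P)[b$edges$subtype == 1]
  expect_lt(mean(em[own1, 1]), mean(em[own1, 2]))  # ligand drop negative
})
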