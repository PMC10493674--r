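types2 <- c("neurons", "microglia")

test_that("profiles summarize per-type expression correctly", {
  counts <- rbind(LIG = c(1, 2, 3, 0, 0, 0, 5, 0, 0, 1),
                  REC = c(0, 0, 0, 2, 2, 2, 1, 1, 1, 1),
                  HK  = rep(3, 10))
  colnames(counts) <- sprintf("c%02d", 1:10)
  m <- cell_matrix(counts, data.frame(sample = "S"))
  m$values <- m$counts          # use raw values so means are checkable
  m$cell_meta$cell_type <- rep(types2, each = 5)
  p <- build_profiles(m)
  expect_equal(unname(p$mean["LIG", "neurons"]), mean(c(1, 2, 3, 0, 0)))
  expect_equal(unname(p$detect["LIG", "neurons"]), 0.6)
  expect_equal(unname(p$detect["HK", ]), c(1, 1),
               ignore_attr = TRUE)
  expect_equal(p$mu, mean(counts))

  # trimean with linear-interpolation quartiles: 0..8 -> 4
  expect_equal(trimean(0:8), 4)
  expect_equal(trimean(c(0, 0, 0, 10)), 0.625)  # Q3 = 2.5 by type-7

  # a type with < 3 cells is excluded with a warning
  m$cell_meta$cell_type <- c(rep("neurons", 8), rep("microglia", 2))
  expect_warning(p2 <- build_profiles(m), "microglia")
  expect_equal(p2$types, "neurons")

  # "other cells" never enter scoring profiles
  m$cell_meta$cell_type <- c(rep("neurons", 5), rep("other cells", 5))
  expect_equal(build_profiles(m)$types, "neurons")
})

test_that("hill score saturates with half-saturation at 0.5", {
  pair <- list(lr_pair("LIG", "REC"))
  mk <- function(l, r) {
    tm <- rbind(LIG = c(l, 0), REC = c(0, r))
    colnames(tm) <- types2
    fake_profile(tm, trimean_mat = tm)
  }
  s <- function(l, r) {
    t <- score_hill(mk(l, r), pair)
    t$score[t$sender == "neurons" & t$receiver == "microglia"]
  }
  expect_equal(s(0, 3), 0)
  expect_equal(s(1, 0.5), 0.5)            # l*r = 0.5
  expect_equal(s(100, 100), 1, tolerance = 1e-3)
  vals <- vapply(c(0.1, 1, 10, 100), function(l) s(l, 1), 0)
  expect_true(all(diff(vals) > 0) && all(vals < 1))
})

test_that("regularized score is 0.5 at l = r = mu and monotone", {
  pair <- list(lr_pair("LIG", "REC"))
  mk <- function(l, r, mu) {
    mm <- rbind(LIG = c(l, 0), REC = c(0, r))
    colnames(mm) <- types2
    fake_profile(mm, mu = mu)
  }
  s <- function(l, r, mu) {
    t <- score_regularized(mk(l, r, mu), pair)
    t$score[t$sender == "neurons" & t$receiver == "microglia"]
  }
  expect_equal(s(2, 2, 2), 0.5)
  expect_equal(s(0, 5, 1), 0)
  vals <- vapply(c(0.5, 1, 2, 4), function(l) s(l, 1, 1), 0)
  expect_true(all(diff(vals) > 0))
  expect_error(score_regularized(mk(1, 1, 0), pair), "zero")
})

test_that("scaled-product score spans [0, 100] with degenerate rules", {
  pair <- list(lr_pair("LIG", "REC"))
  mm <- rbind(LIG = c(4, 1), REC = c(0.5, 2))
  colnames(mm) <- types2
  t <- score_product(fake_profile(mm), pair)
  # ligand maximal in sender, receptor maximal in receiver -> 10 x 10
  expect_equal(t$score[t$sender == "neurons" & t$receiver == "microglia"],
               100)
  expect_equal(t$score[t$sender == "microglia" & t$receiver == "neurons"],
               0)

  # constant nonzero gene scales to 10; constant zero to 0
  mm2 <- rbind(LIG = c(3, 3), REC = c(0, 0))
  colnames(mm2) <- types2
  t2 <- score_product(fake_profile(mm2), pair)
  expect_true(all(t2$score == 0))          # receptor zero everywhere
  mm3 <- rbind(LIG = c(3, 3), REC = c(1, 2))
  colnames(mm3) <- types2
  t3 <- score_product(fake_profile(mm3), pair)
  expect_equal(t3$score[t3$sender == "neurons" & t3$receiver == "microglia"],
               10 * 10)                    # both at scaled max
})

test_that("gated score gates on detection and above-average mean", {
  pair <- list(lr_pair("LIG", "REC"))
  mm <- rbind(LIG = c(2, 0.5), REC = c(1, 3))
  colnames(mm) <- types2

  # ligand detected in only 5% of sender cells -> no entry
  det_low <- rbind(LIG = c(0.05, 0.5), REC = c(0.5, 0.5))
  colnames(det_low) <- types2
  t <- score_gated(fake_profile(mm, detect_mat = det_low), pair)
  expect_false(any(t$sender == "neurons" & t$receiver == "microglia"))

  # both genes pass -> product of means
  det_ok <- matrix(0.5, 2, 2, dimnames = dimnames(mm))
  t2 <- score_gated(fake_profile(mm, detect_mat = det_ok), pair)
  expect_equal(t2$score[t2$sender == "neurons" & t2$receiver == "microglia"],
               2 * 3)

  # uniform expression never exceeds its across-type mean -> no entries
  flat <- matrix(1, 2, 2, dimnames = dimnames(mm))
  t3 <- score_gated(fake_profile(flat, detect_mat = det_ok), pair)
  expect_equal(nrow(t3), 0)
})

test_that("all scorers zero out or drop pairs with silent ligands", {
  pairs <- list(lr_pair("LIG", "RECA+RECB"), lr_pair("GONE", "RECA"))
  mm <- rbind(LIG = c(0, 1), RECA = c(1, 2), RECB = c(2, 1))
  colnames(mm) <- types2
  p <- fake_profile(mm, mu = 1)
  for (f in list(score_hill, score_regularized, score_product)) {
    t <- f(p, pairs)
    # ligand zero in sender 'neurons' -> score 0 from that sender
    expect_true(all(t$score[t$sender == "neurons"] == 0))
    # gene absent from the matrix counts as zero everywhere
    expect_true(all(t$score[t$pair_id == "GONE_RECA"] == 0))
  }
  tg <- score_gated(p, pairs)
  expect_false(any(tg$sender == "neurons"))
  expect_false(any(tg$pair_id == "GONE_RECA"))
})

test_that("raising the planted fold never lowers planted scores", {
  score_at <- function(fold) {
    pp <- data.frame(ligand = "GENE0001", receptor = "GENE0002",
                     sender = "neurons", receiver = "microglia",
                     condition = "AD", signal_fold = fold)
    cfg <- sim_config(n_cells_per_type = 50, n_genes = 250,
                      planted_pairs = pp, seed = 17)
    m <- simulate_sc(cfg, list(sample = "S1", disease = "AD"))
    m <- annotate_truth(normalize_log(filter_cells(m)))
    p <- build_profiles(m)
    pairs <- list(lr_pair("GENE0001", "GENE0002"))
    tabs <- list(score_hill(p, pairs), score_regularized(p, pairs),
                 score_product(p, pairs), score_gated(p, pairs))
    vapply(tabs, function(t) {
      v <- t$score[t$sender == "neurons" & t$receiver == "microglia"]
      if (length(v)) v else 0
    }, 0)
  }
  s1 <- score_at(1); s4 <- score_at(4); s8 <- score_at(8)
  expect_true(all(s4 >= s1 - 1e-9))
  expect_true(all(s8 >= s4 - 1e-9))
  expect_gt(sum(s8), sum(s1))
})
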