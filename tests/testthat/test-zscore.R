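test_that("set z-score is centered, affine-invariant and matches its formula", {
  v <- stats::setNames(c(1, 2, 3, 4, 5, 3), sprintf("G%d", 1:6))
  # members with mean equal to the global mean (3) -> z = 0, p = 1
  res <- set_zscore(v, c("G2", "G6", "G5")) # values 2, 3, 5 -> wait mean 10/3
  res0 <- set_zscore(v, c("G1", "G5", "G6")) # values 1, 5, 3 -> mean 3
  expect_equal(res0$z, 0)
  expect_equal(res0$p_value, 1)
  # explicit formula check
  mem <- c("G1", "G2")
  expect_equal(res$n_measured, 3)
  byhand <- (mean(v[mem]) - mean(v)) * sqrt(2) / stats::sd(v)
  expect_equal(set_zscore(v, mem)$z, byhand)
  # invariant to adding a constant and to positive rescaling
  expect_equal(set_zscore(v + 7, mem)$z, byhand)
  expect_equal(set_zscore(v * 3.5, mem)$z, byhand)
  # degenerate inputs
  expect_error(set_zscore(stats::setNames(rep(1, 5), sprintf("G%d", 1:5)), "G1"),
               "variance")
  expect_null(set_zscore(v, "NOT_THERE"))
  # missing member values reduce n_measured
  v2 <- v; v2["G1"] <- NA
  expect_equal(set_zscore(v2, mem)$n_measured, 1)
})

test_that("the z-score mean scales as delta * sqrt(n) under a planted shift", {
  set.seed(31)
  n_genes <- 2000; n_mem <- 10; reps <- 4000; delta <- 0.5
  genes <- sprintf("G%04d", seq_len(n_genes))
  fc <- matrix(rnorm(n_genes * reps), n_genes, reps,
               dimnames = list(genes, sprintf("R%04d", seq_len(reps))))
  fc[seq_len(n_mem), ] <- fc[seq_len(n_mem), ] + delta
  M <- matrix(0, n_genes, 1); M[seq_len(n_mem), 1] <- 1
  z1 <- as.vector(regnetr:::set_zscore_matrix(M, fc)$z)
  se <- stats::sd(z1) / sqrt(reps)
  expect_lt(abs(mean(z1) - delta * sqrt(n_mem)), 3 * se + 0.02)
  # doubling delta doubles the expected z
  fc2 <- fc; fc2[seq_len(n_mem), ] <- fc2[seq_len(n_mem), ] + delta
  z2 <- as.vector(regnetr:::set_zscore_matrix(M, fc2)$z)
  se2 <- stats::sd(z2) / sqrt(reps)
  expect_lt(abs(mean(z2) - 2 * delta * sqrt(n_mem)), 3 * se2 + 0.04)
})

test_that("under the null about 5% of |z| values exceed 1.96", {
  set.seed(32)
  n_genes <- 1000; n_mem <- 20; draws <- 10000
  v <- rnorm(n_genes)
  M <- vapply(seq_len(draws), function(i) {
    m <- numeric(n_genes); m[sample.int(n_genes, n_mem)] <- 1; m
  }, numeric(n_genes))
  fc <- matrix(v, n_genes, 1,
               dimnames = list(sprintf("G%04d", 1:n_genes), "C1"))
  z <- regnetr:::set_zscore_matrix(M, fc)$z[, 1]
  frac <- mean(abs(z) > 1.96)
  expect_lt(abs(frac - 0.05), 0.05 * 0.3 + 3 * sqrt(0.05 * 0.95 / draws))
})

test_that("condition screen activates overlap-specific signal only", {
  fx <- screen_fixture(delta = 2, parent_delta = 0)
  ov <- all_pairwise_overlaps(fx$tfbs, fx$funcs,
                              universe = rownames(fx$fc), q_max = 1)
  sc <- condition_screen(ov, fx$fc, fx$tfbs, fx$funcs)
  expect_equal(nrow(sc), 1)
  expect_true(sc$activated)
  # oracle: recompute the three z's directly from the definition
  v <- fx$fc[, 1]
  zfun <- function(members) {
    mv <- v[names(v) %in% members]
    (mean(mv) - mean(v)) * sqrt(length(mv)) / stats::sd(v)
  }
  expect_equal(sc$z_overlap, zfun(fx$overlap_genes), tolerance = 1e-12)
  expect_equal(sc$z_tfbs, zfun(fx$tfbs$sets$T1), tolerance = 1e-12)
  expect_equal(sc$z_func, zfun(fx$funcs$sets$F1), tolerance = 1e-12)
  expect_equal(sc$p_overlap, 2 * pnorm(-abs(sc$z_overlap)), tolerance = 1e-12)

  # whole parent set shifted -> parent significant -> not activated
  fx2 <- screen_fixture(delta = 0, parent_delta = 2)
  ov2 <- all_pairwise_overlaps(fx2$tfbs, fx2$funcs,
                               universe = rownames(fx2$fc), q_max = 1)
  sc2 <- condition_screen(ov2, fx2$fc, fx2$tfbs, fx2$funcs)
  expect_false(sc2$activated)
  expect_lte(sc2$q_tfbs, 0.05)
})

test_that("pure noise rarely activates any pair", {
  act <- vapply(1:100, function(s) {
    fx <- screen_fixture(n_genes = 200, set_size = 50, overlap = 20,
                         delta = 0, seed = 4000 + s)
    ov <- all_pairwise_overlaps(fx$tfbs, fx$funcs,
                                universe = rownames(fx$fc), q_max = 1)
    sc <- condition_screen(ov, fx$fc, fx$tfbs, fx$funcs)
    any(sc$activated)
  }, logical(1))
  expect_gte(sum(!act), 95)
})

test_that("activation always implies an overlap q-value at the threshold", {
  fx <- screen_fixture(delta = 2)
  ov <- all_pairwise_overlaps(fx$tfbs, fx$funcs,
                              universe = rownames(fx$fc), q_max = 1)
  for (qs in c(0.02, 0.2)) {
    sc <- condition_screen(ov, fx$fc, fx$tfbs, fx$funcs, q_sig = qs)
    expect_true(all(sc$q_overlap[sc$activated] <= qs))
  }
})

test_that("conditions with too few measured genes are skipped with a warning", {
  fx <- screen_fixture()
  fc <- cbind(fx$fc, C002 = NA_real_)
  ov <- all_pairwise_overlaps(fx$tfbs, fx$funcs,
                              universe = rownames(fc), q_max = 1)
  expect_warning(sc <- condition_screen(ov, fc, fx$tfbs, fx$funcs), "C002")
  expect_false(any(sc$activated[sc$condition == "C002"]))
})
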