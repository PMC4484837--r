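two_group_cm <- function(k, n1, n2) {
  rownames(k) <- paste0("g", seq_len(nrow(k)))
  colnames(k) <- paste0("s", seq_len(ncol(k)))
  count_matrix(k, group = rep(c("A", "B"), c(n1, n2)))
}

test_that("common dispersion: zero for within-group-constant counts, ~0 for Poisson", {
  k <- cbind(c(10, 20), c(10, 20), c(30, 5), c(30, 5))
  cm <- two_group_cm(k, 2, 2)
  expect_equal(estimate_common_dispersion(cm, raw_factors(cm)), 0)

  set.seed(31)
  kp <- matrix(rpois(2000 * 10, lambda = rep(exp(runif(2000, 3, 6)), 10)), 2000, 10)
  cmp <- two_group_cm(kp, 5, 5)
  expect_lt(estimate_common_dispersion(cmp, raw_factors(cmp)), 0.02)

  set.seed(32)
  mu <- exp(runif(2000, 4, 7))
  knb <- matrix(rnbinom(2000 * 10, size = 1 / 0.2, mu = rep(mu, 10)), 2000, 10)
  cmnb <- two_group_cm(knb, 5, 5)
  est <- estimate_common_dispersion(cmnb, raw_factors(cmnb))
  expect_gt(est, 0.1); expect_lt(est, 0.3)
})

test_that("Poisson-limit exact test equals a direct binomial oracle", {
  set.seed(41)
  k <- matrix(rnbinom(100 * 6, size = 5, mu = 60), 100, 6)
  cm <- two_group_cm(k, 3, 3)
  de <- nb_exact_test(cm, raw_factors(cm), phi = 0)
  s1 <- rowSums(k[, 1:3]); s2 <- rowSums(k[, 4:6])
  expected <- mapply(oracle_binom_two_sided, s1, s2, 3, 3)
  expect_equal(de$p_value, unname(expected), tolerance = 1e-12)
})

test_that("balanced symmetric outcome has p = 1 and equal means give zero fold change", {
  cm <- two_group_cm(cbind(5, 5), 1, 1)
  de <- nb_exact_test(cm, raw_factors(cm), phi = 0)
  expect_equal(de$p_value, 1)
  expect_equal(de$log2_fold_change, 0)
  # zero-total gene: p = 1, flagged
  cm0 <- two_group_cm(rbind(c(5, 5), c(0, 0)), 1, 1)
  de0 <- nb_exact_test(cm0, raw_factors(cm0), phi = 0)
  expect_equal(de0$p_value[2], 1)
  expect_true(de0$zero_total[2])
  expect_equal(de0$log2_fold_change[2], 0)
})

test_that("exact-test p-values are invariant to relabeling the groups", {
  set.seed(42)
  k <- matrix(rnbinom(60 * 8, size = 5, mu = 80), 60, 8)
  cm1 <- two_group_cm(k, 4, 4)
  cm2 <- cm1
  cm2$group <- factor(rev(as.character(cm1$group)), levels = c("B", "A"))
  for (phi in c(0, 0.15)) {
    d1 <- nb_exact_test(cm1, raw_factors(cm1), phi = phi)
    d2 <- nb_exact_test(cm2, raw_factors(cm2), phi = phi)
    expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
  }
})

test_that("uniform count scaling leaves binomial-limit p-values unchanged", {
  set.seed(43)
  k <- matrix(rnbinom(50 * 6, size = 5, mu = 40), 50, 6)
  cm1 <- two_group_cm(k, 3, 3)
  cm2 <- two_group_cm(k * 2L, 3, 3)
  d1 <- nb_exact_test(cm1, raw_factors(cm1), phi = 0, total_cap = 1e9)
  d2 <- nb_exact_test(cm2, raw_factors(cm2), phi = 0, total_cap = 1e9)
  # doubling all counts sharpens each gene's test symmetrically; the binomial
  # conditioning keeps p-values ordered the same and highly correlated
  expect_gt(cor(log(d1$p_value), log(d2$p_value)), 0.98)
})

test_that("BH adjustment matches a hand-stepped oracle and contracts hold", {
  p <- c(0.01, 0.04, 0.03)
  expect_equal(adjust_p_values(p), c(0.03, 0.04, 0.04))
  expect_equal(adjust_p_values(p), oracle_bh(p))
  set.seed(44)
  pr <- runif(200)
  expect_equal(adjust_p_values(pr), oracle_bh(pr))
  expect_true(all(adjust_p_values(pr) >= pr))
  expect_equal(adjust_p_values(0.2), 0.2)          # single p unchanged
  expect_equal(adjust_p_values(rep(1, 5)), rep(1, 5))
  expect_error(adjust_p_values(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling is ordered, thresholded and monotone in alpha", {
  set.seed(45)
  sim <- generate_counts(synthetic_spec(300, c(5, 5), phi = 0.05,
                                        de_fraction = 0.1, seed = 45))
  de <- nb_exact_test(sim$cm, raw_factors(sim$cm), phi = 0.05)
  degs10 <- call_degs(de, 0.10)
  degs05 <- call_degs(de, 0.05)
  degs001 <- call_degs(de, 0.001)
  expect_true(all(degs05 %in% degs10))
  expect_true(all(degs001 %in% degs05))
  adj <- de$adj_p_value[match(degs05, de$gene_id)]
  expect_true(!is.unsorted(adj))
  # perfectly balanced counts: nothing can be called at any threshold
  flat <- two_group_cm(matrix(rep(c(10, 25, 40), 4), 3), 2, 2)
  de_flat <- nb_exact_test(flat, raw_factors(flat), phi = 0)
  expect_length(call_degs(de_flat, 0.05), 0L)
})

test_that("MA coordinates are views of the result", {
  sim <- generate_counts(synthetic_spec(200, c(3, 3), phi = 0.05, seed = 46))
  de <- nb_exact_test(sim$cm, raw_factors(sim$cm), phi = 0.05)
  mv <- ma_values(de)
  expect_equal(nrow(mv) + attr(mv, "n_omitted"), nrow(de))
  expect_true(all(mv$A == log10(de$base_mean[de$base_mean > 0])))
  i <- which(de$gene_id == mv$gene_id[1])
  expect_equal(mv$M[1], de$log2_fold_change[i])
})

test_that("null false-positive rate is calibrated and strong DE is powered", {
  sim <- generate_counts(synthetic_spec(2000, c(5, 5), phi = 0.1,
                                        size_factors = rep(1, 10), seed = 51))
  de <- nb_exact_test(sim$cm, raw_factors(sim$cm), phi = 0.1)
  fpr <- mean(de$p_value < 0.05)
  expect_gte(fpr, 0.03); expect_lte(fpr, 0.07)

  simde <- generate_counts(synthetic_spec(1000, c(5, 5), phi = 0.1,
                                          de_fraction = 0.1, log2fc = 2,
                                          seed = 52))
  sf <- median_ratio_factors(simde$cm)
  dede <- nb_exact_test(simde$cm, sf, phi = 0.1)
  degs <- call_degs(dede, 0.05)
  power <- mean(simde$truth$de_genes %in% degs)
  expect_gt(power, 0.8)
})
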