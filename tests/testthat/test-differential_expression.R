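test_that("size factors follow the median-of-ratios definition", {
  cnt <- make_counts(200, mu = 200, disp = 0.05, seed = 1)
  doubled <- cbind(col1 = cnt[, 1], col2 = 2L * cnt[, 1])
  expect_equal(unname(size_factors_median_of_ratios(doubled)),
               c(1 / sqrt(2), sqrt(2)))
  same <- cbind(a = cnt[, 1], b = cnt[, 1], c = cnt[, 1])
  expect_equal(unname(size_factors_median_of_ratios(same)), rep(1, 3))
  expect_equal(unname(size_factors_median_of_ratios(cnt[, 1, drop = FALSE])),
               1)
  # independent oracle: DESeq2's implementation (up to its geometric-mean
  # scaling convention)
  sf <- size_factors_median_of_ratios(cnt)
  sf_deseq <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(unname(sf / exp(mean(log(sf)))),
               unname(sf_deseq / exp(mean(log(sf_deseq)))), tolerance = 1e-10)
  # all-zero-containing genes: positive-subset fallback warns
  cnt0 <- cnt
  cnt0[, 1][seq(1, 200, 2)] <- 0L
  cnt0[, 2][seq(2, 200, 2)] <- 0L
  cnt0[cbind(1:200, sample(3:6, 200, TRUE))] <- 0L
  has_all_pos <- any(rowSums(cnt0 > 0) == ncol(cnt0))
  if (!has_all_pos) expect_warning(size_factors_median_of_ratios(cnt0), "positive")
})

test_that("cross-normalization uses the supplied factors and validates input", {
  cnt <- make_counts(50, mu = 100, disp = 0.05, seed = 2)
  expect_equal(unname(apply_cross_normalization(cnt, rep(1, 6))),
               unname(cnt), ignore_attr = TRUE)
  norm <- apply_cross_normalization(cnt, c(2, 1, 1, 1, 1, 1))
  expect_equal(norm[, 1], cnt[, 1] / 2)
  expect_error(apply_cross_normalization(cnt, rep(1, 3)), "one size factor")
  expect_error(apply_cross_normalization(cnt, c(0, rep(1, 5))), "positive")
})

test_that("log2 fold changes are invariant to common count scaling", {
  # the NB MLE is invariant up to the (tiny) change in the Poisson part of
  # the mean-variance decomposition when counts are rescaled
  cnt <- make_counts(100, mu = 300, disp = 0.05, reps = 3,
                     lfc = rep(c(0, 1), each = 50), seed = 3)
  cond <- rep(c("a", "b"), each = 3)
  sf <- size_factors_median_of_ratios(cnt)
  disp <- rep(0.05, 100)
  r1 <- nb_wald_test(cnt, cond, sf, dispersions = disp)
  r2 <- nb_wald_test(cnt * 4L, cond, sf * 4, dispersions = disp)
  expect_lt(max(abs(r1$log2_fc - r2$log2_fc)), 0.01)
  expect_equal(r1$log2_fc, r2$log2_fc, tolerance = 0.01)
})

test_that("estimate_dispersion recovers planted dispersion scales", {
  cond <- rep(c("a", "b"), each = 3)
  cnt <- make_counts(1000, mu = 500, disp = 0.05, seed = 4)
  d <- estimate_dispersion(cnt, rep(1, 6), cond)
  expect_gt(median(d), 0.035)
  expect_lt(median(d), 0.065)

  cntp <- make_counts(1000, mu = 500, disp = 0, seed = 5)
  dp <- estimate_dispersion(cntp, rep(1, 6), cond)
  expect_lt(median(dp), 0.01)

  # constant counts across samples sit at the floor
  cntc <- matrix(100L, nrow = 5, ncol = 6)
  expect_equal(estimate_dispersion(cntc, rep(1, 6), cond), rep(1e-8, 5),
               tolerance = 1e-6)

  # single replicate per group falls back to a global value with a warning
  expect_warning(dg <- estimate_dispersion(cnt[, c(1, 4)], rep(1, 2),
                                           c("a", "b")), "global")
  expect_length(unique(dg), 1L)
})

test_that("nb_wald_test matches an independent ML fit on a small fixture", {
  cnt <- make_counts(20, mu = 150, disp = 0.1, reps = 3,
                     lfc = rep(c(0, 1.5), 10), seed = 6)
  cond <- rep(c("a", "b"), each = 3)
  sf <- c(0.9, 1.0, 1.1, 1.05, 0.95, 1.0)
  disp <- rep(0.1, 20)
  res <- nb_wald_test(cnt, cond, sf, dispersions = disp, min_filter_mean = 0)
  X <- cbind(1, rep(c(0, 1), each = 3))
  for (g in 1:20) {
    nll <- function(beta) {
      mu <- sf * exp(X %*% beta)
      -sum(dnbinom(cnt[g, ], mu = mu, size = 1 / 0.1, log = TRUE))
    }
    fit <- optim(c(log(mean(cnt[g, ])), 0), nll, method = "BFGS",
                 hessian = TRUE)
    expect_equal(res$log2_fc[g], fit$par[2] / log(2), tolerance = 1e-3)
    se_oracle <- sqrt(solve(fit$hessian)[2, 2]) / log(2)
    expect_equal(res$wald_stat[g], (fit$par[2] / log(2)) / se_oracle,
                 tolerance = 5e-3)
  }
})

test_that("planted effects are recovered with calibrated uncertainty", {
  # at 3v3, dispersion 0.05, mean 500 the analytic SE of the log2FC is
  # sqrt(2/3 * (1/500 + 0.05)) / ln 2 ~ 0.27, so recovery is checked as
  # coverage of the 95% Wald interval rather than a fixed +/- band
  lfc <- rep(2, 300)
  cnt <- make_counts(300, mu = 500, disp = 0.05, lfc = lfc, seed = 12)
  res <- nb_wald_test(cnt, rep(c("a", "b"), each = 3), rep(1, 6),
                      dispersions = rep(0.05, 300))
  covered <- abs(res$log2_fc - 2) <= 1.96 * res$lfc_se
  expect_gt(mean(covered), 0.90)
  expect_equal(mean(res$log2_fc), 2, tolerance = 0.05)
  se_analytic <- sqrt(2 / 3 * (1 / 500 + 0.05)) / log(2)
  expect_equal(median(res$lfc_se), se_analytic, tolerance = 0.1)
})

test_that("nb_wald_test handles degenerate genes", {
  cnt <- make_counts(10, mu = 200, disp = 0.05, seed = 7)
  cnt[1, ] <- 50L # identical counts in both groups
  cnt[2, 4:6] <- 0L # all-zero condition
  cond <- rep(c("a", "b"), each = 3)
  res <- nb_wald_test(cnt, cond, rep(1, 6))
  expect_equal(res$log2_fc[1], 0, tolerance = 1e-6)
  expect_gt(res$p_value[1], 0.99)
  expect_true(is.finite(res$log2_fc[2]))
  expect_equal(res$status[2], "ridged")
  expect_error(nb_wald_test(cnt, rep("a", 6), rep(1, 6)), "two levels")
})

test_that("low-count genes are excluded from BH by independent filtering", {
  cnt <- make_counts(50, mu = 200, disp = 0.05, seed = 8)
  cnt[1:5, ] <- matrix(rpois(30, 1), nrow = 5)
  res <- nb_wald_test(cnt, rep(c("a", "b"), each = 3), rep(1, 6))
  expect_true(all(is.na(res$p_adj[res$status == "low_count"])))
  expect_true(all(res$base_mean[res$status == "low_count"] < 5))
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("call_degs applies both thresholds", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2_fc = c(2, 1.0, 3.0, -2),
                    p_adj = c(0.01, 0.01, 0.2, 0.01))
  degs <- call_degs(res, alpha = 0.05, lfc_threshold = 1.5)
  expect_identical(degs$up, "a") # b fails |1.5|, c fails alpha
  expect_identical(degs$down, "d")
  expect_length(intersect(degs$up, degs$down), 0)
})

test_that("cpm normalizes columns to a million", {
  cnt <- matrix(c(100L, 0L, 999900L, 500L, 500L, 999000L), ncol = 2)
  cc <- cpm(cnt)
  expect_equal(cc[1, 1], 100)
  expect_equal(colSums(cc), c(1e6, 1e6))
  expect_error(cpm(cnt, library_sizes = c(0, 1)), "positive")
  # replicate log-CPM correlation at moderate dispersion
  set.seed(9)
  sim <- make_counts(500, mu = rlnorm(500, log(300), 1.2), disp = 0.05,
                     seed = 9)
  lc <- log2(cpm(sim) + 1)
  expect_gt(cor(lc[, 1], lc[, 2]), 0.95)
})

test_that("permuted null labels give uniform p-values", {
  cnt <- make_counts(1000, mu = 400, disp = 0.05, seed = 10)
  set.seed(11)
  cond <- sample(rep(c("a", "b"), each = 3)) # permuted labels, null data
  res <- nb_wald_test(cnt, cond, size_factors_median_of_ratios(cnt))
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})
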