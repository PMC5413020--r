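test_that("signed fold change follows the +/- ratio convention", {
  expect_equal(signed_fold_change(c(10, 10), c(20, 20)), -2)
  expect_equal(signed_fold_change(c(20, 20), c(10, 10)), 2)
  expect_equal(signed_fold_change(c(5, 5), c(5, 5)), 1) # no change -> +1
  # antisymmetry
  set.seed(3)
  for (i in 1:10) {
    a <- rlnorm(5); b <- rlnorm(5)
    expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a),
                 tolerance = 1e-12)
  }
  expect_error(signed_fold_change(c(0, 0), c(1, 1)), "positive")
})

test_that("moderated t with d0 = 0 is exactly the classical pooled t", {
  prior0 <- list(s0_sq = 1, d0 = 0)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    b <- rnorm(sample(3:9, 1))
    got <- moderated_t(a, b, prior0)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df_total, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t with an infinite prior fixes the variance at s0^2", {
  got <- moderated_t(c(3, 3), c(1, 1), list(s0_sq = 1, d0 = Inf))
  expect_equal(got$t, 2) # 2 / sqrt(1/2 + 1/2)
  expect_equal(got$df_total, Inf)
  # identical groups: t = 0, p = 1
  same <- moderated_t(c(1, 2, 3), c(1, 2, 3), list(s0_sq = 1, d0 = 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("variance prior recovers known hyperparameters by simulation", {
  set.seed(123)
  d0 <- 4; s0 <- 1; d <- 10; n <- 5000
  sigma2 <- d0 * s0 / rchisq(n, d0)          # scaled-inv-chi-square draws
  s2 <- sigma2 * rchisq(n, d) / d            # observed sample variances
  fit <- fit_variance_prior(s2, d)
  expect_gt(fit$d0, 3); expect_lt(fit$d0, 5)
  expect_gt(fit$s0_sq, 0.9); expect_lt(fit$s0_sq, 1.1)
})

test_that("homogeneous variances give an infinite-df prior at their value", {
  fit <- fit_variance_prior(rep(2.5, 100), df = 10)
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s0_sq, 2.5, tolerance = 1e-12)
  two <- fit_variance_prior(c(1, 1), df = 5)
  expect_equal(two$s0_sq, 1, tolerance = 1e-12)
  expect_error(fit_variance_prior(c(0, 0), df = 5), "zero")
})

test_that("finite-df prior fit agrees with the limma moment estimator", {
  set.seed(42)
  s2 <- 2 / rchisq(2000, 6) * rchisq(2000, 12) / 12
  fit <- fit_variance_prior(s2, 12)
  ref <- limma::fitFDist(s2, df1 = 12)
  expect_equal(fit$d0, ref$df2, tolerance = 1e-6)
  expect_equal(fit$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("BH q-values match a brute-force step-up oracle", {
  # hand step-up: q_i = min over j >= rank(i) of p_(j) * m / j
  brute_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      r <- which(ord == i)
      q[i] <- min(pmin(1, p[ord][r:m] * m / (r:m)))
    }
    q
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  base_p <- c(0.001, 0.02, 0.04, 0.2, 0.9)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  for (k in seq_len(nrow(perms))) {
    p <- base_p[perms[k, ]]
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("feature selection uses strict p and fold-change cuts", {
  res <- data.frame(p = c(0.04, 0.04, 0.05, 0.01),
                    fold_change = c(-1.6, 1.5, 3.0, 1.51))
  out <- suppressMessages(select_features(res))
  expect_identical(out$selected, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("family meta-analysis combines p-values by Fisher's method", {
  got <- combine_family_contrasts(c(0.5, 0.5))
  x <- -2 * (log(0.5) + log(0.5))
  expect_equal(got$statistic, x, tolerance = 1e-12)
  # chi-square(4) survival has the closed form exp(-x/2) * (1 + x/2)
  expect_equal(got$p_combined, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(combine_family_contrasts(c(1, 1, 1))$p_combined, 1)
  # concordant strong signals reinforce below the individual minimum
  for (p in c(0.04, 0.01, 0.001)) {
    expect_lt(combine_family_contrasts(rep(p, 4))$p_combined, p)
  }
  expect_warning(out <- combine_family_contrasts(c(0, 0.5)), "floored")
  expect_gt(out$p_combined, 0)
  expect_error(combine_family_contrasts(0.5), "two families")
})

test_that("null features keep nominal type-I error", {
  set.seed(2024)
  n_feat <- 1000L
  vals <- exp(matrix(rnorm(n_feat * 38, 10, 0.5), n_feat, 38))
  tt <- toy_table(vals, classes = rep(c("case", "control"), c(8, 30)))
  res <- suppressMessages(differential_analysis(tt))
  frac <- mean(res$p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), n_feat, 0.05) / n_feat
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("detection rate is monotone in the planted effect size", {
  set.seed(99)
  n_per <- 200L
  effects <- c(1.5, 2, 4)
  sdlog <- sqrt(log(1 + 0.2^2))
  vals <- lapply(effects, function(fc) {
    m <- exp(matrix(rnorm(n_per * 38, log(1e5), sdlog), n_per, 38))
    m[, 1:8] <- m[, 1:8] * fc
    m
  })
  tt <- toy_table(do.call(rbind, vals),
                  classes = rep(c("case", "control"), c(8, 30)))
  res <- suppressMessages(differential_analysis(tt))
  hit <- tapply(res$p < 0.05, rep(seq_along(effects), each = n_per), mean)
  expect_true(all(diff(hit) >= 0))
  expect_gt(hit[length(effects)], 0.95)
})

test_that("differential analysis returns a coherent result table", {
  co <- generate_cohort(small_design())
  pre <- suppressMessages(preprocess_table(co$table))
  res <- suppressMessages(differential_analysis(pre))
  expect_s3_class(res, "differential_result")
  expect_equal(nrow(res), nrow(pre$intensity))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(all(abs(res$fold_change) >= 1))
  # q is monotone non-decreasing in sorted-p order
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  expect_s3_class(attr(res, "prior"), "shrinkage_estimate")
})
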