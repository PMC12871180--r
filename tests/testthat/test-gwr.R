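make_table <- function(n, seed, beta = c(2, 1.5), noise = 0.1, scale = 100) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, scale), runif(n, 0, scale))
  x <- rnorm(n)
  X <- cbind(intercept = 1, x = x)
  y <- as.vector(X %*% beta) + rnorm(n, 0, noise)
  obs_table(y, X, coords)
}

test_that("kernel weights follow the printed forms", {
  gs <- kernel_spec("gaussian", 10)
  bs <- kernel_spec("bisquare", 10)
  expect_equal(kernel_weight(0, gs), 1)
  expect_equal(kernel_weight(0, bs), 1)
  expect_equal(kernel_weight(10, bs), 0)        # weight zero at the bandwidth
  expect_equal(kernel_weight(15, bs), 0)        # and beyond
  expect_equal(kernel_weight(5, bs), 0.5625)    # (1 - 0.25)^2
  expect_equal(kernel_weight(10, gs), exp(-0.5))
  expect_error(kernel_spec("gaussian", -1), "positive")
  expect_error(kernel_weight(-2, gs), "nonnegative")
})

test_that("weight matrices decay monotonically and hit 1 at the target", {
  coords <- random_coords(30, 31)
  spec <- kernel_spec("gaussian", 20)
  w <- weight_matrix(coords, coords[7, ], spec)
  expect_equal(w[7], 1)
  d <- sqrt(rowSums((coords - matrix(coords[7, ], 30, 2, byrow = TRUE))^2))
  expect_true(all(diff(w[order(d)]) <= 1e-12))
  # huge bandwidth: all weights near 1
  wide <- kernel_spec("gaussian", 1e6 * max(d))
  expect_true(all(abs(weight_matrix(coords, coords[7, ], wide) - 1) < 1e-6))
})

test_that("local fits solve the weighted normal equations exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:30, 1)
    p <- sample(2:3, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    coords <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    tab <- obs_table(y, X, coords)
    spec <- kernel_spec("gaussian", runif(1, 5, 40))
    i <- sample(n, 1)
    w <- weight_matrix(coords, coords[i, ], spec)
    lf <- local_fit(tab, i, spec)
    expect_equal(unname(lf$beta), as.vector(brute_wls(X, diag(w), y)),
                 tolerance = 1e-10)
    expect_equal(lf$fitted, sum(X[i, ] * lf$beta), tolerance = 1e-12)
  }
})

test_that("equal weights reduce the local fit to OLS; tiny bandwidths raise", {
  tab <- make_table(40, 1)
  lf <- local_fit(tab, 3, kernel_spec("gaussian", 1e9))
  ols <- fit_ols(tab)
  expect_equal(unname(lf$beta), unname(ols$betas), tolerance = 1e-8)
  expect_error(local_fit(tab, 3, kernel_spec("gaussian", 1e-6)),
               "singularity at location 3")
})

test_that("GWR reproduces noise-free constant-coefficient data exactly", {
  set.seed(2)
  tab <- make_table(50, 2, beta = c(1, -2), noise = 0)
  fit <- fit_gwr(tab, kernel_spec("gaussian", 30))
  expect_equal(unname(fit$betas),
               matrix(rep(c(1, -2), each = 50), 50), tolerance = 1e-8)
  expect_equal(fit$fitted + fit$residuals, tab$y, tolerance = 1e-12)
  expect_true(all(fit$local_r2 <= 1 + 1e-12))
})

test_that("GWR at a global-limit bandwidth collapses to OLS (AICc included)", {
  tab <- make_table(60, 3)
  diam <- max(dist(tab$coords))
  fit <- fit_gwr(tab, kernel_spec("gaussian", 1e6 * diam))
  ols <- fit_ols(tab)
  expect_lt(max(abs(sweep(fit$betas, 2, ols$betas))), 1e-6)
  expect_lt(max(abs(fit$fitted - ols$fitted)), 1e-6)
  expect_equal(fit$hat_trace, tab$p, tolerance = 1e-4)
  expect_lt(abs(fit$aicc - ols$aicc), 0.1)
})

test_that("AICc follows the corrected small-sample formula", {
  # frozen arithmetic: n=100, rss=100, trS=3
  expect_equal(aicc(100, 100, 3),
               100 * log(2 * pi) + 100 * 103 / 95, tolerance = 1e-12)
  # strictly increasing in rss at fixed trS
  expect_true(all(diff(vapply(c(50, 100, 200, 400),
                              function(r) aicc(100, r, 3), 0)) > 0))
  expect_error(aicc(10, 5, 9), "saturated")
})

test_that("AICc-based selection penalizes overfitting on constant-coefficient data", {
  # constant true beta + noise: small bandwidths overfit, the selected
  # bandwidth is effectively global (AICc no worse than OLS)
  tab <- make_table(150, 4, noise = 0.3)
  ols <- fit_ols(tab)
  sel <- select_bandwidth(tab, b_min = 5, b_max = 500)
  expect_gt(fit_gwr(tab, kernel_spec("gaussian", 5))$aicc, ols$aicc)
  expect_lte(sel$aicc, ols$aicc + 2)
  expect_gt(sel$bandwidth, 25)
  # degenerate interval returns its endpoint, flagged
  one <- select_bandwidth(tab, b_min = 50, b_max = 50.005)
  expect_true(one$boundary)
  expect_equal(one$bandwidth, 50, tolerance = 0.01)
})

test_that("bandwidth selection goes local for sharply varying coefficients", {
  set.seed(6)
  n <- 150
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  x <- rnorm(n)
  b1 <- sin(2 * pi * coords[, 1] / 100) * cos(2 * pi * coords[, 2] / 100)
  y <- 2 + b1 * x + rnorm(n, 0, 0.05)
  tab <- obs_table(y, cbind(1, x), coords)
  sel <- select_bandwidth(tab, b_min = 5, b_max = 200)
  expect_lt(sel$bandwidth, 100)    # interior or at the lower boundary
  gwr <- fit_gwr(tab, kernel_spec("gaussian", sel$bandwidth))
  # recovered slope surface tracks the true field's sign almost everywhere
  expect_gt(mean(sign(gwr$betas[, 2]) == sign(b1)), 0.9)
  expect_gt(model_metrics(y, gwr$fitted)$r2,
            model_metrics(y, fit_ols(tab)$fitted)$r2)
})

test_that("OLS and ridge baselines behave at their limits", {
  tab <- make_table(50, 7, noise = 0)
  expect_lt(max(abs(fit_ols(tab)$residuals)), 1e-10)

  noisy <- make_table(50, 8, noise = 0.5)
  r0 <- fit_ridge(noisy, lambda = 0)
  expect_equal(unname(r0$betas), unname(fit_ols(noisy)$betas),
               tolerance = 1e-8)
  rInf <- fit_ridge(noisy, lambda = 1e12)
  expect_lt(abs(rInf$betas[2]), 1e-6)
  expect_equal(unname(rInf$betas[1]), mean(noisy$y), tolerance = 1e-4)
  expect_error(fit_ridge(noisy, lambda = -1), ">= 0")
  # cross-check against the augmented-least-squares identity for ridge
  lam <- 2.5
  ours <- fit_ridge(noisy, lambda = lam)
  Z <- scale(noisy$X[, -1, drop = FALSE])
  aug_X <- rbind(Z, sqrt(lam) * diag(ncol(Z)))
  aug_y <- c(noisy$y - mean(noisy$y), rep(0, ncol(Z)))
  bs <- qr.solve(aug_X, aug_y)
  expect_equal(unname(ours$betas[-1]),
               unname(bs / attr(Z, "scaled:scale")), tolerance = 1e-8)
  # OLS residuals orthogonal to the design
  ols <- fit_ols(noisy)
  expect_lt(max(abs(crossprod(noisy$X, ols$residuals))), 1e-8)
})

test_that("model metrics match hand arithmetic", {
  m <- model_metrics(c(0, 1, 2), c(0, 1, 1))
  expect_equal(m$r2, 0.5)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$mse, 1 / 3)
  y <- rnorm(10)
  perf <- model_metrics(y, y)
  expect_equal(perf$r2, 1); expect_equal(perf$mae, 0); expect_equal(perf$mse, 0)
  expect_equal(model_metrics(y, rep(mean(y), 10))$r2, 0)
  expect_error(model_metrics(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("GWR residuals on noise-free training data are flagged degenerate", {
  tab <- make_table(30, 9, noise = 0)
  g <- build_graph(tab$coords)
  fit <- fit_gwr(tab, kernel_spec("gaussian", 50))
  res <- residual_autocorrelation(round(fit$residuals, 12), g)
  expect_true(res$degenerate)
})
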