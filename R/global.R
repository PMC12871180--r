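#' Global ordinary least squares baseline
#'
#' Plain OLS of the response on the design, with AICc computed from the
#' same formula as the GWR fit using `tr(S) = p`, so the two models share
#' an information-criterion scale.
#'
#' @param table an [obs_table()].
#' @return object of class `global_fit` with `betas`, `fitted`,
#'   `residuals`, `aicc`, `model = "ols"`.
#' @export
fit_ols <- function(table) {
  stopifnot(inherits(table, "obs_table"))
  fit <- lm.fit(table$X, table$y)
  if (fit$rank < table$p) stop("rank-deficient design", call. = FALSE)
  res <- as.vector(fit$residuals)
  structure(list(betas = fit$coefficients, fitted = as.vector(fit$fitted.values),
                 residuals = res,
                 aicc = aicc(table$n, sum(res^2), table$p),
                 model = "ols", n = table$n, p = table$p),
            class = "global_fit")
}

#' Global ridge regression baseline
#'
#' L2-penalized least squares with the intercept unpenalized and the
#' non-intercept predictors z-scored internally (coefficients are reported
#' on the original scale). `lambda = 0` reproduces OLS.
#'
#' @param table an [obs_table()]; first design column must be the intercept.
#' @param lambda ridge penalty (>= 0, default 1).
#' @return `global_fit` with `model = "ridge"` and `lambda` recorded.
#' @export
fit_ridge <- function(table, lambda = 1) {
  stopifnot(inherits(table, "obs_table"))
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  X <- table$X; y <- table$y
  if (!all(X[, 1] == 1)) stop("first design column must be intercept",
                              call. = FALSE)
  Z <- X[, -1, drop = FALSE]
  mu <- colMeans(Z)
  sdz <- apply(Z, 2, sd)
  if (any(sdz == 0)) stop("constant predictor column", call. = FALSE)
  Zs <- sweep(sweep(Z, 2, mu), 2, sdz, "/")
  yc <- y - mean(y)
  p1 <- ncol(Zs)
  bs <- solve(crossprod(Zs) + diag(lambda, p1), crossprod(Zs, yc))
  beta <- as.vector(bs) / sdz
  intercept <- mean(y) - sum(mu * beta)
  coefs <- c(intercept, beta)
  names(coefs) <- colnames(X)
  fitted <- as.vector(X %*% coefs)
  res <- y - fitted
  structure(list(betas = coefs, fitted = fitted, residuals = res,
                 aicc = aicc(table$n, sum(res^2), table$p),
                 model = "ridge", lambda = lambda,
                 n = table$n, p = table$p),
            class = "global_fit")
}

#' Goodness-of-fit metrics
#'
#' @param y observed response (nonzero variance).
#' @param fitted fitted values, same length.
#' @return list with `r2` (`1 - RSS/TSS`), `mae`, `mse`.
#' @export
model_metrics <- function(y, fitted) {
  if (length(y) != length(fitted) || length(y) < 2)
    stop("y and fitted must share length >= 2", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("degenerate: zero-variance response", call. = FALSE)
  res <- y - fitted
  list(r2 = 1 - sum(res^2) / tss, mae = mean(abs(res)), mse = mean(res^2))
}

#' Spatial autocorrelation of model residuals
#'
#' Moran's I and Geary's C of a fit's residuals over the cell adjacency
#' graph, with permutation p-values; near-zero residual autocorrelation is
#' the signature that the local model has absorbed the spatial structure.
#' Exactly constant residuals (noise-free interpolation) are reported as a
#' degenerate result rather than an error.
#'
#' @param residuals residual vector.
#' @param graph a [build_graph()] over the same cells.
#' @param n_perm,seed passed to [permutation_test()].
#' @return one-row data frame: `morans_i`, `gearys_c`, `p_morans`,
#'   `p_gearys`, `n_permutations`, `seed`, `degenerate`.
#' @export
residual_autocorrelation <- function(residuals, graph, n_perm = 999,
                                     seed = 1) {
  if (var(residuals) == 0)
    return(data.frame(morans_i = NA_real_, gearys_c = NA_real_,
                      p_morans = NA_real_, p_gearys = NA_real_,
                      n_permutations = n_perm, seed = seed,
                      degenerate = TRUE))
  mi <- permutation_test(residuals, graph, "morans", n_perm, seed)
  gc <- permutation_test(residuals, graph, "gearys", n_perm, seed)
  data.frame(morans_i = mi$observed, gearys_c = gc$observed,
             p_morans = mi$p_value, p_gearys = gc$p_value,
             n_permutations = n_perm, seed = seed, degenerate = FALSE)
}
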