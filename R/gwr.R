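#' Kernel specification for geographically weighted regression
#'
#' @param family `"gaussian"` (infinite support, `exp(-d^2 / (2 b^2))`) or
#'   `"bisquare"` (compact support, `(1 - (d/b)^2)^2` for `d < b`, else 0).
#' @param bandwidth kernel bandwidth `b` in pixels, > 0.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "bisquare"), bandwidth) {
  family <- match.arg(family)
  if (!is.numeric(bandwidth) || bandwidth <= 0 || !is.finite(bandwidth))
    stop("bandwidth must be a positive finite number", call. = FALSE)
  structure(list(family = family, bandwidth = bandwidth),
            class = "kernel_spec")
}

#' Kernel weight as a function of distance
#'
#' @param d nonnegative distances (pixels); vectorized.
#' @param spec a [kernel_spec()].
#' @return weights in [0, 1].
#' @export
kernel_weight <- function(d, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  b <- spec$bandwidth
  switch(spec$family,
    gaussian = exp(-d^2 / (2 * b^2)),
    bisquare = ifelse(d < b, (1 - (d / b)^2)^2, 0))
}

#' Diagonal spatial weights for one target location
#'
#' @param coords `n x 2` matrix of observation coordinates.
#' @param target length-2 `(u, v)` of the fitting location.
#' @param spec a [kernel_spec()].
#' @return numeric vector of the diagonal of `W(u, v)`.
#' @export
weight_matrix <- function(coords, target, spec) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty coords", call. = FALSE)
  d <- sqrt((coords[, 1] - target[1])^2 + (coords[, 2] - target[2])^2)
  kernel_weight(d, spec)
}

#' Observation table for the regression stage
#'
#' @param y response vector (e.g. log marker intensity per cell).
#' @param X design matrix including an intercept column; `n > ncol(X)`.
#' @param coords `n x 2` matrix of `(u, v)` cell coordinates in pixels.
#' @return object of class `obs_table`.
#' @export
obs_table <- function(y, X, coords) {
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  n <- length(y)
  if (nrow(X) != n || nrow(coords) != n)
    stop("y, X and coords must have matching rows", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(X)) || !all(is.finite(coords)))
    stop("non-finite values in observation table", call. = FALSE)
  if (n <= ncol(X)) stop("need n > p observations", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- c("intercept", paste0("x", seq_len(ncol(X) - 1)))
  structure(list(y = y, X = X, coords = coords, n = n, p = ncol(X)),
            class = "obs_table")
}

#' Build an observation table from a cell feature table
#'
#' @param cells data frame from [build_cell_table()].
#' @param marker marker name.
#' @param response feature suffix used as response
#'   (default `log1p_integrated_density`).
#' @param predictors morphometric predictor columns (default `morph_score`).
#' @return an [obs_table()] with intercept + predictors design.
#' @export
marker_obs_table <- function(cells, marker,
                             response = "log1p_integrated_density",
                             predictors = "morph_score") {
  ycol <- paste0(marker, "__", response)
  if (is.null(cells[[ycol]])) stop("missing column ", ycol, call. = FALSE)
  X <- cbind(intercept = 1,
             as.matrix(cells[, predictors, drop = FALSE]))
  obs_table(cells[[ycol]], X, as.matrix(cells[, c("u", "v")]))
}

#' Local weighted least-squares fit at one observation
#'
#' Solves the kernel-weighted normal equations
#' `beta(u_i, v_i) = (X' W X)^{-1} X' W y` centered at observation
#' `target_index`, via a rank-revealing QR of the weighted design. Also
#' returns the fitting location's leverage (its diagonal entry of the hat
#' matrix), which accumulates into the model's effective parameter count.
#'
#' @param table an [obs_table()].
#' @param target_index observation index (fitting location).
#' @param spec a [kernel_spec()].
#' @param weights optional precomputed weight vector for this location.
#' @return list with `beta`, `hat_ii`, `fitted`.
#' @export
local_fit <- function(table, target_index, spec, weights = NULL) {
  stopifnot(inherits(table, "obs_table"))
  w <- weights %||% weight_matrix(table$coords,
                                  table$coords[target_index, ], spec)
  sw <- sqrt(w)
  Xs <- table$X * sw
  qr_ <- qr(Xs, tol = 1e-10)
  if (qr_$rank < table$p)
    stop("localized singularity at location ", target_index,
         " (bandwidth too small)", call. = FALSE)
  beta <- qr.coef(qr_, table$y * sw)
  xi <- table$X[target_index, ]
  R <- qr.R(qr_)
  t_ <- backsolve(R, xi[qr_$pivot], transpose = TRUE)
  hat_ii <- sum(t_^2) * w[target_index]
  list(beta = beta, hat_ii = hat_ii, fitted = sum(xi * beta))
}

#' Fit geographically weighted regression at every observation
#'
#' Runs [local_fit()] at each cell location, assembling the coefficient
#' surfaces, fitted values, residuals, hat-matrix trace (effective
#' parameters), error variance `rss / (n - tr(S))`, AICc, and a local R^2
#' computed from the locally weighted residual and total sums of squares
#' (the latter about the locally weighted mean).
#'
#' @param table an [obs_table()].
#' @param spec a [kernel_spec()].
#' @param distances optional precomputed `n x n` distance matrix.
#' @return object of class `gwr_fit`.
#' @export
fit_gwr <- function(table, spec, distances = NULL) {
  stopifnot(inherits(table, "obs_table"), inherits(spec, "kernel_spec"))
  n <- table$n; p <- table$p
  D <- distances %||% as.matrix(dist(table$coords))
  betas <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(table$X)))
  fitted <- hat_ii <- local_r2 <- numeric(n)
  y <- table$y; X <- table$X
  for (i in seq_len(n)) {
    w <- kernel_weight(D[, i], spec)
    lf <- local_fit(table, i, spec, weights = w)
    betas[i, ] <- lf$beta
    fitted[i] <- lf$fitted
    hat_ii[i] <- lf$hat_ii
    ri <- y - as.vector(X %*% lf$beta)
    ybar_w <- sum(w * y) / sum(w)
    tss_w <- sum(w * (y - ybar_w)^2)
    local_r2[i] <- if (tss_w > 0) 1 - sum(w * ri^2) / tss_w else NA_real_
  }
  residuals <- y - fitted
  rss <- sum(residuals^2)
  trS <- sum(hat_ii)
  structure(list(betas = betas, fitted = fitted, residuals = residuals,
                 hat_trace = trS,
                 sigma2_hat = rss / (n - trS),
                 aicc = aicc(n, rss, trS),
                 local_r2 = local_r2, kernel = spec, n = n, p = p),
            class = "gwr_fit")
}

#' Corrected AIC for (geographically weighted) regression
#'
#' `AICc = 2 n log(sigma_hat) + n log(2 pi) + n (n + tr(S)) /
#' (n - 2 - tr(S))` with `sigma_hat = sqrt(rss / n)` and `tr(S)` the
#' effective number of parameters; a global OLS fit uses the same formula
#' with `tr(S) = p`, putting both models on a common scale.
#'
#' @param n number of observations.
#' @param rss residual sum of squares.
#' @param hat_trace effective parameter count `tr(S)`.
#' @return AICc value (`-Inf` for an exact interpolation with `rss = 0`).
#' @export
aicc <- function(n, rss, hat_trace) {
  if (n - 2 - hat_trace <= 0)
    stop("AICc saturated: need n > tr(S) + 2", call. = FALSE)
  if (rss < 0) stop("rss must be nonnegative", call. = FALSE)
  sigma <- sqrt(rss / n)
  2 * n * log(sigma) + n * log(2 * pi) +
    n * (n + hat_trace) / (n - 2 - hat_trace)
}

#' AICc-based bandwidth selection by golden-section search
#'
#' Minimizes `AICc(fit_gwr(table, b))` over `[b_min, b_max]` by
#' golden-section search (default tolerance 0.01 px). Defaults:
#' `b_min = 1.5 x` the median nearest-neighbor distance (a floor below
#' which local designs degenerate) and `b_max =` the spot diameter.
#' Bandwidths whose fit is singular score `+Inf`. If the minimizer lands at
#' (or within tolerance of) an endpoint the result is flagged as a boundary
#' solution.
#'
#' @param table an [obs_table()].
#' @param family kernel family.
#' @param b_min,b_max search interval (pixels); see defaults above.
#' @param tol search tolerance in pixels.
#' @param distances optional precomputed distance matrix.
#' @return list with `bandwidth`, `aicc`, `boundary` (logical), `family`,
#'   `b_min`, `b_max`, `n_evals`.
#' @export
select_bandwidth <- function(table, family = "gaussian", b_min = NULL,
                             b_max = NULL, tol = 0.01, distances = NULL) {
  stopifnot(inherits(table, "obs_table"))
  D <- distances %||% as.matrix(dist(table$coords))
  if (is.null(b_min)) {
    nn <- apply(D + diag(Inf, table$n), 2, min)
    b_min <- 1.5 * median(nn)
  }
  if (is.null(b_max)) b_max <- max(D)
  if (!(b_min > 0) || !(b_max >= b_min))
    stop("need 0 < b_min <= b_max", call. = FALSE)
  n_evals <- 0L
  obj <- function(b) {
    n_evals <<- n_evals + 1L
    tryCatch(fit_gwr(table, kernel_spec(family, b), distances = D)$aicc,
             error = function(e) Inf)
  }
  if (b_max - b_min < tol) {
    return(list(bandwidth = b_min, aicc = obj(b_min), boundary = TRUE,
                family = family, b_min = b_min, b_max = b_max,
                n_evals = n_evals))
  }
  phi <- (sqrt(5) - 1) / 2
  a <- b_min; b <- b_max
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- obj(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- obj(x2)
    }
  }
  bstar <- (a + b) / 2
  fstar <- obj(bstar)
  # compare with the endpoints: AICc monotone in b means the optimum is there
  f_lo <- obj(b_min); f_hi <- obj(b_max)
  cand <- c(b_min, bstar, b_max)
  fv <- c(f_lo, fstar, f_hi)
  if (all(!is.finite(fv))) stop("all candidate bandwidths singular",
                                call. = FALSE)
  best <- which.min(fv)
  bandwidth <- cand[best]
  boundary <- bandwidth <= b_min + tol || bandwidth >= b_max - tol
  list(bandwidth = bandwidth, aicc = fv[best], boundary = boundary,
       family = family, b_min = b_min, b_max = b_max, n_evals = n_evals)
}
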