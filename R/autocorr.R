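#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `S0` the total weight. Positive values indicate spatial
#' clustering of like values; the permutation-null expectation is
#' `-1 / (n - 1)`.
#'
#' @param values numeric vector, one per graph node, nonzero variance.
#' @param graph a [build_graph()] result.
#' @return Moran's I.
#' @export
morans_i <- function(values, graph) {
  check_autocorr_input(values, graph)
  z <- values - mean(values)
  W <- graph$W
  n <- graph$n
  S0 <- sum(W)
  as.numeric((n / S0) * (t(z) %*% (W %*% z)) / sum(z^2))
}

#' Geary's C spatial autocorrelation
#'
#' `C = ((n - 1) / (2 S0)) * sum_ij w_ij (v_i - v_j)^2 / sum_i z_i^2`;
#' expectation 1 under the permutation null, values below 1 indicate
#' clustering.
#'
#' @inheritParams morans_i
#' @return Geary's C.
#' @export
gearys_c <- function(values, graph) {
  check_autocorr_input(values, graph)
  z <- values - mean(values)
  trip <- Matrix::summary(graph$W)
  S0 <- sum(trip$x)
  num <- sum(trip$x * (values[trip$i] - values[trip$j])^2)
  ((graph$n - 1) / (2 * S0)) * num / sum(z^2)
}

#' @noRd
check_autocorr_input <- function(values, graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (length(values) != graph$n)
    stop("values length must equal graph size", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  if (var(values) == 0)
    stop("degenerate input: values have zero variance", call. = FALSE)
  invisible(TRUE)
}

#' Permutation test for spatial autocorrelation
#'
#' Two-sided permutation p-value for Moran's I or Geary's C: values are
#' randomly reassigned to nodes, and the p-value is
#' `(1 + #{|stat_perm - E0| >= |stat_obs - E0|}) / (n_perm + 1)` with `E0`
#' the null expectation (`-1/(n-1)` for Moran, 1 for Geary). Deterministic
#' given the seed.
#'
#' @inheritParams morans_i
#' @param statistic `"morans"` or `"gearys"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @return list with `statistic` name, `observed`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
permutation_test <- function(values, graph, statistic = c("morans", "gearys"),
                             n_perm = 999, seed = 1) {
  statistic <- match.arg(statistic)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  check_autocorr_input(values, graph)
  n <- graph$n
  P <- with_seed(seed,
    vapply(seq_len(n_perm), function(b) values[sample.int(n)],
           numeric(n)))
  if (statistic == "morans") {
    obs <- morans_i(values, graph)
    e0 <- -1 / (n - 1)
    Z <- P - colMeans(P)[col(P)]
    W <- graph$W
    S0 <- sum(W)
    perm <- (n / S0) * colSums(Z * as.matrix(W %*% Z)) / colSums(Z^2)
  } else {
    obs <- gearys_c(values, graph)
    e0 <- 1
    trip <- Matrix::summary(graph$W)
    S0 <- sum(trip$x)
    D2 <- (P[trip$i, , drop = FALSE] - P[trip$j, , drop = FALSE])^2
    Z <- P - colMeans(P)[col(P)]
    perm <- ((n - 1) / (2 * S0)) * colSums(trip$x * D2) / colSums(Z^2)
  }
  p <- (1 + sum(abs(perm - e0) >= abs(obs - e0))) / (n_perm + 1)
  list(statistic = statistic, observed = obs, p_value = p,
       n_perm = n_perm, seed = seed)
}

#' Permutation-tested Moran's I and Geary's C for each marker
#'
#' Runs both autocorrelation statistics with permutation significance on a
#' per-marker response column (by default the log1p-transformed integrated
#' density), producing the screening table [select_markers()] consumes.
#'
#' @param cells per-cell feature table from [build_cell_table()].
#' @param graph a [build_graph()] over the same cells.
#' @param markers marker names; default: inferred from `<marker>__` columns.
#' @param response_feature feature suffix used as the tested value.
#' @param n_perm,seed passed to [permutation_test()].
#' @return data frame with one row per marker: `marker`, `morans_i`,
#'   `gearys_c`, `p_morans`, `p_gearys`, `n_permutations`, `seed`.
#' @export
autocorr_screen <- function(cells, graph, markers = NULL,
                            response_feature = "log1p_integrated_density",
                            n_perm = 999, seed = 1) {
  markers <- markers %||% marker_names_from_table(cells)
  if (length(markers) == 0) stop("no marker columns found", call. = FALSE)
  rows <- lapply(seq_along(markers), function(k) {
    m <- markers[k]
    vals <- cells[[paste0(m, "__", response_feature)]]
    if (is.null(vals)) stop("missing column for marker ", m, call. = FALSE)
    mi <- permutation_test(vals, graph, "morans", n_perm, seed + k)
    gc <- permutation_test(vals, graph, "gearys", n_perm, seed + k)
    data.frame(marker = m, morans_i = mi$observed, gearys_c = gc$observed,
               p_morans = mi$p_value, p_gearys = gc$p_value,
               n_permutations = n_perm, seed = seed + k)
  })
  do.call(rbind, rows)
}

#' @noRd
marker_names_from_table <- function(cells) {
  cols <- grep("__", names(cells), value = TRUE)
  unique(sub("__.*$", "", cols))
}

#' Screen markers by Moran's I significance
#'
#' Keeps markers whose Moran's I permutation p-value is at most `alpha`,
#' ranks them by |Moran's I| descending, and truncates to the `top_k`
#' strongest, mirroring the study design of carrying only spatially
#' structured markers into the local regression stage.
#'
#' @param results data frame from [autocorr_screen()].
#' @param alpha significance level (default 0.05).
#' @param top_k maximum number of markers retained (default 8).
#' @return character vector of selected marker names (possibly empty).
#' @export
select_markers <- function(results, alpha = 0.05, top_k = 8) {
  stopifnot(nrow(results) >= 1)
  keep <- results[results$p_morans <= alpha, , drop = FALSE]
  keep <- keep[order(-abs(keep$morans_i)), , drop = FALSE]
  head(keep$marker, top_k)
}
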