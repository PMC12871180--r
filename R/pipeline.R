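#' Configuration for an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (simulate a spot) or `"real"` (load a spot
#'   directory written in the [write_sample()] layout).
#' @param sample a `synthetic_sample` (synthetic mode; simulated from
#'   `seed` if omitted).
#' @param dir spot directory (real mode).
#' @param n_cells,shape,truth,marker_names forwarded to [simulate_sample()]
#'   when `sample` is omitted.
#' @param alpha Moran's I screening level.
#' @param top_k maximum markers carried into regression.
#' @param kernel_family `"gaussian"` or `"bisquare"`.
#' @param bandwidth fixed bandwidth in pixels, or `NULL` for AICc-based
#'   selection.
#' @param n_perm permutations for significance testing.
#' @param seed integer seed controlling simulation and permutation tests.
#' @param threshold_scope `"cell"` or `"image"` positivity thresholds.
#' @param response intensity feature used as regression/screening response.
#' @param predictors morphometric predictor columns (default MorphScore).
#' @param ridge_lambda ridge penalty.
#' @param out_dir if non-NULL, stage artifacts are written there as CSV.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real"), sample = NULL,
                       dir = NULL, n_cells = 300, shape = c(512, 512),
                       truth = NULL, marker_names = paste0("marker", 1:4),
                       alpha = 0.05, top_k = 8,
                       kernel_family = "gaussian", bandwidth = NULL,
                       n_perm = 999, seed = 1,
                       threshold_scope = "cell",
                       response = "log1p_integrated_density",
                       predictors = "morph_score",
                       ridge_lambda = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "real" && (is.null(dir) || !dir.exists(dir)))
    stop("real mode requires an existing spot directory", call. = FALSE)
  structure(list(mode = mode, sample = sample, dir = dir,
                 n_cells = n_cells, shape = shape, truth = truth,
                 marker_names = marker_names, alpha = alpha, top_k = top_k,
                 kernel_family = kernel_family, bandwidth = bandwidth,
                 n_perm = n_perm, seed = seed,
                 threshold_scope = threshold_scope, response = response,
                 predictors = predictors, ridge_lambda = ridge_lambda,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full morphology-protein coupling pipeline on one spot
#'
#' Stages: obtain the spot (simulate or load), normalize channels by robust
#' percentile rescaling, extract per-cell features and MorphScore, build the
#' Delaunay adjacency graph, screen markers by permutation-tested Moran's I,
#' then per selected marker fit OLS, ridge and GWR (with AICc bandwidth
#' selection unless a fixed bandwidth is configured) and assemble the
#' comparison report: R2/MAE/MSE per model, AICc for OLS and GWR,
#' `delta_aicc = aicc_ols - aicc_gwr` (positive favors GWR), and residual
#' Moran's I / Geary's C for OLS and GWR. Fully reproducible given the
#' configured seed.
#'
#' @param config a [run_config()].
#' @return list with `report` (per-marker comparison data frame), `cells`
#'   (feature table), `screen` (autocorrelation screen), `selected`,
#'   `fits` (per-marker list of fit objects), `graph`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  res <- tryCatch({
    if (config$mode == "synthetic") {
      sample <- config$sample %||% simulate_sample(
        n_cells = config$n_cells, shape = config$shape,
        truth = config$truth, marker_names = config$marker_names,
        seed = config$seed)
      label_image <- sample$label_image
      channels <- sample$channels
    } else {
      loaded <- load_sample(config$dir)
      label_image <- loaded$label_image
      channels <- loaded$channels
    }

    stage <- "preprocess"
    channels <- lapply(channels, function(ch) robust_rescale(ch)$raster)

    stage <- "features"
    cells <- build_cell_table(label_image, channels,
                              threshold_scope = config$threshold_scope)

    stage <- "graph"
    graph <- build_graph(as.matrix(cells[, c("u", "v")]))

    stage <- "screen"
    screen <- autocorr_screen(cells, graph,
                              response_feature = config$response,
                              n_perm = config$n_perm, seed = config$seed)
    selected <- select_markers(screen, alpha = config$alpha,
                               top_k = config$top_k)

    stage <- "fit"
    D <- as.matrix(dist(as.matrix(cells[, c("u", "v")])))
    fits <- list()
    rows <- list()
    for (m in selected) {
      tab <- marker_obs_table(cells, m, response = config$response,
                              predictors = config$predictors)
      ols <- fit_ols(tab)
      ridge <- fit_ridge(tab, lambda = config$ridge_lambda)
      if (is.null(config$bandwidth)) {
        bw <- select_bandwidth(tab, family = config$kernel_family,
                               distances = D)
      } else {
        bw <- list(bandwidth = config$bandwidth, boundary = FALSE)
      }
      gwr <- fit_gwr(tab, kernel_spec(config$kernel_family, bw$bandwidth),
                     distances = D)
      mo <- model_metrics(tab$y, ols$fitted)
      mr <- model_metrics(tab$y, ridge$fitted)
      mg <- model_metrics(tab$y, gwr$fitted)
      ac_o <- residual_autocorrelation(ols$residuals, graph,
                                       n_perm = config$n_perm,
                                       seed = config$seed)
      ac_g <- residual_autocorrelation(gwr$residuals, graph,
                                       n_perm = config$n_perm,
                                       seed = config$seed)
      fits[[m]] <- list(ols = ols, ridge = ridge, gwr = gwr,
                        bandwidth = bw)
      rows[[m]] <- data.frame(
        marker = m,
        r2_ols = mo$r2, r2_ridge = mr$r2, r2_gwr = mg$r2,
        mae_ols = mo$mae, mae_ridge = mr$mae, mae_gwr = mg$mae,
        mse_ols = mo$mse, mse_ridge = mr$mse, mse_gwr = mg$mse,
        aicc_ols = ols$aicc, aicc_gwr = gwr$aicc,
        delta_aicc = ols$aicc - gwr$aicc,
        morans_resid_ols = ac_o$morans_i, morans_resid_gwr = ac_g$morans_i,
        gearys_resid_ols = ac_o$gearys_c, gearys_resid_gwr = ac_g$gearys_c,
        bandwidth = bw$bandwidth, boundary_flag = isTRUE(bw$boundary))
    }
    report <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
              else data.frame()
    list(report = report, cells = cells, screen = screen,
         selected = selected, fits = fits, graph = graph, config = config)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cell_table(res$cells, file.path(config$out_dir, "cells.csv"))
    write_cell_table(res$screen, file.path(config$out_dir, "autocorr.csv"))
    if (nrow(res$report))
      write_cell_table(res$report, file.path(config$out_dir, "report.csv"))
    edges <- res$graph$edges
    trip <- Matrix::summary(res$graph$W)
    write_cell_table(data.frame(i = trip$i, j = trip$j, w = trip$x),
                     file.path(config$out_dir, "graph.csv"))
  }
  res
}

#' Feature-by-feature Pearson correlation table
#'
#' Correlation matrix over all numeric feature columns of a cell table
#' (identifier columns dropped), the tabular form of a feature correlation
#' heat map. Constant columns get correlation 0 off-diagonal and are listed
#' in the `degenerate` attribute.
#'
#' @param cells per-cell feature table, >= 3 rows.
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `degenerate` names constant columns.
#' @export
correlation_heatmap_table <- function(cells) {
  stopifnot(nrow(cells) >= 3)
  num <- cells[, setdiff(names(cells)[vapply(cells, is.numeric, TRUE)],
                         "cell_id"), drop = FALSE]
  sds <- vapply(num, sd, 0)
  degen <- names(num)[sds == 0 | !is.finite(sds)]
  M <- suppressWarnings(cor(as.matrix(num)))
  M[!is.finite(M)] <- 0
  diag(M) <- 1
  attr(M, "degenerate") <- degen
  M
}
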