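#' Sample cell centroids on a jittered grid
#'
#' Draws `n_cells` distinct centroid locations inside an `(H, W)` raster by
#' jittering a regular grid. The jitter amplitude is 40% of the grid pitch
#' (clamped so that the minimum pairwise distance stays at least 2 px), which
#' produces Voronoi regions with naturally varying area and elongation.
#'
#' @param n_cells number of centroids (>= 3).
#' @param shape integer `(H, W)`; both at least 32.
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return `n_cells x 2` matrix with columns `u`, `v` (0-based pixel
#'   coordinates, u = column).
#' @export
generate_centroids <- function(n_cells, shape, seed) {
  stopifnot(length(shape) == 2)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (n_cells < 3) stop("n_cells must be >= 3", call. = FALSE)
  if (H < 32 || W < 32) stop("shape must be at least 32 x 32", call. = FALSE)
  capacity <- floor(H / 2) * floor(W / 2)
  if (n_cells > capacity)
    stop("n_cells = ", n_cells, " exceeds grid capacity ", capacity,
         " for a ", H, " x ", W, " raster", call. = FALSE)
  pitch <- sqrt(H * W / n_cells)
  nx <- ceiling(W / pitch); ny <- ceiling(H / pitch)
  gx <- W / nx; gy <- H / ny
  if (gx < 2 || gy < 2) stop("grid pitch below 2 px; reduce n_cells",
                             call. = FALSE)
  jx <- min(0.4 * gx, (gx - 2) / 2)
  jy <- min(0.4 * gy, (gy - 2) / 2)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  with_seed(seed, {
    keep <- sample.int(nrow(grid), n_cells)
    u <- (grid$ix[keep] - 0.5) * gx - 0.5 + runif(n_cells, -jx, jx)
    v <- (grid$iy[keep] - 0.5) * gy - 0.5 + runif(n_cells, -jy, jy)
    cbind(u = pmin(pmax(u, 0), W - 1), v = pmin(pmax(v, 0), H - 1))
  })
}

#' Voronoi tessellation of a raster by nearest centroid
#'
#' Assigns every pixel to its nearest centroid (Euclidean distance between
#' pixel center and centroid; ties go to the lower cell id), emulating the
#' Voronoi-like cell tessellations seen in segmented multiplexed images.
#'
#' @param centroids `n x 2` matrix of `(u, v)` coordinates (>= 3 rows,
#'   no duplicates).
#' @param shape integer `(H, W)`.
#' @return integer `H x W` label matrix with values `1..n`; row `r`, column
#'   `c` is the pixel at `u = c - 1`, `v = r - 1`.
#' @export
tessellate <- function(centroids, shape) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 3) stop("need at least 3 centroids", call. = FALSE)
  if (anyDuplicated(centroids)) stop("duplicate centroids", call. = FALSE)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  u <- rep(0:(W - 1), each = H)   # column-major over H x W matrix
  v <- rep(0:(H - 1), times = W)
  best <- rep.int(1L, H * W)
  bestd <- (u - centroids[1, 1])^2 + (v - centroids[1, 2])^2
  for (k in seq_len(nrow(centroids))[-1]) {
    d <- (u - centroids[k, 1])^2 + (v - centroids[k, 2])^2
    closer <- d < bestd
    best[closer] <- k
    bestd[closer] <- d[closer]
  }
  lab <- matrix(best, nrow = H, ncol = W)
  if (length(unique(best)) < nrow(centroids))
    stop("tessellation produced an empty region; centroids too close",
         call. = FALSE)
  lab
}

#' Describe the generating truth of a synthetic spot
#'
#' Bundles, per marker, the true intercept surface `beta0(u, v)` and
#' morphology slope surface `beta1(u, v)` together with the cell-level noise
#' standard deviation. Used by [render_channels()] and kept alongside
#' simulated samples so parameter recovery can be checked.
#'
#' @param markers named list; each element a list with components `beta0`
#'   and `beta1`, both [field_spec()] objects.
#' @param noise_sd cell-level Gaussian noise SD (>= 0), intensity units.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(markers, noise_sd = 0.3) {
  stopifnot(is.list(markers), length(markers) >= 1,
            !is.null(names(markers)), noise_sd >= 0)
  for (m in markers)
    stopifnot(inherits(m$beta0, "field_spec"), inherits(m$beta1, "field_spec"))
  structure(list(markers = markers, noise_sd = noise_sd),
            class = "synthetic_truth")
}

#' Default truth for a heterogeneous synthetic cohort
#'
#' Every marker gets a gaussian-bump intercept surface (amplitude 6, length
#' scale 256 px, keeping rendered intensities comfortably nonnegative) and a
#' zero-mean sinusoidal morphology slope (amplitude 1, wavelength 256 px),
#' i.e. two full slope periods across a default 512 px spot.
#'
#' @param marker_names character vector of marker names.
#' @param noise_sd cell-level noise SD.
#' @param beta1_kind field kind for the slope surface (set to `"constant"`
#'   with `beta1_amplitude = 0` to obtain pure-noise markers).
#' @param beta0_kind,beta0_amplitude,beta1_amplitude,length_scale overrides.
#' @return a [synthetic_truth()].
#' @export
default_truth <- function(marker_names, noise_sd = 0.3,
                          beta0_kind = "gaussian-bump", beta0_amplitude = 6,
                          beta1_kind = "zero-mean-sinusoid",
                          beta1_amplitude = 1, length_scale = 256) {
  markers <- lapply(marker_names, function(nm) list(
    beta0 = field_spec(beta0_kind, beta0_amplitude, length_scale),
    beta1 = field_spec(beta1_kind, beta1_amplitude, length_scale)
  ))
  names(markers) <- marker_names
  synthetic_truth(markers, noise_sd)
}

#' Render marker channel rasters from a label image and truth fields
#'
#' For each marker, cell `i` receives the mean intensity
#' `beta0(u_i, v_i) + beta1(u_i, v_i) * morph_score_i + eps_i` with
#' `eps_i ~ N(0, noise_sd^2)` evaluated at its centroid; pixels inside the
#' cell share that value plus i.i.d. pixel noise with SD equal to 10% of
#' `noise_sd`. Rasters are clipped at 0 (intensities are nonnegative).
#'
#' @param label_image integer label matrix from [tessellate()].
#' @param centroids `n x 2` centroid matrix matching labels `1..n`.
#' @param morph_scores numeric vector, one score per cell.
#' @param truth a [synthetic_truth()].
#' @param seed integer seed; rendering is deterministic given the seed.
#' @return named list of `H x W` numeric channel rasters, plus attribute
#'   `cell_values` (matrix of true per-cell mean intensities, cells x
#'   markers, before pixel noise and clipping).
#' @export
render_channels <- function(label_image, centroids, morph_scores, truth,
                            seed) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (length(morph_scores) != n)
    stop("need one morph_score per cell", call. = FALSE)
  if (max(label_image) != n)
    stop("label image and centroids disagree on cell count", call. = FALSE)
  stopifnot(inherits(truth, "synthetic_truth"))
  shape <- dim(label_image)
  sd_cell <- truth$noise_sd
  sd_pix <- 0.1 * sd_cell
  with_seed(seed, {
    cellvals <- matrix(NA_real_, n, length(truth$markers),
                       dimnames = list(NULL, names(truth$markers)))
    channels <- vector("list", length(truth$markers))
    names(channels) <- names(truth$markers)
    for (m in names(truth$markers)) {
      b0 <- eval_field(truth$markers[[m]]$beta0, centroids[, 1],
                       centroids[, 2], shape)
      b1 <- eval_field(truth$markers[[m]]$beta1, centroids[, 1],
                       centroids[, 2], shape)
      ci <- b0 + b1 * morph_scores + rnorm(n, 0, sd_cell)
      cellvals[, m] <- ci
      ras <- matrix(0, shape[1], shape[2])
      inside <- label_image > 0L
      ras[inside] <- ci[label_image[inside]]
      if (sd_pix > 0) ras[inside] <- ras[inside] + rnorm(sum(inside), 0, sd_pix)
      channels[[m]] <- pmax(ras, 0)
    }
    attr(channels, "cell_values") <- cellvals
    channels
  })
}

#' Simulate one MIBI-like spot end to end
#'
#' Generates centroids, tessellates the spot, computes per-cell
#' morphometrics and the MorphScore, and renders marker channels whose
#' per-cell intensity follows the spatially varying linear model in the
#' MorphScore defined by `truth`. The MorphScore used for rendering is the
#' same PCA score the analysis side recomputes, so the generative model is
#' exactly the one the regression assumes.
#'
#' @param n_cells number of cells (default 300).
#' @param shape raster `(H, W)` (default 512 x 512).
#' @param truth a [synthetic_truth()]; defaults to [default_truth()] over
#'   `marker_names`.
#' @param marker_names used only when `truth` is NULL.
#' @param seed integer seed.
#' @return object of class `synthetic_sample`: list with `label_image`,
#'   `channels`, `centroids`, `morph` (per-cell morphometrics data frame),
#'   `morph_score`, `cell_values` (true per-cell mean intensities),
#'   `truth`, `seed`.
#' @export
simulate_sample <- function(n_cells = 300, shape = c(512, 512),
                            truth = NULL,
                            marker_names = paste0("marker", 1:4),
                            seed = 1) {
  truth <- truth %||% default_truth(marker_names)
  cents <- generate_centroids(n_cells, shape, seed)
  lab <- tessellate(cents, shape)
  morph <- region_morphometrics(lab)
  ms <- morph_score(morph[, morph_feature_names(), drop = FALSE])
  ch <- render_channels(lab, cents, ms$score, truth, seed + 1L)
  structure(list(label_image = lab, channels = ch[seq_along(ch)],
                 centroids = cents, morph = morph, morph_score = ms$score,
                 cell_values = attr(ch, "cell_values"),
                 truth = truth, seed = seed),
            class = "synthetic_sample")
}

#' Simulate cell-level data without rendering rasters
#'
#' Same generative model as [simulate_sample()] — jittered-grid Voronoi
#' cells, morphometric MorphScore, per-cell response
#' `beta0 + beta1 * score + N(0, noise_sd^2)` — but stopping at the
#' per-cell values instead of rendering pixel rasters. Useful for
#' simulation studies where only the cell table matters.
#'
#' @inheritParams simulate_sample
#' @return list with `centroids`, `morph`, `morph_score`, `values`
#'   (cells x markers matrix), `beta_true` (per marker, list of `beta0`,
#'   `beta1` vectors at the centroids), `truth`, `seed`.
#' @export
simulate_cells <- function(n_cells = 300, shape = c(512, 512), truth = NULL,
                           marker_names = "marker1", seed = 1) {
  truth <- truth %||% default_truth(marker_names)
  cents <- generate_centroids(n_cells, shape, seed)
  lab <- tessellate(cents, shape)
  morph <- region_morphometrics(lab)
  ms <- morph_score(morph[, morph_feature_names(), drop = FALSE])
  with_seed(seed + 1L, {
    vals <- matrix(NA_real_, n_cells, length(truth$markers),
                   dimnames = list(NULL, names(truth$markers)))
    betas <- list()
    for (m in names(truth$markers)) {
      b0 <- eval_field(truth$markers[[m]]$beta0, cents[, 1], cents[, 2], shape)
      b1 <- eval_field(truth$markers[[m]]$beta1, cents[, 1], cents[, 2], shape)
      vals[, m] <- b0 + b1 * ms$score + rnorm(n_cells, 0, truth$noise_sd)
      betas[[m]] <- list(beta0 = b0, beta1 = b1)
    }
    list(centroids = cents, morph = morph, morph_score = ms$score,
         values = vals, beta_true = betas, truth = truth, seed = seed)
  })
}

#' Write a synthetic sample to a directory
#'
#' Writes `label.tif` (16-bit labels), one 32-bit float TIFF per channel
#' (stored scaled into [0, 1]; the scale is recorded in the sidecar), and a
#' `sample.json` sidecar holding the truth specification, channel scales and
#' seed. [load_sample()] reads the directory back.
#'
#' @param sample a `synthetic_sample`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "synthetic_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- sample$label_image
  if (max(lab) > 65535) stop("more than 65535 cells; cannot store 16-bit",
                             call. = FALSE)
  tiff::writeTIFF(lab / 65535, file.path(dir, "label.tif"),
                  bits.per.sample = 16)
  scales <- vapply(sample$channels, function(ch) max(ch, 1e-12), 0)
  for (m in names(sample$channels))
    tiff::writeTIFF(sample$channels[[m]] / scales[[m]],
                    file.path(dir, paste0(m, ".tif")), bits.per.sample = 32)
  meta <- list(
    markers = names(sample$channels),
    channel_scale = as.list(scales),
    noise_sd = sample$truth$noise_sd,
    seed = sample$seed,
    truth = lapply(sample$truth$markers, function(m) list(
      beta0 = unclass(m$beta0), beta1 = unclass(m$beta1))),
    centroids = unname(as.data.frame(sample$centroids))
  )
  jsonlite::write_json(meta, file.path(dir, "sample.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
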