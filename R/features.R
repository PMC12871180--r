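#' Gini coefficient of an intensity distribution
#'
#' `G = sum_ij |v_i - v_j| / (2 n^2 mean(v))`, a scale-invariant measure of
#' how unevenly signal is spread across a cell's pixels (0 = perfectly even).
#' Defined as 0 when the mean is 0 (all-zero signal).
#'
#' @param values nonnegative numeric vector.
#' @return Gini coefficient in [0, 1).
#' @export
gini <- function(values) {
  if (length(values) == 0) stop("empty values", call. = FALSE)
  if (any(values < 0)) stop("gini requires nonnegative values", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  if (m == 0) return(0)
  s <- sort(values)
  (2 * sum(seq_len(n) * s) / (n * sum(s))) - (n + 1) / n
}

#' Count 8-connected blobs in a binary mask
#'
#' Number of 8-connected components of `TRUE` pixels, via iterative flood
#' fill. Used on the positive-signal mask inside one cell.
#'
#' @param mask logical matrix.
#' @return nonnegative integer component count.
#' @export
count_blobs <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  H <- nrow(mask); W <- ncol(mask)
  todo <- which(mask)
  if (length(todo) == 0) return(0L)
  seen <- matrix(FALSE, H, W)
  comp <- 0L
  for (px in todo) {
    if (seen[px]) next
    comp <- comp + 1L
    stack <- px
    seen[px] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% H + 1L
      c <- (cur - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > H || cc < 1L || cc > W) next
        idx <- (cc - 1L) * H + rr
        if (mask[idx] && !seen[idx]) {
          seen[idx] <- TRUE
          stack <- c(stack, idx)
        }
      }
    }
  }
  comp
}

#' Per-cell marker intensity features
#'
#' Given one cell's pixel intensities and a positivity threshold, computes
#' the feature block used throughout the pipeline: fraction of positive
#' pixels, integrated density (sum), mean, mean of the top 5% of pixels
#' (`ceiling(0.05 n)` pixels, at least one), maximum, Gini coefficient,
#' number of positive-signal blobs, and log1p / square-root transforms of
#' integrated density and top-5% mean.
#'
#' @param pixels numeric vector of the cell's pixel intensities.
#' @param threshold positivity threshold (pixels strictly above count).
#' @param coords optional integer `n x 2` matrix of the pixels' `(u, v)`
#'   positions; required for `blob_count` (otherwise `NA`).
#' @return named numeric vector of features.
#' @export
intensity_features <- function(pixels, threshold, coords = NULL) {
  n <- length(pixels)
  if (n == 0) stop("empty pixel vector", call. = FALSE)
  pos <- pixels > threshold
  k <- max(1L, ceiling(0.05 * n))
  top5 <- mean(sort(pixels, decreasing = TRUE)[seq_len(k)])
  blob <- NA_integer_
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 2)
    if (!any(pos)) blob <- 0L else {
      uu <- coords[pos, 1]; vv <- coords[pos, 2]
      msk <- matrix(FALSE, max(vv) - min(vv) + 1L, max(uu) - min(uu) + 1L)
      msk[cbind(vv - min(vv) + 1L, uu - min(uu) + 1L)] <- TRUE
      blob <- count_blobs(msk)
    }
  }
  idens <- sum(pixels)
  c(positive_fraction = mean(pos),
    integrated_density = idens,
    mean_intensity = mean(pixels),
    top5_mean = top5,
    max_intensity = max(pixels),
    gini = gini(pixels),
    blob_count = blob,
    log1p_integrated_density = log1p(idens),
    sqrt_integrated_density = sqrt(idens),
    log1p_top5_mean = log1p(top5),
    sqrt_top5_mean = sqrt(top5))
}

#' Names of the morphometric feature columns
#' @return character vector.
#' @export
morph_feature_names <- function() {
  c("area", "perimeter", "eccentricity", "solidity", "extent",
    "equivalent_diameter")
}

#' Morphometrics of one pixel region
#'
#' Standard region properties from a set of member pixel coordinates:
#' area (pixel count), perimeter (count of 4-neighbor boundary edges),
#' eccentricity (from the eigenvalues of the second central moment matrix;
#' 0 for a single pixel), solidity (area over the area of the convex hull of
#' the pixel squares), extent (area over bounding-box area) and equivalent
#' diameter `sqrt(4 area / pi)`.
#'
#' @param coords integer `n x 2` matrix of `(u, v)` pixel coordinates.
#' @return named numeric vector of the six morphometrics.
#' @export
morphometrics <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty region", call. = FALSE)
  u <- coords[, 1]; v <- coords[, 2]
  n <- nrow(coords)
  # perimeter: exposed 4-neighbor edges (integer-encoded membership test)
  M <- max(max(u), max(v)) + 3
  key <- (u + 1) * M + (v + 1)
  exposed <- 0L
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    exposed <- exposed + sum(!(((u + d[1] + 1) * M + (v + d[2] + 1)) %in% key))
  du <- u - mean(u); dv <- v - mean(v)
  muu <- mean(du^2); mvv <- mean(dv^2); muv <- mean(du * dv)
  tr <- muu + mvv
  disc <- sqrt(max((muu - mvv)^2 + 4 * muv^2, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  # solidity: pixels in the region over pixels inside the convex hull of
  # member pixel centers (discrete hull area, regionprops convention)
  hull_area <- n
  if (n >= 3) {
    hidx <- chull(u, v)
    if (length(hidx) >= 3) {
      cand <- expand.grid(u = min(u):max(u), v = min(v):max(v))
      inside <- sp::point.in.polygon(cand$u, cand$v, u[hidx], v[hidx])
      hull_area <- max(sum(inside > 0), n)
    }
  }
  bbox <- (max(u) - min(u) + 1) * (max(v) - min(v) + 1)
  c(area = n,
    perimeter = exposed,
    eccentricity = ecc,
    solidity = min(n / hull_area, 1),
    extent = n / bbox,
    equivalent_diameter = sqrt(4 * n / pi))
}

#' Morphometrics for every cell of a label image
#'
#' @param label_image integer label matrix (0 = background).
#' @return data frame with `cell_id`, centroid `u`, `v`, and the six
#'   morphometric columns, one row per cell.
#' @export
region_morphometrics <- function(label_image) {
  lab <- as.vector(label_image)
  keep <- lab > 0
  if (!any(keep)) stop("label image contains no cells", call. = FALSE)
  H <- nrow(label_image); W <- ncol(label_image)
  u <- rep(0:(W - 1), each = H)[keep]
  v <- rep(0:(H - 1), times = W)[keep]
  ids <- sort(unique(lab[keep]))
  idx <- split(seq_along(u), lab[keep])
  rows <- lapply(as.character(ids), function(id) {
    i <- idx[[id]]
    m <- morphometrics(cbind(u[i], v[i]))
    c(cell_id = as.integer(id), u = mean(u[i]), v = mean(v[i]), m)
  })
  as.data.frame(do.call(rbind, rows))
}

#' MorphScore: first principal component of z-scored morphometrics
#'
#' Columns are z-scored (mean 0, SD 1; near-constant columns dropped), then
#' projected onto the first principal component. The sign is fixed so that
#' the loading on `area` (or the first retained column if `area` was
#' dropped) is nonnegative, making larger cells score higher by convention.
#'
#' @param morph data frame or matrix of morphometric columns, n >= 3 rows.
#' @return list with `score` (numeric, mean 0), `explained_variance_ratio`,
#'   `loadings` (named), and `dropped` (names of constant columns removed).
#' @export
morph_score <- function(morph) {
  X <- as.matrix(morph)
  if (nrow(X) < 3) stop("need at least 3 cells for MorphScore", call. = FALSE)
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds < 1e-12]
  X <- X[, sds >= 1e-12, drop = FALSE]
  if (ncol(X) == 0) stop("all morphometric columns constant", call. = FALSE)
  Z <- scale(X)
  p <- prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- p$rotation[, 1, drop = FALSE]
  load1 <- stats::setNames(as.vector(rot), rownames(rot))
  anchor <- if ("area" %in% names(load1)) "area" else names(load1)[1]
  if (load1[[anchor]] < 0) load1 <- -load1
  score <- as.vector(Z %*% load1)
  list(score = score,
       explained_variance_ratio = p$sdev[1]^2 / sum(p$sdev^2),
       loadings = load1,
       dropped = dropped)
}

#' Assemble the per-cell feature table for one spot
#'
#' Combines centroids, morphometrics, MorphScore and, per marker, the
#' [intensity_features()] block (columns named `<marker>__<feature>`).
#' Thresholding is per cell per marker by default; with
#' `threshold_scope = "image"` a single threshold per marker is computed
#' from all cell pixels pooled.
#'
#' @param label_image integer label matrix.
#' @param channels named list of channel rasters (same shape as the mask).
#' @param threshold_scope `"cell"` or `"image"`.
#' @return data frame, one row per cell.
#' @export
build_cell_table <- function(label_image, channels,
                             threshold_scope = c("cell", "image")) {
  threshold_scope <- match.arg(threshold_scope)
  for (m in names(channels))
    if (!identical(dim(channels[[m]]), dim(label_image)))
      stop("channel ", m, " shape differs from label image", call. = FALSE)
  morph <- region_morphometrics(label_image)
  ms <- morph_score(morph[, morph_feature_names(), drop = FALSE])
  out <- cbind(morph, morph_score = ms$score)
  lab <- as.vector(label_image)
  keep <- lab > 0
  H <- nrow(label_image); W <- ncol(label_image)
  uu <- rep(0:(W - 1), each = H)[keep]
  vv <- rep(0:(H - 1), times = W)[keep]
  idx <- split(seq_along(uu), lab[keep])
  idx <- idx[as.character(morph$cell_id)]
  for (m in names(channels)) {
    chv <- as.vector(channels[[m]])[keep]
    thr_img <- if (threshold_scope == "image") cell_threshold(chv) else NULL
    feats <- t(vapply(idx, function(i) {
      px <- chv[i]
      thr <- thr_img %||% cell_threshold(px)
      intensity_features(px, thr, cbind(uu[i], vv[i]))
    }, intensity_features(1, 0, matrix(c(0L, 0L), 1))))
    colnames(feats) <- paste0(m, "__", colnames(feats))
    out <- cbind(out, as.data.frame(feats))
  }
  rownames(out) <- NULL
  attr(out, "morph_score_info") <- ms[c("explained_variance_ratio",
                                        "loadings", "dropped")]
  out
}
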