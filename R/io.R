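#' Robust percentile rescaling of a channel raster
#'
#' Clips pixel intensities to the `p_lo`th and `p_hi`th percentiles
#' (computed over all pixels, background included) and rescales affinely to
#' [0, 1], the standard normalization for mass-spectrometry imaging channels
#' whose dynamic range is dominated by a few hot pixels. A constant raster
#' (degenerate percentiles) maps to all zeros and is flagged rather than
#' producing NaN.
#'
#' @param raster numeric matrix, finite.
#' @param p_lo,p_hi clip percentiles in percent (defaults 1 and 99).
#' @return list with `raster` (values in [0, 1]), `p_lo_value`,
#'   `p_hi_value` (the clip intensities), and `degenerate` flag.
#' @export
robust_rescale <- function(raster, p_lo = 1, p_hi = 99) {
  if (length(raster) == 0) stop("empty raster", call. = FALSE)
  if (!all(is.finite(raster))) stop("raster contains non-finite values",
                                    call. = FALSE)
  stopifnot(p_lo >= 0, p_hi <= 100, p_lo < p_hi)
  q <- quantile(raster, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
  if (q[1] == q[2]) {
    out <- raster * 0
    return(list(raster = out, p_lo_value = q[1], p_hi_value = q[2],
                degenerate = TRUE))
  }
  out <- (pmin(pmax(raster, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  list(raster = out, p_lo_value = q[1], p_hi_value = q[2],
       degenerate = FALSE)
}

#' Extract cell centroids from a label image
#'
#' One row per nonzero label; the centroid is the unweighted mean of member
#' pixel centers in the package's 0-based `(u, v) = (column, row)`
#' convention.
#'
#' @param label_image integer matrix, 0 = background.
#' @return data frame with columns `cell_id`, `u`, `v`, ordered by cell id.
#' @export
extract_centroids <- function(label_image) {
  lab <- as.vector(label_image)
  if (any(lab < 0)) stop("labels must be nonnegative", call. = FALSE)
  keep <- lab > 0
  if (!any(keep)) stop("label image contains no cells", call. = FALSE)
  H <- nrow(label_image); W <- ncol(label_image)
  u <- rep(0:(W - 1), each = H)[keep]
  v <- rep(0:(H - 1), times = W)[keep]
  f <- factor(lab[keep])
  data.frame(cell_id = as.integer(levels(f)),
             u = as.vector(tapply(u, f, mean)),
             v = as.vector(tapply(v, f, mean)),
             row.names = NULL)
}

#' Load a spot directory written by [write_sample()]
#'
#' Reads the label TIFF and every channel TIFF named in the JSON sidecar,
#' undoing the storage scaling, and checks that all rasters share the mask's
#' shape.
#'
#' @param dir directory containing `label.tif`, `<marker>.tif` files and
#'   `sample.json`.
#' @return list with `label_image` (integer matrix), `channels` (named list
#'   of numeric matrices) and `meta` (the parsed sidecar).
#' @export
load_sample <- function(dir) {
  sidecar <- file.path(dir, "sample.json")
  labf <- file.path(dir, "label.tif")
  for (f in c(sidecar, labf))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  lab <- tiff::readTIFF(labf, as.is = TRUE)
  storage.mode(lab) <- "integer"
  channels <- list()
  for (m in meta$markers) {
    f <- file.path(dir, paste0(m, ".tif"))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    ch <- tiff::readTIFF(f) * meta$channel_scale[[m]]
    if (!identical(dim(ch), dim(lab)))
      stop("shape mismatch between ", f, " and label.tif", call. = FALSE)
    channels[[m]] <- ch
  }
  list(label_image = lab, channels = channels, meta = meta)
}

#' Write / read a per-cell feature table as CSV
#'
#' Plain CSV with a header row, one row per cell; numeric columns survive a
#' round trip to full double precision (17 significant digits).
#'
#' @param table data frame, one row per cell.
#' @param path CSV path.
#' @return `path` invisibly ([write_cell_table()]); the table
#'   ([read_cell_table()]).
#' @export
write_cell_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  read.csv(path, check.names = FALSE)
}
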