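#' Otsu threshold of a pixel vector
#'
#' Exhaustive maximization of between-class variance over candidate
#' thresholds (midpoints between consecutive sorted unique values), suitable
#' for the short continuous-valued pixel vectors of a single cell.
#'
#' @param pixels numeric vector.
#' @return threshold; `+Inf` for a constant input (no positive pixels).
#' @export
otsu_threshold <- function(pixels) {
  if (length(pixels) == 0) stop("empty pixel vector", call. = FALSE)
  v <- sort(unique(pixels))
  if (length(v) < 2) return(Inf)
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(pixels)
  s <- sort(pixels)
  csum <- cumsum(s)
  # class split after index k for candidate k (s sorted, cand between uniques)
  k <- findInterval(cand, s)
  w0 <- k / n
  m0 <- csum[k] / k
  m1 <- (csum[n] - csum[k]) / (n - k)
  between <- w0 * (1 - w0) * (m0 - m1)^2
  cand[which.max(between)]
}

#' Li minimum cross-entropy threshold with Otsu fallback
#'
#' Iterates the fixed-point update of Li's minimum cross-entropy criterion,
#' `t <- (mu_fg - mu_bg) / (log(mu_fg) - log(mu_bg))`, on the
#' minimum-shifted pixel values. If the input is degenerate (fewer than
#' three distinct values) or the iteration fails to converge, falls back to
#' [otsu_threshold()]; a constant input yields `+Inf` (no positives).
#'
#' @param pixels numeric vector (one cell's pixels).
#' @param max_iter,tol iteration controls.
#' @return threshold on the original intensity scale.
#' @export
cell_threshold <- function(pixels, max_iter = 100, tol = NULL) {
  if (length(pixels) == 0) stop("empty pixel vector", call. = FALSE)
  if (!all(is.finite(pixels))) stop("non-finite pixels", call. = FALSE)
  nuniq <- length(unique(pixels))
  if (nuniq < 2) return(Inf)
  if (nuniq < 3) return(otsu_threshold(pixels))
  lo <- min(pixels)
  x <- pixels - lo
  rng <- max(x)
  tol <- tol %||% (rng * 1e-6)
  eps <- rng * 1e-12 + .Machine$double.eps
  t_cur <- mean(x)
  for (it in seq_len(max_iter)) {
    bg <- x[x <= t_cur]; fg <- x[x > t_cur]
    if (length(bg) == 0 || length(fg) == 0) return(otsu_threshold(pixels))
    m_bg <- max(mean(bg), eps)
    m_fg <- max(mean(fg), eps)
    if (abs(log(m_fg) - log(m_bg)) < 1e-15) return(otsu_threshold(pixels))
    t_new <- (m_fg - m_bg) / (log(m_fg) - log(m_bg))
    if (!is.finite(t_new)) return(otsu_threshold(pixels))
    if (abs(t_new - t_cur) < tol) return(t_new + lo)
    t_cur <- t_new
  }
  otsu_threshold(pixels)
}
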