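#' Specify a smooth coefficient field over a spot
#'
#' A `field_spec` describes one spatially varying regression coefficient
#' surface beta(u, v) that the synthetic generator imposes, in intensity
#' units per unit of the predictor (or plain intensity units for the
#' intercept surface).
#'
#' Field kinds:
#' \describe{
#'   \item{constant}{`amplitude` everywhere; `length_scale` unused.}
#'   \item{linear-gradient}{linear ramp along u from `-amplitude` at the
#'     left edge to `+amplitude` at the right edge (zero-mean across the
#'     spot); `length_scale` unused.}
#'   \item{gaussian-bump}{`amplitude * exp(-d^2 / (2 * length_scale^2))`
#'     with `d` the distance to the spot center.}
#'   \item{zero-mean-sinusoid}{`amplitude * sin(2*pi*u / length_scale) *
#'     cos(2*pi*v / length_scale)`; `length_scale` is the wavelength, and
#'     the surface has zero spatial mean over whole periods.}
#' }
#'
#' @param kind one of `"constant"`, `"linear-gradient"`, `"gaussian-bump"`,
#'   `"zero-mean-sinusoid"`.
#' @param amplitude finite numeric amplitude.
#' @param length_scale positive length scale in pixels.
#' @return an object of class `field_spec`.
#' @export
#' @examples
#' f <- field_spec("gaussian-bump", amplitude = 2, length_scale = 64)
#' eval_field(f, u = 128, v = 128, shape = c(256, 256))
field_spec <- function(kind = c("constant", "linear-gradient",
                                "gaussian-bump", "zero-mean-sinusoid"),
                       amplitude = 1, length_scale = 128) {
  kind <- match.arg(kind)
  if (!is.finite(amplitude)) stop("amplitude must be finite", call. = FALSE)
  if (!is.finite(length_scale) || length_scale <= 0)
    stop("length_scale must be > 0", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude,
                 length_scale = length_scale),
            class = "field_spec")
}

#' Evaluate a coefficient field at locations
#'
#' @param spec a [field_spec()].
#' @param u,v numeric vectors of 0-based pixel coordinates
#'   (u = column, v = row).
#' @param shape integer `(H, W)` raster shape the field lives on; used to
#'   anchor the gradient range and the bump center.
#' @return numeric vector of field values at `(u, v)`.
#' @export
eval_field <- function(spec, u, v, shape) {
  stopifnot(inherits(spec, "field_spec"), length(u) == length(v),
            length(shape) == 2)
  H <- shape[1]; W <- shape[2]
  a <- spec$amplitude; L <- spec$length_scale
  switch(spec$kind,
    "constant" = rep(a, length(u)),
    "linear-gradient" = a * (2 * u / (W - 1) - 1),
    "gaussian-bump" = {
      d2 <- (u - (W - 1) / 2)^2 + (v - (H - 1) / 2)^2
      a * exp(-d2 / (2 * L^2))
    },
    "zero-mean-sinusoid" = a * sin(2 * pi * u / L) * cos(2 * pi * v / L)
  )
}
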