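# sRGB rendering of multispectral stacks for visual QC.
#
# The render is for inspection, not colorimetric accuracy: band
# transmittances are interpolated to a 5-nm grid over 380-780 nm, weighted
# by a daylight illuminant and the CIE 1931 2-degree color matching
# functions, converted to linear sRGB with the standard D65 matrix,
# white-balanced so that full transmittance (glass) renders as pure white,
# then gamma-encoded.

# Piecewise-Gaussian analytic approximation of the CIE 1931 2-degree color
# matching functions (Wyman, Sloan & Shirley 2013, J. Computer Graphics
# Techniques 2(2)); accurate to about 1% of peak, ample for a QC render.
cie1931_cmf <- function(wl) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  xbar <- 1.056 * g(wl, 599.8, 37.9, 31.0) +
          0.362 * g(wl, 442.0, 16.0, 26.7) -
          0.065 * g(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * g(wl, 568.8, 46.9, 40.5) +
          0.286 * g(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * g(wl, 437.0, 11.8, 36.0) +
          0.681 * g(wl, 459.0, 26.0, 13.8)
  cbind(x = xbar, y = ybar, z = zbar)
}

# Relative spectral power of the rendering illuminant: Planckian radiator at
# 6504 K, a smooth analytic stand-in for average daylight (D65 has the same
# correlated color temperature). The residual chromaticity difference is
# removed by the glass white balance in ms_to_srgb().
daylight_spd <- function(wl) {
  h <- 6.62607015e-34; c <- 2.99792458e8; kb <- 1.380649e-23
  lam <- wl * 1e-9
  m <- lam^-5 / (exp(h * c / (lam * kb * 6504)) - 1)
  m / max(m)
}

# linear sRGB (D65) from CIE XYZ, IEC 61966-2-1
xyz_to_linear_srgb <- matrix(c(
   3.2406, -1.5372, -0.4986,
  -0.9689,  1.8758,  0.0415,
   0.0557, -0.2040,  1.0570), 3, 3, byrow = TRUE)

srgb_gamma <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Render a multispectral stack as an sRGB image
#'
#' Converts per-band transmittance `T_k = g_k / g0_k` into a display sRGB
#' image: transmittances are linearly interpolated onto a 5-nm wavelength
#' grid (constant extrapolation beyond the outer bands), integrated against
#' a daylight illuminant and the CIE 1931 color matching functions to XYZ,
#' mapped to linear sRGB, white-balanced so a fully transmitting pixel is
#' exactly white, then gamma-encoded and clipped to `[0, 1]`.
#'
#' The render is exposure-invariant: scaling `g` and `g0` together leaves
#' it unchanged.
#'
#' @param image an [ms_image]; bands outside 380-780 nm are dropped with a
#'   warning.
#' @param white a [white_reference] matching the image bands.
#' @return Object of class `rgb_image`: list with `data` (H x W x 3,
#'   gamma-encoded sRGB in `[0, 1]`).
#' @examples
#' img <- ms_image(array(50, c(2, 2, 5)), seq(460, 620, 40))
#' rgb <- ms_to_srgb(img, white_reference(rep(50, 5)))  # glass -> white
#' @export
ms_to_srgb <- function(image, white) {
  stopifnot(inherits(image, "ms_image"))
  white <- as_white(white)
  n <- dim(image$data)[3L]
  if (length(white) != n)
    stop("band-count mismatch between image and white reference", call. = FALSE)
  vis <- image$wavelengths_nm >= 380 & image$wavelengths_nm <= 780
  if (!any(vis))
    stop("no bands in the visible range 380-780 nm", call. = FALSE)
  if (!all(vis))
    warning(sum(!vis), " band(s) outside 380-780 nm ignored in the render")
  wl <- image$wavelengths_nm[vis]
  d <- dim(image$data)
  tmat <- matrix(image$data, d[1] * d[2], d[3])[, vis, drop = FALSE]
  tmat <- sweep(tmat, 2L, unclass(white)[vis], "/")

  grid <- seq(380, 780, by = 5)
  # interpolation matrix: row k of `w` gives band weights for grid point k
  w <- interp_weights(wl, grid)
  spd <- daylight_spd(grid) * cie1931_cmf(grid)       # illuminant * cmf
  xyz <- tmat %*% t(w) %*% spd                        # pixels x 3
  rgb <- xyz %*% t(xyz_to_linear_srgb)
  white_rgb <- drop(rep(1, length(grid)) %*% spd %*% t(xyz_to_linear_srgb))
  rgb <- sweep(rgb, 2L, white_rgb, "/")               # glass -> (1,1,1)
  out <- array(srgb_gamma(rgb), c(d[1], d[2], 3L))
  structure(list(data = out), class = "rgb_image")
}

# sparse-free linear interpolation weights from sample points x onto grid,
# constant beyond the range of x
interp_weights <- function(x, grid) {
  n <- length(x)
  w <- matrix(0, length(grid), n)
  for (k in seq_along(grid)) {
    g <- grid[k]
    if (g <= x[1]) w[k, 1] <- 1
    else if (g >= x[n]) w[k, n] <- 1
    else {
      i <- findInterval(g, x)
      f <- (g - x[i]) / (x[i + 1] - x[i])
      w[k, i] <- 1 - f
      w[k, i + 1] <- f
    }
  }
  w
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("rgb_image: %d x %d, sRGB in [0,1]\n", d[1], d[2]))
  invisible(x)
}

#' Mean sRGB feature vector of a patch
#'
#' Averages the gamma-encoded sRGB channels over a pixel mask, yielding the
#' length-3 `(R, G, B)` feature vector in `[0, 1]` used by the RGB-based
#' baseline discriminant.
#'
#' @param rgb an `rgb_image` from [ms_to_srgb()].
#' @param mask logical H x W matrix; must select at least one pixel.
#' @return Named numeric vector `c(R =, G =, B =)`.
#' @export
srgb_features <- function(rgb, mask) {
  stopifnot(inherits(rgb, "rgb_image"))
  mask <- check_mask(mask, dim(rgb$data)[1:2])
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  out <- vapply(1:3, function(k) mean(rgb$data[, , k][mask]), 0)
  names(out) <- c("R", "G", "B")
  out
}
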