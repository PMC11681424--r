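#' Convert band intensities to spectral absorbance
#'
#' Computes the per-pixel, per-band base-10 absorbance (optical density)
#' `alpha_k = log10(g0_k / g_k)` from a multispectral stack and a white
#' (glass) reference. Under a narrowband sensitivity approximation each
#' channel samples the spectrum at its center wavelength, so the channel
#' absorbance is the log-ratio of incident to transmitted counts.
#'
#' Intensities are clipped below at `floor` before the logarithm so that
#' zero or near-zero counts (quantization, dark current) produce a large
#' finite absorbance rather than `Inf`. Pixels brighter than the glass
#' (shot noise) yield small negative absorbances, which are kept: the
#' least-squares unmixing absorbs them.
#'
#' @param image an [ms_image].
#' @param white a [white_reference] with matching band count.
#' @param floor positive lower clip for transmitted counts before the log
#'   (default 1 count).
#' @return An [absorbance_image] of the same spatial size and band set.
#' @examples
#' img <- ms_image(array(c(100, 10), c(1, 1, 2)), c(440, 460))
#' a <- compute_absorbance(img, white_reference(c(100, 100)))
#' a$data[1, 1, ]  # 0 and 1
#' @export
compute_absorbance <- function(image, white, floor = 1) {
  stopifnot(inherits(image, "ms_image"))
  white <- as_white(white)
  n <- dim(image$data)[3L]
  if (length(white) != n)
    stop("band-count mismatch: image has ", n, " bands, white reference has ",
         length(white), call. = FALSE)
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("`floor` must be a single positive number", call. = FALSE)
  g0 <- rep(unclass(white), each = prod(dim(image$data)[1:2]))
  a <- log10(g0 / pmax(image$data, floor))
  absorbance_image(array(a, dim(image$data)), image$wavelengths_nm)
}

as_white <- function(white) {
  if (inherits(white, "white_reference")) white else white_reference(white)
}

#' Lambert-Beer forward model
#'
#' Renders the noiseless multispectral observation of a dye amount map:
#' per pixel and band, `g_k = g0_k * 10^(-[H c]_k)` where `H` is the stain
#' matrix and `c` the dye amount vector. This is the exact inverse of
#' [compute_absorbance()] followed by [unmix()] in the noiseless case.
#'
#' @param amounts a [dye_amount_map]; dye names must match `stains`.
#' @param stains a [stain_matrix].
#' @param white a [white_reference] with one entry per stain-matrix band.
#' @return An [ms_image] with the stain matrix's band set.
#' @export
forward_model <- function(amounts, stains, white) {
  stopifnot(inherits(amounts, "dye_amount_map"), inherits(stains, "stain_matrix"))
  white <- as_white(white)
  if (!identical(amounts$dye_names, stains$dye_names))
    stop("dye names of amounts (", paste(amounts$dye_names, collapse = ","),
         ") and stain matrix (", paste(stains$dye_names, collapse = ","),
         ") differ", call. = FALSE)
  n <- nrow(stains$coefficients)
  if (length(white) != n)
    stop("white reference length does not match stain-matrix band count",
         call. = FALSE)
  if (any(amounts$data < 0))
    warning("negative dye amounts in forward model; transmittance will exceed the glass level")
  d <- dim(amounts$data)
  cmat <- matrix(amounts$data, d[1] * d[2], d[3])     # pixels x dyes
  alpha <- tcrossprod(cmat, stains$coefficients)      # pixels x bands
  g <- sweep(10^(-alpha), 2L, unclass(white), "*")
  ms_image(array(g, c(d[1], d[2], n)), stains$wavelengths_nm)
}

# Moore-Penrose pseudo-inverse via SVD; tol relative to largest singular value
pinv <- function(x, tol = sqrt(.Machine$double.eps)) {
  s <- svd(x)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Unmix per-pixel dye amounts from absorbance
#'
#' Solves the linear mixing model `a = H c` independently at every pixel by
#' applying the Moore-Penrose pseudo-inverse of the stain matrix,
#' `c = H^+ a`, the least-squares amount estimate for an overdetermined
#' system (more bands than dyes). Negative solutions, which arise from
#' noise, can be clipped to zero after solving; downstream masking and
#' patch logic assume nonnegative amounts.
#'
#' @param absorbance an [absorbance_image].
#' @param stains a [stain_matrix] with the same band set (M < N, full
#'   column rank).
#' @param clip_negative clip negative amount estimates to 0 after solving
#'   (default `TRUE`).
#' @return A raw (unnormalized) [dye_amount_map].
#' @seealso [forward_model()] for the inverse, [normalize_amounts()].
#' @export
unmix <- function(absorbance, stains, clip_negative = TRUE) {
  stopifnot(inherits(absorbance, "absorbance_image"),
            inherits(stains, "stain_matrix"))
  n <- dim(absorbance$data)[3L]
  if (n != nrow(stains$coefficients))
    stop("band-count mismatch: absorbance has ", n, " bands, stain matrix has ",
         nrow(stains$coefficients), call. = FALSE)
  if (!isTRUE(all.equal(absorbance$wavelengths_nm, stains$wavelengths_nm)))
    warning("absorbance and stain-matrix wavelengths differ; unmixing by band order")
  d <- dim(absorbance$data)
  amat <- matrix(absorbance$data, d[1] * d[2], d[3])  # pixels x bands
  cmat <- amat %*% t(pinv(stains$coefficients))       # pixels x dyes
  if (clip_negative) cmat[cmat < 0] <- 0
  dye_amount_map(array(cmat, c(d[1], d[2], ncol(cmat))), stains$dye_names)
}
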