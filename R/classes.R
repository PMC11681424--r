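#' Multispectral image stack
#'
#' Container for an H x W x N stack of nonnegative band intensities together
#' with the band center wavelengths. Band order follows the third array
#' dimension and must match the (strictly increasing) wavelength vector.
#'
#' @param data numeric array, H x W x N, intensities in arbitrary camera
#'   units; all values must be nonnegative and finite. A matrix is accepted
#'   for a single-band image.
#' @param wavelengths_nm strictly increasing numeric vector of band center
#'   wavelengths in nanometres, one per band.
#' @param pixel_size_um optional positive pixel pitch in micrometres.
#' @return An object of class `ms_image` with elements `data`,
#'   `wavelengths_nm` and `pixel_size_um`.
#' @examples
#' img <- ms_image(array(100, c(4, 4, 3)), c(440, 460, 480))
#' dim(img)
#' @export
ms_image <- function(data, wavelengths_nm, pixel_size_um = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an H x W x N array", call. = FALSE)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  n <- dim(data)[3L]
  if (length(wavelengths_nm) != n)
    stop("number of bands (", n, ") does not match length(wavelengths_nm) (",
         length(wavelengths_nm), ")", call. = FALSE)
  if (n < 1L) stop("at least one band is required", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  if (any(data < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (n > 1L && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be strictly increasing", call. = FALSE)
  if (length(pixel_size_um) == 0L) pixel_size_um <- NULL
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0))
    stop("pixel_size_um must be a positive number", call. = FALSE)
  structure(list(data = data, wavelengths_nm = wavelengths_nm,
                 pixel_size_um = pixel_size_um),
            class = "ms_image")
}

#' @export
dim.ms_image <- function(x) dim(x$data)

#' @export
print.ms_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ms_image: %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm)))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  if (!is.null(x$pixel_size_um))
    cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  invisible(x)
}

#' White (glass) reference intensities
#'
#' Per-band incident-light intensities measured over an unstained glass
#' region, used to convert raw counts into transmittance and absorbance.
#' Typically obtained with [glass_reference()] as the mean over a
#' user-designated glass area.
#'
#' @param g0 positive numeric vector, one intensity per band.
#' @return Object of class `white_reference` (a validated numeric vector).
#' @export
white_reference <- function(g0) {
  g0 <- as.numeric(g0)
  if (length(g0) < 1L || anyNA(g0) || any(!is.finite(g0)) || any(g0 <= 0))
    stop("white reference intensities must all be positive and finite",
         call. = FALSE)
  structure(g0, class = "white_reference")
}

#' @export
print.white_reference <- function(x, ...) {
  cat("white_reference:", length(x), "bands, intensities",
      paste(signif(unclass(x), 4), collapse = " "), "\n")
  invisible(x)
}

#' Measure a white reference from a glass region
#'
#' Averages the intensities of an [ms_image] over a designated unstained
#' glass area, one mean per band.
#'
#' @param image an [ms_image].
#' @param mask logical H x W matrix marking the glass area (`TRUE` = glass).
#' @return A [white_reference] of length N.
#' @export
glass_reference <- function(image, mask) {
  stopifnot(inherits(image, "ms_image"))
  mask <- check_mask(mask, dim(image$data)[1:2])
  if (!any(mask)) stop("glass mask is empty", call. = FALSE)
  n <- dim(image$data)[3L]
  g0 <- vapply(seq_len(n), function(k) mean(image$data[, , k][mask]), 0)
  white_reference(g0)
}

#' Absorbance image
#'
#' H x W x N stack of per-band spectral absorbances (base-10 optical
#' densities). Usually produced by [compute_absorbance()]; the constructor
#' only validates.
#'
#' @param data numeric H x W x N array of finite absorbances (negative
#'   values can occur from noise when a pixel is brighter than the glass).
#' @param wavelengths_nm band centers, as in [ms_image()].
#' @return Object of class `absorbance_image`.
#' @export
absorbance_image <- function(data, wavelengths_nm) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an H x W x N array", call. = FALSE)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (dim(data)[3L] != length(wavelengths_nm))
    stop("band count does not match wavelengths_nm", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("absorbance must be finite everywhere; clip saturated pixels first",
         call. = FALSE)
  structure(list(data = data, wavelengths_nm = wavelengths_nm),
            class = "absorbance_image")
}

#' @export
dim.absorbance_image <- function(x) dim(x$data)

#' @export
print.absorbance_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("absorbance_image: %d x %d pixels, %d bands, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' Stain matrix
#'
#' N x M matrix whose columns are the unit-norm spectral absorption
#' coefficient vectors of the M dyes sampled at the N band wavelengths.
#' Unmixing solves `absorbance = coefficients %*% amounts` per pixel, so the
#' matrix must be tall (M < N) and of full column rank.
#'
#' @param coefficients numeric N x M matrix, nonnegative entries.
#' @param dye_names character vector of M dye labels; defaults to the
#'   matrix column names, or `c("H","EY","LG","OG")` when M = 4.
#' @param wavelengths_nm band centers (length N, strictly increasing).
#' @param normalize if `TRUE` (default) columns are rescaled to unit
#'   Euclidean norm.
#' @param max_condition error if the condition number exceeds this bound
#'   (near-collinear dye spectra make unmixing unstable).
#' @return Object of class `stain_matrix` with elements `coefficients`
#'   (dimnames set), `dye_names`, `wavelengths_nm`, `condition_number`.
#' @seealso [build_stain_matrix()], [default_spectra()], [unmix()]
#' @export
stain_matrix <- function(coefficients, dye_names = NULL, wavelengths_nm,
                         normalize = TRUE, max_condition = 1e6) {
  coefficients <- as.matrix(coefficients)
  n <- nrow(coefficients); m <- ncol(coefficients)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (is.null(dye_names)) {
    dye_names <- colnames(coefficients)
    if (is.null(dye_names) && m == 4L) dye_names <- c("H", "EY", "LG", "OG")
    if (is.null(dye_names)) dye_names <- paste0("dye", seq_len(m))
  }
  if (length(dye_names) != m)
    stop("dye_names must have one entry per column", call. = FALSE)
  if (anyDuplicated(dye_names))
    stop("dye_names must be unique", call. = FALSE)
  if (length(wavelengths_nm) != n)
    stop("wavelengths_nm must have one entry per row", call. = FALSE)
  if (m >= n)
    stop("need fewer dyes than bands (M < N); got M = ", m, ", N = ", n,
         call. = FALSE)
  if (anyNA(coefficients) || any(!is.finite(coefficients)))
    stop("coefficients must be finite", call. = FALSE)
  if (any(coefficients < 0))
    stop("spectral absorption coefficients must be nonnegative", call. = FALSE)
  nrm <- sqrt(colSums(coefficients^2))
  if (any(nrm == 0))
    stop("zero column for dye(s): ",
         paste(dye_names[nrm == 0], collapse = ", "), call. = FALSE)
  if (normalize) coefficients <- sweep(coefficients, 2L, nrm, "/")
  sv <- svd(coefficients, nu = 0, nv = 0)$d
  kappa <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(kappa) || kappa > max_condition) {
    stop("stain matrix is rank deficient or ill conditioned (condition ",
         "number ", format(kappa, digits = 4), "); collinear dyes: ",
         paste(collinear_pairs(coefficients, dye_names), collapse = "; "),
         call. = FALSE)
  }
  dimnames(coefficients) <- list(wavelengths_nm, dye_names)
  structure(list(coefficients = coefficients, dye_names = dye_names,
                 wavelengths_nm = wavelengths_nm, condition_number = kappa),
            class = "stain_matrix")
}

# name the most nearly collinear column pairs (cosine > 0.999)
collinear_pairs <- function(coefficients, dye_names) {
  u <- sweep(coefficients, 2L, sqrt(colSums(coefficients^2)), "/")
  g <- abs(crossprod(u))
  bad <- which(g > 0.999 & upper.tri(g), arr.ind = TRUE)
  if (nrow(bad) == 0L) return("(no single collinear pair; joint degeneracy)")
  apply(bad, 1L, function(ij) paste(dye_names[ij[1]], "~", dye_names[ij[2]]))
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat(sprintf("stain_matrix: %d bands x %d dyes (%s), condition number %.3g\n",
              nrow(x$coefficients), ncol(x$coefficients),
              paste(x$dye_names, collapse = ", "), x$condition_number))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Per-pixel dye amount map
#'
#' H x W x M stack of unitless relative dye amounts, one plane per dye, as
#' produced by [unmix()]. Amounts are raw pseudo-inverse estimates until
#' passed through [normalize_amounts()], which sets the `normalized` flag.
#'
#' @param data numeric H x W x M array (a matrix is promoted to M = 1).
#' @param dye_names character vector of M dye labels.
#' @param normalized logical flag; `TRUE` after reference-value division.
#' @return Object of class `dye_amount_map`.
#' @export
dye_amount_map <- function(data, dye_names, normalized = FALSE) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an H x W x M array", call. = FALSE)
  if (dim(data)[3L] != length(dye_names))
    stop("number of planes does not match dye_names", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("dye amounts must be finite", call. = FALSE)
  structure(list(data = data, dye_names = as.character(dye_names),
                 normalized = isTRUE(normalized)),
            class = "dye_amount_map")
}

#' @export
dim.dye_amount_map <- function(x) dim(x$data)

#' @export
print.dye_amount_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dye_amount_map: %d x %d pixels, %d dyes (%s)%s\n",
              d[1], d[2], d[3], paste(x$dye_names, collapse = ", "),
              if (x$normalized) ", normalized" else ""))
  for (i in seq_len(d[3]))
    cat(sprintf("  %-3s range [%.4g, %.4g]  mean %.4g\n", x$dye_names[i],
                min(x$data[, , i]), max(x$data[, , i]), mean(x$data[, , i])))
  invisible(x)
}

# internal: validate a logical H x W mask against expected dimensions
check_mask <- function(mask, dims) {
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical H x W matrix", call. = FALSE)
  if (!identical(dim(mask), as.integer(dims)))
    stop("mask dimensions ", paste(dim(mask), collapse = " x "),
         " do not match image dimensions ", paste(dims, collapse = " x "),
         call. = FALSE)
  mask
}
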