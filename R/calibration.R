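#' Estimate one stain vector from single-stain absorbance samples
#'
#' A specimen stained with a single dye has, at every pixel, an absorbance
#' spectrum proportional to that dye's spectral absorption coefficient
#' vector: `a = beta * eps` with `beta` the local dye abundance. The
#' direction is therefore recovered by normalizing each sampled pixel
#' spectrum to unit Euclidean norm (removing `beta`), averaging the unit
#' vectors over pixels to suppress noise, and renormalizing the mean.
#'
#' @param pixels numeric matrix with one absorbance spectrum per row
#'   (pixels x bands), or a list of equal-length numeric vectors.
#' @param min_pixels warn when fewer samples than this are supplied
#'   (default 25, i.e. a 5 x 5 patch).
#' @return Unit-norm numeric vector of length N (the estimated stain
#'   matrix column). Warns if any entry is negative, which indicates the
#'   samples were not from a single-stain region.
#' @examples
#' v <- c(1, 2, 2) / 3
#' estimate_stain_vector(rbind(2 * v, 5 * v))  # recovers v
#' @export
estimate_stain_vector <- function(pixels, min_pixels = 25L) {
  if (is.list(pixels)) pixels <- do.call(rbind, pixels)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L) stop("no calibration pixels supplied", call. = FALSE)
  if (anyNA(pixels)) stop("calibration pixels contain NA", call. = FALSE)
  nrm <- sqrt(rowSums(pixels^2))
  if (any(nrm == 0)) {
    warning(sum(nrm == 0), " all-zero calibration pixel(s) skipped")
    pixels <- pixels[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
    if (nrow(pixels) == 0L)
      stop("all calibration pixels are zero", call. = FALSE)
  }
  if (nrow(pixels) < min_pixels)
    warning("only ", nrow(pixels), " calibration pixels (< ", min_pixels,
            "); the estimate may be noisy")
  v <- colMeans(pixels / nrm)
  v <- v / sqrt(sum(v^2))
  if (any(v < 0))
    warning("estimated stain vector has negative entries; ",
            "check that the samples come from a single-stain region")
  v
}

#' Assemble a stain matrix from per-dye vectors
#'
#' Binds estimated stain vectors into a [stain_matrix], preserving the
#' given dye order, and validates rank/conditioning.
#'
#' @param vectors named list of equal-length numeric vectors, one per dye
#'   (typically from [estimate_stain_vector()]).
#' @param wavelengths_nm band centers, length matching the vectors.
#' @param max_condition conditioning bound passed to [stain_matrix()];
#'   collinear columns raise an error naming the offending dyes.
#' @return A [stain_matrix].
#' @export
build_stain_matrix <- function(vectors, wavelengths_nm, max_condition = 1e6) {
  if (!is.list(vectors) || is.null(names(vectors)) || any(names(vectors) == ""))
    stop("`vectors` must be a named list (one entry per dye)", call. = FALSE)
  if (length(vectors) < 2L) stop("need at least two dyes", call. = FALSE)
  len <- vapply(vectors, length, 0L)
  if (length(unique(len)) != 1L)
    stop("all stain vectors must have the same length", call. = FALSE)
  stain_matrix(do.call(cbind, vectors), dye_names = names(vectors),
               wavelengths_nm = wavelengths_nm, max_condition = max_condition)
}

#' Reference values for dye-amount normalization
#'
#' For each dye, takes a high percentile (default the 99th) of its raw
#' unmixed amounts over a user-designated well-stained region — nuclei for
#' hematoxylin, cytoplasm for the counterstains. Dividing raw amounts by
#' these references scales a well-stained region to about unit amount,
#' making maps comparable across dyes.
#'
#' @param amounts raw [dye_amount_map].
#' @param regions named list of logical H x W masks, one per dye to
#'   calibrate; each mask must be nonempty.
#' @param percentile percentile in (0, 100] (default 99).
#' @return Named numeric vector of positive reference values `q`, class
#'   `reference_values`.
#' @seealso [normalize_amounts()], [preset_reference_values()]
#' @export
compute_reference_values <- function(amounts, regions, percentile = 99) {
  stopifnot(inherits(amounts, "dye_amount_map"))
  if (!is.list(regions) || is.null(names(regions)))
    stop("`regions` must be a named list of masks", call. = FALSE)
  unknown <- setdiff(names(regions), amounts$dye_names)
  if (length(unknown))
    stop("unknown dye(s) in regions: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]", call. = FALSE)
  q <- vapply(names(regions), function(dye) {
    mask <- check_mask(regions[[dye]], dim(amounts$data)[1:2])
    if (!any(mask)) stop("empty mask for dye ", dye, call. = FALSE)
    plane <- amounts$data[, , match(dye, amounts$dye_names)]
    stats::quantile(plane[mask], percentile / 100, names = FALSE)
  }, 0)
  reference_values(q)
}

#' @rdname compute_reference_values
#' @param q named positive numeric vector of reference values.
#' @export
reference_values <- function(q) {
  if (is.list(q)) q <- unlist(q)
  if (is.null(names(q)) || any(names(q) == ""))
    stop("reference values must be named by dye", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("reference values must be positive and finite", call. = FALSE)
  structure(q, class = "reference_values")
}

#' @export
print.reference_values <- function(x, ...) {
  cat("reference_values:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Normalize dye amounts by reference values
#'
#' Divides each dye plane elementwise by that dye's reference value and
#' sets the `normalized` flag. Refuses to normalize twice.
#'
#' @param amounts a raw [dye_amount_map].
#' @param refs a [reference_values] covering every dye of `amounts`.
#' @return A normalized [dye_amount_map].
#' @export
normalize_amounts <- function(amounts, refs) {
  stopifnot(inherits(amounts, "dye_amount_map"))
  refs <- reference_values(refs)
  if (amounts$normalized)
    stop("amounts are already normalized", call. = FALSE)
  missing <- setdiff(amounts$dye_names, names(refs))
  if (length(missing))
    stop("no reference value for dye(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  q <- unclass(refs)[amounts$dye_names]
  d <- dim(amounts$data)
  out <- amounts$data / rep(q, each = d[1] * d[2])
  dye_amount_map(out, amounts$dye_names, normalized = TRUE)
}

#' Background thresholds from a user-selected glass region
#'
#' The glass background of a real slide retains a slight residual stain, so
#' a pixel is only treated as unstained when every dye amount falls below a
#' per-dye threshold. The thresholds are taken from the histogram of
#' amounts inside a user-selected background region, by default its 99th
#' percentile per dye.
#'
#' @param amounts a [dye_amount_map] (raw or normalized; thresholds apply
#'   to whichever scale they were derived on).
#' @param background_mask logical H x W mask of the selected glass area.
#' @param percentile percentile in (0, 100] (default 99).
#' @return Named nonnegative numeric vector `t`, class
#'   `background_thresholds`.
#' @export
derive_background_thresholds <- function(amounts, background_mask,
                                         percentile = 99) {
  stopifnot(inherits(amounts, "dye_amount_map"))
  mask <- check_mask(background_mask, dim(amounts$data)[1:2])
  if (!any(mask)) stop("background mask is empty", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]", call. = FALSE)
  t <- vapply(seq_along(amounts$dye_names), function(i)
    stats::quantile(amounts$data[, , i][mask], percentile / 100,
                    names = FALSE), 0)
  names(t) <- amounts$dye_names
  background_thresholds(t)
}

#' @rdname derive_background_thresholds
#' @param t named nonnegative numeric vector of thresholds.
#' @export
background_thresholds <- function(t) {
  if (is.list(t)) t <- unlist(t)
  if (is.null(names(t)) || any(names(t) == ""))
    stop("thresholds must be named by dye", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("thresholds must be nonnegative and finite", call. = FALSE)
  structure(t, class = "background_thresholds")
}

#' @export
print.background_thresholds <- function(x, ...) {
  cat("background_thresholds:\n")
  print(signif(unclass(x), 4))
  invisible(x)
}

#' Mask stained pixels using background thresholds
#'
#' A pixel is background when the amounts of *all* dyes fall below their
#' thresholds; it is stained as soon as any single dye reaches its
#' threshold. Returns the stained-pixel mask.
#'
#' @param amounts a [dye_amount_map].
#' @param thresholds a [background_thresholds] covering every dye of
#'   `amounts`.
#' @return Logical H x W matrix, `TRUE` for stained (non-background)
#'   pixels.
#' @export
apply_background_mask <- function(amounts, thresholds) {
  stopifnot(inherits(amounts, "dye_amount_map"))
  thresholds <- background_thresholds(thresholds)
  missing <- setdiff(amounts$dye_names, names(thresholds))
  if (length(missing))
    stop("no threshold for dye(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  t <- unclass(thresholds)[amounts$dye_names]
  d <- dim(amounts$data)
  below <- amounts$data < rep(t, each = d[1] * d[2])
  # background iff below threshold in every dye plane
  matrix(rowSums(matrix(below, d[1] * d[2], d[3])) < d[3], d[1], d[2])
}
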