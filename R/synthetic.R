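# Synthetic phantoms with known ground truth. Scenes emulate single-layer
# Papanicolaou cytology: elliptical cells (H-stained nucleus over a
# counterstained cytoplasm) on glass that retains a slight residual stain,
# imaged through the Lambert-Beer forward model with Poisson shot noise and
# ADC quantization.

#' Default synthetic dye absorption spectra
#'
#' Builds a four-dye stain matrix with the qualitative spectral shapes of
#' the Papanicolaou dyes, evaluated on the given band grid and
#' unit-normalized: hematoxylin (H) a broad peak between 550 and 600 nm,
#' eosin Y (EY) a sharp peak between 500 and 550 nm, light green SF (LG)
#' absorbing in the red around 630 nm and very low between 480 and 540 nm,
#' and orange G (OG) absorbing near 480 nm with negligible absorption
#' beyond 530 nm.
#'
#' These are synthetic stand-ins for measured single-stain spectra, meant
#' for phantoms and tests, not for unmixing real slides.
#'
#' @param wavelengths_nm band grid; at least 5 bands (default: the 14-band
#'   acquisition grid with centers 440-700 nm in 20-nm steps).
#' @return A [stain_matrix] with dyes `H, EY, LG, OG`.
#' @export
default_spectra <- function(wavelengths_nm = seq(440, 700, by = 20)) {
  wl <- as.numeric(wavelengths_nm)
  if (length(wl) < 5L)
    stop("need at least 5 bands for four non-collinear dye spectra",
         call. = FALSE)
  peak <- function(mu, sigma) exp(-0.5 * ((wl - mu) / sigma)^2)
  co <- cbind(
    H  = peak(575, 45) + 0.05,
    EY = peak(520, 18) + 0.02,
    LG = 0.9 * peak(630, 35) + 0.25 * peak(440, 25) + 0.01,
    OG = peak(480, 25) + 0.35 * peak(440, 20) + 0.005
  )
  stain_matrix(co, wavelengths_nm = wl)
}

#' Specify a synthetic cell
#'
#' An elliptical cytoplasm with a concentric elliptical nucleus, each
#' carrying its own dye-amount vector. Composition order in the scene is
#' nucleus over cytoplasm over glass.
#'
#' @param center `c(row, col)` center in pixels (1-based, may be
#'   fractional).
#' @param cyto_axes,nucleus_axes `c(a_row, a_col)` ellipse semi-axes in
#'   pixels; the nucleus should be inside the cytoplasm.
#' @param cyto_amounts,nucleus_amounts named dye-amount vectors.
#' @return A list of class `phantom_cell`.
#' @export
phantom_cell <- function(center, cyto_axes, cyto_amounts,
                         nucleus_axes = cyto_axes / 3,
                         nucleus_amounts = NULL) {
  stopifnot(length(center) == 2L, length(cyto_axes) == 2L,
            all(cyto_axes > 0), length(nucleus_axes) == 2L,
            all(nucleus_axes >= 0))
  structure(list(center = as.numeric(center),
                 cyto_axes = as.numeric(cyto_axes),
                 cyto_amounts = cyto_amounts,
                 nucleus_axes = as.numeric(nucleus_axes),
                 nucleus_amounts = nucleus_amounts),
            class = "phantom_cell")
}

#' Specify a synthetic multispectral scene
#'
#' Geometry plus acquisition parameters for [render_phantom()]. The glass
#' background carries a small residual stain, as on real slides; `photons`
#' sets the expected photon count at the white level per band (shot-noise
#' scale, `Inf` = noiseless) and `bit_depth` the ADC quantization (`NULL` =
#' none). The seed is mandatory so every rendered phantom is reproducible.
#'
#' @param width,height image size in pixels.
#' @param cells list of [phantom_cell] objects.
#' @param dye_names active dye set (default `c("H","EY","LG","OG")`).
#' @param glass_amounts named dye amounts of the background glass; default
#'   a slight residual 0.01 of each dye.
#' @param photons expected photon count per band at full (glass)
#'   transmission; default `1e4`.
#' @param bit_depth quantization bit depth (default 12).
#' @param seed integer RNG seed (required).
#' @return A list of class `phantom_scene`.
#' @export
phantom_scene <- function(width, height, cells = list(),
                          dye_names = c("H", "EY", "LG", "OG"),
                          glass_amounts = NULL, photons = 1e4,
                          bit_depth = 12L, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is required for reproducible phantoms", call. = FALSE)
  if (width < 1 || height < 1) stop("empty scene", call. = FALSE)
  if (!is.infinite(photons) && photons <= 0)
    stop("photons must be positive or Inf", call. = FALSE)
  if (is.null(glass_amounts))
    glass_amounts <- stats::setNames(rep(0.01, length(dye_names)), dye_names)
  for (cell in cells) stopifnot(inherits(cell, "phantom_cell"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 cells = cells, dye_names = dye_names,
                 glass_amounts = glass_amounts, photons = photons,
                 bit_depth = if (is.null(bit_depth)) NULL else as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

# amount vector aligned to the scene's dye set; missing dyes are zero
align_amounts <- function(x, dye_names) {
  out <- stats::setNames(numeric(length(dye_names)), dye_names)
  if (is.null(x)) return(out)
  if (is.null(names(x))) stop("cell dye amounts must be named", call. = FALSE)
  unknown <- setdiff(names(x), dye_names)
  if (length(unknown))
    stop("unknown dye(s) in cell amounts: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out[names(x)] <- x
  out
}

inside_ellipse <- function(rows, cols, center, axes) {
  ((rows - center[1]) / axes[1])^2 + ((cols - center[2]) / axes[2])^2 <= 1
}

#' Render a phantom scene to a multispectral observation
#'
#' Composites the ground-truth dye amount map (nucleus over cytoplasm over
#' glass; with `overlap_add`, overlapping cytoplasms add their amounts, the
#' absorbance-additive behavior of overlapped cells), pushes it through the
#' Lambert-Beer [forward_model()], then applies Poisson shot noise at the
#' scene's photon count and uniform quantization at its bit depth.
#'
#' @param scene a [phantom_scene].
#' @param stains a [stain_matrix] covering the scene's dyes (default
#'   [default_spectra()] on its band grid).
#' @param white a [white_reference] (default: 1000 counts per band).
#' @param overlap_add add cytoplasm amounts where cells overlap instead of
#'   painting the later cell over the earlier (default `FALSE`).
#' @return List with `image` ([ms_image]), `truth` (ground-truth
#'   [dye_amount_map]), `labels` (H x W character matrix:
#'   `"glass"`/`"cytoplasm"`/`"nucleus"`), `white`.
#' @export
render_phantom <- function(scene, stains = NULL, white = NULL,
                           overlap_add = FALSE) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (is.null(stains)) stains <- default_spectra()
  stopifnot(inherits(stains, "stain_matrix"))
  if (!setequal(stains$dye_names, scene$dye_names))
    stop("stain matrix dyes do not match the scene's dye set", call. = FALSE)
  if (is.null(white))
    white <- white_reference(rep(1000, nrow(stains$coefficients)))
  white <- as_white(white)
  h <- scene$height; w <- scene$width
  m <- length(scene$dye_names)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  truth <- array(rep(align_amounts(scene$glass_amounts, scene$dye_names),
                     each = h * w), c(h, w, m))
  labels <- matrix("glass", h, w)
  for (cell in scene$cells) {
    cy <- inside_ellipse(rows, cols, cell$center, cell$cyto_axes)
    ca <- align_amounts(cell$cyto_amounts, scene$dye_names)
    for (i in seq_len(m)) {
      plane <- truth[, , i]
      plane[cy] <- if (overlap_add)
        plane[cy] + ca[i] - ifelse(labels[cy] == "glass",
                                   align_amounts(scene$glass_amounts,
                                                 scene$dye_names)[i], 0)
      else ca[i]
      truth[, , i] <- plane
    }
    labels[cy] <- "cytoplasm"
    if (!is.null(cell$nucleus_amounts) && all(cell$nucleus_axes > 0)) {
      nu <- inside_ellipse(rows, cols, cell$center, cell$nucleus_axes)
      na <- align_amounts(cell$nucleus_amounts, scene$dye_names)
      for (i in seq_len(m)) {
        plane <- truth[, , i]
        plane[nu] <- na[i]
        truth[, , i] <- plane
      }
      labels[nu] <- "nucleus"
    }
  }
  truth_map <- dye_amount_map(truth, scene$dye_names)
  # reorder stain columns to the scene's dye order
  ord <- match(scene$dye_names, stains$dye_names)
  stains_o <- stain_matrix(stains$coefficients[, ord, drop = FALSE],
                           dye_names = scene$dye_names,
                           wavelengths_nm = stains$wavelengths_nm,
                           normalize = FALSE)
  img <- forward_model(truth_map, stains_o, white)
  g <- img$data
  if (is.finite(scene$photons)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(scene$seed)
    scale <- scene$photons / max(white)
    g <- array(stats::rpois(length(g), g * scale) / scale, dim(g))
  }
  if (!is.null(scene$bit_depth)) {
    step <- max(white) / (2^scene$bit_depth - 1)
    g <- round(g / step) * step
  }
  list(image = ms_image(g, stains_o$wavelengths_nm),
       truth = truth_map, labels = labels, white = white)
}

#' Synthetic single-stain calibration stack
#'
#' Renders a phantom stained with one dye only at varying abundance (a
#' field of random positive amounts), for exercising the stain-vector
#' calibration path.
#'
#' @param dye dye name present in `stains`.
#' @param stains a [stain_matrix].
#' @param n_pixels number of calibration pixels (rendered as an
#'   `n_pixels x 1` strip).
#' @param amount_range abundance range of the dye (uniform).
#' @param photons,bit_depth,seed acquisition parameters as in
#'   [phantom_scene()].
#' @param white optional [white_reference].
#' @return List as from [render_phantom()], plus `dye`.
#' @export
single_stain_phantom <- function(dye, stains = default_spectra(),
                                 n_pixels = 100L, amount_range = c(0.5, 1.5),
                                 photons = 1e4, bit_depth = 12L, seed,
                                 white = NULL) {
  stopifnot(dye %in% stains$dye_names)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(white))
    white <- white_reference(rep(1000, nrow(stains$coefficients)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  beta <- stats::runif(n_pixels, amount_range[1], amount_range[2])
  amounts <- array(0, c(n_pixels, 1L, length(stains$dye_names)))
  amounts[, 1L, match(dye, stains$dye_names)] <- beta
  truth <- dye_amount_map(amounts, stains$dye_names)
  img <- forward_model(truth, stains, white)
  g <- img$data
  if (is.finite(photons)) {
    scale <- photons / max(white)
    g <- array(stats::rpois(length(g), g * scale) / scale, dim(g))
  }
  if (!is.null(bit_depth)) {
    step <- max(white) / (2^bit_depth - 1)
    g <- round(g / step) * step
  }
  list(image = ms_image(g, stains$wavelengths_nm), truth = truth,
       labels = matrix("cytoplasm", n_pixels, 1L), white = white, dye = dye)
}

#' Synthetic two-class EC/LEGH feature dataset
#'
#' Draws per-patch mean dye-amount vectors around class means that emulate
#' the clinical contrast between the two mucin types: EC mucin is eosin-Y
#' rich and essentially orange-G free, LEGH mucin is orange-G rich with
#' reduced eosin Y, and hematoxylin is near zero in both (mucin areas
#' exclude nuclei). Amounts are normal around the class mean with common
#' spread, truncated at zero.
#'
#' @param n_ec,n_legh samples per class.
#' @param ec_mean,legh_mean named mean amount vectors (defaults above, on
#'   the normalized-amount scale).
#' @param spread common per-feature standard deviation (default 0.08).
#' @param seed integer RNG seed (required).
#' @return `data.frame` with a `label` factor (`EC`/`LEGH`) and one column
#'   per dye.
#' @export
make_two_class_dataset <- function(n_ec, n_legh,
                                   ec_mean = c(H = 0.02, EY = 0.55,
                                               LG = 0.15, OG = 0.01),
                                   legh_mean = c(H = 0.02, EY = 0.25,
                                                 LG = 0.20, OG = 0.35),
                                   spread = 0.08, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_ec >= 1, n_legh >= 1, spread >= 0,
            identical(names(ec_mean), names(legh_mean)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draw <- function(n, mu) {
    x <- matrix(stats::rnorm(n * length(mu), rep(mu, each = n), spread),
                n, length(mu), dimnames = list(NULL, names(mu)))
    x[x < 0] <- 0
    x
  }
  out <- rbind(
    data.frame(label = "EC", draw(n_ec, ec_mean), check.names = FALSE),
    data.frame(label = "LEGH", draw(n_legh, legh_mean), check.names = FALSE)
  )
  out$label <- factor(out$label, c("EC", "LEGH"))
  out
}
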