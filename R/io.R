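# File formats: multispectral stacks and dye maps travel as multi-page
# 32-bit float TIFF plus a sidecar JSON (<path>.json) carrying wavelengths
# or dye names and an intensity scale factor (pages are stored in [0,1]).
# Matrices, reference values, thresholds and models use CSV/JSON.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  meta <- meta[!vapply(meta, is.null, TRUE)]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar metadata file: ", sp, call. = FALSE)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

write_pages <- function(data, path) {
  scale <- max(data, 1e-12)
  pages <- lapply(seq_len(dim(data)[3L]),
                  function(k) data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  scale
}

read_pages <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  arr <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  arr * scale
}

#' Read and write multispectral TIFF stacks
#'
#' Stacks are stored as multi-page float TIFF (one page per band, ascending
#' wavelength) with a `<path>.json` sidecar holding `wavelengths_nm`, the
#' intensity `scale` and optionally `pixel_size_um`. 16-bit unsigned pages
#' written by other tools are also accepted (read as integer counts) when
#' the sidecar carries no scale.
#'
#' @param image an [ms_image].
#' @param path TIFF file path.
#' @return `write_ms_tiff` returns `path` invisibly; `read_ms_tiff` returns
#'   an [ms_image].
#' @export
write_ms_tiff <- function(image, path) {
  stopifnot(inherits(image, "ms_image"))
  scale <- write_pages(image$data, path)
  write_sidecar(path, list(type = "ms_image",
                           wavelengths_nm = image$wavelengths_nm,
                           scale = scale,
                           pixel_size_um = image$pixel_size_um))
  invisible(path)
}

#' @rdname write_ms_tiff
#' @export
read_ms_tiff <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta$wavelengths_nm))
    stop("sidecar lacks wavelengths_nm", call. = FALSE)
  scale <- meta$scale
  if (is.null(scale)) {
    # foreign 16-bit stack: recover integer counts
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  } else {
    arr <- read_pages(path, scale)
  }
  ms_image(arr, meta$wavelengths_nm, pixel_size_um = meta$pixel_size_um)
}

#' Read and write dye amount maps
#'
#' One multi-page float TIFF (one page per dye) with a sidecar JSON holding
#' `dye_names`, `normalized` and the storage `scale`.
#'
#' @param amounts a [dye_amount_map].
#' @param path TIFF file path.
#' @return `write_dye_maps` returns `path` invisibly; `read_dye_maps`
#'   returns a [dye_amount_map].
#' @export
write_dye_maps <- function(amounts, path) {
  stopifnot(inherits(amounts, "dye_amount_map"))
  if (any(amounts$data < 0))
    stop("cannot store negative dye amounts; unmix with clip_negative = TRUE",
         call. = FALSE)
  scale <- write_pages(amounts$data, path)
  write_sidecar(path, list(type = "dye_amount_map",
                           dye_names = amounts$dye_names,
                           normalized = amounts$normalized, scale = scale))
  invisible(path)
}

#' @rdname write_dye_maps
#' @export
read_dye_maps <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta$dye_names) || is.null(meta$scale))
    stop("sidecar lacks dye_names/scale", call. = FALSE)
  dye_amount_map(read_pages(path, meta$scale), meta$dye_names,
                 normalized = isTRUE(meta$normalized))
}

#' Read and write stain matrices
#'
#' CSV layout: a `wavelength_nm` column followed by one column per dye
#' (rows = bands). The JSON layout stores `wavelengths_nm`, `dye_names` and
#' the coefficient matrix row by row. `read_stain_matrix` dispatches on the
#' file extension and reports the condition number via the constructor.
#'
#' @param stains a [stain_matrix].
#' @param path file path ending in `.csv` or `.json`.
#' @return `read_stain_matrix` returns a [stain_matrix];
#'   `write_stain_matrix` returns `path` invisibly.
#' @export
write_stain_matrix <- function(stains, path) {
  stopifnot(inherits(stains, "stain_matrix"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- data.frame(wavelength_nm = stains$wavelengths_nm,
                     stains$coefficients, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(
      list(wavelengths_nm = stains$wavelengths_nm,
           dye_names = stains$dye_names,
           coefficients = unname(as.data.frame(t(stains$coefficients)))),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else stop("unsupported stain matrix format: .", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_stain_matrix
#' @export
read_stain_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"wavelength_nm" %in% names(df))
      stop("stain matrix CSV needs a wavelength_nm column", call. = FALSE)
    wl <- df$wavelength_nm
    co <- as.matrix(df[setdiff(names(df), "wavelength_nm")])
    stain_matrix(co, wavelengths_nm = wl, normalize = FALSE)
  } else if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    co <- t(as.matrix(as.data.frame(j$coefficients)))
    dimnames(co) <- NULL
    stain_matrix(co, dye_names = j$dye_names,
                 wavelengths_nm = j$wavelengths_nm, normalize = FALSE)
  } else stop("unsupported stain matrix format: .", ext, call. = FALSE)
}

#' Read and write per-dye scalar JSON files
#'
#' [reference_values()] and [background_thresholds()] are serialized as a
#' flat JSON object keyed by dye name.
#'
#' @param x a `reference_values` or `background_thresholds` object (or a
#'   named vector for the matching constructor).
#' @param path JSON file path.
#' @return Readers return the constructed object; writers return `path`
#'   invisibly.
#' @export
write_dye_values <- function(x, path) {
  jsonlite::write_json(as.list(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dye_values
#' @export
read_reference_values <- function(path) {
  reference_values(unlist(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' @rdname write_dye_values
#' @export
read_background_thresholds <- function(path) {
  background_thresholds(unlist(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' Bundled normalization reference values
#'
#' The reference values (99th-percentile raw amounts over well-stained
#' clinical regions) published with the original clinical calibration of
#' this method: `Q_EY = 2.003`, `Q_H = 1.889`, `Q_LG = 2.550`,
#' `Q_OG = 1.213`. They apply only to amounts unmixed with that study's
#' measured stain matrix; recalibrate with [compute_reference_values()]
#' for any other acquisition.
#'
#' @return A [reference_values] object.
#' @export
preset_reference_values <- function() {
  read_reference_values(system.file("presets", "reference_values.json",
                                    package = "papunmix", mustWork = TRUE))
}

#' Read and write discriminant models as JSON
#'
#' A single model is stored as `{feature_names, weights, bias, name}`; a
#' file may also hold a named object of several models (as the bundled
#' presets file does).
#'
#' @param models a [discriminant_model] or named list of them.
#' @param path JSON file path.
#' @return `read_discriminants` returns a named list of
#'   [discriminant_model]; `write_discriminants` returns `path` invisibly.
#' @export
write_discriminants <- function(models, path) {
  if (inherits(models, "discriminant_model")) models <- list(model = models)
  out <- lapply(models, function(m)
    list(feature_names = m$feature_names, weights = m$weights,
         bias = m$bias, positive_label = m$positive_label, name = m$name))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_discriminants
#' @export
read_discriminants <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(j, function(m)
    discriminant_model(m$feature_names, m$weights, m$bias,
                       positive_label = m$positive_label %||% "LEGH",
                       name = m$name))
}

#' Rectangle lists and PNG masks
#'
#' Region masks are supplied either as binary PNG images or as JSON lists
#' of rectangles `[x, y, w, h]` in 0-based, half-open pixel coordinates
#' (`x` = column, `y` = row).
#'
#' @param rects numeric matrix or list of `c(x, y, w, h)` rectangles.
#' @param dims target mask dimensions `c(H, W)`.
#' @return Logical H x W matrix.
#' @export
rect_mask <- function(rects, dims) {
  if (is.numeric(rects) && is.null(dim(rects))) rects <- list(rects)
  if (is.matrix(rects)) rects <- asplit(rects, 1L)
  mask <- matrix(FALSE, dims[1], dims[2])
  for (r in rects) {
    r <- as.numeric(r)
    if (length(r) != 4L) stop("rectangles are [x, y, w, h]", call. = FALSE)
    x <- r[1]; y <- r[2]; w <- r[3]; h <- r[4]
    if (w <= 0 || h <= 0 || x < 0 || y < 0 ||
        x + w > dims[2] || y + h > dims[1])
      stop("rectangle [", paste(r, collapse = ", "),
           "] falls outside a ", dims[1], " x ", dims[2], " image",
           call. = FALSE)
    mask[(y + 1):(y + h), (x + 1):(x + w)] <- TRUE
  }
  mask
}

#' @rdname rect_mask
#' @param path PNG or rectangle-JSON file path.
#' @export
read_mask <- function(path, dims) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    check_mask(p > 0.5, dims)
  } else if (ext == "json") {
    rect_mask(jsonlite::read_json(path, simplifyVector = TRUE), dims)
  } else stop("masks are PNG or rectangle JSON; got .", ext, call. = FALSE)
}

#' Write an sRGB render (or mask) as PNG
#'
#' @param rgb an `rgb_image` from [ms_to_srgb()], or a logical matrix
#'   (written as a binary mask).
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  if (inherits(rgb, "rgb_image")) png::writePNG(rgb$data, path)
  else if (is.logical(rgb)) png::writePNG(rgb * 1, path)
  else stop("expected an rgb_image or a logical mask", call. = FALSE)
  invisible(path)
}
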