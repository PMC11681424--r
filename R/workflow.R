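# Batch workflow commands behind the command-line tool (inst/cli/papunmix).
# Each writes its outputs plus a provenance JSON recording the call
# parameters, the seed where randomness is involved, and the package
# version, so identical invocations yield identical outputs.

write_provenance <- function(path, step, params) {
  jsonlite::write_json(
    list(step = step,
         package = "papunmix",
         version = as.character(utils::packageVersion("papunmix")),
         params = params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Calibrate a stain matrix from single-stain stacks
#'
#' For each dye, reads a single-stain multispectral stack, measures the
#' white reference over the given glass rectangle, converts the designated
#' stained rectangles to absorbance and estimates the dye's stain vector;
#' the columns are assembled into a stain matrix written as CSV and JSON.
#'
#' @param stacks named character vector: dye name -> single-stain TIFF path
#'   (see [read_ms_tiff()]).
#' @param glass_rect `c(x, y, w, h)` rectangle (0-based, half-open) of the
#'   glass area in every stack.
#' @param stain_rects single rectangle or named list (by dye) of rectangles
#'   designating well-stained sampling areas.
#' @param out output path stem; writes `<out>.csv`, `<out>.json` and
#'   `<out>.provenance.json`.
#' @param floor count floor for [compute_absorbance()].
#' @return The calibrated [stain_matrix], invisibly.
#' @export
run_calibrate <- function(stacks, glass_rect, stain_rects, out, floor = 1) {
  if (is.null(names(stacks)) || any(names(stacks) == ""))
    stop("`stacks` must be named by dye", call. = FALSE)
  missing <- stacks[!file.exists(stacks)]
  if (length(missing))
    stop("missing single-stain stack(s) for: ",
         paste(names(missing), collapse = ", "), call. = FALSE)
  vectors <- list()
  wl <- NULL
  for (dye in names(stacks)) {
    img <- read_ms_tiff(stacks[[dye]])
    wl <- img$wavelengths_nm
    dims <- dim(img$data)[1:2]
    white <- glass_reference(img, rect_mask(glass_rect, dims))
    absorb <- compute_absorbance(img, white, floor = floor)
    rect <- if (is.list(stain_rects) && !is.null(names(stain_rects)))
      stain_rects[[dye]] else stain_rects
    mask <- rect_mask(rect, dims)
    amat <- matrix(absorb$data, prod(dims), length(wl))[as.vector(mask), ,
                                                        drop = FALSE]
    vectors[[dye]] <- estimate_stain_vector(amat)
  }
  stains <- build_stain_matrix(vectors, wl)
  write_stain_matrix(stains, paste0(out, ".csv"))
  write_stain_matrix(stains, paste0(out, ".json"))
  write_provenance(paste0(out, ".provenance.json"), "calibrate",
                   list(stacks = as.list(stacks), glass_rect = glass_rect,
                        floor = floor,
                        condition_number = stains$condition_number))
  invisible(stains)
}

#' Unmix a multispectral stack into dye amount maps
#'
#' Reads a stack and a stain matrix, measures the white reference over the
#' glass rectangle, computes absorbance, unmixes, optionally normalizes by
#' reference values, and writes the dye maps (multi-page float TIFF with
#' sidecar) plus provenance.
#'
#' @param stack_path multispectral TIFF (with sidecar).
#' @param stain_path stain matrix CSV/JSON.
#' @param glass_rect glass rectangle `c(x, y, w, h)` for the white
#'   reference.
#' @param out output path stem; writes `<out>.tif` (+ sidecar) and
#'   `<out>.provenance.json`.
#' @param refs_path optional reference-values JSON; when given the stored
#'   maps are normalized.
#' @param floor,clip_negative unmixing options (see [compute_absorbance()],
#'   [unmix()]).
#' @return The written [dye_amount_map], invisibly.
#' @export
run_unmix <- function(stack_path, stain_path, glass_rect, out,
                      refs_path = NULL, floor = 1, clip_negative = TRUE) {
  img <- read_ms_tiff(stack_path)
  stains <- read_stain_matrix(stain_path)
  white <- glass_reference(img, rect_mask(glass_rect, dim(img$data)[1:2]))
  amounts <- unmix(compute_absorbance(img, white, floor = floor), stains,
                   clip_negative = clip_negative)
  if (!is.null(refs_path))
    amounts <- normalize_amounts(amounts, read_reference_values(refs_path))
  write_dye_maps(amounts, paste0(out, ".tif"))
  write_provenance(paste0(out, ".provenance.json"), "unmix",
                   list(stack = stack_path, stains = stain_path,
                        glass_rect = glass_rect, refs = refs_path,
                        floor = floor, clip_negative = clip_negative))
  invisible(amounts)
}

#' Mean dye amounts in a selected rectangle
#'
#' Reports the average amount of each dye inside a rectangle of a dye
#' amount map, written as JSON (and returned), mirroring interactive
#' region inspection.
#'
#' @param maps_path dye-map TIFF from [run_unmix()] / [write_dye_maps()].
#' @param rect `c(x, y, w, h)` rectangle, 0-based half-open.
#' @param out optional output path stem for `<out>.json` +
#'   `<out>.provenance.json`.
#' @return Named numeric vector of per-dye means.
#' @export
run_region_report <- function(maps_path, rect, out = NULL) {
  amounts <- read_dye_maps(maps_path)
  mask <- rect_mask(rect, dim(amounts$data)[1:2])
  means <- vapply(seq_along(amounts$dye_names),
                  function(i) mean(amounts$data[, , i][mask]), 0)
  names(means) <- amounts$dye_names
  if (!is.null(out)) {
    jsonlite::write_json(as.list(means), paste0(out, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_provenance(paste0(out, ".provenance.json"), "region_report",
                     list(maps = maps_path, rect = rect))
  }
  means
}

#' Patch classification of a dye amount map
#'
#' Derives background thresholds from a user-selected background rectangle,
#' tiles the map into patches, categorizes them, classifies mucin patches
#' with the given discriminant, and writes the patch table (CSV), the LEGH
#' ratio (JSON) and provenance.
#'
#' @param maps_path dye-map TIFF.
#' @param model a [discriminant_model], a preset name from
#'   [preset_discriminants()] (`"2D"`, `"3D"`, `"sRGB"` — the latter needs
#'   RGB features and is not valid here), or a model JSON path.
#' @param background_rect rectangle of unstained glass used for
#'   [derive_background_thresholds()].
#' @param out output path stem; writes `<out>_patches.csv`,
#'   `<out>_summary.json`, `<out>.provenance.json`.
#' @param patch_size,b_percent,percentile patch logic parameters.
#' @return List with `patches` (data frame) and `legh_ratio`, invisibly.
#' @export
run_classify <- function(maps_path, model, background_rect, out,
                         patch_size = 10L, b_percent = 90, percentile = 99) {
  amounts <- read_dye_maps(maps_path)
  if (is.character(model)) {
    presets <- preset_discriminants()
    model <- if (model %in% names(presets)) presets[[model]]
             else read_discriminants(model)[[1L]]
  }
  stopifnot(inherits(model, "discriminant_model"))
  thr <- derive_background_thresholds(
    amounts, rect_mask(background_rect, dim(amounts$data)[1:2]),
    percentile = percentile)
  patches <- analyze_patches(amounts, thr, patch_size = patch_size,
                             b_percent = b_percent, model = model)
  ratio <- if (any(patches$label == "mucin")) cluster_legh_ratio(patches)
           else NA_real_
  utils::write.csv(patches, paste0(out, "_patches.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(legh_ratio = ratio, n_patches = nrow(patches),
         n_mucin = sum(patches$label == "mucin"),
         n_nucleus = sum(patches$label == "nucleus"),
         n_background = sum(patches$label == "background"),
         thresholds = as.list(unclass(thr))),
    paste0(out, "_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  write_provenance(paste0(out, ".provenance.json"), "classify",
                   list(maps = maps_path, background_rect = background_rect,
                        patch_size = patch_size, b_percent = b_percent,
                        percentile = percentile,
                        model = list(feature_names = model$feature_names,
                                     weights = model$weights,
                                     bias = model$bias)))
  invisible(list(patches = patches, legh_ratio = ratio, thresholds = thr))
}

#' Generate a phantom fixture bundle
#'
#' Renders a phantom scene and writes the observation stack, ground-truth
#' dye maps, label mask PNGs, the stain matrix used, an sRGB render and
#' provenance — a self-contained, reproducible test fixture.
#'
#' @param scene a [phantom_scene].
#' @param out output directory (created if needed).
#' @param stains optional [stain_matrix]; defaults to [default_spectra()].
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(scene, out, stains = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ph <- render_phantom(scene, stains = stains)
  paths <- c(stack = file.path(out, "stack.tif"),
             truth = file.path(out, "truth.tif"),
             stains = file.path(out, "stains.csv"),
             render = file.path(out, "render.png"),
             labels = file.path(out, "labels.csv"),
             provenance = file.path(out, "provenance.json"))
  write_ms_tiff(ph$image, paths[["stack"]])
  write_dye_maps(ph$truth, paths[["truth"]])
  write_stain_matrix(if (is.null(stains)) default_spectra() else stains,
                     paths[["stains"]])
  write_rgb_png(ms_to_srgb(ph$image, ph$white), paths[["render"]])
  utils::write.csv(as.data.frame(ph$labels), paths[["labels"]],
                   row.names = FALSE)
  write_provenance(paths[["provenance"]], "simulate",
                   list(width = scene$width, height = scene$height,
                        n_cells = length(scene$cells),
                        photons = scene$photons,
                        bit_depth = scene$bit_depth, seed = scene$seed))
  invisible(paths)
}
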