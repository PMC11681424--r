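#' Tile an image into non-overlapping square patches
#'
#' Lays a patch grid anchored at the image origin (top-left, 0-based);
#' right and bottom remainders narrower than `patch_size` are discarded.
#'
#' @param dims integer vector `c(H, W)` (extra entries such as a dye count
#'   are ignored), or an object with a `dim()` method.
#' @param patch_size side length in pixels (default 10).
#' @return `data.frame` with 0-based top-left corners `row0`, `col0` and
#'   `size`; one row per patch, in row-major order.
#' @examples
#' nrow(tile_patches(c(105, 98)))  # 10 x 9 = 90 patches
#' @export
tile_patches <- function(dims, patch_size = 10L) {
  if (!is.numeric(dims)) dims <- dim(dims)
  if (length(dims) < 2L) stop("`dims` must give height and width", call. = FALSE)
  patch_size <- as.integer(patch_size)
  if (is.na(patch_size) || patch_size < 1L)
    stop("patch_size must be a positive integer", call. = FALSE)
  nr <- dims[1] %/% patch_size
  nc <- dims[2] %/% patch_size
  if (nr == 0L || nc == 0L)
    return(data.frame(row0 = integer(), col0 = integer(), size = integer()))
  grid <- expand.grid(col0 = (seq_len(nc) - 1L) * patch_size,
                      row0 = (seq_len(nr) - 1L) * patch_size)
  data.frame(row0 = grid$row0, col0 = grid$col0, size = patch_size)
}

# extract the H x W x M sub-array of one patch (0-based origin)
patch_slab <- function(amounts, row0, col0, size) {
  amounts$data[(row0 + 1L):(row0 + size), (col0 + 1L):(col0 + size), ,
               drop = FALSE]
}

#' Categorize a patch as nucleus, background or mucin
#'
#' Votes over the patch pixels: a pixel is *H-stained* when its hematoxylin
#' amount is at or above the H background threshold, and *non-stained* when
#' every dye amount is below its threshold. If strictly more than half the
#' pixels are H-stained the patch is a cell nucleus; otherwise if the
#' non-stained share exceeds `b_percent` it is background; everything else
#' is treated as (mucinous) cytoplasm.
#'
#' @param patch numeric `size x size x M` array of dye amounts for one
#'   patch, with dye planes ordered as in `names(thresholds)`.
#' @param thresholds a [background_thresholds] covering all M dyes.
#' @param h_dye name of the nuclear dye (default `"H"`).
#' @param b_percent background vote threshold in percent (default 90; needs
#'   adjusting per image set).
#' @return One of `"nucleus"`, `"background"`, `"mucin"`.
#' @export
categorize_patch <- function(patch, thresholds, h_dye = "H", b_percent = 90) {
  thresholds <- background_thresholds(thresholds)
  if (!h_dye %in% names(thresholds))
    stop("unknown nuclear dye: ", h_dye, call. = FALSE)
  if (b_percent < 0 || b_percent > 100)
    stop("b_percent must be in [0, 100]", call. = FALSE)
  d <- dim(patch)
  if (length(d) != 3L || d[3] != length(thresholds))
    stop("patch must be size x size x M with M matching thresholds",
         call. = FALSE)
  npix <- d[1] * d[2]
  t <- unclass(thresholds)
  h_stained <- patch[, , match(h_dye, names(t))] >= t[[h_dye]]
  below <- matrix(patch < rep(t, each = npix), npix, d[3])
  nonstained <- rowSums(below) == d[3]
  if (sum(h_stained) > npix / 2) "nucleus"
  else if (sum(nonstained) > npix * b_percent / 100) "background"
  else "mucin"
}

#' Mean dye amounts over the stained pixels of a patch
#'
#' Averages each dye plane over the pixels where at least one dye reaches
#' its background threshold (the "area where any dye exists"); unstained
#' pixels are excluded from the mean.
#'
#' @inheritParams categorize_patch
#' @return Named numeric vector of length M, or all-`NA` when the patch has
#'   no stained pixel.
#' @export
patch_mean_amounts <- function(patch, thresholds) {
  thresholds <- background_thresholds(thresholds)
  d <- dim(patch)
  if (length(d) != 3L || d[3] != length(thresholds))
    stop("patch must be size x size x M with M matching thresholds",
         call. = FALSE)
  npix <- d[1] * d[2]
  t <- unclass(thresholds)
  below <- matrix(patch < rep(t, each = npix), npix, d[3])
  stained <- rowSums(below) < d[3]
  out <- rep(NA_real_, d[3])
  names(out) <- names(t)
  if (!any(stained)) return(out)
  pm <- matrix(patch, npix, d[3])
  out[] <- colMeans(pm[stained, , drop = FALSE])
  out
}

#' Patch-level analysis of a dye amount map
#'
#' Tiles a dye amount map, categorizes every patch (nucleus / background /
#' mucin), computes per-patch mean amounts over stained pixels, and — when
#' a discriminant model is given — scores and classifies the mucin patches
#' as EC or LEGH.
#'
#' @param amounts a [dye_amount_map] (normalized amounts if the thresholds
#'   were derived on normalized amounts).
#' @param thresholds a [background_thresholds].
#' @param patch_size patch side in pixels (default 10).
#' @param b_percent background vote threshold, see [categorize_patch()].
#' @param h_dye nuclear dye name (default `"H"`).
#' @param model optional [discriminant_model]; mucin patches get a score
#'   and an EC/LEGH class.
#' @return `data.frame`: `row0`, `col0`, `size`, `label`, one `mean_<dye>`
#'   column per dye, and (with a model) `score`, `class`. Warns and returns
#'   zero rows when the map is smaller than one patch.
#' @seealso [cluster_legh_ratio()]
#' @export
analyze_patches <- function(amounts, thresholds, patch_size = 10L,
                            b_percent = 90, h_dye = "H", model = NULL) {
  stopifnot(inherits(amounts, "dye_amount_map"))
  thresholds <- background_thresholds(thresholds)
  if (!setequal(names(thresholds), amounts$dye_names))
    stop("threshold dye set does not match the amount map", call. = FALSE)
  t <- unclass(thresholds)[amounts$dye_names]  # align order to map planes
  tiles <- tile_patches(dim(amounts$data), patch_size)
  if (nrow(tiles) == 0L) {
    warning("image smaller than one patch; no patches analyzed")
    empty <- tiles
    empty$label <- character()
    for (dye in amounts$dye_names) empty[[paste0("mean_", dye)]] <- numeric()
    return(empty)
  }
  labs <- character(nrow(tiles))
  means <- matrix(NA_real_, nrow(tiles), length(amounts$dye_names))
  for (i in seq_len(nrow(tiles))) {
    slab <- patch_slab(amounts, tiles$row0[i], tiles$col0[i], tiles$size[i])
    labs[i] <- categorize_patch(slab, t, h_dye = h_dye, b_percent = b_percent)
    means[i, ] <- patch_mean_amounts(slab, t)
  }
  colnames(means) <- paste0("mean_", amounts$dye_names)
  out <- cbind(tiles, label = labs, as.data.frame(means))
  if (!is.null(model)) {
    stopifnot(inherits(model, "discriminant_model"))
    feat_cols <- paste0("mean_", model$feature_names)
    if (!all(feat_cols %in% colnames(out)))
      stop("model features not among the map's dyes: ",
           paste(model$feature_names, collapse = ", "), call. = FALSE)
    out$score <- NA_real_
    out$class <- NA_character_
    muc <- which(out$label == "mucin" & stats::complete.cases(out[feat_cols]))
    if (length(muc)) {
      x <- as.matrix(out[muc, feat_cols, drop = FALSE])
      colnames(x) <- model$feature_names
      out$score[muc] <- decision_values(model, x)
      out$class[muc] <- classify(model, x)
    }
  }
  out
}

#' LEGH ratio of a cell cluster
#'
#' Fraction of mucin patches classified as LEGH, excluding nucleus and
#' background patches — the cluster-level diagnostic summary.
#'
#' @param patches patch table from [analyze_patches()] run with a model
#'   (needs `label` and `class` columns).
#' @return A number in `[0, 1]`, or `NA` (with a warning) when the cluster
#'   contains no mucin patch.
#' @export
cluster_legh_ratio <- function(patches) {
  if (!all(c("label", "class") %in% names(patches)))
    stop("`patches` must come from analyze_patches() with a model",
         call. = FALSE)
  muc <- patches$label == "mucin" & !is.na(patches$class)
  if (!any(muc)) {
    warning("no mucin patches; LEGH ratio undefined")
    return(NA_real_)
  }
  mean(patches$class[muc] == "LEGH")
}
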