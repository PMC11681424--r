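# Shared synthetic fixtures, built in code at test time.

test_stains <- function() default_spectra()

test_white <- function(n = 14L, level = 1000) white_reference(rep(level, n))

dyes4 <- c("H", "EY", "LG", "OG")

# random nonnegative amount map with a fixed seed
random_amounts <- function(h, w, seed, max_amount = 1) {
  set.seed(seed)
  dye_amount_map(array(stats::runif(h * w * 4, 0, max_amount), c(h, w, 4L)),
                 dyes4)
}

# one-cell scene: OG-rich (LEGH-like) or EY-rich (EC-like) cytoplasm with an
# H-stained nucleus on faintly stained glass
one_cell_scene <- function(kind = c("legh", "ec"), seed, size = 60L,
                           photons = 1e4) {
  kind <- match.arg(kind)
  cyto <- if (kind == "legh") c(EY = 0.25, LG = 0.20, OG = 0.35)
          else                c(EY = 0.55, LG = 0.15, OG = 0.01)
  phantom_scene(size, size,
                cells = list(phantom_cell(c(size / 2, size / 2),
                                          c(size * 0.42, size * 0.42), cyto,
                                          nucleus_axes = c(size / 8, size / 8),
                                          nucleus_amounts = c(H = 1))),
                photons = photons, seed = seed)
}

# full pipeline on a rendered phantom: absorbance -> unmix -> thresholds
unmix_phantom <- function(ph, stains = test_stains(), clip = TRUE) {
  amounts <- unmix(compute_absorbance(ph$image, ph$white), stains,
                   clip_negative = clip)
  thr <- derive_background_thresholds(amounts, ph$labels == "glass")
  list(amounts = amounts, thresholds = thr)
}
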