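test_that("default spectra have the qualitative shapes of the four dyes", {
  s <- default_spectra()
  expect_equal(s$dye_names, dyes4)
  expect_equal(nrow(s$coefficients), 14)
  expect_true(is.finite(s$condition_number))
  expect_equal(unname(sqrt(colSums(s$coefficients^2))), rep(1, 4))
  wl <- s$wavelengths_nm
  # hematoxylin peaks between 550 and 600 nm
  expect_true(wl[which.max(s$coefficients[, "H"])] >= 550 &&
                wl[which.max(s$coefficients[, "H"])] <= 600)
  # eosin Y peaks between 500 and 550 nm
  expect_true(wl[which.max(s$coefficients[, "EY"])] >= 500 &&
                wl[which.max(s$coefficients[, "EY"])] <= 550)
  # orange G is nearly transparent in the red: value at 640 nm < 10% of peak
  og <- s$coefficients[, "OG"]
  expect_lt(og[match(640, wl)], 0.1 * max(og))
  # light green absorbs little between 480 and 540 nm
  lg <- s$coefficients[, "LG"]
  expect_lt(max(lg[wl >= 480 & wl <= 540]), 0.3 * max(lg))
  expect_error(default_spectra(c(440, 500, 560, 620)), "at least 5")
})

test_that("phantom rendering is deterministic under a fixed seed and its
           ground truth matches the scene geometry", {
  sc <- one_cell_scene("legh", seed = 5)
  ph1 <- render_phantom(sc, test_stains())
  ph2 <- render_phantom(sc, test_stains())
  expect_identical(ph1$image$data, ph2$image$data)
  expect_identical(ph1$truth$data, ph2$truth$data)

  # label map and amount map agree: nucleus pixels carry H, cytoplasm OG
  h_plane <- ph1$truth$data[, , 1]
  og_plane <- ph1$truth$data[, , 4]
  expect_true(all(h_plane[ph1$labels == "nucleus"] == 1))
  expect_true(all(og_plane[ph1$labels == "cytoplasm"] == 0.35))
  expect_true(all(ph1$truth$data[, , 2][ph1$labels == "glass"] == 0.01))
  expect_error(phantom_scene(10, 10, seed = NULL), "seed")
})

test_that("in the noiseless limit unmixing recovers the phantom ground truth", {
  sc <- phantom_scene(30, 30,
                      cells = list(phantom_cell(c(15, 15), c(12, 12),
                                                c(EY = 0.3, OG = 0.5),
                                                nucleus_axes = c(4, 4),
                                                nucleus_amounts = c(H = 0.9))),
                      photons = Inf, bit_depth = NULL, seed = 2)
  ph <- render_phantom(sc, test_stains())
  rec <- unmix(compute_absorbance(ph$image, ph$white, floor = 1e-9),
               test_stains(), clip_negative = FALSE)
  expect_lt(max(abs(rec$data - ph$truth$data)), 1e-6)
})

test_that("unmixing error decreases as the photon count increases", {
  stains <- test_stains()
  rmse_at <- function(photons, seed) {
    sc <- one_cell_scene("legh", seed = seed, size = 40, photons = photons)
    ph <- render_phantom(sc, stains)
    rec <- unmix(compute_absorbance(ph$image, ph$white), stains,
                 clip_negative = FALSE)
    sqrt(mean((rec$data - ph$truth$data)^2))
  }
  # average over a few seeds to stay within sampling error
  err <- vapply(c(1e2, 1e3, 1e4), function(ph)
    mean(vapply(1:3, function(s) rmse_at(ph, 100 + s), 0)), 0)
  expect_true(all(diff(err) < 0))
})

test_that("overlapping cells add their cytoplasm amounts when requested", {
  cells <- list(
    phantom_cell(c(10, 8), c(6, 6), c(EY = 0.4), nucleus_axes = c(0, 0)),
    phantom_cell(c(10, 14), c(6, 6), c(LG = 0.3), nucleus_axes = c(0, 0)))
  sc <- phantom_scene(20, 20, cells = cells, glass_amounts = c(
    H = 0, EY = 0, LG = 0, OG = 0), photons = Inf, bit_depth = NULL, seed = 3)
  ph <- render_phantom(sc, test_stains(), overlap_add = TRUE)
  # a pixel inside both ellipses carries both dyes
  expect_equal(ph$truth$data[10, 11, 2], 0.4)
  expect_equal(ph$truth$data[10, 11, 3], 0.3)
  ph2 <- render_phantom(sc, test_stains(), overlap_add = FALSE)
  expect_equal(ph2$truth$data[10, 11, 2], 0)  # painted over
})

test_that("two-class feature generator reflects the EC/LEGH dye contrast", {
  d <- make_two_class_dataset(50, 60, seed = 9)
  expect_equal(as.vector(table(d$label)), c(50, 60))
  mu <- aggregate(d[dyes4], list(d$label), mean)
  ec <- unlist(mu[mu$Group.1 == "EC", dyes4])
  legh <- unlist(mu[mu$Group.1 == "LEGH", dyes4])
  expect_gt(ec[["EY"]], legh[["EY"]])   # EC is EY-rich
  expect_gt(legh[["OG"]], ec[["OG"]])   # LEGH is OG-rich
  expect_lt(max(ec[["H"]], legh[["H"]]), 0.1)  # mucin carries almost no H
  expect_lt(ec[["OG"]], 0.05)           # EC is essentially OG-free

  # spread 0 collapses each class onto its mean
  d0 <- make_two_class_dataset(5, 5, spread = 0, seed = 1)
  expect_true(all(d0$EY[d0$label == "EC"] == 0.55))

  # swapping the class means negates the fitted weights
  d1 <- make_two_class_dataset(100, 100, seed = 13)
  d2 <- make_two_class_dataset(100, 100,
                               ec_mean = c(H = 0.02, EY = 0.25, LG = 0.20,
                                           OG = 0.35),
                               legh_mean = c(H = 0.02, EY = 0.55, LG = 0.15,
                                             OG = 0.01),
                               seed = 13)
  m1 <- fit_fisher(d1[d1$label == "EC", c("EY", "OG")],
                   d1[d1$label == "LEGH", c("EY", "OG")])
  m2 <- fit_fisher(d2[d2$label == "EC", c("EY", "OG")],
                   d2[d2$label == "LEGH", c("EY", "OG")])
  # swapped class means flip the discriminant direction (the draws differ,
  # so the match is directional, not exact)
  expect_identical(sign(m1$weights), -sign(m2$weights))
  cosang <- sum(m1$weights * -m2$weights) /
    sqrt(sum(m1$weights^2) * sum(m2$weights^2))
  expect_gt(cosang, 0.99)
})

test_that("single-stain phantoms carry only the requested dye", {
  ph <- single_stain_phantom("OG", test_stains(), n_pixels = 50,
                             photons = Inf, bit_depth = NULL, seed = 4)
  expect_true(all(ph$truth$data[, , 1:3] == 0))
  expect_true(all(ph$truth$data[, , 4] > 0))
})
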