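test_that("flat-field graphs have uniform weights and trivial paths", {
  bs <- bscan(matrix(0.5, 20, 15), 3, 10)
  g <- build_gradient_graph(bs, "dark_to_light")
  expect_true(all(g$gradient == 0))
  p <- find_boundary(g)
  # every admissible path has identical cost (nc - 1 edges of 2 + eps)
  expect_equal(p$cost, 14 * (2 + 1e-5))
})

test_that("an ideal step edge forces the path onto the edge row", {
  img <- matrix(0.1, 30, 25)
  img[16:30, ] <- 0.9  # edge between rows 15 and 16
  bs <- bscan(img, 3, 10)
  p <- find_boundary(build_gradient_graph(bs, "dark_to_light", sigma = 1))
  expect_true(all(p$rows %in% 15:16))
  expect_equal(length(unique(p$rows)), 1L)
})

test_that("dynamic-programming solve equals exhaustive path enumeration", {
  set.seed(31)
  for (i in 1:25) {
    img <- matrix(runif(36), 6, 6)
    g <- build_gradient_graph(bscan(img, 1, 1),
                              sample(c("dark_to_light", "light_to_dark"), 1),
                              sigma = runif(1, 0, 1.5))
    expect_equal(find_boundary(g)$cost, brute_force_min_path(g),
                 tolerance = 1e-12)
  }
})

test_that("band constraints are honored and can be fully binding", {
  bs <- bscan(matrix(runif(200), 20, 10), 3, 10)
  g <- build_gradient_graph(bs, "dark_to_light")
  band <- rbind(rep(7, 10), rep(7, 10))
  expect_equal(find_boundary(g, band)$rows, rep(7L, 10))
  band[, 4] <- c(9, 8)  # empty band in column 4
  expect_error(find_boundary(g, band), "band empty")
})

test_that("shrinking the band around the truth never increases error", {
  out <- generate_bscan(quick_bscan_spec(noise_sd = 0.05, seed = 5))
  g <- build_gradient_graph(out$bscan, "dark_to_light", sigma = 0.7)
  truth <- out$truth$boundaries_px["ilm", ]
  nc <- length(truth)
  err_for <- function(half) {
    band <- rbind(truth - half, truth + half)
    max(abs(find_boundary(g, band)$rows - truth))
  }
  errs <- vapply(c(20, 10, 5, 2), err_for, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("noise-free segmentation recovers every surface within a pixel", {
  out <- generate_bscan(quick_bscan_spec(noise_sd = 0, seed = 11))
  seg <- segment_layers(out$bscan)
  mae <- rowMeans(abs(seg$surfaces - out$truth$boundaries_px))
  expect_true(all(mae <= 1), info = paste(round(mae, 2), collapse = " "))
})

test_that("segmentation is translation-equivariant (noise-free)", {
  base <- quick_bscan_spec(noise_sd = 0, seed = 1)
  shifted <- quick_bscan_spec(noise_sd = 0, seed = 1,
                              ilm_depth_um = base$ilm_depth_um + 4 * 3.0,
                              n_rows = base$n_rows)
  s1 <- segment_layers(generate_bscan(base)$bscan)
  s2 <- segment_layers(generate_bscan(shifted)$bscan)
  expect_equal(s2$surfaces, s1$surfaces + 4, tolerance = 1e-8)
})

test_that("surface ordering holds on random phantoms or fails loudly", {
  for (s in 1:10) {
    th <- matrix(runif(5, 0.8, 1.3) * c(28.46, 72.40, 17.52, 10.15, 110.93),
                 5, 96)
    out <- generate_bscan(bscan_phantom_spec(
      n_columns = 96, layer_thicknesses = th, noise_sd = 0.03, seed = s))
    seg <- segment_layers(out$bscan)
    expect_true(all(apply(seg$surfaces, 2, diff) >= 0))
  }
})

test_that("manual overrides replace a surface and bad ones are caught", {
  out <- generate_bscan(quick_bscan_spec(noise_sd = 0, seed = 2))
  truth_ilm <- out$truth$boundaries_px["ilm", ]
  seg <- segment_layers(out$bscan, overrides = list(ilm = truth_ilm))
  expect_equal(seg$surfaces["ilm", ], truth_ilm)
  # an override that violates ordering must raise, not reorder
  expect_error(
    segment_layers(out$bscan,
                   overrides = list(ilm = rep(1000, 128))),
    "band empty|ordering")
})

test_that("thickness averaging equals a per-column re-summation oracle", {
  out <- generate_bscan(quick_bscan_spec(noise_sd = 0, seed = 6))
  seg <- segment_layers(out$bscan)
  th <- compute_thicknesses(seg)
  s <- seg$surfaces
  fov <- seg$fovea_column
  half_px <- 1 * 1000 / 2 / seg$lateral_pitch
  idx <- which(abs(seq_len(ncol(s)) - fov) <= half_px)
  oracle <- 0
  for (j in idx) oracle <- oracle + (s["inl_opl", j] - s["ipl_inl", j])
  oracle <- oracle / length(idx) * seg$axial_pitch
  expect_equal(th$inl_um, unname(oracle), tolerance = 1e-12)
})

test_that("coincident boundaries give zero thickness; wide regions error", {
  s <- matrix(rep(c(10, 20, 20, 30, 35, 90), 50), 6, 50)
  rownames(s) <- octaphen:::surface_names()
  bset <- structure(list(surfaces = s, axial_pitch = 3, lateral_pitch = 125,
                         fovea_column = 25), class = "boundary_set")
  th <- compute_thicknesses(bset)
  expect_equal(th$gcl_ipl_um, 0)  # rnfl_gcl == ipl_inl
  expect_error(
    compute_thicknesses(bset, region_diameters = list(
      rnfl = 6, gcl_ipl = 6, inl = 1, opl = 1, total = 1,
      central_subfield = 7)),
    "wider than the scan")
})

test_that("DME exclusion threshold is inclusive at 275 um", {
  expect_true(dme_exclusion_check(list(central_subfield_um = 275.0)))
  expect_false(dme_exclusion_check(list(central_subfield_um = 274.9)))
  # the normal-BCVA group mean total thickness is retained
  expect_false(dme_exclusion_check(list(central_subfield_um = 240.69)))
})
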