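# Shared phantom for the heavier OCTA tests (generated once per run).
octa_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_angiogram(angiogram_phantom_spec(
        target_skeleton_density = 0.072, seed = 2))
    }
    cache
  }
})

test_that("quality gate applies the strict SSI < 40 rule", {
  img <- matrix(0.5, 10, 10)
  expect_false(quality_gate(enface_angiogram(img, ssi = 35)))
  expect_true(quality_gate(enface_angiogram(img, ssi = 69)))
  expect_true(quality_gate(enface_angiogram(img, ssi = 40)))
  expect_warning(pass <- quality_gate(enface_angiogram(img)), "no SSI")
  expect_true(pass)
})

test_that("bicubic upsampling preserves constants, size, and the mean", {
  const <- enface_angiogram(matrix(0.37, 304, 304))
  up <- upsample_angiogram(const)
  expect_equal(dim(up), c(1024L, 1024L))
  expect_equal(range(up), c(0.37, 0.37), tolerance = 1e-12)
  # smooth random field: integral preserved within 1%
  set.seed(8)
  sm <- gaussian_smooth(matrix(runif(304^2), 304, 304), 8)
  up2 <- bicubic_resample(sm, 1024)
  expect_lt(abs(mean(up2) - mean(sm)) / mean(sm), 0.01)
  expect_error(upsample_angiogram(
    structure(list(intensity = matrix(0, 10, 20), center = c(5, 10),
                   scan_width_mm = 3), class = "enface_angiogram")),
    "square")
})

test_that("binarization recovers resolvable vessels and rejects flat fields", {
  # width-2 vessels survive the 304-pixel export; Dice vs the drawn mask
  out <- generate_angiogram(angiogram_phantom_spec(
    target_skeleton_density = 0.072, vessel_width_px = 2, seed = 3))
  up <- upsample_angiogram(out$angiogram)
  bin <- binarize_vessels(up)
  tm <- out$truth$vessel_mask_hi
  dice <- 2 * sum(bin & tm) / (sum(bin) + sum(tm))
  expect_gte(dice, 0.9)
  expect_false(any(binarize_vessels(matrix(0, 64, 64))))
  # Otsu threshold symmetry under intensity inversion (one-bin quantization)
  set.seed(1)
  v <- matrix(runif(2500)^2, 50, 50)
  expect_lt(abs((1 - otsu_threshold(1 - v)) - otsu_threshold(v)), 2 / 256)
})

test_that("skeleton is a thin subset of the binary mask and idempotent", {
  maps <- vessel_maps(octa_fixture()$angiogram)
  expect_true(all(maps$binary[maps$skeleton]))
  expect_identical(skeletonize(maps$skeleton), maps$skeleton)
  # no 2x2 solid blocks
  sk <- maps$skeleton
  blocks <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -ncol(sk)]
  expect_false(any(blocks))
})

test_that("vessel density equals a per-pixel loop oracle and bounds checks", {
  maps <- vessel_maps(octa_fixture()$angiogram)
  geom <- annulus_geometry()
  vd <- vessel_density(maps, geom)
  n <- nrow(maps$skeleton)
  px_mm <- n / 3
  n_sk <- 0L; n_ann <- 0L
  ctr <- maps$center
  for (r in seq_len(n)) {
    d2 <- (r - ctr[1])^2 + (seq_len(n) - ctr[2])^2
    inside <- d2 >= (0.3 * px_mm)^2 & d2 <= (1.25 * px_mm)^2
    n_ann <- n_ann + sum(inside)
    n_sk <- n_sk + sum(inside & maps$skeleton[r, ])
  }
  expect_identical(vd, n_sk / n_ann)
  # empty skeleton
  empty <- maps
  empty$skeleton <- empty$skeleton & FALSE
  expect_equal(vessel_density(empty, geom), 0)
  # annulus outside the image
  off <- maps
  off$center <- c(10, 10)
  expect_error(vessel_density(off, geom), "bounds")
})

test_that("density measurement is insensitive to 90-degree rotation", {
  an <- octa_fixture()$angiogram
  rot <- enface_angiogram(t(an$intensity)[ncol(an$intensity):1, ],
                          an$scan_width_mm, an$plexus)
  vd0 <- vessel_density(vessel_maps(an))
  vd90 <- vessel_density(vessel_maps(rot))
  expect_lt(abs(vd90 - vd0) / vd0, 0.02)
})

test_that("density increases with target density (nested stroke patterns)", {
  vds <- vapply(c(0.032, 0.052, 0.072), function(d) {
    out <- generate_angiogram(angiogram_phantom_spec(
      target_skeleton_density = d, seed = 4))
    vessel_density(vessel_maps(out$angiogram))
  }, numeric(1))
  expect_true(all(diff(vds) > 0))
})

test_that("FAZ area recovers the analytic disc and degenerates to the frame", {
  out <- octa_fixture()
  maps <- vessel_maps(out$angiogram)
  fz <- faz_area(maps)
  expect_lt(abs(fz - pi * 0.3^2) / (pi * 0.3^2), 0.15)
  # avascular limit: the whole 3 x 3 mm frame
  blank <- enface_angiogram(matrix(0, 304, 304))
  expect_equal(faz_area(vessel_maps(blank)), 9)
})

test_that("quantify_angiogram bundles metrics with provenance parameters", {
  out <- octa_fixture()
  an <- out$angiogram
  an$ssi <- 55
  q <- quantify_angiogram(an)
  expect_true(q$ssi_pass)
  expect_lt(abs(q$vd - out$truth$skeleton_density) /
              out$truth$skeleton_density, 0.10)
  expect_equal(q$parameters$outer_diameter_mm, 2.5)
  expect_equal(q$parameters$inner_exclusion_diameter_mm, 0.6)
})
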