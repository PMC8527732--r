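# Synthetic macular OCT B-scan phantoms with known layer boundaries.
#
# The phantom is a piecewise-constant axial intensity profile per column:
# vitreous background, then RNFL, GCL-IPL, INL, OPL and outer retina, then
# background again. Boundaries are anti-aliased with linear partial-volume
# so sub-pixel ground truth is meaningful. Intensities follow the usual
# SD-OCT appearance (bright RNFL, darker plexiform/nuclear layers, bright
# outer retinal complex).

layer_names <- function() c("rnfl", "gcl_ipl", "inl", "opl", "outer")

surface_names <- function() {
  c("ilm", "rnfl_gcl", "ipl_inl", "inl_opl", "opl_onl", "outer_boundary")
}

#' Specification of a B-scan phantom
#'
#' @param n_columns number of A-scans (image columns).
#' @param n_rows image depth in pixels; defaults to fit the layer stack with
#'   margin.
#' @param axial_pitch axial sampling, micrometers per pixel.
#' @param lateral_pitch lateral sampling, micrometers per pixel.
#' @param layer_thicknesses five thicknesses in micrometers for
#'   (RNFL, GCL-IPL, INL, OPL, outer retina); either length-5 or a
#'   5 x n_columns matrix of per-column profiles.
#' @param layer_intensities mean grayscale of the five layers, in \[0, 1\].
#' @param background_intensity vitreous / sub-retinal grayscale.
#' @param ilm_depth_um depth of the inner limiting membrane below the top
#'   edge, micrometers.
#' @param foveal_pit logical; carve a Gaussian foveal depression into the
#'   inner layers.
#' @param pit_depth_frac fractional inner-layer thinning at the pit center.
#' @param pit_width_um Gaussian half-width of the pit, micrometers.
#' @param noise_sd additive Gaussian noise SD in grayscale units.
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @return an object of class `bscan_phantom_spec`.
#' @export
bscan_phantom_spec <- function(n_columns = 304,
                               n_rows = NULL,
                               axial_pitch = 3.0,
                               lateral_pitch = 6000 / n_columns,
                               layer_thicknesses = c(28.46, 72.40, 17.52,
                                                     10.15, 110.93),
                               layer_intensities = c(0.85, 0.45, 0.30,
                                                     0.55, 0.70),
                               background_intensity = 0.05,
                               ilm_depth_um = 60,
                               foveal_pit = FALSE,
                               pit_depth_frac = 0.6,
                               pit_width_um = 350,
                               noise_sd = 0,
                               seed = 1L) {
  th <- layer_thicknesses
  if (is.matrix(th)) {
    assert_that(nrow(th) == 5 && ncol(th) == n_columns,
                "thickness matrix must be 5 x n_columns")
  } else {
    assert_that(length(th) == 5, "need five layer thicknesses")
    th <- matrix(th, nrow = 5, ncol = n_columns)
  }
  assert_that(all(th > 0), "layer thicknesses must be strictly positive")
  assert_that(length(layer_intensities) == 5 &&
                all(layer_intensities >= 0 & layer_intensities <= 1),
              "layer intensities must be five values in [0, 1]")
  stack <- c(background_intensity, layer_intensities, background_intensity)
  assert_that(all(abs(diff(stack)) >= 0.05),
              "adjacent layers need intensity contrast >= 0.05")
  assert_that(axial_pitch > 0 && lateral_pitch > 0, "pitches must be > 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  if (is.null(n_rows)) {
    n_rows <- ceiling((ilm_depth_um + max(colSums(th))) / axial_pitch + 20)
  }
  structure(list(
    n_columns = as.integer(n_columns), n_rows = as.integer(n_rows),
    axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
    layer_thicknesses = th, layer_intensities = layer_intensities,
    background_intensity = background_intensity, ilm_depth_um = ilm_depth_um,
    foveal_pit = isTRUE(foveal_pit), pit_depth_frac = pit_depth_frac,
    pit_width_um = pit_width_um, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "bscan_phantom_spec")
}

#' Construct a B-scan object
#'
#' @param intensity numeric matrix in \[0, 1\], rows = depth.
#' @param axial_pitch,lateral_pitch micrometers per pixel.
#' @param fovea_column pixel column of the foveal center (defaults to image
#'   center).
#' @return an object of class `bscan`.
#' @export
bscan <- function(intensity, axial_pitch, lateral_pitch,
                  fovea_column = NULL) {
  assert_that(is.matrix(intensity) && all(is.finite(intensity)),
              "intensity must be a finite numeric matrix")
  assert_that(axial_pitch > 0 && lateral_pitch > 0, "pitches must be > 0")
  structure(list(
    intensity = intensity, axial_pitch = axial_pitch,
    lateral_pitch = lateral_pitch,
    fovea_column = fovea_column %||% ((ncol(intensity) + 1) %/% 2)
  ), class = "bscan")
}

#' Generate a synthetic B-scan with ground-truth boundaries
#'
#' @param spec a [bscan_phantom_spec()].
#' @return list with elements `bscan` (a [bscan()]) and `truth` (list with
#'   `boundaries_px`, a 6 x n_columns matrix of per-column surface depths in
#'   pixel-row units for ILM, RNFL/GCL, IPL/INL, INL/OPL, OPL/ONL and the
#'   outer retinal boundary, and `thickness_um`, the 5 x n_columns profile
#'   actually rendered).
#' @export
generate_bscan <- function(spec) {
  stopifnot(inherits(spec, "bscan_phantom_spec"))
  th <- spec$layer_thicknesses
  nc <- spec$n_columns; nr <- spec$n_rows
  if (spec$foveal_pit) {
    x_um <- (seq_len(nc) - (nc + 1) / 2) * spec$lateral_pitch
    dip <- 1 - spec$pit_depth_frac * exp(-x_um^2 / (2 * spec$pit_width_um^2))
    th[1:4, ] <- th[1:4, ] * rep(dip, each = 4)  # inner layers thin at pit
  }
  depth_um <- rbind(spec$ilm_depth_um, spec$ilm_depth_um + apply(th, 2, cumsum))
  if (max(depth_um) / spec$axial_pitch > nr - 2) {
    stop("cumulative layer depth exceeds image height", call. = FALSE)
  }
  b_px <- depth_um / spec$axial_pitch  # 6 x nc, depth from top edge in px
  stack <- c(spec$background_intensity, spec$layer_intensities,
             spec$background_intensity)
  img <- matrix(stack[1], nr, nc)
  rows <- seq_len(nr)
  for (k in 1:6) {
    # pixel i spans depth [i-1, i); coverage of "below surface k"
    cov <- pmin(pmax(outer(rows, b_px[k, ], "-"), 0), 1)
    img <- img + (stack[k + 1] - stack[k]) * cov
  }
  img <- local_seed(spec$seed, {
    if (spec$noise_sd > 0)
      img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    else img
  })
  img <- clip01(img)
  boundaries <- b_px + 0.5  # pixel-row coordinates (row i has center i - 0.5)
  rownames(boundaries) <- surface_names()
  rownames(th) <- layer_names()
  list(
    bscan = bscan(img, spec$axial_pitch, spec$lateral_pitch),
    truth = list(boundaries_px = boundaries, thickness_um = th)
  )
}
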