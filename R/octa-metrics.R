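# En-face OCTA quantification: signal-quality gate, bicubic upsampling to
# 1024 x 1024, vesselness binarization, skeleton vessel density in the
# 2.5-mm perifoveal annulus (0.6-mm central exclusion), and FAZ area.
#
# Density convention: printed vessel densities in the 0.05-0.07 range are
# skeleton-pixel fractions (centerline length density), not area fractions
# of the binary mask (which would be ~0.3-0.5). `vessel_density` therefore
# counts skeleton pixels over annulus pixels.

#' Signal-quality gate
#'
#' Fails scans whose signal strength index (SSI) is below `min_ssi`
#' (device scans with SSI < 40 are conventionally excluded). A missing SSI
#' passes with a warning.
#'
#' @param angiogram an [enface_angiogram()].
#' @param min_ssi exclusion threshold; the comparison is strict (`ssi <
#'   min_ssi` fails, `ssi == min_ssi` passes).
#' @return logical: `TRUE` = pass.
#' @export
quality_gate <- function(angiogram, min_ssi = 40) {
  stopifnot(inherits(angiogram, "enface_angiogram"))
  if (is.null(angiogram$ssi)) {
    warning("no SSI recorded; passing quality gate unchecked", call. = FALSE)
    return(TRUE)
  }
  angiogram$ssi >= min_ssi
}

#' Upsample an angiogram to measurement resolution
#'
#' Bicubic interpolation to `size` x `size` (default 1024), clipped to
#' \[0, 1\].
#'
#' @param angiogram an [enface_angiogram()] (square image).
#' @param size output side length.
#' @return numeric matrix `size` x `size`.
#' @export
upsample_angiogram <- function(angiogram, size = 1024L) {
  stopifnot(inherits(angiogram, "enface_angiogram"))
  assert_that(nrow(angiogram$intensity) == ncol(angiogram$intensity),
              "angiogram must be square")
  bicubic_resample(angiogram$intensity, size)
}

#' Binarize a grayscale perfusion image
#'
#' Frangi-style vesselness enhancement followed by Otsu global
#' thresholding. The thresholded image is the mean of the range-normalized
#' intensity and the vesselness map: the vesselness term suppresses
#' background noise while the intensity term preserves the full vessel
#' caliber (pure vesselness thins vessels and cuts junctions). An
#' all-constant image yields an empty mask.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param sigmas vesselness scales in pixels.
#' @param beta,c_frac vesselness parameters, see [frangi_vesselness()].
#' @return logical vessel mask.
#' @export
binarize_vessels <- function(image, sigmas = c(1.5, 3), beta = 1,
                             c_frac = 0.25) {
  rng <- range(image)
  if (diff(rng) < 1e-8) {  # flat field (tolerates resampling round-off)
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  v <- frangi_vesselness(image, sigmas = sigmas, beta = beta, c_frac = c_frac)
  enhanced <- ((image - rng[1]) / diff(rng) + v) / 2
  enhanced > otsu_threshold(enhanced)
}

#' Compute upsampled/binary/skeleton maps for an angiogram
#'
#' @param angiogram an [enface_angiogram()].
#' @param size measurement resolution (default 1024).
#' @param ... passed to [binarize_vessels()].
#' @return an object of class `vessel_maps` with elements `upsampled`,
#'   `binary`, `skeleton`, plus the source geometry (`scan_width_mm`,
#'   `center` rescaled to the upsampled grid).
#' @export
vessel_maps <- function(angiogram, size = 1024L, ...) {
  up <- upsample_angiogram(angiogram, size)
  bin <- binarize_vessels(up, ...)
  skel <- skeletonize(bin)
  scale <- size / nrow(angiogram$intensity)
  structure(list(
    upsampled = up, binary = bin, skeleton = skel,
    scan_width_mm = angiogram$scan_width_mm,
    center = (angiogram$center - 0.5) * scale + 0.5
  ), class = "vessel_maps")
}

#' Annulus geometry for vessel-density measurement
#'
#' The measurement region is the 2.5-mm-diameter annulus around the fovea
#' with the central 0.6-mm disc excluded.
#'
#' @param outer_diameter_mm,inner_exclusion_diameter_mm region diameters.
#' @param scan_width_mm physical scan width.
#' @param grid_size measurement grid side length.
#' @return an object of class `annulus_geometry`.
#' @export
annulus_geometry <- function(outer_diameter_mm = 2.5,
                             inner_exclusion_diameter_mm = 0.6,
                             scan_width_mm = 3.0,
                             grid_size = 1024L) {
  assert_that(inner_exclusion_diameter_mm < outer_diameter_mm &&
                outer_diameter_mm <= scan_width_mm,
              "need inner < outer <= scan width")
  structure(list(
    outer_diameter_mm = outer_diameter_mm,
    inner_exclusion_diameter_mm = inner_exclusion_diameter_mm,
    scan_width_mm = scan_width_mm, grid_size = as.integer(grid_size),
    pixel_size_mm = scan_width_mm / grid_size
  ), class = "annulus_geometry")
}

# Logical annulus mask on an n x n grid (pixel centers at 1..n).
annulus_mask <- function(n, center, r_inner_px, r_outer_px) {
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+")
  d2 >= r_inner_px^2 & d2 <= r_outer_px^2
}

#' Skeleton vessel density in the measurement annulus
#'
#' Density = skeleton-pixel count inside the annulus divided by the annulus
#' pixel count (dimensionless, in \[0, 1\]).
#'
#' @param maps a [vessel_maps()] object.
#' @param geom an [annulus_geometry()].
#' @return numeric scalar.
#' @export
vessel_density <- function(maps, geom = annulus_geometry(
                             scan_width_mm = maps$scan_width_mm,
                             grid_size = nrow(maps$skeleton))) {
  stopifnot(inherits(maps, "vessel_maps"), inherits(geom, "annulus_geometry"))
  n <- nrow(maps$skeleton)
  px_mm <- 1 / geom$pixel_size_mm
  r_out <- geom$outer_diameter_mm / 2 * px_mm
  assert_that(maps$center[1] - r_out >= 0.5 && maps$center[1] + r_out <= n + 0.5 &&
                maps$center[2] - r_out >= 0.5 && maps$center[2] + r_out <= n + 0.5,
              "annulus exceeds image bounds")
  ann <- annulus_mask(n, maps$center,
                      geom$inner_exclusion_diameter_mm / 2 * px_mm, r_out)
  sum(maps$skeleton & ann) / sum(ann)
}

#' Foveal avascular zone area
#'
#' The vessel mask is morphologically closed to bridge capillary gaps; the
#' FAZ is the avascular connected component containing the fovea, and its
#' area is the pixel count times the pixel area.
#'
#' @param maps a [vessel_maps()] object.
#' @param geom an [annulus_geometry()] (supplies the pixel size).
#' @param closing_radius_px structuring-element radius for the closing.
#' @return FAZ area in square millimeters.
#' @export
faz_area <- function(maps, geom = annulus_geometry(
                       scan_width_mm = maps$scan_width_mm,
                       grid_size = nrow(maps$binary)),
                     closing_radius_px = 2) {
  stopifnot(inherits(maps, "vessel_maps"))
  closed <- binary_close(maps$binary, closing_radius_px)
  open <- !closed
  start <- round(maps$center)
  if (!open[start[1], start[2]]) {
    # fovea fell on a vessel pixel: search the nearest avascular pixel
    # within 0.1 mm
    reach_px <- ceiling(0.1 / geom$pixel_size_mm)
    offs <- disc_offsets(reach_px)
    offs <- offs[order(offs$dr^2 + offs$dc^2), ]
    found <- FALSE
    for (i in seq_len(nrow(offs))) {
      r <- start[1] + offs$dr[i]; c <- start[2] + offs$dc[i]
      if (r >= 1 && r <= nrow(open) && c >= 1 && c <= ncol(open) &&
          open[r, c]) {
        start <- c(r, c); found <- TRUE; break
      }
    }
    if (!found) {
      stop("no avascular pixel within 0.1 mm of the fovea center",
           call. = FALSE)
    }
  }
  comp <- connected_component(open, start)
  sum(comp) * geom$pixel_size_mm^2
}

#' Quantify one en-face angiogram
#'
#' Runs the quality gate, upsampling, binarization, skeletonization, and
#' the annular density and FAZ measurements.
#'
#' @param angiogram an [enface_angiogram()].
#' @param geom an [annulus_geometry()].
#' @param min_ssi quality-gate threshold.
#' @param ... passed to [vessel_maps()].
#' @return list with `vd`, `faz_area_mm2`, `ssi_pass`, and `parameters`.
#' @export
quantify_angiogram <- function(angiogram,
                               geom = annulus_geometry(
                                 scan_width_mm = angiogram$scan_width_mm),
                               min_ssi = 40, ...) {
  pass <- if (is.null(angiogram$ssi)) TRUE else angiogram$ssi >= min_ssi
  maps <- vessel_maps(angiogram, size = geom$grid_size, ...)
  list(
    vd = vessel_density(maps, geom),
    faz_area_mm2 = faz_area(maps, geom),
    ssi_pass = pass,
    parameters = list(
      plexus = angiogram$plexus, ssi = angiogram$ssi, min_ssi = min_ssi,
      outer_diameter_mm = geom$outer_diameter_mm,
      inner_exclusion_diameter_mm = geom$inner_exclusion_diameter_mm,
      grid_size = geom$grid_size
    )
  )
}
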