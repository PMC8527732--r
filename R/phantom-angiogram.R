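# Synthetic en-face OCTA angiogram phantoms.
#
# Capillaries are simulated as smooth random-walk strokes rasterized as
# one-pixel centerlines on the 1024-grid (the resolution at which the
# pipeline measures skeleton density), dilated to the vessel caliber,
# cleared inside a central avascular disc, and block-averaged down to the
# native 304 x 304 export size. Strokes are added until the centerline
# density inside the 2.5-mm measurement annulus reaches the target, giving
# direct control of the quantity the pipeline measures.

#' Specification of an en-face angiogram phantom
#'
#' @param image_size native export size in pixels (square).
#' @param scan_width_mm physical scan width.
#' @param target_skeleton_density target centerline-pixel fraction inside
#'   the 2.5-mm annulus at measurement (1024) resolution; must be in
#'   (0, 0.2), or 0 for an avascular phantom.
#' @param faz_radius_mm radius of the central avascular disc.
#' @param vessel_width_px vessel caliber in native pixels.
#' @param vessel_intensity,background_intensity grayscale of vessels and
#'   background.
#' @param noise_sd additive Gaussian noise SD on the exported image.
#' @param plexus slab label, `"SRCP"` or `"DRCP"`.
#' @param ssi optional signal strength index in \[0, 100\].
#' @param seed integer RNG seed.
#' @return an object of class `angiogram_phantom_spec`.
#' @export
angiogram_phantom_spec <- function(image_size = 304,
                                   scan_width_mm = 3.0,
                                   target_skeleton_density = 0.072,
                                   faz_radius_mm = 0.3,
                                   vessel_width_px = 1,
                                   vessel_intensity = 0.85,
                                   background_intensity = 0.08,
                                   noise_sd = 0,
                                   plexus = "DRCP",
                                   ssi = NULL,
                                   seed = 1L) {
  assert_that(target_skeleton_density >= 0 && target_skeleton_density < 0.2,
              "target_skeleton_density must be in [0, 0.2)")
  assert_that(faz_radius_mm < scan_width_mm / 2,
              "faz_radius_mm must be smaller than half the scan width")
  assert_that(vessel_width_px >= 1, "vessel_width_px must be >= 1")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(
    image_size = as.integer(image_size), scan_width_mm = scan_width_mm,
    target_skeleton_density = target_skeleton_density,
    faz_radius_mm = faz_radius_mm, vessel_width_px = vessel_width_px,
    vessel_intensity = vessel_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, plexus = plexus, ssi = ssi, seed = as.integer(seed)
  ), class = "angiogram_phantom_spec")
}

#' Construct an en-face angiogram object
#'
#' @param intensity square numeric matrix in \[0, 1\].
#' @param scan_width_mm physical width of the field.
#' @param plexus `"SRCP"` or `"DRCP"`.
#' @param ssi optional signal strength index in \[0, 100\].
#' @param center fovea pixel coordinates `c(row, col)`; defaults to the
#'   image center.
#' @param slab_definition free-text slab metadata.
#' @return an object of class `enface_angiogram`.
#' @export
enface_angiogram <- function(intensity, scan_width_mm = 3.0,
                             plexus = c("DRCP", "SRCP"), ssi = NULL,
                             center = NULL, slab_definition = "") {
  plexus <- match.arg(plexus)
  assert_that(is.matrix(intensity) && nrow(intensity) == ncol(intensity),
              "angiogram must be a square matrix")
  assert_that(scan_width_mm > 0, "scan_width_mm must be > 0")
  if (!is.null(ssi))
    assert_that(ssi >= 0 && ssi <= 100, "ssi must be in [0, 100]")
  n <- nrow(intensity)
  structure(list(
    intensity = intensity, scan_width_mm = scan_width_mm, plexus = plexus,
    ssi = ssi, center = center %||% c((n + 1) / 2, (n + 1) / 2),
    slab_definition = slab_definition
  ), class = "enface_angiogram")
}

# One smooth random-walk stroke rasterized to 1-px pixels on an n x n grid.
# Returns an index vector (column-major).
walk_stroke <- function(n, len, turn_sd = 0.25) {
  start <- runif(2, 0.05 * n, 0.95 * n)
  theta <- runif(1, 0, 2 * pi) + cumsum(rnorm(len, 0, turn_sd))
  ys <- start[1] + cumsum(sin(theta))
  xs <- start[2] + cumsum(cos(theta))
  r <- pmin(pmax(round(ys), 1), n)
  c <- pmin(pmax(round(xs), 1), n)
  unique(r + n * (c - 1L))
}

#' Generate a synthetic en-face angiogram with ground truth
#'
#' @param spec an [angiogram_phantom_spec()].
#' @param hires_size measurement grid size (the pipeline's upsample target).
#' @param max_strokes saturation guard; an error is raised if the target
#'   density is not reached.
#' @return list with elements `angiogram` (an [enface_angiogram()]) and
#'   `truth` (list with `skeleton_density` measured on the centerline
#'   raster inside the annulus, `faz_area_mm2`, `centerline_hi` and
#'   `vessel_mask_hi` logical matrices at `hires_size`).
#' @export
generate_angiogram <- function(spec, hires_size = 1024L,
                               max_strokes = 20000L) {
  stopifnot(inherits(spec, "angiogram_phantom_spec"))
  n <- as.integer(hires_size)
  px_mm <- n / spec$scan_width_mm
  ctr <- (n + 1) / 2
  ann <- annulus_mask(n, c(ctr, ctr), 0.3 * px_mm, 1.25 * px_mm)
  n_ann <- sum(ann)
  faz_r_px <- spec$faz_radius_mm * px_mm
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  faz_disc <- d2 <= faz_r_px^2

  centerline <- matrix(FALSE, n, n)
  local_seed(spec$seed, {
    if (spec$target_skeleton_density > 0) {
      # terminal capillary ring bounding the FAZ (the anatomical margin
      # that closes the avascular zone)
      ang <- seq(0, 2 * pi, length.out = ceiling(4 * pi * faz_r_px))
      rr <- pmin(pmax(round(ctr + (faz_r_px + 0.5) * sin(ang)), 1), n)
      cc <- pmin(pmax(round(ctr + (faz_r_px + 0.5) * cos(ang)), 1), n)
      centerline[unique(rr + n * (cc - 1L))] <- TRUE
      count_ann <- sum(centerline & ann)
      target_count <- spec$target_skeleton_density * n_ann
      stroke_len <- round(0.6 * n)
      strokes <- 0L
      # keep new centerlines >= 2 px away from existing ones so that
      # parallel strokes do not merge into one thick vessel (which would
      # halve the measurable skeleton length); crossings remain possible
      # because excluded pixels just split a stroke into segments
      forbidden <- centerline
      offs <- disc_offsets(2)
      grow <- function(mask, idx) {
        r <- (idx - 1L) %% n + 1L
        c <- (idx - 1L) %/% n + 1L
        for (i in seq_len(nrow(offs))) {
          r2 <- r + offs$dr[i]; c2 <- c + offs$dc[i]
          ok <- r2 >= 1 & r2 <= n & c2 >= 1 & c2 <= n
          mask[r2[ok] + n * (c2[ok] - 1L)] <- TRUE
        }
        mask
      }
      forbidden <- grow(forbidden, which(centerline))
      while (count_ann < target_count) {
        strokes <- strokes + 1L
        if (strokes > max_strokes) {
          stop("target skeleton density unreachable: pattern saturated ",
               "after ", max_strokes, " strokes", call. = FALSE)
        }
        idx <- walk_stroke(n, stroke_len)
        idx <- idx[!forbidden[idx] & !faz_disc[idx]]
        centerline[idx] <- TRUE
        forbidden <- grow(forbidden, idx)
        count_ann <- count_ann + sum(ann[idx])
      }
    }
    invisible(NULL)
  })

  width_hi <- spec$vessel_width_px * n / spec$image_size
  vessel_hi <- binary_dilate(centerline, max(1, width_hi / 2))
  img_hi <- matrix(spec$background_intensity, n, n)
  img_hi[vessel_hi] <- spec$vessel_intensity
  img <- bicubic_resample(img_hi, spec$image_size)
  img <- local_seed(derive_seed(spec$seed, 1L), {
    if (spec$noise_sd > 0)
      img + matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img))
    else img
  })
  truth_density <- sum(centerline & ann) / n_ann
  if (spec$target_skeleton_density > 0 &&
      abs(truth_density - spec$target_skeleton_density) >
        0.1 * spec$target_skeleton_density) {
    stop("achieved centerline density deviates > 10% from target",
         call. = FALSE)
  }
  list(
    angiogram = enface_angiogram(clip01(img), spec$scan_width_mm,
                                 spec$plexus, spec$ssi),
    truth = list(
      skeleton_density = truth_density,
      faz_area_mm2 = pi * spec$faz_radius_mm^2,
      centerline_hi = centerline,
      vessel_mask_hi = vessel_hi
    )
  )
}
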