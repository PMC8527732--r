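# Intraretinal layer segmentation by gradient-weighted shortest-path search.
#
# Each boundary is the minimum-cost left-to-right path through a graph
# whose nodes are pixels and whose edges connect 8-neighbours with
# left-to-right progress (column c -> c+1, row change in {-1, 0, +1});
# edge weight is 2 - (g_a + g_b) + eps with g the signed vertical gradient
# under the boundary's polarity, normalized to [0, 1]. Zero-cost virtual
# side columns make entry and exit rows free. Because edges only move
# rightward the global optimum is found exactly by dynamic programming
# over columns; ties prefer the shallower row.
#
# The six surfaces are found sequentially, highest-contrast first (ILM and
# the outer retinal boundary), each later search restricted to a band
# clipped inside previously found surfaces, which guarantees the ordering
# invariant by construction.

PATH_EPS <- 1e-5

#' Build the gradient graph for boundary search
#'
#' @param bscan a [bscan()] (>= 3 rows).
#' @param polarity `"dark_to_light"` for boundaries where intensity
#'   increases with depth, `"light_to_dark"` otherwise.
#' @param sigma Gaussian pre-smoothing SD in pixels.
#' @return an object of class `gradient_graph` holding the normalized
#'   polarity-signed gradient; edge weight between nodes a, b is
#'   `2 - (g_a + g_b) + 1e-5`.
#' @export
build_gradient_graph <- function(bscan,
                                 polarity = c("dark_to_light",
                                              "light_to_dark"),
                                 sigma = 1.5) {
  stopifnot(inherits(bscan, "bscan"))
  polarity <- match.arg(polarity)
  img <- bscan$intensity
  assert_that(nrow(img) >= 3, "image needs at least 3 rows")
  sm <- gaussian_smooth(img, sigma)
  nr <- nrow(sm)
  # vertical central difference, replicated at the top/bottom rows
  d <- (sm[c(2:nr, nr), , drop = FALSE] -
          sm[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
  g <- if (polarity == "dark_to_light") d else -d
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  structure(list(gradient = g, n_rows = nr, n_cols = ncol(g),
                 polarity = polarity, eps = PATH_EPS),
            class = "gradient_graph")
}

#' Minimum-cost boundary path within a search band
#'
#' Exact dynamic-programming solve of the left-to-right shortest path,
#' restricted per column to `band`. Ties prefer the shallower (smaller)
#' row, then the smaller column (implied by the left-to-right sweep).
#'
#' @param graph a [build_gradient_graph()] result.
#' @param band `NULL` (full image) or a 2 x n_cols matrix of inclusive
#'   `(low, high)` row limits per column.
#' @return list with `rows` (per-column row index of the path) and `cost`
#'   (total path cost).
#' @export
find_boundary <- function(graph, band = NULL) {
  stopifnot(inherits(graph, "gradient_graph"))
  g <- graph$gradient
  nr <- graph$n_rows; nc <- graph$n_cols
  if (is.null(band)) band <- rbind(rep(1, nc), rep(nr, nc))
  band <- rbind(pmax(1, ceiling(band[1, ])), pmin(nr, floor(band[2, ])))
  if (any(band[1, ] > band[2, ])) {
    stop("search band empty in column(s) ",
         paste(utils::head(which(band[1, ] > band[2, ]), 5), collapse = ", "),
         call. = FALSE)
  }
  rows_idx <- seq_len(nr)
  inband <- function(cc) rows_idx >= band[1, cc] & rows_idx <= band[2, cc]

  cost <- matrix(Inf, nr, nc)
  parent <- matrix(NA_integer_, nr, nc)
  cost[inband(1), 1] <- 0
  for (cc in 2:nc) {
    prev <- cost[, cc - 1] - g[, cc - 1]
    # predecessor preference on ties: r-1 (shallower), then r, then r+1
    cand_up <- c(Inf, prev[-nr]); up_row <- c(NA, seq_len(nr - 1))
    cand_same <- prev; same_row <- seq_len(nr)
    cand_down <- c(prev[-1], Inf); down_row <- c(seq_len(nr - 1) + 1, NA)
    best <- cand_up; best_row <- up_row
    swap <- cand_same < best
    best[swap] <- cand_same[swap]; best_row[swap] <- same_row[swap]
    swap <- cand_down < best
    best[swap] <- cand_down[swap]; best_row[swap] <- down_row[swap]
    total <- best + (2 + graph$eps) - g[, cc]
    ok <- inband(cc) & is.finite(best)
    cost[ok, cc] <- total[ok]
    parent[ok, cc] <- best_row[ok]
  }
  end_col <- cost[, nc]
  if (!any(is.finite(end_col))) stop("no admissible path", call. = FALSE)
  r <- which.min(end_col)  # which.min returns the first (shallowest) tie
  path <- integer(nc)
  path[nc] <- r
  for (cc in nc:2) path[cc - 1] <- parent[path[cc], cc]
  list(rows = path, cost = end_col[r])
}

# Default surface search plan: name, polarity, and how the band is derived.
surface_plan <- function() {
  list(
    list(name = "ilm", polarity = "dark_to_light"),
    list(name = "outer_boundary", polarity = "light_to_dark"),
    list(name = "rnfl_gcl", polarity = "light_to_dark"),
    list(name = "ipl_inl", polarity = "light_to_dark"),
    list(name = "inl_opl", polarity = "dark_to_light"),
    list(name = "opl_onl", polarity = "dark_to_light")
  )
}

#' Segment the six intraretinal surfaces of a B-scan
#'
#' Finds ILM and the outer retinal boundary first (the highest-contrast
#' surfaces), then the four interior surfaces inside the enclosed band,
#' clipping each search band inside previously found surfaces. A
#' user-supplied override replaces a surface (mirroring manual correction
#' after visual inspection). An ordering violation raises an error with
#' diagnostics rather than silently reordering.
#'
#' @param bscan a [bscan()].
#' @param sigma gradient pre-smoothing SD in pixels.
#' @param margin band clearance below/above already-found surfaces, pixels.
#' @param thin_margin clearance around the thin plexiform surfaces, pixels.
#' @param refine logical: parabolic sub-pixel refinement of each surface
#'   around the integer path (shift clamped to half a pixel).
#' @param overrides named list of per-column row vectors replacing the
#'   search for those surfaces.
#' @return an object of class `boundary_set`: a 6 x n_cols matrix `surfaces`
#'   (rows named ilm, rnfl_gcl, ipl_inl, inl_opl, opl_onl, outer_boundary,
#'   in depth order) of per-column row coordinates.
#' @export
segment_layers <- function(bscan, sigma = 0.7, margin = 3, thin_margin = 2,
                           refine = TRUE, overrides = list()) {
  stopifnot(inherits(bscan, "bscan"))
  nc <- ncol(bscan$intensity); nr <- nrow(bscan$intensity)
  graphs <- list(
    dark_to_light = build_gradient_graph(bscan, "dark_to_light", sigma),
    light_to_dark = build_gradient_graph(bscan, "light_to_dark", sigma)
  )
  found <- list()
  subpixel <- function(rows, polarity) {
    if (!refine) return(rows)
    g <- graphs[[polarity]]$gradient
    r0 <- pmin(pmax(rows, 2), nr - 1)
    cols <- seq_len(nc)
    gm <- g[cbind(r0 - 1, cols)]; g0 <- g[cbind(r0, cols)]
    gp <- g[cbind(r0 + 1, cols)]
    denom <- gm - 2 * g0 + gp
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (gm - gp) / denom, 0)
    rows + pmin(pmax(shift, -0.5), 0.5)
  }
  search <- function(polarity, lo, hi) {
    subpixel(find_boundary(graphs[[polarity]], rbind(lo, hi))$rows, polarity)
  }
  get <- function(name, polarity, lo, hi) {
    if (!is.null(overrides[[name]])) {
      ov <- overrides[[name]]
      assert_that(length(ov) == nc, "override length must equal column count")
      return(ov)
    }
    search(polarity, lo, hi)
  }
  full_lo <- rep(1, nc); full_hi <- rep(nr, nc)
  found$ilm <- get("ilm", "dark_to_light", full_lo, full_hi)
  found$outer_boundary <- get("outer_boundary", "light_to_dark",
                              found$ilm + margin, full_hi)
  found$rnfl_gcl <- get("rnfl_gcl", "light_to_dark",
                        found$ilm + margin,
                        found$outer_boundary - margin)
  found$ipl_inl <- get("ipl_inl", "light_to_dark",
                       found$rnfl_gcl + margin,
                       found$outer_boundary - margin)
  found$inl_opl <- get("inl_opl", "dark_to_light",
                       found$ipl_inl + thin_margin,
                       found$outer_boundary - margin)
  found$opl_onl <- get("opl_onl", "dark_to_light",
                       found$inl_opl + thin_margin,
                       found$outer_boundary - thin_margin)
  surfaces <- do.call(rbind, found[surface_names()])
  bad <- which(apply(surfaces, 2, function(col) any(diff(col) < 0)))
  if (length(bad) > 0) {
    stop("surface ordering violated in column(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         "; first offending column depths: ",
         paste(round(surfaces[, bad[1]], 1), collapse = " "), call. = FALSE)
  }
  structure(list(surfaces = surfaces,
                 axial_pitch = bscan$axial_pitch,
                 lateral_pitch = bscan$lateral_pitch,
                 fovea_column = bscan$fovea_column),
            class = "boundary_set")
}

#' Regional thickness averages from segmented boundaries
#'
#' Per-layer thickness is `(lower - upper) * axial_pitch` averaged over the
#' columns within the region half-width around the fovea column: the
#' central 6-mm circle for RNFL and GCL-IPL, the central 1-mm circle for
#' INL, OPL, total retina and the central subfield.
#'
#' @param boundaries a [segment_layers()] result.
#' @param region_diameters named list of region diameters in mm.
#' @return an object of class `thickness_set` with fields `rnfl_um`,
#'   `gcl_ipl_um`, `inl_um`, `opl_um`, `total_um`, `central_subfield_um`.
#' @export
compute_thicknesses <- function(boundaries,
                                region_diameters = list(
                                  rnfl = 6, gcl_ipl = 6, inl = 1, opl = 1,
                                  total = 1, central_subfield = 1)) {
  stopifnot(inherits(boundaries, "boundary_set"))
  s <- boundaries$surfaces
  nc <- ncol(s)
  fov <- boundaries$fovea_column
  cols_in <- function(diam_mm) {
    if (diam_mm * 1000 > nc * boundaries$lateral_pitch + 1e-6) {
      stop("region (", diam_mm, " mm) wider than the scan", call. = FALSE)
    }
    half_px <- diam_mm * 1000 / 2 / boundaries$lateral_pitch
    which(abs(seq_len(nc) - fov) <= half_px)
  }
  mean_th <- function(lower, upper, diam) {
    idx <- cols_in(diam)
    mean((s[lower, idx] - s[upper, idx]) * boundaries$axial_pitch)
  }
  structure(list(
    rnfl_um = mean_th("rnfl_gcl", "ilm", region_diameters$rnfl),
    gcl_ipl_um = mean_th("ipl_inl", "rnfl_gcl", region_diameters$gcl_ipl),
    inl_um = mean_th("inl_opl", "ipl_inl", region_diameters$inl),
    opl_um = mean_th("opl_onl", "inl_opl", region_diameters$opl),
    total_um = mean_th("outer_boundary", "ilm", region_diameters$total),
    central_subfield_um = mean_th("outer_boundary", "ilm",
                                  region_diameters$central_subfield)
  ), class = "thickness_set")
}

#' Diabetic macular edema exclusion check
#'
#' Eyes with a central subfield thickness of at least 275 micrometers are
#' excluded (the threshold is inclusive).
#'
#' @param thicknesses a [compute_thicknesses()] result (or a list with
#'   `central_subfield_um`).
#' @param threshold_um exclusion threshold.
#' @return logical: `TRUE` means exclude.
#' @export
dme_exclusion_check <- function(thicknesses, threshold_um = 275) {
  csf <- thicknesses$central_subfield_um
  assert_that(!is.null(csf) && is.finite(csf),
              "central_subfield_um missing")
  csf >= threshold_um
}
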