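# Image-processing primitives: Gaussian smoothing, binary morphology,
# Otsu thresholding, Frangi-style vesselness, skeletonization,
# connected components. All operate on plain matrices.

# Shift matrix content by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Smooth along one axis by shift-accumulate convolution with edge
# renormalization (equivalent to a row-normalized band operator but much
# faster than a dense matmul on large images).
smooth_axis <- function(img, sigma, axis) {
  half <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-half:half)^2 / (2 * sigma^2))
  acc <- img * 0
  norm <- acc
  ones <- matrix(1, nrow(img), ncol(img))
  for (k in seq_along(w)) {
    off <- k - half - 1L
    dr <- if (axis == 1) off else 0L
    dc <- if (axis == 2) off else 0L
    acc <- acc + w[k] * shift_matrix(img, dr, dc, 0)
    norm <- norm + w[k] * shift_matrix(ones, dr, dc, 0)
  }
  acc / norm
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian blur with edge renormalization.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels (0 returns the input).
#' @return smoothed matrix.
#' @export
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  smooth_axis(smooth_axis(img, sigma, 1), sigma, 2)
}

# Disc-shaped structuring-element offsets.
disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Binary morphology with a disc structuring element
#'
#' `binary_dilate` treats outside-image as background, `binary_erode` as
#' foreground (so closing is extensive at the borders).
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return logical matrix.
#' @export
binary_dilate <- function(mask, radius) {
  offs <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_matrix(mask, offs$dr[i], offs$dc[i], FALSE)
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius) {
  offs <- disc_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_matrix(mask, offs$dr[i], offs$dc[i], TRUE)
  out
}

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

#' Otsu's global threshold
#'
#' @param img numeric matrix in \[0, 1\].
#' @param n_bins histogram resolution.
#' @return threshold in \[0, 1\]; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.vector(img)
  v <- v[is.finite(v)]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                          1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

#' Frangi-style vesselness filter
#'
#' Hessian-eigenvalue vesselness for bright curvilinear structures on a dark
#' background, maximized over scales.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param sigmas vector of scales (pixels).
#' @param beta blob-suppression parameter.
#' @param c_frac structureness parameter as a fraction of the maximum
#'   Hessian norm at each scale.
#' @return vesselness map rescaled to \[0, 1\].
#' @export
frangi_vesselness <- function(img, sigmas = c(1.5, 3), beta = 0.5,
                              c_frac = 0.5) {
  best <- matrix(0, nrow(img), ncol(img))
  for (s in sigmas) {
    sm <- gaussian_smooth(img, s)
    # scale-normalized second derivatives (rows = y, cols = x)
    dyy <- (shift_matrix(sm, -1, 0, NA) - 2 * sm + shift_matrix(sm, 1, 0, NA))
    dxx <- (shift_matrix(sm, 0, -1, NA) - 2 * sm + shift_matrix(sm, 0, 1, NA))
    dy  <- (shift_matrix(sm, -1, 0, NA) - shift_matrix(sm, 1, 0, NA)) / 2
    dxy <- (shift_matrix(dy, 0, -1, NA) - shift_matrix(dy, 0, 1, NA)) / 2
    dxx[!is.finite(dxx)] <- 0; dyy[!is.finite(dyy)] <- 0
    dxy[!is.finite(dxy)] <- 0
    dxx <- dxx * s^2; dyy <- dyy * s^2; dxy <- dxy * s^2
    tmp <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
    mu <- (dxx + dyy) / 2
    e1 <- mu + tmp; e2 <- mu - tmp
    # lam2 = larger |.|; bright vessels need lam2 < 0
    swap <- abs(e1) > abs(e2)
    lam1 <- ifelse(swap, e2, e1)
    lam2 <- ifelse(swap, e1, e2)
    S2 <- lam1^2 + lam2^2
    c2 <- (c_frac * sqrt(max(S2)))^2
    if (c2 == 0) next
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[lam2 >= 0] <- 0
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected centerline.
#'
#' @param mask logical matrix.
#' @return logical matrix, a subset of `mask`.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .cpp_thin(mask)
}

#' Connected component containing a pixel
#'
#' 4-connected flood fill over `open` from `start`.
#'
#' @param open logical matrix of admissible pixels.
#' @param start integer `c(row, col)` (1-based).
#' @return logical matrix marking the component (all-FALSE if `start` is not
#'   open).
#' @export
connected_component <- function(open, start) {
  stopifnot(is.logical(open), length(start) == 2)
  .cpp_flood_fill(open, as.integer(start[1]) - 1L, as.integer(start[2]) - 1L)
}
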