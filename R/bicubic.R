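# Bicubic (Keys cubic convolution, a = -0.5) resampling.
#
# Separable: the 2-D resample is W_r %*% img %*% t(W_c) where W_* are the
# 1-D cubic interpolation operators. Pixel centers are aligned
# (x_in = (i_out + 0.5) * n_in/n_out - 0.5); edges replicate.

keys_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
    ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

# n_out x n_in interpolation operator for one axis.
cubic_operator <- function(n_in, n_out) {
  x <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5  # 0-based input coords
  base <- floor(x)
  t <- x - base
  W <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), n_in - 1) + 1  # replicate edges
    w <- keys_kernel(t - k)
    W[cbind(seq_len(n_out), idx)] <- W[cbind(seq_len(n_out), idx)] + w
  }
  W
}

#' Resample a grayscale image by bicubic interpolation
#'
#' @param img numeric matrix in \[0, 1\].
#' @param n_out output side length in pixels (output is `n_out` x `n_out`
#'   scaled per-axis; non-square inputs are resampled per axis).
#' @return numeric matrix, clipped to \[0, 1\].
#' @export
bicubic_resample <- function(img, n_out) {
  stopifnot(is.matrix(img), n_out >= 2)
  Wr <- cubic_operator(nrow(img), n_out)
  Wc <- cubic_operator(ncol(img), n_out)
  clip01(Wr %*% img %*% t(Wc))
}
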