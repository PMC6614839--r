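# Internal numeric helpers shared across modules.
#
# Coordinate convention used throughout the package: a frame is a numeric
# matrix m[row, col]; the pixel at m[r, c] has its *center* at
# (x, y) = (c - 1, r - 1), i.e. 0-based coordinates with integer pixel
# centers. All focus positions are in these pixel units unless a column is
# explicitly suffixed _nm or _um.

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

#' Peak (mode) of a kernel density estimate
#'
#' Location of the highest point of a Gaussian KDE. Used for the
#' characteristic-intensity estimate and for seeding stoichiometry peak fits.
#'
#' @param x numeric values.
#' @param bw kernel standard deviation; default `stats::bw.nrd0`.
#' @param n grid size.
#' @return the abscissa of the KDE maximum.
#' @export
kde_peak <- function(x, bw = NULL, n = 512) {
  x <- x[is.finite(x)]
  abort_if(length(x) < 2, "need at least two finite values for a KDE peak")
  d <- stats::density(x, bw = bw %||% stats::bw.nrd0(x), n = n)
  d$x[which.max(d$y)]
}

# Separable Gaussian blur with replicated edges. Frames are small (<= a few
# hundred pixels a side) so direct convolution is fast enough.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(r + 1):(r + length(v))])
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

# Sub-pixel image translation via Fourier shift theorem (periodic boundary).
# Positive dx moves content toward larger x (columns), dy toward larger y.
fourier_shift <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  fy <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  ph <- exp(-2i * pi * (outer(fy, rep(1, nc)) * dy + outer(rep(1, nr), fx) * dx))
  Re(fft(fft(m) * ph, inverse = TRUE) / (nr * nc))
}

# Circular cross-correlation surface of two equal-size matrices, normalized
# so a perfect match scores 1. Entry [i, j] corresponds to displacement
# (dy = i - 1, dx = j - 1) modulo the image size, of features in `a`
# relative to `b`.
xcorr2 <- function(a, b) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  denom <- sqrt(sum(a0^2) * sum(b0^2))
  if (denom == 0) return(matrix(0, nrow(a), ncol(a)))
  cc <- Re(fft(fft(b0) * Conj(fft(a0)), inverse = TRUE)) / length(a)
  cc / denom
}

# wrap an index on 1..n to a signed displacement in (-n/2, n/2]
wrap_disp <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)

# 1D parabolic sub-pixel refinement around a discrete argmax
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (den == 0) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}

seed_from <- function(seed, stage) {
  # derive independent, reproducible sub-seeds below 2^31
  (as.integer(seed) * 48271 + stage * 9973) %% 2147483629L
}
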