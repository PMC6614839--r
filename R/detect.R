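#' Find candidate foci in one frame
#'
#' Bright diffraction-limited spots are enhanced with a Gaussian band-pass
#' (difference of sigma = 1 px and sigma = 5 px blurs), thresholded at the
#' transformed image's mean + `k` SD, and local maxima are kept. Maxima
#' closer than one ROI radius are merged to the brighter seed.
#'
#' @param frame numeric matrix.
#' @param k threshold multiplier on the band-pass SD.
#' @param roi_radius merge radius in pixels.
#' @return tibble of integer seed coordinates `x`, `y` (0-based centers).
#' @export
find_candidates <- function(frame, k = 3.5, roi_radius = 5) {
  dog <- gauss_blur(frame, 1) - gauss_blur(frame, 5)
  thr <- mean(dog) + k * sd(dog)
  if (!is.finite(thr) || sd(dog) == 0) {
    return(tibble(x = integer(0), y = integer(0)))
  }
  nr <- nrow(dog); nc <- ncol(dog)
  # strict local maxima over the 8-neighbourhood, away from the border
  cand <- which(dog > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr & cand[, 2] > 1 & cand[, 2] < nc, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(tibble(x = integer(0), y = integer(0)))
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    v <- dog[r, c]
    nb <- dog[(r - 1):(r + 1), (c - 1):(c + 1)]
    v >= max(nb) && sum(nb == v) == 1
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0) return(tibble(x = integer(0), y = integer(0)))
  vals <- dog[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][d2 <= roi_radius^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(x = as.integer(cand[, 2] - 1), y = as.integer(cand[, 1] - 1))
}

#' Sub-pixel centroid by iterative Gaussian masking
#'
#' Background-corrected pixels in a local window are weighted by a Gaussian
#' mask centered on the current estimate and the intensity-weighted centroid
#' is recomputed, iterating until the update falls below `tol` pixels (or
#' `max_iter`). Estimates that wander outside the window are discarded.
#'
#' @param frame numeric matrix.
#' @param seed length-2 c(x, y) starting position (pixels, 0-based).
#' @param mask_sigma Gaussian mask sigma in pixels (about the PSF width).
#' @param half half-size of the square analysis window (17x17 by default).
#' @param tol convergence tolerance in pixels.
#' @param max_iter iteration cap.
#' @return c(x, y) converged centroid, or c(NA, NA) when discarded.
#' @export
refine_centroid <- function(frame, seed, mask_sigma = 1.5, half = 8L,
                            tol = 1e-3, max_iter = 200L) {
  nr <- nrow(frame); nc <- ncol(frame)
  cx0 <- round(seed[1]); cy0 <- round(seed[2])
  xs <- max(0, cx0 - half):min(nc - 1, cx0 + half)
  ys <- max(0, cy0 - half):min(nr - 1, cy0 + half)
  win <- frame[ys + 1, xs + 1, drop = FALSE]
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  # background from the window pixels outside the central circle
  d2c <- (gx - seed[1])^2 + (gy - seed[2])^2
  bgpix <- win[d2c > 25]
  bg <- if (length(bgpix)) mean(bgpix) else 0
  v <- pmax(win - bg, 0)
  if (sum(v) == 0) return(c(NA_real_, NA_real_))
  est <- as.numeric(seed)
  for (it in seq_len(max_iter)) {
    w <- exp(-((gx - est[1])^2 + (gy - est[2])^2) / (2 * mask_sigma^2))
    m <- v * w
    s <- sum(m)
    if (s == 0) return(c(NA_real_, NA_real_))
    new <- c(sum(m * gx), sum(m * gy)) / s
    if (new[1] < min(xs) || new[1] > max(xs) ||
        new[2] < min(ys) || new[2] > max(ys)) {
      return(c(NA_real_, NA_real_))
    }
    if (sqrt(sum((new - est)^2)) < tol) return(new)
    est <- new
  }
  est
}

#' Measure focus intensity and signal-to-noise ratio
#'
#' Intensity is the summed pixel intensity inside a circular region of
#' interest (radius `roi_radius`, pixel-center membership) around the
#' centroid, corrected for the background estimated as the mean pixel value
#' of the surrounding 17x17 square excluding the circle. SNR is the mean
#' background-corrected circular-ROI pixel divided by the SD of the square's
#' background pixels. Near the frame edge the square shrinks symmetrically.
#'
#' @param frame numeric matrix.
#' @param centroid c(x, y) pixels.
#' @param roi_radius circular ROI radius in pixels.
#' @param half background-square half-size (17x17 default).
#' @return list with `intensity`, `snr`, `background`.
#' @export
measure_focus <- function(frame, centroid, roi_radius = 5, half = 8L) {
  nr <- nrow(frame); nc <- ncol(frame)
  cx <- round(centroid[1]); cy <- round(centroid[2])
  h <- min(half, cx, nc - 1 - cx, cy, nr - 1 - cy)
  if (h < roi_radius) h <- min(half, max(roi_radius, h))
  xs <- max(0, cx - h):min(nc - 1, cx + h)
  ys <- max(0, cy - h):min(nr - 1, cy + h)
  win <- frame[ys + 1, xs + 1, drop = FALSE]
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  incirc <- (gx - centroid[1])^2 + (gy - centroid[2])^2 <= roi_radius^2
  bgpix <- win[!incirc]
  if (length(bgpix) < 2) return(list(intensity = NA_real_, snr = NA_real_,
                                     background = NA_real_))
  bg <- mean(bgpix)
  bsd <- sd(bgpix)
  roivals <- win[incirc] - bg
  intensity <- sum(roivals)
  snr <- if (bsd == 0) {
    if (isTRUE(all.equal(mean(roivals), 0))) 0 else Inf
  } else mean(roivals) / bsd
  list(intensity = intensity, snr = snr, background = bg)
}

#' Detect foci across a stack
#'
#' Runs candidate finding, iterative Gaussian-mask localization and
#' ROI photometry on every page, keeping foci with SNR above the acceptance
#' threshold.
#'
#' @param stack a [slim_stack()].
#' @param snr_min acceptance threshold on SNR (foci must exceed it).
#' @param mask_sigma localization mask sigma (px).
#' @param roi_radius circular ROI radius (px).
#' @param k candidate threshold multiplier (see [find_candidates()]).
#' @return tibble: `channel`, `frame`, `x`, `y`, `intensity`, `snr`.
#' @export
detect_foci <- function(stack, snr_min = 0.4, mask_sigma = 1.5,
                        roi_radius = 5, k = 3.5) {
  out <- purrr::map(seq_along(stack$frames), function(i) {
    fr <- stack$frames[[i]]
    cand <- find_candidates(fr, k = k, roi_radius = roi_radius)
    if (nrow(cand) == 0) return(NULL)
    rows <- purrr::map(seq_len(nrow(cand)), function(j) {
      ctr <- refine_centroid(fr, c(cand$x[j], cand$y[j]),
                             mask_sigma = mask_sigma)
      if (any(is.na(ctr))) return(NULL)
      m <- measure_focus(fr, ctr, roi_radius = roi_radius)
      tibble(channel = stack$channel[i], frame = stack$frame[i],
             x = ctr[1], y = ctr[2], intensity = m$intensity, snr = m$snr)
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(channel = character(), frame = integer(), x = numeric(),
                  y = numeric(), intensity = numeric(), snr = numeric()))
  }
  # deduplicate converged centroids that collapsed onto the same focus
  res <- res |>
    dplyr::group_by(.data$channel, .data$frame) |>
    dplyr::arrange(dplyr::desc(.data$intensity), .by_group = TRUE) |>
    dplyr::filter(!duplicated(paste(round(.data$x), round(.data$y)))) |>
    dplyr::ungroup()
  res[res$snr > snr_min, ]
}
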