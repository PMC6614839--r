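#' Render simulated trajectories into an image stack
#'
#' Every unbleached fluorophore contributes a 2D Gaussian point-spread
#' function of the channel's sigma, integrating `brightness` counts. Motion
#' blur is emulated by accumulating the PSF at `substeps` Brownian-bridge
#' sub-positions within each frame. Pool monomers are rendered the same way
#' at unit stoichiometry. The camera model adds, per pixel, a gamma
#' approximation of EM-amplified shot noise (mean preserved), Gaussian read
#' noise and a constant offset; with `camera_noise = FALSE` the image is the
#' deterministic offset + signal.
#'
#' @param truth a [sim_tracks()] result.
#' @param config the generating [slim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @param bf_shift_px known sub-pixel (dx, dy) translation encoded between
#'   the two returned brightfield images, for registration tests.
#' @return list with `stack` (a [slim_stack()], channel-interleaved when two
#'   channels are configured), `brightfield` (list `a`, `b`, `shift_px`) and
#'   `truth` passed through.
#' @export
render_stack <- function(truth, config, seed = NULL, bf_shift_px = c(0, 0)) {
  seed <- seed %||% config$seed
  nx <- config$field_px[1]; ny <- config$field_px[2]
  nF <- config$n_frames
  dt_s <- config$frame_ms / 1000
  px_per_um <- 1000 / config$pixel_nm
  mx <- 2^config$bit_depth - 1

  withr::with_seed(seed_from(seed, 7L), {
    channel_frames <- list()
    for (ch in config$channels) {
      sig_px <- config$psf_sigma_nm[[ch]] / config$pixel_nm
      ids <- truth$foci$id[truth$foci$channel == ch]
      pos <- truth$positions[truth$positions$id %in% ids, ]
      frames <- vector("list", nF)
      for (f in 0:(nF - 1)) {
        img <- matrix(0, ny, nx)
        pf <- pos[pos$frame == f, ]
        pf <- pf[pf$survivors > 0, ]
        if (nrow(pf) > 0) {
          nxt <- pos[pos$frame == min(f + 1, nF - 1), ]
          for (i in seq_len(nrow(pf))) {
            amp <- config$brightness * pf$survivors[i]
            Dfoc <- truth$foci$D[truth$foci$id == pf$id[i]]
            if (isTRUE(pf$bound[i])) Dfoc <- 0
            p1 <- nxt[nxt$id == pf$id[i], ]
            sub <- sub_positions(c(pf$x[i], pf$y[i]),
                                 if (nrow(p1)) c(p1$x, p1$y) else c(pf$x[i], pf$y[i]),
                                 config$substeps, Dfoc, dt_s, px_per_um)
            for (j in seq_len(nrow(sub))) {
              img <- add_psf(img, sub[j, 1], sub[j, 2], sig_px,
                             amp / nrow(sub))
            }
          }
        }
        # diffuse pool (first-species channel only)
        if (nrow(truth$pool) > 0 && ch == truth$pool$channel[1]) {
          pp <- truth$pool_positions[truth$pool_positions$frame == f &
                                       truth$pool_positions$alive, ]
          for (i in seq_len(nrow(pp))) {
            img <- add_psf(img, pp$x[i], pp$y[i], sig_px, config$brightness)
          }
        }
        frames[[f + 1]] <- apply_camera(img, config)
        if (any(frames[[f + 1]] > mx)) {
          message(sprintf("render_stack: clipping %d saturated pixels (frame %d, %s)",
                          sum(frames[[f + 1]] > mx), f, ch))
          frames[[f + 1]] <- pmin(frames[[f + 1]], mx)
        }
      }
      channel_frames[[ch]] <- frames
    }

    if (length(config$channels) == 2 && config$alternating) {
      pages <- vector("list", 2 * nF)
      channel <- character(2 * nF); frame <- integer(2 * nF)
      for (f in 0:(nF - 1)) {
        pages[[2 * f + 1]] <- channel_frames[[config$channels[1]]][[f + 1]]
        pages[[2 * f + 2]] <- channel_frames[[config$channels[2]]][[f + 1]]
        channel[2 * f + 1:2] <- config$channels
        frame[2 * f + 1:2] <- f
      }
    } else {
      pages <- do.call(c, unname(channel_frames))
      channel <- rep(config$channels, each = nF)
      frame <- rep(0:(nF - 1), times = length(config$channels))
    }
    stack <- slim_stack(pages, channel, frame, config$pixel_nm, config$frame_ms)

    # textured brightfield pair with a known encoded shift
    label <- attr(truth$cells, "label")
    base <- matrix(1000, ny, nx)
    if (!is.null(label)) base <- base - 300 * (label > 0)
    base <- base + gauss_blur(matrix(rnorm(ny * nx, 0, 120), ny, nx), 1.5)
    bf <- list(a = base, b = fourier_shift(base, bf_shift_px[1], bf_shift_px[2]),
               shift_px = bf_shift_px)

    list(stack = stack, brightfield = bf, truth = truth)
  })
}

#' One-call simulation of a full dataset
#'
#' Convenience wrapper: cells, trajectories and rendered images from one
#' config and seed.
#'
#' @inheritParams render_stack
#' @param config a [slim_config()].
#' @return as [render_stack()], plus `cells`.
#' @export
simulate_dataset <- function(config, seed = NULL, bf_shift_px = c(0, 0)) {
  seed <- seed %||% config$seed
  cells <- sim_cells(config, seed = seed_from(seed, 1L))
  truth <- sim_tracks(config, cells, seed = seed_from(seed, 2L))
  out <- render_stack(truth, config, seed = seed_from(seed, 3L),
                      bf_shift_px = bf_shift_px)
  out$cells <- cells
  out
}

# Brownian-bridge sub-frame positions between consecutive frame positions.
sub_positions <- function(p0, p1, substeps, D, dt_s, px_per_um) {
  if (substeps <= 1 || D <= 0) return(matrix(p0, 1))
  n <- substeps
  out <- matrix(NA_real_, n, 2)
  out[1, ] <- p0
  sd_sub <- sqrt(2 * D * dt_s / n) * px_per_um
  cur <- p0
  for (j in 2:n) {
    remain <- n - j + 1
    mu <- cur + (p1 - cur) / remain
    s <- sd_sub * sqrt((remain - 1) / remain)
    cur <- mu + rnorm(2, 0, s)
    out[j, ] <- cur
  }
  out
}

# Add `amount` counts as a discrete Gaussian PSF centered at (x, y) pixels.
# The kernel is normalized over its full window so an interior spot
# integrates to exactly `amount`.
add_psf <- function(img, x, y, sigma_px, amount) {
  r <- ceiling(4 * sigma_px) + 1L
  cx <- round(x); cy <- round(y)
  xs <- (cx - r):(cx + r); ys <- (cy - r):(cy + r)
  kx <- dnorm(xs, mean = x, sd = sigma_px)
  ky <- dnorm(ys, mean = y, sd = sigma_px)
  k <- outer(ky, kx)
  k <- k / sum(k) * amount
  rows <- ys + 1L; cols <- xs + 1L
  okr <- rows >= 1 & rows <= nrow(img)
  okc <- cols >= 1 & cols <= ncol(img)
  if (!any(okr) || !any(okc)) return(img)
  img[rows[okr], cols[okc]] <- img[rows[okr], cols[okc]] + k[okr, okc]
  img
}

# EMCCD model: Poisson photons at the pre-gain mean, gamma-amplified
# (scale = gain) so the mean equals the noiseless signal, plus Gaussian
# read noise and offset.
apply_camera <- function(img, config) {
  if (!config$camera_noise) return(img + config$offset)
  lam <- img / config$em_gain
  n <- matrix(rpois(length(lam), lam), nrow(img))
  amp <- matrix(0, nrow(img), ncol(img))
  nz <- n > 0
  if (any(nz)) amp[nz] <- rgamma(sum(nz), shape = n[nz], scale = config$em_gain)
  amp + matrix(rnorm(length(img), 0, config$read_noise_sd), nrow(img)) +
    config$offset
}
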