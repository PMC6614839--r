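# shared fixtures, all generated in code

# a frame with Gaussian spots of given integrated amplitudes on a constant
# background, optionally Poisson-noised
spot_frame <- function(centers, amplitudes, size = c(64, 64), sigma = 1.5,
                       background = 100, poisson = FALSE) {
  img <- matrix(background, size[2], size[1])
  for (i in seq_len(nrow(centers))) {
    img <- slimfieldr:::add_psf(img, centers[i, 1], centers[i, 2], sigma,
                                amplitudes[i])
  }
  if (poisson) img <- matrix(rpois(length(img), img), nrow(img))
  img
}

# amplitude giving a target SNR under the package's definition
# (mean BG-corrected ROI pixel / SD of background pixels), for Poisson
# background `b`: roughly snr * n_roi * sqrt(b)
amp_for_snr <- function(snr, background = 100, roi_radius = 5) {
  n_roi <- sum(outer((-8):8, (-8):8,
                     function(x, y) x^2 + y^2 <= roi_radius^2))
  snr * n_roi * sqrt(background)
}

# small two-colour simulated dataset reused across tests
small_dataset <- function(seed = 7, n_frames = 15, n_cells = 3) {
  cfg <- slim_config(
    field_px = c(128, 128), n_frames = n_frames, n_cells = n_cells,
    species = list(
      sim_species("rep", "green", n_per_cell = 2, S = 6,
                  modes = data.frame(mode = "immobile", D = 0, weight = 1)),
      sim_species("dnaq", "red", n_per_cell = 1, S = 3,
                  modes = data.frame(mode = "immobile", D = 0, weight = 1))),
    substeps = 1, seed = seed)
  simulate_dataset(cfg)
}

# synthetic photobleach track table: S molecules of brightness i1 with
# per-frame bleach probability p and Gaussian measurement noise
bleach_tracks <- function(n_tracks, S, i1 = 2000, p = 0.1, n_frames = 30,
                          noise_sd = 150, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_tracks), function(id) {
      surv <- simulate_bleaching(S, p, n_frames)
      tibble::tibble(track_id = id, channel = "green",
                     frame = 0:(n_frames - 1),
                     x = 10, y = 10,
                     intensity = surv * i1 + rnorm(n_frames, 0, noise_sd))
    })
  })
}
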