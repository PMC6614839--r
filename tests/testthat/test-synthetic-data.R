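# forward simulator: geometry, Brownian calibration, bleaching, rendering

test_that("cell placement produces rods of the correct area, reproducibly", {
  cfg <- slim_config(n_cells = 0)
  expect_length(sim_cells(cfg), 0)

  cfg1 <- slim_config(field_px = c(64, 64), n_cells = 1,
                      cell_length_um = 3, cell_width_um = 1, seed = 3)
  cells <- sim_cells(cfg1)
  L <- 3000 / 80; W <- 1000 / 80
  analytic <- pi * (W / 2)^2 + (L - W) * W
  expect_lt(abs(sum(cells[[1]]) - analytic) / analytic, 0.05)

  expect_identical(sim_cells(cfg1), sim_cells(cfg1))

  # impossible packing fails loudly
  cfg_bad <- slim_config(field_px = c(48, 48), n_cells = 6)
  expect_error(sim_cells(cfg_bad), "non-overlapping")
})

test_that("trajectories obey Brownian statistics and stay confined", {
  cfg <- slim_config(
    field_px = c(64, 64), n_frames = 10001, n_cells = 0, channels = "green",
    species = list(sim_species("s", "green", 1, S = 1,
                               modes = data.frame(mode = "fast", D = 1,
                                                  weight = 1))),
    substeps = 1, seed = 5)
  tru <- sim_tracks(cfg, sim_cells(cfg), confine = FALSE)
  um <- 80 / 1000
  dx <- diff(tru$positions$x) * um
  dy <- diff(tru$positions$y) * um
  # per-axis mean squared step = 2 D dt = 0.01 um^2
  expect_lt(abs(mean(dx^2) - 0.01) / 0.01, 0.05)
  expect_lt(abs(mean(dy^2) - 0.01) / 0.01, 0.05)
  # empirical MSD at lag k ~ 4 D dt k
  msd <- track_msd(tru$positions$x, tru$positions$y, 80, 3)
  expect_true(all(abs(msd - 4 * 1 * 0.005 * (1:3)) / (0.02 * (1:3)) < 0.05))

  # D = 0 with no tether jitter: nothing moves
  cfg0 <- slim_config(
    field_px = c(64, 64), n_frames = 20, n_cells = 1, channels = "green",
    species = list(sim_species("s", "green", 2, S = 1,
                               modes = data.frame(mode = "immobile", D = 0,
                                                  weight = 1))),
    tether_sd_nm = 0, substeps = 1, seed = 2)
  tru0 <- sim_tracks(cfg0, sim_cells(cfg0))
  disp <- tru0$positions |>
    dplyr::group_by(id) |>
    dplyr::summarise(moved = max(abs(diff(x))) + max(abs(diff(y))))
  expect_true(all(disp$moved == 0))

  # confined positions lie inside the owning cell
  cfgc <- slim_config(
    field_px = c(96, 96), n_frames = 50, n_cells = 1, channels = "green",
    species = list(sim_species("s", "green", 5, S = 1,
                               modes = data.frame(mode = "fast", D = 1.3,
                                                  weight = 1))),
    substeps = 1, seed = 8)
  cells <- sim_cells(cfgc)
  truc <- sim_tracks(cfgc, cells)
  geom <- attr(cells, "centers")[1, ]
  inside <- slimfieldr:::in_rod(truc$positions$x, truc$positions$y, geom)
  expect_true(all(inside))

  expect_error(sim_species("s", modes = data.frame(mode = "fast", D = -1,
                                                   weight = 1)),
               "must be >= 0")
})

test_that("bound-state dwells are exponential with the configured mean", {
  cfg <- slim_config(
    field_px = c(600, 600), n_frames = 2, n_cells = 1,
    cell_length_um = 40, cell_width_um = 30, channels = "green",
    species = list(sim_species("s", "green", 10000, S = 1,
                               modes = data.frame(mode = "bound", D = 0,
                                                  weight = 1),
                               dwell_ms = 6.5)),
    substeps = 1, seed = 4)
  tru <- sim_tracks(cfg, sim_cells(cfg))
  k <- tru$foci$dwell_frames
  # discretized exponential: E[k] = 1 / (1 - exp(-dt/tau))
  q <- exp(-5 / 6.5)
  ek <- 1 / (1 - q)
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - ek), 3 * se)
})

test_that("photobleaching is single-step, irreversible and binomial in mean", {
  expect_identical(simulate_bleaching(0, 0.1, 5), rep(0L, 5))
  expect_identical(simulate_bleaching(6, 1, 5), c(6L, 0L, 0L, 0L, 0L))
  expect_error(simulate_bleaching(6, 1.5, 5), "\\[0, 1\\]")

  traces <- withr::with_seed(10, {
    replicate(10000, simulate_bleaching(6, 0.1, 10))
  })
  expect_true(all(apply(traces, 2, function(v) all(diff(v) <= 0))))
  expect_true(all(traces[1, ] == 6))
  means <- rowMeans(traces)
  expected <- 6 * 0.9^(0:9)
  # 3 SE of a binomial mean over 1e4 reps
  se <- sqrt(6 * 0.9^(0:9) * (1 - 0.9^(0:9)) / 10000)
  expect_true(all(abs(means - expected) <= 3 * se + 1e-9))
})

test_that("rendering conserves photons and respects the camera model", {
  cfg <- slim_config(
    field_px = c(48, 48), n_frames = 3, n_cells = 1, channels = "green",
    species = list(), camera_noise = FALSE, read_noise_sd = 0, em_gain = 1,
    offset = 100, pool_copies = 0, substeps = 1, seed = 1)
  out <- simulate_dataset(cfg)
  for (fr in out$stack$frames) expect_true(all(fr == 100))

  cfgm <- slim_config(
    field_px = c(48, 48), n_frames = 5, n_cells = 1, channels = "green",
    species = list(sim_species("s", "green", 1, S = 4,
                               modes = data.frame(mode = "immobile", D = 0,
                                                  weight = 1))),
    camera_noise = FALSE, offset = 100, bleach_prob = 0.3,
    tether_sd_nm = 0, substeps = 1, seed = 6)
  outm <- simulate_dataset(cfgm)
  surv <- outm$truth$positions$survivors
  for (f in seq_along(outm$stack$frames)) {
    integrated <- sum(outm$stack$frames[[f]] - 100)
    expect_equal(integrated, 2000 * surv[f], tolerance = 1e-9)
  }
})

test_that("identical config and seed give byte-identical output", {
  a <- small_dataset(seed = 42)
  b <- small_dataset(seed = 42)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$positions, b$truth$positions)
  expect_identical(a$brightfield, b$brightfield)
})
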