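# Chung-Kennedy filtering, characteristic intensity, stoichiometry peaks,
# copy number and pool analysis

test_that("Chung-Kennedy filtering preserves edges and suppresses noise", {
  expect_equal(chung_kennedy(rep(42, 10)), rep(42, 10))

  step <- c(rep(100, 10), rep(50, 10))
  filt <- chung_kennedy(step)
  expect_equal(filt[1:10], rep(100, 10))
  expect_equal(filt[11:20], rep(50, 10))

  expect_error(chung_kennedy(1:5, window = 3), "longer than twice")

  res <- withr::with_seed(5, {
    purrr::map_dfr(1:200, function(i) {
      tr <- c(rep(100, 15), rep(50, 15)) + rnorm(30, 0, 10)
      f <- chung_kennedy(tr)
      # edge location: largest absolute jump in the filtered trace
      edge <- which.max(abs(diff(f)))
      tibble::tibble(
        sd_ratio = sd(tr[3:13] - 100) / sd(f[3:13] - mean(f[3:13])),
        edge_err = abs(edge - 15))
    })
  })
  expect_gte(mean(res$sd_ratio), 1.5)
  expect_lte(stats::quantile(res$edge_err, 0.9), 1)
})

test_that("characteristic intensity is recovered from bleach tails", {
  # constant S = 1 traces: the estimate is the plateau itself
  tr1 <- purrr::map_dfr(1:25, function(id) {
    tibble::tibble(track_id = id, channel = "green", frame = 0:14,
                   x = 0, y = 0, intensity = 2000)
  })
  est1 <- characteristic_intensity(tr1)
  expect_equal(est1$estimate, 2000, tolerance = 0.02)

  # stochastic bleaching from mixed stoichiometries
  trs <- bleach_tracks(120, S = 6, i1 = 2000, p = 0.1, seed = 11)
  est <- characteristic_intensity(trs)
  expect_lt(abs(est$estimate - 2000) / 2000, 0.10)
  expect_true(est$ci[1] <= est$estimate && est$estimate <= est$ci[2])

  # two fluorophore species mixed -> multimodal tail warning
  mixed <- dplyr::bind_rows(
    bleach_tracks(60, S = 4, i1 = 1500, p = 0.05, noise_sd = 60, seed = 3),
    bleach_tracks(60, S = 4, i1 = 6000, p = 0.05, noise_sd = 60, seed = 4) |>
      dplyr::mutate(track_id = track_id + 1000))
  expect_warning(characteristic_intensity(mixed), "multimodal")

  expect_error(characteristic_intensity(trs[trs$track_id <= 5, ]),
               "at least 20 tracks")
})

test_that("initial-intensity intercept converts to molecules", {
  r <- track_stoichiometry(c(12000, 10000, 8000), 2000)
  expect_equal(r$intercept, 12000)
  expect_equal(r$S, 6)

  r2 <- track_stoichiometry(c(2000, 2000, 2000), 2000)
  expect_equal(r2$S, 1)

  r3 <- track_stoichiometry(c(-100, -200, -300), 2000)
  expect_equal(r3$S, 0)
  expect_true(r3$flagged)

  expect_error(track_stoichiometry(c(1, 2), 2000), "at least three")
  expect_error(track_stoichiometry(1:3, 0), "i_single")
})

test_that("stoichiometry is invariant to a global intensity rescaling", {
  trs <- bleach_tracks(60, S = 6, seed = 21)
  est <- suppressWarnings(characteristic_intensity(trs))
  s1 <- stoichiometries(trs, est)
  trs2 <- dplyr::mutate(trs, intensity = intensity * 3.7)
  est2 <- suppressWarnings(characteristic_intensity(trs2))
  s2 <- stoichiometries(trs2, est2)
  expect_equal(est2$estimate / est$estimate, 3.7, tolerance = 0.05)
  expect_equal(s2$S, s1$S, tolerance = 0.05)
})

test_that("Gaussian peak fitting recovers positions and merges duplicates", {
  vals <- withr::with_seed(7, c(rnorm(100, 3, 0.8), rnorm(100, 6, 0.8)))
  m <- fit_stoich_peaks(vals, n_peaks = 2)
  expect_equal(nrow(m$peaks), 2)
  expect_lt(abs(m$peaks$position[1] - 3), 0.5)
  expect_lt(abs(m$peaks$position[2] - 6), 0.5)

  tight <- withr::with_seed(8, rnorm(80, 5, 0.4))
  m1 <- fit_stoich_peaks(tight, n_peaks = "auto")
  expect_equal(nrow(m1$peaks), 1)

  # requesting 3 peaks on well-separated 2-mode data: the surplus component
  # converges onto an existing peak and is merged away
  vals2 <- withr::with_seed(9, c(rnorm(150, 3, 0.5), rnorm(150, 9, 0.5)))
  m3 <- fit_stoich_peaks(vals2, n_peaks = 3)
  expect_equal(nrow(m3$peaks), 2)
  expect_true(all(diff(m3$peaks$position) >= m3$bw))
})

test_that("peak spacing arithmetic matches the worked examples", {
  s <- peak_spacing(c(8, 14, 20, 25))
  expect_equal(s$mean, mean(c(6, 6, 5)))
  expect_equal(s$nearest_integer, 6L)

  expect_equal(peak_spacing(c(6, 12, 18, 24))$mean, 6)

  s2 <- peak_spacing(c(2.5, 2.5 + 4.2))
  expect_equal(s2$mean, 4.2)
  expect_equal(s2$sd, 0)

  expect_error(peak_spacing(5), "at least two")
})

test_that("whole-cell pixel integration recovers the pool copy number", {
  cfg <- slim_config(
    field_px = c(96, 96), n_frames = 12, n_cells = 1, channels = "green",
    species = list(), pool_copies = 300, pool_D = 1,
    em_gain = 10, read_noise_sd = 2, offset = 100, substeps = 1, seed = 13)
  d <- simulate_dataset(cfg)
  mask <- d$cells[[1]]
  cc <- cell_copy_number(get_channel(d$stack, "green"), mask, 2000)
  expect_lt(abs(cc$copies - 300) / 300, 0.15)

  # doubling the characteristic intensity halves the estimate exactly
  cc2 <- cell_copy_number(get_channel(d$stack, "green"), mask, 4000)
  expect_equal(cc2$copies, cc$copies / 2)

  # an empty cell reads ~0 against the 300-copy scale
  cfg0 <- slim_config(
    field_px = c(96, 96), n_frames = 12, n_cells = 1, channels = "green",
    species = list(), pool_copies = 0, em_gain = 10, read_noise_sd = 2,
    offset = 100, substeps = 1, seed = 14)
  d0 <- simulate_dataset(cfg0)
  cc0 <- cell_copy_number(get_channel(d0$stack, "green"), d0$cells[[1]], 2000)
  expect_lt(abs(cc0$copies), 10)
})

test_that("pool-focus expectation follows the disc/area geometry", {
  cfg <- slim_config(field_px = c(64, 64), n_cells = 1, seed = 3)
  cells <- sim_cells(cfg)
  mask <- cells[[1]]
  expect_equal(pool_stoichiometry(0, mask)$expected, 0)

  ps <- pool_stoichiometry(300, mask, pixel_nm = 80, resolution_nm = 230)
  area_um2 <- sum(mask) * 0.08^2
  analytic <- 300 * pi * 0.23^2 / area_um2
  expect_equal(ps$expected, analytic)

  # Monte-Carlo cross-check of the uniform-placement expectation
  geom <- attr(cells, "centers")[1, ]
  mc <- withr::with_seed(4, {
    pts <- slimfieldr:::sample_in_rod(4000, geom)
    ref <- slimfieldr:::sample_in_rod(4000, geom)
    mean(colSums(
      (outer(pts[, 1], ref[, 1], "-")^2 +
         outer(pts[, 2], ref[, 2], "-")^2) < (230 / 80)^2) / 4000 * 300)
  })
  expect_lt(abs(mc - analytic) / analytic, 0.1)

  # sparse monomeric pool: measured brightness ~ 1 molecule -> "monomer"
  expect_equal(pool_stoichiometry(10, mask, measured_S = 1.2)$verdict,
               "monomer")
  expect_equal(pool_stoichiometry(10, mask, measured_S = 6)$verdict,
               "oligomer")
})

test_that("a diffuse pool inflates recovered focus stoichiometry", {
  run <- function(pool) {
    cfg <- slim_config(
      field_px = c(160, 160), n_frames = 20, n_cells = 3, channels = "green",
      species = list(sim_species("rep", "green", 2, S = 6,
                                 modes = data.frame(mode = "immobile", D = 0,
                                                    weight = 1))),
      pool_copies = pool, pool_D = 3, substeps = 1, seed = 37)
    d <- simulate_dataset(cfg)
    tracks <- detect_foci(get_channel(d$stack, "green")) |>
      link_foci() |> accept_tracks(4)
    st <- stoichiometries(tracks, 2000)
    kde_peak(st$S, bw = 0.7)
  }
  s_clean <- run(0)
  s_pool <- run(150)
  expect_gt(s_pool, s_clean)
  expect_lt(s_pool - s_clean, 6)
})
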