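# MSD, microscopic D, gamma-mixture decomposition, immobile fractions,
# dwell kinetics, Stokes-Einstein

test_that("MSD matches closed forms for stationary and ballistic tracks", {
  expect_equal(track_msd(rep(3, 10), rep(4, 10)), rep(0, 3))

  # straight line, step s px: MSD(k) = (k s px_um)^2
  s <- 2
  x <- seq(0, 18, s); y <- rep(0, 10)
  msd <- track_msd(x, y, pixel_nm = 80)
  expect_equal(msd, ((1:3) * s * 0.08)^2)

  expect_error(track_msd(1:3, 1:3, max_lag = 3), "too short")
})

test_that("the intercept-constrained fit recovers D and handles statics", {
  msd_exact <- 4 * 1.0 * (1:3) * 0.005 + 4 * 0.04^2
  expect_equal(microscopic_d(msd_exact, 5, 40), 1.0)

  flat <- rep(4 * 0.04^2, 3)
  expect_equal(microscopic_d(flat, 5, 40), 0)

  # immobile tracks under 40 nm noise stay in the immobile regime
  D_imm <- withr::with_seed(9, {
    vapply(1:300, function(i) {
      x <- rnorm(8, 0, 0.5); y <- rnorm(8, 0, 0.5)
      microscopic_d(track_msd(x, y), 5, 40)
    }, numeric(1))
  })
  expect_lt(mean(D_imm), 0.09)
  expect_gt(mean(D_imm), -0.09)
})

test_that("microscopic D is unbiased on free Brownian motion", {
  sim_D <- function(D, n, L = 8, sigma_nm = 40, seed = 1) {
    withr::with_seed(seed, {
      vapply(seq_len(n), function(i) {
        steps <- matrix(rnorm(2 * (L - 1), 0, sqrt(2 * D * 0.005)), ncol = 2)
        pos <- apply(rbind(c(0, 0), steps), 2, cumsum) * 1000 / 80
        pos <- pos + matrix(rnorm(2 * L, 0, sigma_nm / 80), ncol = 2)
        microscopic_d(track_msd(pos[, 1], pos[, 2]), 5, sigma_nm)
      }, numeric(1))
    })
  }
  for (D in c(0.1, 0.4, 1.3)) {
    est <- sim_D(D, 500, seed = round(100 * D))
    se <- sd(est) / sqrt(500)
    expect_lt(abs(mean(est) - D), max(0.05 * D, 3 * se))
  }
  # more localization noise widens but does not bias the estimate
  lo <- sim_D(0.4, 800, sigma_nm = 10, seed = 41)
  hi <- sim_D(0.4, 800, sigma_nm = 60, seed = 42)
  expect_gt(sd(hi), sd(lo))
  expect_lt(abs(mean(hi) - mean(lo)),
            3 * sqrt(sd(hi)^2 / 800 + sd(lo)^2 / 800))
})

test_that("the gamma mixture density is normalized and fits single modes", {
  x <- seq(0, 60, 0.01)
  dens <- slimfieldr:::gamma_mix_density(x, c(0.3, 1.5), c(0.4, 0.6), 3)
  expect_equal(sum(dens) * 0.01, 1, tolerance = 1e-3)

  D1 <- withr::with_seed(12, rgamma(500, 3, rate = 3 / 1.0))
  m1 <- fit_gamma_mixture(D1, K = 1)
  expect_lt(abs(m1$components$D_mean - 1.0) / 1.0, 0.10)

  # degenerate sample collapses to one component under auto selection
  md <- fit_gamma_mixture(rep(0.5, 50), K = "auto")
  expect_equal(nrow(md$components), 1)
  expect_equal(md$components$D_mean, 0.5)
})

test_that("mixture assignment splits immobile fractions by label", {
  D <- withr::with_seed(13, {
    c(rgamma(100, 3, rate = 3 / 0.05), rgamma(900, 3, rate = 3 / 1.3))
  })
  mix <- fit_gamma_mixture(D, K = 2, method = "mle")
  truth_imm <- rep(c(TRUE, FALSE), c(100, 900))

  frac_all <- immobile_fraction(mix, rep(TRUE, 1000))
  f <- frac_all$fraction[frac_all$colocalized]
  expect_lt(abs(f - 0.10), 2 * sqrt(0.1 * 0.9 / 1000) + 0.02)
  expect_true(is.na(frac_all$fraction[!frac_all$colocalized]))

  # all-immobile input assigns everything to the slowest component
  Dimm <- withr::with_seed(14, rgamma(200, 3, rate = 3 / 0.05))
  mimm <- fit_gamma_mixture(Dimm, K = 1)
  fi <- immobile_fraction(mimm, rep(TRUE, 200))
  expect_equal(fi$fraction[fi$colocalized], 1)
})

test_that("dwell counting follows the frame-zero fork definition", {
  forks <- tibble::tibble(x = 10, y = 10)
  # colocalized for 4 frames then departs
  tr <- tibble::tibble(track_id = 1L, frame = 0:7,
                       x = c(10, 10.1, 9.9, 10, 30, 31, 32, 33),
                       y = 10)
  dw <- dwell_times(tr, forks)
  expect_equal(dw$dwell_frames, 4L)
  expect_false(dw$censored)

  # never within the overlap radius: dwell 0
  tr0 <- dplyr::mutate(tr, x = x + 100)
  expect_equal(dwell_times(tr0, forks)$dwell_frames, 0L)

  # colocalized to the very end: right-censored
  trc <- tibble::tibble(track_id = 1L, frame = 0:3, x = 10, y = 10)
  expect_true(dwell_times(trc, forks)$censored)
})

test_that("dwell histograms decay and the exponential fit is consistent", {
  sim_dwells <- function(tau, n, seed) {
    withr::with_seed(seed, pmax(1, ceiling(rexp(n, 1 / tau) / 5)))
  }
  d65 <- sim_dwells(6.5, 500, 15)
  tab <- tabulate(d65)
  expect_true(all(diff(tab[tab > 0][1:3]) <= 0))

  fit <- fit_dwell_exponential(d65, 5)
  expect_lt(abs(fit$tau_ms - 6.5) / 6.5, 0.2)

  # consistency: error shrinks with sample size
  errs <- vapply(c(50, 500, 5000), function(n) {
    abs(fit_dwell_exponential(sim_dwells(6.5, n, n), 5, n_boot = 20)$tau_ms - 6.5)
  }, numeric(1))
  expect_lt(errs[3], 0.5)
  expect_lt(errs[3], errs[1] + 0.5)

  # all one-frame dwells: resolution-limit flag
  f1 <- fit_dwell_exponential(rep(1, 30), 5)
  expect_true(f1$at_resolution_limit)

  expect_error(fit_dwell_exponential(rep(2, 5), 5), "at least 20")
})

test_that("Stokes-Einstein conversions are exact and invertible", {
  D <- stokes_einstein(r_nm = 5, eta_cp = 10, temperature_K = 303)
  expect_equal(round(D), 4)  # ~4 um^2/s as printed for a ~5 nm radius
  expect_equal(stokes_einstein(r_nm = 5, eta_cp = 20, temperature_K = 303),
               D / 2)
  r_back <- stokes_einstein(D_um2_s = D, eta_cp = 10, temperature_K = 303)
  expect_equal(r_back, 5, tolerance = 1e-12)
  expect_error(stokes_einstein(), "exactly one")
  expect_error(stokes_einstein(D_um2_s = 1, eta_cp = -1), "must be > 0")
})
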