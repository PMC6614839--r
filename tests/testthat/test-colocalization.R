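# channel registration, overlap integral, colocalized fractions, baseline,
# stoichiometry relationships, fraction comparison

test_that("brightfield registration recovers shifts to sub-pixel accuracy", {
  base <- withr::with_seed(1, {
    slimfieldr:::gauss_blur(matrix(rnorm(96 * 96, 500, 120), 96), 2)
  })
  s0 <- register_channels(base, base)
  expect_equal(as.numeric(s0), c(0, 0), tolerance = 1e-6)

  shifted <- slimfieldr:::fourier_shift(base, 3.4, -2.1)
  s <- register_channels(base, shifted)
  expect_lt(abs(s[["dx"]] - 3.4), 0.5)
  expect_lt(abs(s[["dy"]] - (-2.1)), 0.5)

  # the simulator's encoded brightfield shift round-trips the same way
  cfg <- slim_config(field_px = c(96, 96), n_frames = 2, n_cells = 2,
                     species = list(), seed = 11)
  d <- simulate_dataset(cfg, bf_shift_px = c(3.4, -2.1))
  sb <- register_channels(d$brightfield$a, d$brightfield$b)
  expect_lt(abs(sb[["dx"]] - 3.4), 0.5)
  expect_lt(abs(sb[["dy"]] - (-2.1)), 0.5)

  noise_a <- withr::with_seed(3, matrix(rnorm(64 * 64), 64))
  noise_b <- withr::with_seed(4, matrix(rnorm(64 * 64), 64))
  expect_error(register_channels(noise_a, noise_b), "registration failed")
})

test_that("the overlap integral matches its closed form and symmetries", {
  expect_equal(overlap_integral(c(0, 0), c(0, 0), 1.5, 1.5), 1)
  expect_lt(overlap_integral(c(0, 0), c(50, 0), 1.5, 1.5), 1e-10)
  expect_equal(overlap_integral(c(0, 0), c(1.5, 0), 1.5, 1.5), exp(-0.25))

  # numerical cross-check: normalized product integral of two 2D Gaussians
  num_overlap <- function(d, sa, sb) {
    g <- expand.grid(x = seq(-12, 12, 0.05), y = seq(-12, 12, 0.05))
    fa <- dnorm(g$x, 0, sa) * dnorm(g$y, 0, sa)
    fb <- dnorm(g$x, d, sb) * dnorm(g$y, 0, sb)
    sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2))
  }
  expect_equal(overlap_integral(c(0, 0), c(1.5, 0), 1.5, 1.5),
               num_overlap(1.5, 1.5, 1.5), tolerance = 1e-3)
  expect_equal(overlap_integral(c(0, 0), c(2, 0), 1.2, 1.8),
               num_overlap(2, 1.2, 1.8), tolerance = 1e-3)

  # symmetric in arguments, invariant to joint translation and rotation
  expect_equal(overlap_integral(c(1, 2), c(3, 4), 1.2, 1.8),
               overlap_integral(c(3, 4), c(1, 2), 1.8, 1.2))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(overlap_integral(c(1, 2), c(3, 4), 1.5, 1.5),
               overlap_integral(as.numeric(R %*% c(1, 2)) + 5,
                                as.numeric(R %*% c(3, 4)) + 5, 1.5, 1.5))
})

test_that("colocalized fractions hit the designed truth and the extremes", {
  fa <- tibble::tibble(frame = 0L, x = seq(10, 90, 10), y = 50)
  res_same <- colocalized_fraction(fa, fa)
  expect_equal(res_same$fraction_a, 1)
  expect_equal(res_same$fraction_b, 1)

  fb_far <- dplyr::mutate(fa, y = 200)
  expect_equal(colocalized_fraction(fa, fb_far)$fraction_a, 0)

  sim <- function(seed, frac, n = 200) {
    cfg <- slim_config(field_px = c(400, 400), n_cells = 10, seed = seed)
    cells <- sim_cells(cfg)
    geoms <- attr(cells, "centers")
    withr::with_seed(seed + 1, {
      cell_of <- sample(nrow(geoms), n, TRUE)
      xy <- do.call(rbind, lapply(seq_len(n), function(i) {
        slimfieldr:::sample_in_rod(1, geoms[cell_of[i], ])
      }))
      fa <- tibble::tibble(frame = 0L, x = xy[, 1], y = xy[, 2],
                           cell = cell_of)
      is_c <- runif(n) < frac
      fb <- fa[is_c, ]
      fb$x <- fb$x + rnorm(nrow(fb), 0, 0.25)
      fb$y <- fb$y + rnorm(nrow(fb), 0, 0.25)
      exy <- do.call(rbind, lapply(seq_len(n - nrow(fb)), function(i) {
        slimfieldr:::sample_in_rod(1, geoms[sample(nrow(geoms), 1), ])
      }))
      fb <- dplyr::bind_rows(fb, tibble::tibble(frame = 0L, x = exy[, 1],
                                                y = exy[, 2]))
      list(fa = fa, fb = fb, cells = cells, true_frac = mean(is_c))
    })
  }
  s <- sim(5, 0.7)
  res <- colocalized_fraction(s$fa, s$fb)
  expect_lt(abs(res$fraction_a - s$true_frac),
            2 * sqrt(0.7 * 0.3 / 200) + 0.02)
})

test_that("the random-overlap baseline matches geometry and is calibrated", {
  cfg <- slim_config(field_px = c(64, 64), n_cells = 1, seed = 3)
  cells <- sim_cells(cfg)
  g <- attr(cells, "centers")
  fa <- tibble::tibble(frame = 0L, x = g$cx, y = g$cy, cell = 1L)
  fb <- tibble::tibble(frame = 0L, x = g$cx, y = g$cy)
  bl <- random_overlap_baseline(fa, fb, cells, n_rand = 3000, seed = 9)
  # single-pair analytic chance level: pi r^2 / A at the distance where the
  # overlap threshold is crossed
  s2 <- 1.5^2 + 1.75^2
  r_thr <- sqrt(-2 * s2 * log(0.75 * s2 / (2 * 1.5 * 1.75)))
  area <- pi * (g$width_px / 2)^2 + (g$length_px - g$width_px) * g$width_px
  analytic <- pi * r_thr^2 / area
  mc_se <- sqrt(analytic * (1 - analytic) / 3000)
  expect_lt(abs(bl$baseline - analytic), 3 * mc_se)

  # determinism under a fixed seed
  bl2 <- random_overlap_baseline(fa, fb, cells, n_rand = 100, seed = 4)
  bl3 <- random_overlap_baseline(fa, fb, cells, n_rand = 100, seed = 4)
  expect_identical(bl2$draws, bl3$draws)

  # null calibration: an observation that is itself random placement gives
  # an unremarkable p-value
  obs_random <- withr::with_seed(21, {
    xy <- slimfieldr:::sample_in_rod(1, g)
    colocalized_fraction(tibble::tibble(frame = 0L, x = xy[1], y = xy[2]),
                         fb)
  })
  bl4 <- random_overlap_baseline(fa, fb, cells, n_rand = 400, seed = 5,
                                 observed = obs_random)
  expect_gt(bl4$p_value, 0.01)
})

test_that("origin-constrained stoichiometry gradients behave", {
  x <- c(1, 2, 3, 4); y <- 2 * x
  r <- stoichiometry_ratio(x, y)
  expect_equal(r$slope, 2)
  expect_equal(r$ci[1], r$ci[2])
  expect_equal(r$r_pearson, 1)

  sim <- withr::with_seed(6, {
    xx <- sample(c(3, 6), 70, TRUE)
    yy <- 2 * xx + rnorm(70, 0, 3)
    stoichiometry_ratio(xx, yy)
  })
  expect_true(sim$ci[1] <= 2 && 2 <= sim$ci[2])

  unc <- withr::with_seed(7, stoichiometry_ratio(rnorm(200, 10), rnorm(200, 10)))
  expect_lt(abs(unc$r_pearson), 0.15)

  expect_error(stoichiometry_ratio(1:2, 1:2), "at least three")
})

test_that("fraction comparison uses the z-test with an exact fallback", {
  mk <- function(k, n) {
    structure(list(n_pairs = k, n_a = n, n_b = n), class = "slim_coloc")
  }
  same <- compare_fractions(mk(35, 70), mk(35, 70))
  expect_equal(same$p_value, 1)
  expect_equal(same$z, 0)

  r <- compare_fractions(mk(49, 70), mk(28, 70))
  expect_equal(r$test, "two-proportion z")
  expect_lt(r$p_value, 0.05)
  # hand-checked two-proportion formula
  p_pool <- 77 / 140
  z_hand <- (0.7 - 0.4) / sqrt(p_pool * (1 - p_pool) * (2 / 70))
  expect_equal(r$z, z_hand)

  f <- compare_fractions(mk(1, 2), mk(1, 2))
  expect_equal(f$test, "fisher")
  expect_equal(f$p_value, 1)
})
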