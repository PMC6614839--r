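#' Mean squared displacement of one track
#'
#' MSD(k) is the mean squared Euclidean displacement over all overlapping
#' frame pairs separated by k frames, in um^2.
#'
#' @param x,y positions in pixels, frame order.
#' @param pixel_nm pixel size.
#' @param max_lag largest lag (track must exceed it in length).
#' @return numeric vector MSD at lags 1..max_lag (um^2).
#' @export
track_msd <- function(x, y, pixel_nm = 80, max_lag = 3) {
  n <- length(x)
  abort_if(n < max_lag + 1, "track too short for the requested lags")
  um <- pixel_nm / 1000
  vapply(seq_len(max_lag), function(k) {
    dx <- (x[(k + 1):n] - x[1:(n - k)]) * um
    dy <- (y[(k + 1):n] - y[1:(n - k)]) * um
    mean(dx^2 + dy^2)
  }, numeric(1))
}

#' Microscopic diffusion coefficient from short-lag MSD
#'
#' Least-squares slope of MSD against lag time with the intercept fixed at
#' the localization-precision MSD, 4*sigma^2 (2D). D = slope / 4. Values
#' can be <= 0 for immobile foci whose noise happens to fall below the
#' fixed intercept; callers floor them for mixture fitting.
#'
#' @param msd MSD values at lags 1..length(msd) (um^2).
#' @param frame_ms lag-1 interval in ms.
#' @param loc_precision_nm localization precision sigma (nm).
#' @return D in um^2/s (unfloored).
#' @export
microscopic_d <- function(msd, frame_ms = 5, loc_precision_nm = 40) {
  t <- seq_along(msd) * frame_ms / 1000
  icpt <- 4 * (loc_precision_nm / 1000)^2
  slope <- sum(t * (msd - icpt)) / sum(t^2)
  slope / 4
}

#' Per-track diffusion coefficients
#'
#' Computes the 3-point MSD and the intercept-constrained D for every track
#' long enough; non-positive estimates are floored at `floor_D` and
#' flagged.
#'
#' @param tracks linked track tibble (`track_id`, `frame`, `x`, `y`).
#' @param pixel_nm,frame_ms acquisition scale.
#' @param loc_precision_nm localization precision (nm).
#' @param max_lag MSD points per track.
#' @param floor_D positive floor applied to D <= 0 (um^2/s).
#' @return tibble `track_id`, `n_frames`, `D_raw`, `D`, `floored`.
#' @export
track_diffusion <- function(tracks, pixel_nm = 80, frame_ms = 5,
                            loc_precision_nm = 40, max_lag = 3,
                            floor_D = 1e-3) {
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= max_lag + 1) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      D_raw = microscopic_d(track_msd(.data$x, .data$y, pixel_nm, max_lag),
                            frame_ms, loc_precision_nm),
      .groups = "drop") |>
    dplyr::mutate(D = pmax(.data$D_raw, floor_D),
                  floored = .data$D_raw <= floor_D)
}

# mixture density: sum of gamma components with shape n and mean Dbar_i
gamma_mix_density <- function(D, means, weights, shape) {
  rowSums(vapply(seq_along(means), function(i) {
    weights[i] * dgamma(D, shape = shape, rate = shape / means[i])
  }, numeric(length(D))))
}

#' Gamma-mixture decomposition of diffusion coefficients
#'
#' The distribution of single-track D estimates obtained from n averaged
#' MSD points follows, for each mobility mode, a gamma density of shape n
#' and mean equal to the mode's true D. The mixture
#' \eqn{f(D)=\sum_i w_i \,\Gamma(D; n, n/\bar D_i)} is fitted to the binned
#' kernel density estimate of the D values by least squares; K = "auto"
#' picks the component count with the lowest reduced chi-squared. Each
#' track is assigned to its maximum-posterior component.
#'
#' @param D per-track diffusion coefficients (> 0; floor applied upstream).
#' @param K component count, or "auto" (1..4).
#' @param shape gamma shape = number of averaged MSD points (default 3).
#' @param bw KDE bandwidth; default Sheather-Jones.
#' @param method "kde": least squares of the kernel-convolved mixture
#'   against the KDE curve (the convention followed here; convolving the
#'   model with the same kernel as the data removes the smoothing bias on
#'   narrow components). "mle": maximum likelihood on the raw D values via
#'   EM, which is more stable when components overlap.
#' @return a `slim_dmix`: tibble `components` (mean D, weight, ascending),
#'   `chisq_red`, `assignment` (component per input value), the fitted KDE
#'   curve, and inputs.
#' @export
fit_gamma_mixture <- function(D, K = 3, shape = 3, bw = NULL,
                              method = c("kde", "mle")) {
  method <- match.arg(method)
  D <- D[is.finite(D) & D > 0]
  abort_if(length(D) < 10, "need at least 10 diffusion coefficients")
  if (diff(range(D)) < 1e-10) {
    # degenerate sample: a single point mass supports only one component
    return(structure(list(
      components = tibble(component = 1L, D_mean = mean(D), weight = 1),
      chisq_red = 0, shape = shape, bw = NA_real_,
      assignment = rep(1L, length(D)), D = D,
      kde = tibble(x = mean(D), y = Inf, fit = Inf)), class = "slim_dmix"))
  }
  if (identical(K, "auto")) {
    fits <- purrr::map(1:4, function(k) {
      tryCatch(fit_gamma_mixture(D, k, shape, bw, method),
               error = function(e) NULL)
    })
    fits <- purrr::compact(fits)
    abort_if(!length(fits), "no gamma-mixture fit converged")
    best <- which.min(purrr::map_dbl(fits, "chisq_red"))
    return(fits[[best]])
  }
  K <- as.integer(K)
  bw <- bw %||% tryCatch(stats::bw.SJ(D), error = function(e) stats::bw.nrd0(D))
  d <- stats::density(D, bw = bw, n = 512, from = 0, to = max(D) + 3 * bw)
  dx <- d$x[2] - d$x[1]
  kr <- ceiling(4 * bw / dx)
  kern <- dnorm(seq(-kr, kr) * dx, sd = bw) * dx
  convolve_model <- function(y) {
    yp <- c(rep(0, kr), y, rep(0, kr))
    as.numeric(stats::filter(yp, kern, sides = 2))[(kr + 1):(kr + length(y))]
  }

  if (method == "mle") {
    means <- as.numeric(quantile(D, (seq_len(K) * 2 - 1) / (2 * K)))
    w <- rep(1 / K, K)
    for (it in seq_len(2000)) {
      dens <- vapply(seq_len(K), function(k) {
        w[k] * dgamma(D, shape, rate = shape / means[k])
      }, numeric(length(D)))
      r <- dens / pmax(rowSums(dens), 1e-300)
      w_new <- colMeans(r)
      m_new <- colSums(r * D) / pmax(colSums(r), 1e-300)
      done <- max(abs(m_new - means), abs(w_new - w)) < 1e-9
      means <- m_new; w <- w_new
      if (done) break
    }
  } else {
    starts <- list(quantile(D, (seq_len(K) * 2 - 1) / (2 * K)),
                   seq(min(D), max(D), length.out = K + 2)[2:(K + 1)],
                   mean(D) * seq_len(K) / (K / 1.5))
    fit <- NULL
    for (st in starts) {
      st <- pmax(as.numeric(st), 1e-4)
      par0 <- c(log(st), rep(0, K))  # log means, weight logits
      obj <- tryCatch(
        minpack.lm::nls.lm(par0, fn = function(p) {
          means <- exp(p[1:K])
          w <- exp(p[K + 1:K]); w <- w / sum(w)
          convolve_model(gamma_mix_density(d$x, means, w, shape)) - d$y
        }, control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(obj) && obj$info %in% 1:4) { fit <- obj; break }
      if (!is.null(obj) && is.null(fit)) fit <- obj
    }
    abort_if(is.null(fit), "gamma-mixture fit failed from all starting points")
    p <- fit$par
    means <- exp(p[1:K])
    w <- exp(p[K + 1:K]); w <- w / sum(w)
  }
  ord <- order(means); means <- means[ord]; w <- w[ord]
  yhat <- gamma_mix_density(d$x, means, w, shape)
  chisq_red <- sum((d$y - convolve_model(yhat))^2) /
    max(1, length(d$x) - 2 * K)

  post <- vapply(seq_len(K), function(i) {
    w[i] * dgamma(D, shape = shape, rate = shape / means[i])
  }, numeric(length(D)))
  assignment <- max.col(post)

  structure(list(
    components = tibble(component = seq_len(K), D_mean = means, weight = w),
    chisq_red = chisq_red, shape = shape, bw = bw,
    assignment = assignment, D = D,
    kde = tibble(x = d$x, y = d$y, fit = yhat)
  ), class = "slim_dmix")
}

#' @export
print.slim_dmix <- function(x, ...) {
  cat(sprintf("Gamma mixture (shape %d, %d tracks), reduced chi-sq %.4g\n",
              x$shape, length(x$D), x$chisq_red))
  print(x$components)
  invisible(x)
}

#' Immobile fraction by colocalization status
#'
#' Fraction of tracks assigned to the slowest mixture component, split by a
#' logical colocalization label, with binomial standard errors. Empty
#' strata are flagged with NA.
#'
#' @param mixture a [fit_gamma_mixture()] result.
#' @param colocalized logical vector aligned with the mixture's input D
#'   values.
#' @return tibble `colocalized`, `n`, `n_immobile`, `fraction`, `se`.
#' @export
immobile_fraction <- function(mixture, colocalized) {
  abort_if(length(colocalized) != length(mixture$assignment),
           "one colocalization label per track required")
  imm <- mixture$assignment == 1L
  purrr::map_dfr(c(TRUE, FALSE), function(lab) {
    sel <- colocalized == lab
    n <- sum(sel)
    k <- sum(imm[sel])
    p <- if (n > 0) k / n else NA_real_
    tibble(colocalized = lab, n = n, n_immobile = k, fraction = p,
           se = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_)
  })
}

#' Dwell time of tracks at frame-zero fork positions
#'
#' For each track, counts the consecutive frames from the track start whose
#' focus overlaps (overlap integral >= threshold) any reference focus
#' detected at time zero (e.g. DnaQ fork marks), after registration. A
#' dwell equal to the full track length is right-censored.
#'
#' @param tracks linked track tibble.
#' @param fork_foci tibble of frame-zero reference foci (`x`, `y`), already
#'   in the tracks' coordinate frame.
#' @param sigma_a,sigma_b PSF sigmas (px) for the overlap.
#' @param threshold overlap acceptance threshold.
#' @return tibble `track_id`, `dwell_frames`, `censored` (dwell ran to the
#'   track end), `n_frames`.
#' @export
dwell_times <- function(tracks, fork_foci, sigma_a = 1.5, sigma_b = 1.75,
                        threshold = 0.75) {
  s2 <- sigma_a^2 + sigma_b^2
  pref <- 2 * sigma_a * sigma_b / s2
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  purrr::map_dfr(split(tracks, tracks$track_id), function(tr) {
    ov <- vapply(seq_len(nrow(tr)), function(i) {
      if (nrow(fork_foci) == 0) return(0)
      d2 <- (fork_foci$x - tr$x[i])^2 + (fork_foci$y - tr$y[i])^2
      max(pref * exp(-d2 / (2 * s2)))
    }, numeric(1))
    ok <- ov >= threshold
    dw <- if (!ok[1]) 0L else as.integer(rle(ok)$lengths[1])
    tibble(track_id = tr$track_id[1], n_frames = nrow(tr),
           dwell_frames = dw, censored = dw == nrow(tr) && dw > 0)
  })
}

#' Exponential (discretized) dwell-time model
#'
#' Frame-count dwells from an exponential residence time of mean tau are
#' geometric: P(k) = (1 - q) q^(k - 1) with q = exp(-dt/tau), respecting
#' the one-frame minimum. The maximum-likelihood tau (right-censored dwells
#' contribute their survival probability; censoring can be disabled) is
#' reported in ms with a bootstrap 95% CI and a chi-squared goodness-of-fit
#' statistic so poor single-exponential fits can be flagged.
#'
#' @param dwells integer dwell lengths in frames (zeros are dropped).
#' @param frame_ms frame interval in ms.
#' @param censored logical right-censoring flags (NULL = none).
#' @param n_boot bootstrap replicates for the CI.
#' @return a `slim_dwell`: `tau_ms`, `ci`, `n`, `gof_p`, flags.
#' @export
fit_dwell_exponential <- function(dwells, frame_ms = 5, censored = NULL,
                                  n_boot = 200) {
  keep <- dwells >= 1
  dwells <- dwells[keep]
  censored <- if (is.null(censored)) rep(FALSE, length(dwells)) else censored[keep]
  abort_if(length(dwells) < 20, "need at least 20 nonzero dwells")

  mle <- function(k, cens) {
    if (all(k == 1 & !cens)) return(frame_ms * 0.01)
    nll <- function(log_tau) {
      q <- exp(-frame_ms / exp(log_tau))
      ll <- sum((k[!cens] - 1) * log(q) + log(1 - q)) +
        sum((k[cens] - 1) * log(q))
      -ll
    }
    exp(optimize(nll, c(log(frame_ms * 0.01), log(frame_ms * 1e3)))$minimum)
  }
  tau <- mle(dwells, censored)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- withr::with_seed(1L, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample(length(dwells), replace = TRUE)
        mle(dwells[i], censored[i])
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }

  # goodness of fit: observed vs geometric expected counts, pooled tails
  q <- exp(-frame_ms / tau)
  kmax <- max(dwells)
  exp_p <- (1 - q) * q^(0:(kmax - 1))
  exp_p[kmax] <- exp_p[kmax] + q^kmax  # pool the tail
  obs <- tabulate(dwells, kmax)
  keep_bins <- exp_p * length(dwells) >= 1
  gof_p <- if (sum(keep_bins) > 1) {
    stat <- sum((obs[keep_bins] - length(dwells) * exp_p[keep_bins])^2 /
                  (length(dwells) * exp_p[keep_bins]))
    stats::pchisq(stat, df = max(1, sum(keep_bins) - 2), lower.tail = FALSE)
  } else NA_real_

  structure(list(tau_ms = tau, ci = ci, n = length(dwells),
                 frame_ms = frame_ms, gof_p = gof_p,
                 at_resolution_limit = tau < frame_ms / 2,
                 dwells = dwells, censored = censored),
            class = "slim_dwell")
}

#' @export
print.slim_dwell <- function(x, ...) {
  cat(sprintf("Dwell model: tau = %.2f ms (95%% CI %.2f-%.2f, n = %d)\n",
              x$tau_ms, x$ci[1], x$ci[2], x$n))
  if (isTRUE(x$at_resolution_limit))
    cat("  note: tau at or below the frame-time resolution limit\n")
  invisible(x)
}

#' Stokes-Einstein conversion between D and hydrodynamic radius
#'
#' r = kB T / (6 pi eta D), invertible: supply exactly one of `D_um2_s` or
#' `r_nm`.
#'
#' @param D_um2_s diffusion coefficient (um^2/s).
#' @param r_nm hydrodynamic radius (nm).
#' @param eta_cp viscosity in centipoise.
#' @param temperature_K absolute temperature.
#' @return the missing quantity (um^2/s or nm).
#' @export
stokes_einstein <- function(D_um2_s = NULL, r_nm = NULL, eta_cp = 10,
                            temperature_K = 303) {
  abort_if(is.null(D_um2_s) == is.null(r_nm),
           "supply exactly one of D_um2_s or r_nm")
  abort_if(eta_cp <= 0 || temperature_K <= 0, "eta and T must be > 0")
  kB <- 1.380649e-23
  eta <- eta_cp * 1e-3
  if (is.null(D_um2_s)) {
    abort_if(r_nm <= 0, "r must be > 0")
    kB * temperature_K / (6 * pi * eta * r_nm * 1e-9) * 1e12  # um^2/s
  } else {
    abort_if(D_um2_s <= 0, "D must be > 0")
    kB * temperature_K / (6 * pi * eta * D_um2_s * 1e-12) * 1e9  # nm
  }
}
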