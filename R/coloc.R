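#' Register two channels from brightfield images
#'
#' The shift between channels is the peak of the normalized 2D
#' cross-correlation of the two brightfield images, refined to sub-pixel
#' precision by parabolic interpolation around the peak. The returned
#' `c(dx, dy)` is such that content at (x, y) in image A appears at
#' (x + dx, y + dy) in image B; subtract it from channel-B focus
#' coordinates to bring them into A's frame.
#'
#' @param bf_a,bf_b equal-size brightfield matrices.
#' @param min_peak registration fails below this correlation peak.
#' @return c(dx, dy) with attribute `peak`.
#' @export
register_channels <- function(bf_a, bf_b, min_peak = 0.2) {
  abort_if(!all(dim(bf_a) == dim(bf_b)), "brightfield images must match in size")
  cc <- xcorr2(bf_a, bf_b)
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  abort_if(max(cc) < min_peak,
           sprintf("registration failed: correlation peak %.3f < %.2f",
                   max(cc), min_peak))
  nr <- nrow(cc); nc <- ncol(cc)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  offy <- parabolic_offset(cc[wrap(pk[1] - 1, nr), pk[2]], cc[pk[1], pk[2]],
                           cc[wrap(pk[1] + 1, nr), pk[2]])
  offx <- parabolic_offset(cc[pk[1], wrap(pk[2] - 1, nc)], cc[pk[1], pk[2]],
                           cc[pk[1], wrap(pk[2] + 1, nc)])
  out <- c(dx = wrap_disp(pk[2], nc) + offx, dy = wrap_disp(pk[1], nr) + offy)
  attr(out, "peak") <- max(cc)
  out
}

#' Overlap integral of two Gaussian foci
#'
#' For unit-normalized 2D Gaussian profiles with widths `sigma_a`, `sigma_b`
#' whose centers are `d` apart, the normalized overlap is
#' \deqn{O = \frac{2\sigma_A\sigma_B}{\sigma_A^2+\sigma_B^2}
#'   \exp\!\left(\frac{-d^2}{2(\sigma_A^2+\sigma_B^2)}\right),}
#' equal to 1 only for coincident, equal-width foci and monotonically
#' decreasing in separation.
#'
#' @param pos_a,pos_b c(x, y) focus centers in a common registered frame
#'   (pixels).
#' @param sigma_a,sigma_b Gaussian widths (pixels).
#' @return overlap in \[0, 1\].
#' @export
overlap_integral <- function(pos_a, pos_b, sigma_a, sigma_b) {
  d2 <- sum((pos_a - pos_b)^2)
  s2 <- sigma_a^2 + sigma_b^2
  2 * sigma_a * sigma_b / s2 * exp(-d2 / (2 * s2))
}

#' Object-based colocalization between two channels
#'
#' Focus pairs within each frame are formed greedily by descending overlap
#' integral and accepted at `threshold` (default 0.75, centers within about
#' one PSF sigma). Channel-B coordinates are first registered into A's frame
#' with `shift`. Fractions carry binomial standard errors.
#'
#' @param foci_a,foci_b per-frame focus tibbles (`frame`, `x`, `y`, ...).
#' @param sigma_a,sigma_b PSF sigmas in pixels.
#' @param threshold overlap acceptance threshold.
#' @param shift c(dx, dy) from [register_channels()].
#' @param by_frame match within frames (default) or over all foci at once.
#' @return a `slim_coloc`: tibble `pairs` (frame, row_a, row_b, distance,
#'   overlap), `fraction_a`, `fraction_b` each with `se`, and counts.
#' @export
colocalized_fraction <- function(foci_a, foci_b, sigma_a = 1.5, sigma_b = 1.75,
                                 threshold = 0.75, shift = c(0, 0),
                                 by_frame = TRUE) {
  fb <- foci_b
  fb$x <- fb$x - shift[1]
  fb$y <- fb$y - shift[2]
  frames <- if (by_frame) sort(unique(c(foci_a$frame, fb$frame))) else NA
  pairs <- list()
  for (f in frames) {
    ia <- if (by_frame) which(foci_a$frame == f) else seq_len(nrow(foci_a))
    ib <- if (by_frame) which(fb$frame == f) else seq_len(nrow(fb))
    if (!length(ia) || !length(ib)) next
    dx <- outer(foci_a$x[ia], fb$x[ib], "-")
    dy <- outer(foci_a$y[ia], fb$y[ib], "-")
    d <- sqrt(dx^2 + dy^2)
    s2 <- sigma_a^2 + sigma_b^2
    ov <- 2 * sigma_a * sigma_b / s2 * exp(-d^2 / (2 * s2))
    cand <- which(ov >= threshold, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(ov[cand], decreasing = TRUE)
    used_a <- logical(length(ia)); used_b <- logical(length(ib))
    for (kk in ord) {
      i <- cand[kk, 1]; j <- cand[kk, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1]] <- tibble(
        frame = if (by_frame) f else NA_integer_,
        row_a = ia[i], row_b = ib[j], distance = d[i, j], overlap = ov[i, j])
    }
  }
  pairs <- if (length(pairs) == 0) {
    tibble(frame = integer(), row_a = integer(), row_b = integer(),
           distance = numeric(), overlap = numeric())
  } else {
    dplyr::bind_rows(pairs)
  }
  n_pairs <- nrow(pairs)
  n_a <- nrow(foci_a); n_b <- nrow(foci_b)
  frac <- function(k, n) {
    p <- if (n > 0) k / n else NA_real_
    list(p = p, se = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_)
  }
  fa <- frac(n_pairs, n_a); fb2 <- frac(n_pairs, n_b)
  structure(list(pairs = pairs, n_a = n_a, n_b = n_b, n_pairs = n_pairs,
                 fraction_a = fa$p, se_a = fa$se,
                 fraction_b = fb2$p, se_b = fb2$se,
                 threshold = threshold, sigma_a = sigma_a, sigma_b = sigma_b),
            class = "slim_coloc")
}

#' @export
print.slim_coloc <- function(x, ...) {
  cat(sprintf("Colocalization: %d pairs; A: %.1f%% +/- %.1f%% (N=%d), B: %.1f%% +/- %.1f%% (N=%d), threshold %.2f\n",
              x$n_pairs, 100 * x$fraction_a, 100 * x$se_a, x$n_a,
              100 * x$fraction_b, 100 * x$se_b, x$n_b, x$threshold))
  invisible(x)
}

#' Random-overlap colocalization baseline
#'
#' Repeatedly re-places the channel-A foci uniformly at random inside their
#' own cells (counts preserved) and recomputes the colocalized fraction,
#' giving the chance-overlap level expected for unrelated foci. When the
#' observed result is supplied an empirical p-value for
#' observed > random is attached.
#'
#' @param foci_a channel-A foci with a `cell` column (or single-cell data
#'   with `cell_masks` of length 1).
#' @param foci_b channel-B foci (already registered).
#' @param cell_masks list of logical masks indexed by cell id, as from
#'   [sim_cells()].
#' @param n_rand randomizations (>= 100 recommended).
#' @param seed RNG seed.
#' @param observed optional `slim_coloc` of the real data.
#' @inheritParams colocalized_fraction
#' @return list `baseline`, `sd`, `draws`, `p_value`.
#' @export
random_overlap_baseline <- function(foci_a, foci_b, cell_masks, n_rand = 1000,
                                    seed = 1, sigma_a = 1.5, sigma_b = 1.75,
                                    threshold = 0.75, by_frame = TRUE,
                                    observed = NULL) {
  geoms <- attr(cell_masks, "centers")
  if (is.null(foci_a$cell)) foci_a$cell <- 1L
  withr::with_seed(seed, {
    draws <- vapply(seq_len(n_rand), function(r) {
      fa <- foci_a
      for (ci in unique(fa$cell)) {
        idx <- which(fa$cell == ci)
        xy <- sample_in_rod(length(idx), geoms[geoms$cell == ci, ])
        fa$x[idx] <- xy[, 1]; fa$y[idx] <- xy[, 2]
      }
      colocalized_fraction(fa, foci_b, sigma_a, sigma_b, threshold,
                           by_frame = by_frame)$fraction_a
    }, numeric(1))
  })
  p <- if (!is.null(observed)) {
    (1 + sum(draws >= observed$fraction_a)) / (n_rand + 1)
  } else NA_real_
  list(baseline = mean(draws), sd = sd(draws), draws = draws, p_value = p)
}

#' Stoichiometry relationship between colocalized foci
#'
#' Least-squares gradient of y on x constrained through the origin
#' (b = sum(xy)/sum(x^2)) with a t-based 95% confidence interval from the
#' residuals, alongside the ordinary Pearson correlation of the raw pairs
#' and the R^2 of the origin-constrained fit (which may be <= 0).
#'
#' @param x,y paired stoichiometries (e.g. DnaQ and Rep molecules per
#'   focus), length >= 3.
#' @return list `slope`, `se`, `ci` (95%), `r_pearson`, `r2_origin`, `n`.
#' @export
stoichiometry_ratio <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  abort_if(n < 3, "need at least three pairs")
  b <- sum(x * y) / sum(x^2)
  res <- y - b * x
  s2 <- sum(res^2) / (n - 1)
  se <- sqrt(s2 / sum(x^2))
  tq <- qt(0.975, n - 1)
  r <- if (sd(x) > 0 && sd(y) > 0) stats::cor(x, y) else NA_real_
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = b, se = se, ci = c(b - tq * se, b + tq * se),
       r_pearson = r, r2_origin = r2, n = n)
}

#' Compare two colocalized fractions
#'
#' Two-proportion z-test on the colocalized counts, falling back to
#' Fisher's exact test when any expected cell count is below 5.
#'
#' @param result_a,result_b `slim_coloc` objects (counts are used, not just
#'   fractions).
#' @param side "a" or "b": which channel's fraction to compare.
#' @return list `p_value`, `z`, `test`.
#' @export
compare_fractions <- function(result_a, result_b, side = "a") {
  k1 <- result_a$n_pairs; n1 <- if (side == "a") result_a$n_a else result_a$n_b
  k2 <- result_b$n_pairs; n2 <- if (side == "a") result_b$n_a else result_b$n_b
  p_pool <- (k1 + k2) / (n1 + n2)
  expected <- c(n1, n2) %o% c(p_pool, 1 - p_pool)
  if (any(expected < 5)) {
    m <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    return(list(p_value = fisher.test(m)$p.value, z = NA_real_,
                test = "fisher"))
  }
  z <- (k1 / n1 - k2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(p_value = 2 * pnorm(-abs(z)), z = z, test = "two-proportion z")
}
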