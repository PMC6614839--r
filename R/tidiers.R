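# broom-style methods for the package's fitted objects

#' @export
tidy.slim_stoich_model <- function(x, ...) x$peaks

#' @export
glance.slim_stoich_model <- function(x, ...) {
  tibble(n = length(x$S), n_peaks = x$n_peaks,
         spacing_mean = if (is.null(x$spacing)) NA_real_ else x$spacing$mean,
         spacing_sd = if (is.null(x$spacing)) NA_real_ else x$spacing$sd,
         spacing_nearest = if (is.null(x$spacing)) NA_integer_ else
           x$spacing$nearest_integer,
         converged = x$converged)
}

#' @export
tidy.slim_dmix <- function(x, ...) x$components

#' @export
glance.slim_dmix <- function(x, ...) {
  tibble(n = length(x$D), k = nrow(x$components), shape = x$shape,
         chisq_red = x$chisq_red)
}

#' @export
tidy.slim_dwell <- function(x, ...) {
  tibble(term = "tau_ms", estimate = x$tau_ms,
         conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @export
glance.slim_dwell <- function(x, ...) {
  tibble(n = x$n, tau_ms = x$tau_ms, gof_p = x$gof_p,
         at_resolution_limit = x$at_resolution_limit)
}

#' @export
tidy.slim_coloc <- function(x, ...) x$pairs

#' @export
glance.slim_coloc <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_pairs = x$n_pairs,
         fraction_a = x$fraction_a, se_a = x$se_a,
         fraction_b = x$fraction_b, se_b = x$se_b,
         threshold = x$threshold)
}

#' @export
autoplot.slim_stoich_model <- function(object, ...) {
  ggplot2::ggplot(object$kde, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$y), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "black") +
    ggplot2::geom_vline(xintercept = object$peaks$position,
                        linetype = "dotted") +
    ggplot2::labs(x = "stoichiometry (molecules)", y = "probability density",
                  title = sprintf("%d Gaussian peak(s), spacing %s",
                                  object$n_peaks,
                                  if (is.null(object$spacing)) "-" else
                                    sprintf("%.1f", object$spacing$mean))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.slim_dmix <- function(object, ...) {
  comp <- purrr::map_dfr(seq_len(nrow(object$components)), function(i) {
    tibble(x = object$kde$x,
           y = object$components$weight[i] *
             dgamma(object$kde$x, shape = object$shape,
                    rate = object$shape / object$components$D_mean[i]),
           component = factor(i))
  })
  ggplot2::ggplot(object$kde, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$y), fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$y, colour = .data$component)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = expression(D ~ (mu * m^2 / s)), y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.slim_dwell <- function(object, ...) {
  q <- exp(-object$frame_ms / object$tau_ms)
  kmax <- max(object$dwells)
  pmf <- tibble(t_ms = (1:kmax) * object$frame_ms,
                expected = length(object$dwells) * (1 - q) * q^(0:(kmax - 1)))
  obs <- tibble(t_ms = object$dwells * object$frame_ms)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t_ms)) +
    ggplot2::geom_histogram(binwidth = object$frame_ms, fill = "grey70",
                            colour = "white",
                            boundary = object$frame_ms / 2) +
    ggplot2::geom_line(data = pmf, ggplot2::aes(y = .data$expected),
                       colour = "red") +
    ggplot2::labs(x = "dwell time (ms)", y = "tracks",
                  title = sprintf("tau = %.1f ms (95%% CI %.1f-%.1f)",
                                  object$tau_ms, object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}

#' Overlay detected foci on a stack page
#'
#' @param stack a [slim_stack()].
#' @param foci tibble with `channel`, `frame`, `x`, `y`.
#' @param page page index (1-based) into the stack.
#' @return a ggplot.
#' @export
plot_foci <- function(stack, foci, page = 1) {
  m <- stack$frames[[page]]
  df <- tidyr::expand_grid(y = 0:(nrow(m) - 1), x = 0:(ncol(m) - 1))
  df$value <- as.vector(t(m))
  sel <- foci[foci$channel == stack$channel[page] &
                foci$frame == stack$frame[page], ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = sel, colour = "red", shape = 1, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
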