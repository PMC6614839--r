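#' Simulate ground-truth focus trajectories
#'
#' For every focus of every species the simulator draws a stoichiometry, a
#' mobility mode and per-frame 2D Brownian positions (per-axis displacement
#' variance 2*D*dt), reflected at the cell boundary. "bound" foci stay at an
#' anchor (jittering with the tether SD) for an exponentially distributed
#' dwell, then unbind and diffuse with `D_after`. Each fluorophore carries an
#' independent geometric bleach frame.
#'
#' @param config a [slim_config()].
#' @param cells output of [sim_cells()]; may be empty only if `confine` is
#'   FALSE.
#' @param seed optional seed overriding `config$seed`.
#' @param confine reflect trajectories at the cell boundary (default). With
#'   FALSE, trajectories are free Brownian walks from the field center
#'   (useful for diffusion calibration).
#' @return a `slim_truth` list with tibbles `foci` (one row per focus:
#'   id, cell, species, channel, S, mode, D, dwell_frames), `positions`
#'   (id, frame, x, y in pixels, bound flag, surviving molecules),
#'   `molecules` (id, molecule, bleach_frame), `pool` and `pool_positions`
#'   for the diffuse monomer pool, plus the cells and config.
#' @export
sim_tracks <- function(config, cells, seed = NULL, confine = TRUE) {
  seed <- seed %||% config$seed
  geoms <- attr(cells, "centers")
  abort_if(confine && (is.null(geoms) || nrow(geoms) == 0) &&
             length(config$species) > 0,
           "no cells available to confine trajectories")
  nF <- config$n_frames
  dt_s <- config$frame_ms / 1000
  px_per_um <- 1000 / config$pixel_nm
  tether_px <- config$tether_sd_nm / config$pixel_nm

  withr::with_seed(seed, {
    foci <- list(); positions <- list(); molecules <- list()
    fid <- 0L

    # anchors: positions of already-simulated species, for bind_to lookups
    anchor_pool <- list()

    for (sp in config$species) {
      n_cells_eff <- if (confine) nrow(geoms) else 1L
      for (ci in seq_len(n_cells_eff)) {
        g <- if (confine) geoms[ci, ] else
          list(cx = config$field_px[1] / 2, cy = config$field_px[2] / 2,
               length_px = Inf, width_px = Inf)
        for (k in seq_len(sp$n_per_cell)) {
          fid <- fid + 1L
          S <- if (length(sp$S) == 1) sp$S else sample(sp$S, 1)
          mi <- sample(nrow(sp$modes), 1, prob = sp$modes$weight)
          mode <- sp$modes$mode[mi]; D <- sp$modes$D[mi]

          if (mode == "bound") {
            anchor <- NULL
            if (!is.null(sp$bind_to)) {
              key <- paste(sp$bind_to, ci)
              if (!is.null(anchor_pool[[key]])) {
                a <- anchor_pool[[key]]
                anchor <- a[sample(nrow(a), 1), ]
              }
            }
            if (is.null(anchor)) {
              anchor <- if (confine) sample_in_rod(1, g, margin = 1) else
                matrix(c(g$cx, g$cy), 1)
            }
            dwell_ms <- rexp(1, rate = 1 / sp$dwell_ms)
            dwell_fr <- max(1L, ceiling(dwell_ms / config$frame_ms))
            xy <- matrix(NA_real_, nF, 2)
            bound <- seq_len(nF) <= dwell_fr
            nb <- min(dwell_fr, nF)
            xy[seq_len(nb), 1] <- anchor[1] + rnorm(nb, 0, tether_px)
            xy[seq_len(nb), 2] <- anchor[2] + rnorm(nb, 0, tether_px)
            if (nb < nF) {
              free <- brownian_path(nF - nb, start = c(anchor[1], anchor[2]),
                                    D = sp$D_after, dt_s = dt_s,
                                    px_per_um = px_per_um,
                                    geom = if (confine) g else NULL)
              xy[(nb + 1):nF, ] <- free
            }
            dwell_true <- dwell_fr
          } else {
            start <- if (confine) drop(sample_in_rod(1, g, margin = 1)) else
              c(g$cx, g$cy)
            xy <- rbind(start,
                        brownian_path(nF - 1, start = start, D = D, dt_s = dt_s,
                                      px_per_um = px_per_um,
                                      geom = if (confine) g else NULL))
            bound <- rep(mode == "immobile", nF)
            dwell_true <- NA_integer_
          }

          bf <- bleach_frames(S, config$bleach_prob)
          surv <- vapply(0:(nF - 1), function(t) sum(bf > t), integer(1))

          foci[[fid]] <- tibble(
            id = fid, cell = if (confine) ci else NA_integer_,
            species = sp$name, channel = sp$channel, S = S, mode = mode,
            D = if (mode == "bound") sp$D_after else D,
            dwell_frames = dwell_true)
          positions[[fid]] <- tibble(
            id = fid, frame = 0:(nF - 1), x = xy[, 1], y = xy[, 2],
            bound = bound, survivors = surv)
          molecules[[fid]] <- tibble(
            id = fid, molecule = seq_len(S),
            bleach_frame = if (S > 0) bf else numeric(0))
          key <- paste(sp$name, ci)
          anchor_pool[[key]] <- rbind(anchor_pool[[key]], xy[1, , drop = FALSE])
        }
      }
    }

    # diffuse monomeric pool
    pool <- list(); pool_positions <- list()
    if (config$pool_copies > 0 && confine && nrow(geoms) > 0) {
      pid <- 0L
      for (ci in seq_len(nrow(geoms))) {
        g <- geoms[ci, ]
        for (k in seq_len(config$pool_copies)) {
          pid <- pid + 1L
          start <- drop(sample_in_rod(1, g))
          xy <- rbind(start, brownian_path(nF - 1, start, config$pool_D,
                                           dt_s, px_per_um, g))
          bf <- bleach_frames(1L, config$bleach_prob)
          pool[[pid]] <- tibble(pool_id = pid, cell = ci,
                                channel = config$channels[1],
                                bleach_frame = bf)
          pool_positions[[pid]] <- tibble(pool_id = pid, frame = 0:(nF - 1),
                                          x = xy[, 1], y = xy[, 2],
                                          alive = (0:(nF - 1)) < bf)
        }
      }
    }

    proto <- list(
      foci = tibble(id = integer(), cell = integer(), species = character(),
                    channel = character(), S = integer(), mode = character(),
                    D = numeric(), dwell_frames = integer()),
      positions = tibble(id = integer(), frame = integer(), x = numeric(),
                         y = numeric(), bound = logical(),
                         survivors = integer()),
      molecules = tibble(id = integer(), molecule = integer(),
                         bleach_frame = numeric()),
      pool = tibble(pool_id = integer(), cell = integer(),
                    channel = character(), bleach_frame = numeric()),
      pool_positions = tibble(pool_id = integer(), frame = integer(),
                              x = numeric(), y = numeric(), alive = logical()))
    bind_or_proto <- function(lst, name) {
      if (length(lst) == 0) proto[[name]] else dplyr::bind_rows(lst)
    }
    structure(list(
      foci = bind_or_proto(foci, "foci"),
      positions = bind_or_proto(positions, "positions"),
      molecules = bind_or_proto(molecules, "molecules"),
      pool = bind_or_proto(pool, "pool"),
      pool_positions = bind_or_proto(pool_positions, "pool_positions"),
      cells = cells, config = config
    ), class = "slim_truth")
  })
}

# n-step Brownian path in pixel units from `start` (excluded from output),
# reflected radially at the rod boundary when `geom` is supplied.
brownian_path <- function(n, start, D, dt_s, px_per_um, geom = NULL) {
  if (n <= 0) return(matrix(numeric(0), 0, 2))
  sd_px <- sqrt(2 * D * dt_s) * px_per_um
  out <- matrix(NA_real_, n, 2)
  cur <- start
  for (i in seq_len(n)) {
    prop <- cur + rnorm(2, 0, sd_px)
    if (!is.null(geom) && is.finite(geom$width_px)) prop <- reflect_rod(prop, geom)
    out[i, ] <- prop
    cur <- prop
  }
  out
}

# mirror a point that escaped the capsule back across its surface
reflect_rod <- function(p, geom) {
  R <- geom$width_px / 2
  hx <- (geom$length_px - geom$width_px) / 2
  cxl <- geom$cx - hx; cxr <- geom$cx + hx
  cx <- min(max(p[1], cxl), cxr)       # closest point on the medial segment
  v <- p - c(cx, geom$cy)
  d <- sqrt(sum(v^2))
  if (d <= R) return(p)
  d_new <- max(2 * R - d, 0)
  if (d_new > R) d_new <- R            # very large steps: clamp to the wall
  c(cx, geom$cy) + v / d * d_new
}
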