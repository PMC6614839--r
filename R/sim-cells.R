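#' Generate non-overlapping rod-shaped cell masks
#'
#' Places `n_cells` horizontal rods (rectangle with hemispherical caps) in
#' the field by rejection sampling, with a margin of one pixel between
#' cells. Masks use the package pixel convention (0-based centers).
#'
#' @param config a [slim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a list of logical matrices (one per cell, full field size), with
#'   attributes `centers` (tibble of cell geometry in pixels) and `label`
#'   (integer matrix, 0 = background, i = cell i).
#' @export
sim_cells <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  nx <- config$field_px[1]; ny <- config$field_px[2]
  n <- config$n_cells
  if (n == 0) {
    out <- list()
    attr(out, "centers") <- tibble(cell = integer(), cx = numeric(),
                                   cy = numeric(), length_px = numeric(),
                                   width_px = numeric())
    attr(out, "label") <- matrix(0L, ny, nx)
    return(out)
  }
  L <- config$cell_length_um * 1000 / config$pixel_nm
  W <- config$cell_width_um * 1000 / config$pixel_nm
  abort_if(L > nx - 2 || W > ny - 2, "field too small for the requested cell size")

  px <- outer(rep(1, ny), 0:(nx - 1))   # x of each pixel center
  py <- outer(0:(ny - 1), rep(1, nx))   # y of each pixel center

  rod_mask <- function(cx, cy) {
    hx <- (L - W) / 2  # half-length of the central segment
    dx <- pmax(abs(px - cx) - hx, 0)
    (dx^2 + (py - cy)^2) <= (W / 2)^2
  }

  withr::with_seed(seed, {
    masks <- list(); centers <- list()
    occupied <- matrix(FALSE, ny, nx)
    tries <- 0L; max_tries <- 200L * n
    while (length(masks) < n) {
      tries <- tries + 1L
      abort_if(tries > max_tries,
               sprintf("could not place %d non-overlapping cells in a %dx%d field",
                       n, nx, ny))
      cx <- runif(1, L / 2 + 1, nx - 1 - L / 2)
      cy <- runif(1, W / 2 + 1, ny - 1 - W / 2)
      m <- rod_mask(cx, cy)
      grown <- rod_mask(cx, cy) | rod_mask(cx + 1, cy) | rod_mask(cx - 1, cy) |
        rod_mask(cx, cy + 1) | rod_mask(cx, cy - 1)
      if (!any(grown & occupied)) {
        occupied <- occupied | grown
        masks[[length(masks) + 1L]] <- m
        centers[[length(centers) + 1L]] <-
          tibble(cell = length(masks), cx = cx, cy = cy, length_px = L, width_px = W)
      }
    }
    label <- matrix(0L, ny, nx)
    for (i in seq_along(masks)) label[masks[[i]]] <- i
    attr(masks, "centers") <- dplyr::bind_rows(centers)
    attr(masks, "label") <- label
    masks
  })
}

# point-in-rod test and uniform sampling inside a rod, in pixel units
in_rod <- function(x, y, geom) {
  hx <- (geom$length_px - geom$width_px) / 2
  dx <- pmax(abs(x - geom$cx) - hx, 0)
  (dx^2 + (y - geom$cy)^2) <= (geom$width_px / 2)^2
}

sample_in_rod <- function(n, geom, margin = 0) {
  out <- matrix(NA_real_, 0, 2)
  g <- geom
  g$width_px <- g$width_px - 2 * margin
  g$length_px <- g$length_px - 2 * margin
  while (nrow(out) < n) {
    m <- 4 * (n - nrow(out)) + 8
    x <- runif(m, g$cx - g$length_px / 2, g$cx + g$length_px / 2)
    y <- runif(m, g$cy - g$width_px / 2, g$cy + g$width_px / 2)
    keep <- in_rod(x, y, g)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}
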