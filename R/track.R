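#' Link per-frame foci into trajectories
#'
#' Foci in consecutive frames of the same channel are paired by greedy
#' nearest-neighbour assignment in ascending distance order, accepting pairs
#' within `max_disp` pixels. Each focus joins at most one track; unmatched
#' foci start new tracks; a missed frame terminates a track (no gap
#' closing). Distance ties break on the lower focus row index, making the
#' result independent of the input ordering of foci within a frame.
#'
#' @param foci tibble from [detect_foci()] (columns channel, frame, x, y,
#'   ...).
#' @param max_disp maximum inter-frame displacement in pixels.
#' @return the foci tibble with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_foci <- function(foci, max_disp = 5) {
  if (nrow(foci) == 0) return(dplyr::mutate(foci, track_id = integer(0)))
  foci <- dplyr::arrange(foci, .data$channel, .data$frame, .data$x, .data$y)
  foci$track_id <- NA_integer_
  next_id <- 1L
  for (ch in unique(foci$channel)) {
    idx_ch <- which(foci$channel == ch)
    frames <- sort(unique(foci$frame[idx_ch]))
    prev_idx <- integer(0)
    for (f in frames) {
      cur_idx <- idx_ch[foci$frame[idx_ch] == f]
      # candidate links from the immediately preceding frame only
      use_prev <- prev_idx[foci$frame[prev_idx] == f - 1L]
      if (length(use_prev) && length(cur_idx)) {
        dx <- outer(foci$x[use_prev], foci$x[cur_idx], "-")
        dy <- outer(foci$y[use_prev], foci$y[cur_idx], "-")
        d <- sqrt(dx^2 + dy^2)
        cand <- which(d <= max_disp, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(d[cand], cand[, 1], cand[, 2])
          used_p <- logical(length(use_prev))
          used_c <- logical(length(cur_idx))
          for (kk in ord) {
            i <- cand[kk, 1]; j <- cand[kk, 2]
            if (used_p[i] || used_c[j]) next
            used_p[i] <- TRUE; used_c[j] <- TRUE
            foci$track_id[cur_idx[j]] <- foci$track_id[use_prev[i]]
          }
        }
      }
      new <- cur_idx[is.na(foci$track_id[cur_idx])]
      if (length(new)) {
        foci$track_id[new] <- next_id + seq_along(new) - 1L
        next_id <- next_id + length(new)
      }
      prev_idx <- cur_idx
    }
  }
  dplyr::arrange(foci, .data$track_id, .data$frame)
}

#' Filter tracks by minimum length
#'
#' The nominal acceptance criterion keeps tracks persisting at least four
#' consecutive frames; a relaxed two-frame variant is used for dim
#' fluorophores.
#'
#' @param tracks tibble with `track_id` and `frame`.
#' @param min_frames minimum track length in frames (>= 1).
#' @return the filtered tibble.
#' @export
accept_tracks <- function(tracks, min_frames = 4) {
  abort_if(min_frames < 1, "min_frames must be >= 1")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= min_frames) |>
    dplyr::ungroup()
}

#' Extend a track's intensity trace beyond its end (overtracking)
#'
#' Keeps measuring the ROI intensity at the track's final centroid for
#' `n_extra` further frames of the same channel, exposing the single-step
#' photobleach tail used to confirm the characteristic single-fluorophore
#' intensity.
#'
#' @param track one track's rows (single `track_id`).
#' @param stack the [slim_stack()] the track came from.
#' @param n_extra frames to append (0 returns the input).
#' @param roi_radius photometry ROI radius (px).
#' @return the track tibble with appended rows flagged `overtracked`.
#' @export
overtrack <- function(track, stack, n_extra, roi_radius = 5) {
  track <- dplyr::arrange(track, .data$frame)
  track$overtracked <- FALSE
  if (n_extra == 0) return(track)
  last <- track[nrow(track), ]
  ch_pages <- which(stack$channel == last$channel)
  avail <- stack$frame[ch_pages]
  extra <- (last$frame + 1):(last$frame + n_extra)
  extra <- extra[extra %in% avail]
  rows <- purrr::map(extra, function(f) {
    pg <- ch_pages[avail == f][1]
    m <- measure_focus(stack$frames[[pg]], c(last$x, last$y),
                       roi_radius = roi_radius)
    out <- last
    out$frame <- f
    out$intensity <- m$intensity
    out$snr <- m$snr
    out$overtracked <- TRUE
    out
  })
  dplyr::bind_rows(track, dplyr::bind_rows(rows))
}
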