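#' Pipeline configuration
#'
#' Collects every analysis threshold in one validated list; all values are
#' echoed into the output metadata. Defaults are the package's standard
#' operating point: SNR > 0.4 acceptance, 5 px circular ROI, 5 px linking
#' radius, 4-frame track acceptance per channel (set a channel to 2 for the
#' relaxed dim-fluorophore criterion), overlap threshold 0.75, localization
#' precision 40 nm.
#'
#' @param snr_min focus acceptance SNR.
#' @param roi_radius photometry ROI radius (px).
#' @param max_disp linking radius (px).
#' @param min_frames named c(green=, red=) minimum track length.
#' @param i_single named c(green=, red=) characteristic-intensity override;
#'   NA entries are calibrated from the data.
#' @param n_peaks named list of peak counts per channel ("auto" or integer).
#' @param coloc_threshold overlap-integral acceptance threshold.
#' @param n_rand random-overlap baseline randomizations.
#' @param psf_sigma_px named c(green=, red=) PSF sigma in pixels.
#' @param loc_precision_nm localization precision for the MSD intercept.
#' @param gamma_K diffusion mixture components ("auto" or integer).
#' @param pixel_nm,frame_ms acquisition scale.
#' @param seed seed for the stochastic stages (baseline, bootstraps).
#' @return a `slim_pipeline_config` list.
#' @export
slim_pipeline_config <- function(snr_min = 0.4, roi_radius = 5, max_disp = 5,
                                 min_frames = c(green = 4, red = 4),
                                 i_single = c(green = NA, red = NA),
                                 n_peaks = list(green = "auto", red = 2),
                                 coloc_threshold = 0.75, n_rand = 100,
                                 psf_sigma_px = c(green = 1.5, red = 1.75),
                                 loc_precision_nm = 40, gamma_K = 3,
                                 pixel_nm = 80, frame_ms = 5, seed = 1L) {
  abort_if(snr_min < 0, "snr_min must be >= 0")
  abort_if(any(min_frames < 1), "min_frames must be >= 1")
  structure(as.list(environment()), class = "slim_pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full Slimfield analysis pipeline
#'
#' detect -> link/accept -> characteristic intensity -> stoichiometry and
#' peaks -> channel registration -> colocalization (+ random baseline when
#' cell masks are supplied) -> diffusion mixture and immobile fraction ->
#' fork dwell times. Stages that lack the data they need (e.g. a second
#' channel) are skipped with a note in the summary.
#'
#' @param stack a [slim_stack()] (one or two channels).
#' @param config a [slim_pipeline_config()].
#' @param brightfield optional list(a, b) for registration.
#' @param cells optional cell masks (as [sim_cells()]) enabling the random
#'   overlap baseline.
#' @return a `slim_results` bundle: tibbles `foci`, `tracks`, `stoich`,
#'   `mobility`, `dwells`, `pairs`; model objects; and `summary`, a flat
#'   list of the headline numbers.
#' @export
run_pipeline <- function(stack, config = slim_pipeline_config(),
                         brightfield = NULL, cells = NULL) {
  channels <- unique(stack$channel)
  chA <- channels[1]
  chB <- if (length(channels) > 1) channels[2] else NULL

  foci <- run_stage("detection", detect_foci(
    stack, snr_min = config$snr_min, roi_radius = config$roi_radius,
    mask_sigma = config$psf_sigma_px[[chA]]))

  tracks <- run_stage("tracking", {
    purrr::map_dfr(channels, function(ch) {
      f <- foci[foci$channel == ch, ]
      if (nrow(f) == 0) return(f)
      linked <- link_foci(f, max_disp = config$max_disp)
      linked$track_id <- paste(ch, linked$track_id, sep = "_")
      accept_tracks(linked, min_frames = config$min_frames[[ch]])
    })
  })

  i_single <- run_stage("characteristic intensity", {
    purrr::map(setNames(channels, channels), function(ch) {
      ov <- config$i_single[[ch]]
      if (!is.na(ov)) return(list(estimate = ov, ci = c(NA, NA)))
      tryCatch(characteristic_intensity(tracks[tracks$channel == ch, ]),
               error = function(e) list(estimate = NA_real_, ci = c(NA, NA)))
    })
  })

  stoich <- run_stage("stoichiometry", {
    out <- purrr::map_dfr(channels, function(ch) {
      est <- i_single[[ch]]$estimate
      tr <- tracks[tracks$channel == ch, ]
      if (!is.finite(est) || nrow(tr) == 0) return(NULL)
      stoichiometries(tr, est)
    })
    if (nrow(out) == 0) {
      out <- tibble(track_id = character(), channel = character(),
                    n_frames = integer(), intercept = numeric(),
                    S = numeric(), flagged = logical())
    }
    out
  })

  peak_models <- run_stage("peak fitting", {
    purrr::map(setNames(channels, channels), function(ch) {
      s <- stoich$S[stoich$channel == ch & !stoich$flagged]
      np <- config$n_peaks[[ch]]
      if (length(s) < 30 && identical(np, "auto")) return(NULL)
      if (length(s) < 10) return(NULL)
      tryCatch(fit_stoich_peaks(s, n_peaks = np), error = function(e) NULL)
    })
  })

  shift <- c(0, 0)
  if (!is.null(brightfield)) {
    shift <- run_stage("registration",
                       register_channels(brightfield$a, brightfield$b))
  }

  coloc <- NULL; baseline <- NULL; ratio <- NULL
  if (!is.null(chB)) {
    fa <- tracks[tracks$channel == chA, ]
    fb <- tracks[tracks$channel == chB, ]
    if (nrow(fa) && nrow(fb)) {
      coloc <- run_stage("colocalization", colocalized_fraction(
        fa, fb, sigma_a = config$psf_sigma_px[[chA]],
        sigma_b = config$psf_sigma_px[[chB]],
        threshold = config$coloc_threshold, shift = shift))
      coloc$pairs$track_a <- fa$track_id[coloc$pairs$row_a]
      coloc$pairs$track_b <- fb$track_id[coloc$pairs$row_b]
      if (!is.null(cells) && length(cells) > 0) {
        fa_cells <- assign_cells(fa, cells)
        baseline <- run_stage("random baseline", random_overlap_baseline(
          fa_cells, fb, cells, n_rand = config$n_rand, seed = config$seed,
          sigma_a = config$psf_sigma_px[[chA]],
          sigma_b = config$psf_sigma_px[[chB]],
          threshold = config$coloc_threshold, observed = coloc))
      }
      if (nrow(stoich)) {
        prs <- dplyr::distinct(coloc$pairs, .data$track_a, .data$track_b)
        sa <- stoich[match(prs$track_a, stoich$track_id), "S", drop = TRUE]
        sb <- stoich[match(prs$track_b, stoich$track_id), "S", drop = TRUE]
        ok <- is.finite(sa) & is.finite(sb)
        if (sum(ok) >= 3) {
          ratio <- run_stage("stoichiometry ratio",
                             stoichiometry_ratio(sb[ok], sa[ok]))
        }
      }
    }
  }

  mobility <- NULL; mixture <- NULL; imm <- NULL
  trA <- tracks[tracks$channel == chA, ]
  if (nrow(trA)) {
    mobility <- run_stage("diffusion", track_diffusion(
      trA, pixel_nm = config$pixel_nm, frame_ms = config$frame_ms,
      loc_precision_nm = config$loc_precision_nm))
    if (nrow(mobility) >= 10) {
      mixture <- tryCatch(
        fit_gamma_mixture(mobility$D, K = config$gamma_K),
        error = function(e) NULL)
      if (!is.null(mixture) && !is.null(coloc)) {
        coloc_ids <- unique(coloc$pairs$track_a)
        imm <- immobile_fraction(mixture, mobility$track_id %in% coloc_ids)
      }
    }
  }

  dwells <- NULL; dwell_model <- NULL
  if (!is.null(chB) && nrow(trA)) {
    forks <- tracks[tracks$channel == chB & tracks$frame == 0, c("x", "y")]
    forks$x <- forks$x - shift[1]; forks$y <- forks$y - shift[2]
    if (nrow(forks)) {
      dwells <- run_stage("dwell times", dwell_times(
        trA, forks, sigma_a = config$psf_sigma_px[[chA]],
        sigma_b = config$psf_sigma_px[[chB]],
        threshold = config$coloc_threshold))
      nz <- dwells[dwells$dwell_frames > 0, ]
      if (nrow(nz) >= 20) {
        dwell_model <- run_stage("dwell fit", fit_dwell_exponential(
          nz$dwell_frames, frame_ms = config$frame_ms,
          censored = nz$censored))
      }
    }
  }

  summary <- list(
    n_foci = nrow(foci),
    n_tracks = dplyr::n_distinct(tracks$track_id),
    i_single = purrr::map_dbl(i_single, "estimate"),
    peaks = purrr::map(peak_models, function(m) if (is.null(m)) NULL else m$peaks$position),
    peak_spacing = purrr::map(peak_models, function(m) {
      if (is.null(m) || is.null(m$spacing)) NULL else m$spacing
    }),
    shift_px = as.numeric(shift),
    coloc_fraction_a = if (!is.null(coloc)) coloc$fraction_a else NA,
    coloc_se_a = if (!is.null(coloc)) coloc$se_a else NA,
    random_baseline = if (!is.null(baseline)) baseline$baseline else NA,
    baseline_p = if (!is.null(baseline)) baseline$p_value else NA,
    ratio_slope = if (!is.null(ratio)) ratio$slope else NA,
    D_modes = if (!is.null(mixture)) mixture$components$D_mean else NA,
    D_weights = if (!is.null(mixture)) mixture$components$weight else NA,
    immobile_fraction = if (!is.null(imm)) imm$fraction[imm$colocalized] else NA,
    tau_ms = if (!is.null(dwell_model)) dwell_model$tau_ms else NA,
    config = unclass_config(config)
  )

  structure(list(foci = foci, tracks = tracks, i_single = i_single,
                 stoich = stoich, peak_models = peak_models, shift = shift,
                 coloc = coloc, baseline = baseline, ratio = ratio,
                 mobility = mobility, mixture = mixture,
                 immobile = imm, dwells = dwells, dwell_model = dwell_model,
                 summary = summary, config = config),
            class = "slim_results")
}

unclass_config <- function(config) {
  out <- unclass(config)
  out[!vapply(out, is.function, logical(1))]
}

assign_cells <- function(foci, cells) {
  label <- attr(cells, "label")
  foci$cell <- vapply(seq_len(nrow(foci)), function(i) {
    r <- round(foci$y[i]) + 1; c <- round(foci$x[i]) + 1
    if (r < 1 || c < 1 || r > nrow(label) || c > ncol(label)) return(NA_integer_)
    v <- label[r, c]
    if (v == 0) NA_integer_ else as.integer(v)
  }, integer(1))
  # foci just outside any mask take the nearest cell
  if (any(is.na(foci$cell))) {
    geoms <- attr(cells, "centers")
    for (i in which(is.na(foci$cell))) {
      d <- (geoms$cx - foci$x[i])^2 + (geoms$cy - foci$y[i])^2
      foci$cell[i] <- geoms$cell[which.min(d)]
    }
  }
  foci
}

#' Write a results bundle to disk
#'
#' CSV tables for foci, tracks, stoichiometries, pairs, mobility and
#' dwells; `summary.json` with the headline quantities; `config.json`
#' embedding every threshold, the seed and a config hash for provenance.
#'
#' @param results a [run_pipeline()] bundle.
#' @param outdir output directory (created if missing).
#' @return invisible vector of paths written.
#' @export
write_results <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return()
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$foci, "foci.csv")
  wr(results$tracks, "tracks.csv")
  wr(results$stoich, "stoichiometry.csv")
  if (!is.null(results$coloc)) wr(results$coloc$pairs, "pairs.csv")
  wr(results$mobility, "mobility.csv")
  wr(results$dwells, "dwells.csv")
  meta <- unclass_config(results$config)
  meta$config_hash <- rlang::hash(meta)
  pj <- file.path(outdir, "config.json")
  jsonlite::write_json(meta, pj, auto_unbox = TRUE, digits = NA, null = "null")
  ps <- file.path(outdir, "summary.json")
  jsonlite::write_json(results$summary, ps, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(c(paths, pj, ps))
}
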