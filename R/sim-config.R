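#' Simulation configuration
#'
#' Builds the parameter set for the forward simulator of Slimfield image
#' stacks: rod-shaped cells, fluorescent foci of known stoichiometry and
#' mobility, stochastic single-step photobleaching, a diffuse monomeric pool
#' and an EMCCD-like camera model. Defaults correspond to the imaging
#' conditions the package targets: 80 nm pixels, 5 ms frames, alternating
#' two-colour excitation, PSF widths of 120 nm (green) and 140 nm (red).
#'
#' @param field_px integer c(nx, ny) field size in pixels.
#' @param pixel_nm pixel size in nm (> 0).
#' @param frame_ms frame interval within each channel in ms (> 0).
#' @param n_frames frames per channel.
#' @param channels channel labels; one or two of "green", "red".
#' @param alternating if TRUE and two channels, pages interleave
#'   green/red/green/... (alternating-laser emulation).
#' @param n_cells number of cells.
#' @param cell_length_um,cell_width_um rod geometry (hemispherically capped).
#' @param species a list of species definitions from [sim_species()].
#' @param brightness single-fluorophore brightness (camera counts integrated
#'   over the PSF, per frame).
#' @param bleach_prob per-molecule, per-frame irreversible bleach probability
#'   in \[0, 1\]. The default 0.1 leaves roughly ten frames of usable signal
#'   before a typical focus has fully bleached, so initial-intensity fits over
#'   the first three frames are well posed.
#' @param psf_sigma_nm named c(green=, red=) PSF Gaussian sigma in nm.
#' @param em_gain EM amplification factor (gamma approximation).
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param offset camera baseline offset (counts).
#' @param camera_noise logical; FALSE renders a noiseless, deterministic
#'   image (offset + signal) for unit tests.
#' @param pool_copies diffuse monomer copy number per cell (channel of the
#'   first species).
#' @param pool_D diffusion coefficient of pool monomers (um^2/s).
#' @param substeps sub-frame position samples accumulated per rendered frame
#'   (motion blur); 1 disables blurring.
#' @param tether_sd_nm positional jitter SD of bound (tethered) foci.
#' @param bit_depth camera bit depth; rendered values are clipped (with a
#'   message) at 2^bit_depth - 1.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a `slim_config` list, validated.
#' @export
slim_config <- function(field_px = c(128L, 128L),
                        pixel_nm = 80,
                        frame_ms = 5,
                        n_frames = 30L,
                        channels = c("green", "red"),
                        alternating = TRUE,
                        n_cells = 4L,
                        cell_length_um = 3,
                        cell_width_um = 1,
                        species = list(),
                        brightness = 2000,
                        bleach_prob = 0.1,
                        psf_sigma_nm = c(green = 120, red = 140),
                        em_gain = 30,
                        read_noise_sd = 3,
                        offset = 100,
                        camera_noise = TRUE,
                        pool_copies = 0,
                        pool_D = 4,
                        substeps = 10L,
                        tether_sd_nm = 20,
                        bit_depth = 16L,
                        seed = 1L) {
  abort_if(pixel_nm <= 0, "pixel_nm must be > 0")
  abort_if(frame_ms <= 0, "frame_ms must be > 0")
  abort_if(bleach_prob < 0 || bleach_prob > 1, "bleach_prob must lie in [0, 1]")
  abort_if(!all(channels %in% c("green", "red")), "channels must be 'green'/'red'")
  abort_if(pool_D < 0, "pool_D must be >= 0")
  abort_if(!is_count(n_frames) || n_frames < 1, "n_frames must be a positive integer")
  for (sp in species) {
    abort_if(any(sp$modes$D < 0), "diffusion coefficients must be >= 0")
  }
  structure(list(
    field_px = as.integer(field_px), pixel_nm = pixel_nm, frame_ms = frame_ms,
    n_frames = as.integer(n_frames), channels = channels,
    alternating = alternating, n_cells = as.integer(n_cells),
    cell_length_um = cell_length_um, cell_width_um = cell_width_um,
    species = species, brightness = brightness, bleach_prob = bleach_prob,
    psf_sigma_nm = psf_sigma_nm, em_gain = em_gain,
    read_noise_sd = read_noise_sd, offset = offset,
    camera_noise = camera_noise, pool_copies = pool_copies, pool_D = pool_D,
    substeps = as.integer(substeps), tether_sd_nm = tether_sd_nm,
    bit_depth = as.integer(bit_depth), seed = as.integer(seed)
  ), class = "slim_config")
}

#' Define a simulated fluorescent species
#'
#' @param name species label (e.g. "rep", "dnaq").
#' @param channel "green" or "red".
#' @param n_per_cell foci of this species per cell.
#' @param S stoichiometry (molecules per focus); a single integer or a vector
#'   sampled uniformly per focus.
#' @param modes a data frame with columns `mode` ("immobile", "slow", "fast"
#'   or "bound"), `D` (um^2/s) and `weight`; one mode is drawn per focus.
#' @param dwell_ms mean dwell of "bound" foci before unbinding (exponential).
#' @param bind_to name of the species whose focus positions act as anchors
#'   for "bound" foci (e.g. the fork marker); NULL anchors at a random
#'   intracellular position.
#' @param D_after diffusion coefficient adopted after unbinding (um^2/s).
#' @return a `slim_species` list.
#' @export
sim_species <- function(name, channel = "green", n_per_cell = 1L, S = 6L,
                        modes = data.frame(mode = "immobile", D = 0, weight = 1),
                        dwell_ms = 6.5, bind_to = NULL, D_after = 1.3) {
  abort_if(any(modes$D < 0), "diffusion coefficients must be >= 0")
  abort_if(any(modes$weight < 0) || sum(modes$weight) <= 0, "invalid mode weights")
  structure(list(name = name, channel = channel,
                 n_per_cell = as.integer(n_per_cell), S = as.integer(S),
                 modes = modes, dwell_ms = dwell_ms, bind_to = bind_to,
                 D_after = D_after),
            class = "slim_species")
}
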