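#' Model parameters
#'
#' Central collection of the model's geometric, filtering and dynamical
#' constants. Values printed in the source study are fixed here (pixels per
#' degree, lesion gradient floor, lateral-kernel shape, bias weights); the
#' remaining gains and time constants are the package's calibrated defaults
#' (see the methods vignette for how they were fixed).
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `hemiscan_params`.
#'
#' @section Geometry:
#' * `px_per_deg = 11`: pixels per degree of visual angle (495 px = 45 deg).
#' * `retina_px = 495`: square retinal window side, px.
#' * `v1_cell_px = 5`: V1 grid cell size (99 x 99 grid).
#' * `ex_pool = 3`: extrastriate pooling factor over V1 (33 x 33 grid).
#' * `par_n = 45`: parietal grid side; parietal cells span 11 px (1 deg).
#'
#' @section Dynamics:
#' * `dt = 2` ms Euler step, time constants `tau_ex`, `tau_it`, `tau_par`.
#' * `onset_ms = 60`: latency before stimulus-driven input reaches cortex.
#' * `ex_gain`: feedforward gain into extrastriate, calibrated so a
#'   high-contrast line drives extrastriate cells to ~1/3 of saturation
#'   without lateral input (`ex_cap = 1`).
#' * `lat_weight = 3`: weight of collinear lateral inputs when the
#'   compensation is enabled (0 otherwise).
#' * `par_drive_gain`, `noise_sd`: parietal input scaling and noise.
#' * `comp_weight_search = 4.4`, `comp_weight_line = 0.9`: spatial
#'   compensation bias weights.
#' * `bis_sigma = 12` parietal cells: width of the bisection-task Gaussian.
#'
#' @export
hemiscan_params <- function(...) {
  p <- list(
    # geometry
    px_per_deg        = 11,
    scene_px          = 1000L,
    retina_px         = 495L,
    v1_cell_px        = 5L,
    ex_pool           = 3L,
    par_n             = 45L,
    # retina / V1 filters (units: V1 grid cells)
    dog_sigma_c       = 0.7,
    dog_sigma_s       = 1.6,
    v1_sigma_long     = c(1.1, 2.2),   # envelope ~1 deg and ~2 deg
    v1_sigma_cross_c  = 0.9,
    v1_sigma_cross_s  = 1.9,
    v1_gain           = c(33.6, 33.6), # per-scale gain: line drives h map to ~1
    end_sigma_c       = 1.0,
    end_sigma_s       = 3.5,
    end_surround_w    = 0.85,
    end_comp_frac     = 0.95,          # "area of maximal activity" cut
    end_win           = 5L,            # comparison strip width, columns
    end_offset_cells  = 1.4,           # outward inset correction, calibrated
    scotoma_margin_px = 30,            # discount ends at the lesion border
    colour_gain       = 1.5,
    # ventral dynamics
    dt                = 2,
    tau_ex            = 20,
    tau_it            = 40,
    ex_cap            = 1,
    ex_gain           = 0.545,         # line drives extrastriate to ~1/3 cap
    ex_inh            = 0.5,
    ex_surr_inh       = 1,             # iso-orientation cross-axis surround
    it_gain           = 2.0,
    it_inh            = 1.5,
    it_bias           = 0.5,
    fb_gain           = 0.4,
    lat_weight        = 3,
    lat_sigma         = 9,
    lat_delta         = 0.5,
    lat_threshold     = 0.2,           # only suprathreshold cells relay
    lat_support       = 0.05,          # feedforward level counting as support
    lat_relay_decay   = 0.6,           # relay attenuation of completed cells
    onset_ms          = 60,
    # parietal
    tau_par           = 20,
    par_drive_gain    = 15,
    par_inh           = 0.15,
    noise_sd          = 0.35,
    comp_weight_search = 4.4,
    comp_weight_line  = 0.9,
    comp_gain         = 3.5,           # search-bias salience-unit conversion
    bis_sigma         = 12,
    extent_threshold  = 0.5,           # fraction of current parietal max
    extent_rf_px      = 55,            # parietal RF radius, px (calibrated)
    # novelty / IOR
    ior_factor        = 0.2,
    ior_radius_px     = 22,
    # trial control
    max_fixations_line   = 20L,
    max_fixations_search = 30L,
    max_fixation_ms   = 400,
    min_fixation_ms   = 250,
    trigger_margin    = 1.2,
    # lesions
    gradient_floor    = 0.6
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "hemiscan_params"
  p
}
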