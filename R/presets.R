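# Frozen preset calibration constants.
#
# CONTROL_AMOUNT_PER_VESICLE: transmitter per vesicle (nM um^2) set once so
# that a single vesicle released at an isolated site produces a 0.45% dF/F0
# amplitude in a 0.5-um ROI under the control sensor -- the movie-level
# counterpart of the amplitude-level quantal size q_true. Recomputed by
# tools in scratch whenever the simulator physics change.
CONTROL_AMOUNT_PER_VESICLE <- 21357

# Median fitted spread length constant of the control preset on the profile
# geometry; the "expanded diffusion profile" threshold is 1.1x this value.
CONTROL_LAMBDA_REF <- 0.73

# Control categorical quanta distribution: Pr = 0.80, mean quanta over
# successes = 1.325, up to 4 vesicles per pulse.
CONTROL_QUANTA_PROBS <- c(0.20, 0.60, 0.15, 0.04, 0.01)

#' Named simulation presets
#'
#' `"control"` reproduces baseline serotonergic transmission: quanta
#' probabilities `(0.20, 0.60, 0.15, 0.04, 0.01)` per pulse (release
#' probability 0.80, mean quanta over successes 1.325), quantal size 0.45%
#' dF/F0 per vesicle, `D_eff = 5` um^2/s and perisynaptic clearance
#' `k_peri = 8.889` 1/s so the spread length `sqrt(D/k)` is 0.75 um,
#' no clearance inside the synaptic cleft, and `k_extra = k_peri / 4`.
#' `"ssri"` models transporter inhibition: all clearance rates scaled by
#' 0.2 and two opposite egress-outlet wedges (half-width 20 deg, clearance
#' further reduced to 10% inside the wedge).
#'
#' Two geometries are provided. `"profile"` (16 x 16 um, dx = 0.1 um) is
#' for single-site diffusion profiling; it runs at a nondimensionally
#' scaled-down diffusion coefficient (D_eff = 5 um^2/s with clearance
#' rescaled so the spread length sqrt(D/k) is preserved), which leaves
#' every spatial profile intact at a fraction of the integration cost.
#' `"volume"` (64 x 64 um, dx = 0.5 um) is for far-field
#' volume-transmission runs with a distal detector; there the ratio of
#' transmitter transit time to stimulus-train duration matters, so it
#' runs at physical-scale D_eff = 100 um^2/s with k_peri = 177.8 1/s
#' (same 0.75 um spread length) and a weak extrasynaptic rate of
#' 0.6 1/s -- far from the synapse-rich neuropil transporters are sparse,
#' and a strong far-field rate would extinguish transmitter over the
#' tens-of-micron transit regardless of release intensity.
#'
#' @param name `"control"` or `"ssri"`.
#' @param geometry `"profile"` or `"volume"`.
#' @param seed Integer root seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A list with elements `config` ([sim_config()]), `sensor`
#'   ([sensor_model()]), `camera` ([camera_model()]), `quanta`
#'   ([quanta_dist()]), `q_true` and `name`.
#' @export
preset <- function(name = c("control", "ssri"),
                   geometry = c("profile", "volume"), seed = 1L, ...) {
  name <- match.arg(name)
  geometry <- match.arg(geometry)
  geo <- switch(geometry,
    profile = list(domain_size = 16, dx = 0.1, boundary = "reflecting",
                   k_extra = 8.889 / 4),
    volume  = list(domain_size = 64, dx = 0.5, boundary = "absorbing",
                   D_eff = 100, k_peri = 100 / 0.75^2, k_extra = 0.6)
  )
  mod <- switch(name,
    control = list(ssri_factor = 1, outlets = list()),
    ssri = list(
      ssri_factor = 0.2,
      outlets = list(
        list(angle = 0, half_width = 20, k_factor = 0.1),
        list(angle = 180, half_width = 20, k_factor = 0.1)
      )
    )
  )
  args <- list(duration = 2, D_eff = 5, r_syn = 0.25, r_peri = 3,
               k_syn = 0, k_peri = 8.889,
               amount_per_vesicle = CONTROL_AMOUNT_PER_VESICLE, seed = seed)
  args[names(geo)] <- geo
  args[names(mod)] <- mod
  over <- list(...)
  args[names(over)] <- over
  cfg <- do.call(sim_config, args)
  list(
    name = name,
    geometry = geometry,
    config = cfg,
    sensor = sensor_model(),
    camera = camera_model(pixel_size = cfg$dx, fps = cfg$output_fps),
    quanta = quanta_dist(CONTROL_QUANTA_PROBS),
    q_true = 0.45
  )
}
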