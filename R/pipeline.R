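# Allowed pipeline configuration keys and defaults. Every analysis
# parameter used by the pipeline stages is settable here.
pipeline_defaults <- function() {
  list(
    mode = "amplitudes",          # "amplitudes" or "movie"
    preset = "control",           # preset name
    geometry = "profile",
    seed = 1L,
    out_dir = NULL,
    n_trials = 40L,
    trial_frequency = 0.1,        # Hz, quantal trial trains
    noise_sd = 0.045,             # amplitude-mode measurement noise, % dF/F0
    threshold_k = 2.5,
    n_pulses = 10L,
    frequency = 16,
    t_start = 0.2,
    n_axons = 1L,
    snr_threshold = 4,
    min_separation = 1.5,
    isolation_radius = 3,
    roi_radius = 0.5,
    dr = 0.1,
    r_max = 8,
    fit_range = c(0, 8),
    band_edges = c(0, 0.5, 3, 8),
    outlet_annulus = c(0.75, 3),
    smooth_frames = 3L,
    camera_noise = FALSE,
    log_level = "info"
  )
}

#' Read and validate a pipeline configuration
#'
#' Configurations are named lists (or YAML files) validated against the
#' published key schema: unknown keys are rejected, known keys override
#' the defaults.
#'
#' @param config Named list or path to a YAML file.
#' @return The merged, validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("no such config file: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a named list or YAML path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  merged <- defaults
  merged[names(config)] <- config
  if (!merged$mode %in% c("amplitudes", "movie")) {
    abort("mode must be 'amplitudes' or 'movie'")
  }
  if (!merged$preset %in% c("control", "ssri")) {
    abort(sprintf("unknown preset '%s'", merged$preset))
  }
  merged
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes simulate -> detect -> profile -> quantal (-> classify, volume
#' geometry) as requested by the configuration and, when `out_dir` is
#' set, writes the result tables as CSV/JSON plus a plain-text log with
#' package version, seed and a parameter digest. Per-site stage failures
#' are recorded in the site table (column `error`) instead of aborting
#' the bundle.
#'
#' @param config Named list or YAML path (see [pipeline_config()]).
#' @return A list of result tables; invisibly writes files when
#'   `out_dir` is configured.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  res <- list(config = cfg)
  if (cfg$mode == "amplitudes") {
    ps <- preset(cfg$preset, geometry = cfg$geometry, seed = cfg$seed)
    site <- release_site(8, 8, quanta = ps$quanta, q_true = ps$q_true)
    protocol <- make_protocol(cfg$n_trials, cfg$trial_frequency)
    amps <- generate_amplitude_series(site, protocol,
                                      noise_sd = cfg$noise_sd,
                                      seed = cfg$seed)
    qa <- quantal_analysis(amps$amplitude_pct, threshold_k = cfg$threshold_k)
    res$amplitudes <- amps
    res$quantal <- tibble::tibble(
      q_pct = qa$quantal_size_q, sigma_pct = qa$sigma_noise,
      pr = qa$release_probability_Pr, avg_quanta = qa$avg_quanta,
      max_quanta = qa$max_quanta, n_trials = qa$n_trials,
      n_success = qa$n_success
    )
    res$histogram <- qa$histogram
  } else {
    ps <- preset(cfg$preset, geometry = cfg$geometry, seed = cfg$seed)
    ctr <- ps$config$domain_size / 2
    site <- release_site(ctr, ctr, quanta = ps$quanta, q_true = ps$q_true)
    protocol <- make_protocol(cfg$n_pulses, cfg$frequency,
                              t_start = cfg$t_start, n_axons = cfg$n_axons)
    cfg_sim <- ps$config
    cfg_sim$duration <- max(protocol$pulse_times) + 1.5
    conc <- simulate_concentration(cfg_sim, site, protocol)
    sensed <- apply_sensor(conc, ps$sensor)
    dff <- if (cfg$camera_noise) {
      cam <- ps$camera
      movie <- render_camera(sensed, cam, seed = cfg$seed)
      compute_dff(movie, baseline_window = c(0, cfg$t_start))
    } else {
      d <- dim(sensed$frames)
      m <- new_dff_movie(sensed$frames, matrix(1, d[1], d[2]),
                         sensed$pixel_size, sensed$fps, sensed$t0,
                         sensed$stimulus_times)
      m$truth <- sensed$truth
      m
    }
    map <- compute_pixel_max_map(dff, smooth_frames = cfg$smooth_frames)
    sites <- detect_release_sites(map, min_separation = cfg$min_separation,
                                  snr_threshold = cfg$snr_threshold,
                                  isolation_radius = cfg$isolation_radius)
    metrics <- purrr::map(seq_len(nrow(sites)), function(i) {
      ctr_i <- c(sites$x_um[i], sites$y_um[i])
      tryCatch({
        prof <- radial_profile(map, ctr_i, dr = cfg$dr, r_max = cfg$r_max)
        fit <- fit_length_constant(prof, fit_range = cfg$fit_range)
        shp <- shape_metrics(map, ctr_i,
                             count_outlets_annulus = cfg$outlet_annulus)
        bands <- band_integrals(map, ctr_i, edges = cfg$band_edges)
        fr <- stats::setNames(bands$fraction,
                              paste0("frac_", gsub("[ .-]", "_",
                                                   gsub(" um", "", bands$band))))
        dplyr::bind_cols(
          tibble::tibble(site_id = sites$site_id[i],
                         lambda_um = fit$lambda, r2 = fit$r_squared),
          shp[, c("fwhm_minor_um", "fwhm_major_um", "aspect_ratio",
                  "roundness", "n_outlets")],
          tibble::as_tibble(as.list(fr)),
          tibble::tibble(error = NA_character_)
        )
      }, error = function(e) {
        tibble::tibble(site_id = sites$site_id[i], error = conditionMessage(e))
      })
    })
    res$map <- map
    res$sites <- sites
    res$metrics <- dplyr::bind_rows(metrics)
    if (cfg$geometry == "volume") {
      distal <- simulate_distal_detector(conc)
      res$distal <- distal
      res$transmission <- classify_transmission(distal)
    }
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
    }
    if (!is.null(res$amplitudes)) wr(res$amplitudes, "amplitudes.csv")
    if (!is.null(res$quantal)) wr(res$quantal, "quantal.csv")
    if (!is.null(res$histogram)) wr(res$histogram, "histogram.csv")
    if (!is.null(res$sites)) wr(res$sites, "sites.csv")
    if (!is.null(res$metrics)) wr(res$metrics, "site_metrics.csv")
    cfg_digest <- cfg[order(names(cfg))]
    cfg_digest$out_dir <- NULL
    jsonlite::write_json(cfg_digest,
                         file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(
      c(sprintf("vesiq %s", as.character(utils::packageVersion("vesiq"))),
        sprintf("seed: %d", cfg$seed),
        sprintf("mode: %s preset: %s geometry: %s",
                cfg$mode, cfg$preset, cfg$geometry)),
      file.path(cfg$out_dir, "run.log")
    )
  }
  invisible(res)
}
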