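#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.quantal_result <- function(x, ...) {
  x$trials |>
    dplyr::mutate(quanta = x$per_trial_quanta)
}

#' @export
glance.quantal_result <- function(x, ...) {
  tibble::tibble(
    quantal_size_q = x$quantal_size_q,
    sigma_noise = x$sigma_noise,
    release_probability_Pr = x$release_probability_Pr,
    avg_quanta = x$avg_quanta,
    max_quanta = x$max_quanta,
    n_trials = x$n_trials,
    n_success = x$n_success
  )
}

#' @export
tidy.spatial_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "p0", "offset"),
    estimate = c(x$lambda, x$p0, x$offset)
  )
}

#' @export
glance.spatial_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, p0 = x$p0, offset = x$offset,
    r_squared = x$r_squared, converged = x$converged,
    at_bound = x$at_bound
  )
}

#' @export
tidy.synaptic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "tau_on", "tau_off", "t0", "rise_10_90"),
    estimate = c(x$amplitude, x$tau_on, x$tau_off, x$t0, x$rise_10_90)
  )
}

#' @export
glance.synaptic_fit <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude, tau_on = x$tau_on, tau_off = x$tau_off,
    rise_10_90 = x$rise_10_90, r_squared = x$r_squared,
    converged = x$converged
  )
}

#' @export
tidy.encode_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "log2(x)"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.encode_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, f_statistic = x$f_statistic,
    p_value = x$p_value, n = x$n
  )
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = c("f_max", "ec50", "hill"),
    estimate = c(x$f_max, x$ec50, x$hill)
  )
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    f_max = x$f_max, ec50 = x$ec50, hill = x$hill,
    r_squared = x$r_squared
  )
}
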