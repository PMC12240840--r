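#' Build a stimulation protocol
#'
#' Evenly spaced electrical pulse trains, e.g. 5 pulses at 64 Hz for
#' release-site identification or 20-pulse trains at 0.1 Hz for quantal
#' trials. Pulse `k` (0-based) falls at `t_start + k / frequency`.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param frequency Pulse rate in Hz (> 0).
#' @param t_start Time of the first pulse in seconds.
#' @param n_axons Number of synchronously stimulated axons (>= 1).
#' @return A `stim_protocol` object with fields `pulse_times`, `n_pulses`,
#'   `frequency`, `n_axons` and `trial_boundaries` (windows that each contain
#'   exactly one pulse; the last window extends one inter-pulse interval past
#'   the final pulse).
#' @examples
#' make_protocol(5, 64, t_start = 1)
#' @export
make_protocol <- function(n_pulses, frequency, t_start = 0, n_axons = 1L) {
  if (!is.numeric(n_pulses) || length(n_pulses) != 1L || n_pulses < 1 ||
      n_pulses != round(n_pulses)) {
    abort("`n_pulses` must be a positive integer")
  }
  assert_scalar_pos(frequency, "frequency")
  if (!is.numeric(n_axons) || n_axons < 1 || n_axons != round(n_axons)) {
    abort("`n_axons` must be a positive integer")
  }
  times <- t_start + (seq_len(n_pulses) - 1) / frequency
  ipi <- 1 / frequency
  bounds <- cbind(start = times, end = times + ipi)
  structure(
    list(
      pulse_times = times,
      n_pulses = as.integer(n_pulses),
      frequency = frequency,
      n_axons = as.integer(n_axons),
      trial_boundaries = bounds
    ),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d pulse(s) at %g Hz from t = %g s, %d axon(s)\n",
    x$n_pulses, x$frequency, x$pulse_times[1], x$n_axons
  ))
  invisible(x)
}

#' Categorical distribution of vesicular quanta per stimulus
#'
#' `probs[k + 1]` is the probability that `k` vesicles are released by one
#' pulse (`k = 0` is a failure). Probabilities must sum to one and the
#' support is capped at 6 quanta.
#'
#' @param probs Numeric probability vector over quanta counts `0..K`.
#' @return A `quanta_dist` object.
#' @export
quanta_dist <- function(probs) {
  if (!is.numeric(probs) || length(probs) < 1L || any(probs < 0) ||
      any(!is.finite(probs))) {
    abort("`probs` must be non-negative finite probabilities")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    abort("`probs` must sum to 1 (tolerance 1e-9)")
  }
  if (length(probs) > 7L) {
    abort("at most 6 quanta per stimulus are supported")
  }
  structure(
    list(probs = probs, k_max = length(probs) - 1L),
    class = "quanta_dist"
  )
}

#' @export
print.quanta_dist <- function(x, ...) {
  cat("<quanta_dist> P(k) =", paste(signif(x$probs, 3), collapse = " "),
      "\n  Pr(release) =", signif(1 - x$probs[1], 4),
      " mean quanta | success =", signif(mean_quanta(x), 4), "\n")
  invisible(x)
}

# Analytic release probability and mean quanta over successes.
release_prob <- function(dist) 1 - dist$probs[1]

mean_quanta <- function(dist) {
  k <- seq_along(dist$probs) - 1
  sum(k * dist$probs) / release_prob(dist)
}
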