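#' Extract a single-site trial trace from a dF/F0 movie
#'
#' Mean dF/F0 over a disc ROI per frame, with per-pulse trial windows
#' taken from the protocol. An ROI smaller than one pixel degenerates to
#' the single nearest pixel.
#'
#' @param dff A `vq_dff` movie.
#' @param center `(x, y)` in um.
#' @param roi_radius ROI radius in um.
#' @param protocol Optional [make_protocol()]; defaults to windows around
#'   the movie's recorded stimulus times.
#' @return A `trial_trace`: tibble (`time_s`, `dff_pct`) with attributes
#'   `windows` (matrix of start/end), `roi_radius`, `fps`.
#' @export
extract_trace <- function(dff, center, roi_radius = 0.5, protocol = NULL) {
  stopifnot(inherits(dff, "vq_dff"))
  rc <- px_of_um(center, dff$pixel_size, dim(dff$frames))
  r <- radius_map(nrow(dff$frames[, , 1]), ncol(dff$frames[, , 1]),
                  center, dff$pixel_size)
  sel <- r <= roi_radius
  if (!any(sel)) {
    sel <- matrix(FALSE, nrow(r), ncol(r))
    sel[rc[1], rc[2]] <- TRUE
  }
  nT <- dim(dff$frames)[3]
  vals <- vapply(seq_len(nT), function(k) mean(dff$frames[, , k][sel]),
                 numeric(1))
  stim <- if (!is.null(protocol)) protocol$pulse_times else dff$stimulus_times
  windows <- if (!is.null(protocol)) {
    protocol$trial_boundaries
  } else if (length(stim)) {
    ends <- c(stim[-1], frame_times(dff)[nT] + 1 / dff$fps)
    cbind(start = stim, end = ends)
  } else {
    NULL
  }
  out <- tibble::tibble(time_s = frame_times(dff), dff_pct = vals)
  attr(out, "windows") <- windows
  attr(out, "roi_radius") <- roi_radius
  attr(out, "fps") <- dff$fps
  class(out) <- c("trial_trace", class(out))
  out
}

# Double-exponential synaptic response: 0 before t0, then
# A (1 - exp(-(t-t0)/tau_on)) exp(-(t-t0)/tau_off).
synaptic_curve <- function(t, A, tau_on, tau_off, t0) {
  dt <- pmax(t - t0, 0)
  A * (1 - exp(-dt / tau_on)) * exp(-dt / tau_off) * (t >= t0)
}

#' Fit the double-exponential synaptic function to one trial
#'
#' Least-squares fit of
#' `f(t) = A (1 - exp(-(t - t0)/tau_on)) exp(-(t - t0)/tau_off)` (zero
#' before `t0`). The reported `amplitude` is the peak of the fitted curve,
#' `tau_off` is the decay time constant, and the 10-90% rise time is
#' computed numerically on the fitted curve (it approaches
#' `ln(9) tau_on` when `tau_off >> tau_on`).
#'
#' @param times,values Trace samples (seconds, percent dF/F0).
#' @param t0 Stimulus onset in seconds (fixed, not fitted).
#' @return A `synaptic_fit`: `amplitude`, `tau_on`, `tau_off`, `t0`,
#'   `rise_10_90`, `r_squared`, `converged`. Non-convergence yields NaN
#'   parameters with `converged = FALSE` (never silently dropped).
#' @export
fit_synaptic <- function(times, values, t0) {
  if (length(times) < 10L) abort("need at least 10 samples spanning rise and decay")
  sel <- is.finite(values)
  times <- times[sel]; values <- values[sel]
  base <- if (any(times < t0)) mean(values[times < t0]) else 0
  v <- values - base
  pk_idx <- which.max(v)
  A0 <- max(v[pk_idx], 1e-6)
  dt_s <- times[2] - times[1]
  rise0 <- max(times[pk_idx] - t0, 2 * dt_s)
  # decay start from the curve area: integral ~ amplitude * tau_off
  area <- sum(pmax(v[times >= t0], 0)) * dt_s
  tau_off0 <- min(max(area / A0, 2 * rise0, 0.05), 300)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        v ~ synaptic_curve(times, A, tau_on, tau_off, t0),
        start = start,
        lower = c(0, 1e-4, 1e-3), upper = c(Inf, 60, 600),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
  }
  fit <- try_fit(list(A = A0 * 1.5, tau_on = rise0 / 2, tau_off = tau_off0))
  if (is.null(fit)) {
    fit <- try_fit(list(A = A0 * 1.2, tau_on = rise0 / 4,
                        tau_off = 5 * tau_off0))
  }
  if (is.null(fit)) {
    return(structure(
      list(amplitude = NaN, tau_on = NaN, tau_off = NaN, t0 = t0,
           rise_10_90 = NaN, r_squared = NaN, converged = FALSE),
      class = "synaptic_fit"
    ))
  }
  cf <- as.list(coef(fit))
  # analytic peak time; amplitude = fitted peak value
  t_pk <- t0 + cf$tau_on * log(1 + cf$tau_off / cf$tau_on)
  amp <- synaptic_curve(t_pk, cf$A, cf$tau_on, cf$tau_off, t0)
  rise <- rise_10_90_of(cf$A, cf$tau_on, cf$tau_off, t0, t_pk, amp)
  rsq <- 1 - sum(residuals(fit)^2) / max(sum((v - mean(v))^2), 1e-300)
  structure(
    list(amplitude = amp, tau_on = cf$tau_on, tau_off = cf$tau_off, t0 = t0,
         rise_10_90 = rise, r_squared = max(0, min(1, rsq)),
         converged = TRUE),
    class = "synaptic_fit"
  )
}

# Numeric 10-90% rise time of the fitted curve via root bracketing.
rise_10_90_of <- function(A, tau_on, tau_off, t0, t_pk, amp) {
  f <- function(t) synaptic_curve(t, A, tau_on, tau_off, t0)
  t10 <- stats::uniroot(function(t) f(t) - 0.1 * amp, c(t0, t_pk),
                        tol = 1e-10)$root
  t90 <- stats::uniroot(function(t) f(t) - 0.9 * amp, c(t10, t_pk),
                        tol = 1e-10)$root
  t90 - t10
}

#' @export
print.synaptic_fit <- function(x, ...) {
  cat(sprintf(
    "<synaptic_fit> amplitude %.3g%%, rise(10-90) %.3g s, tau_off %.3g s, R2 %.3f%s\n",
    x$amplitude, x$rise_10_90, x$tau_off, x$r_squared,
    if (!x$converged) " (NOT CONVERGED)" else ""
  ))
  invisible(x)
}

#' Classify trials into release successes and failures
#'
#' A trial is a success when its amplitude exceeds
#' `threshold_k * sigma_noise`. When `sigma_noise` is not supplied it is
#' estimated as the robust SD of the failure cluster (amplitudes below
#' half the median), iterating classification and re-estimation; with no
#' identifiable failures the series is treated as all successes.
#'
#' @param amplitudes Per-trial amplitudes in percent dF/F0.
#' @param sigma_noise Amplitude noise SD; estimated when NULL.
#' @param threshold_k Success threshold in noise SDs.
#' @return A list: `trials` (tibble `trial`, `amplitude_pct`, `success`),
#'   `pr` (release probability), `sigma_noise`, `n_success`, `n_trials`.
#' @export
classify_events <- function(amplitudes, sigma_noise = NULL,
                            threshold_k = 2.5) {
  n <- length(amplitudes)
  if (!n) abort("no trials to classify")
  if (is.null(sigma_noise)) {
    fail0 <- amplitudes < 0.5 * median(amplitudes[amplitudes > 0])
    if (!any(fail0, na.rm = TRUE)) {
      sigma_noise <- 0
    } else {
      sigma_noise <- max(c(MAD_TO_SD * mad(amplitudes[fail0], constant = 1),
                           sd(amplitudes[fail0]), 1e-12), na.rm = TRUE)
      for (i in 1:3) {
        fail <- amplitudes <= threshold_k * sigma_noise
        if (!any(fail)) break
        sigma_noise <- max(c(sd(amplitudes[fail]),
                             MAD_TO_SD * mad(amplitudes[fail], constant = 1),
                             1e-12), na.rm = TRUE)
      }
    }
  } else if (sigma_noise < 0) {
    abort("`sigma_noise` must be >= 0")
  }
  success <- amplitudes > threshold_k * sigma_noise
  list(
    trials = tibble::tibble(
      trial = seq_len(n),
      amplitude_pct = amplitudes,
      success = success
    ),
    pr = mean(success),
    sigma_noise = sigma_noise,
    n_success = sum(success),
    n_trials = n
  )
}

# Lattice residual: sum over amplitudes of the squared distance to the
# nearest integer multiple of q (multiples >= 1).
lattice_residual <- function(q, amps) {
  k <- pmax(1, round(amps / q))
  sum((amps - k * q)^2)
}

#' Classic equal-spacing quantal analysis
#'
#' Estimates the vesicular quantal size `q` as the spacing that minimises
#' the lattice residual `L(q) = sum_i (A_i - round(A_i / q) q)^2` of the
#' success amplitudes over a grid `q in [0.4, 1.6] * median(A)`, refined
#' locally to full precision. Two anti-aliasing safeguards keep the
#' estimator on the fundamental spacing: sub-half-median successes
#' (gray-zone events that only sub-harmonic lattices can fit) are
#' excluded from the lattice fit, and among spacings whose residual is
#' within `alias_tol` of the global minimum the largest is taken -- a
#' `q/2` lattice folds residuals and can never score worse than `q`, so
#' the raw argmin is systematically biased toward sub-multiples.
#' Per-trial quanta are `max(1, round(A_i / q))`; the average is over
#' successes (failures excluded).
#'
#' @param amplitudes All per-trial amplitudes in percent dF/F0 (failures
#'   included; classification uses [classify_events()]).
#' @param sigma_noise Amplitude noise SD; estimated when NULL.
#' @param threshold_k Success threshold in noise SDs.
#' @param n_grid Number of coarse grid points.
#' @param alias_tol Relative residual tolerance of the largest-spacing
#'   rule.
#' @return A `quantal_result`: `quantal_size_q`, `sigma_noise`,
#'   `release_probability_Pr`, `avg_quanta`, `max_quanta`,
#'   `per_trial_quanta`, `histogram` (tibble of bin mids/counts at `q/4`
#'   bins), `n_trials`, `n_success`, `trials` tibble.
#' @export
quantal_analysis <- function(amplitudes, sigma_noise = NULL,
                             threshold_k = 2.5, n_grid = 1200L,
                             alias_tol = 0.5) {
  cls <- classify_events(amplitudes, sigma_noise, threshold_k)
  succ <- cls$trials$amplitude_pct[cls$trials$success]
  if (!length(succ)) abort("no successes: quantal size undefined")
  if (length(succ) < 5L) {
    warn("fewer than 5 success amplitudes: quantal size estimate is weakly constrained")
  }
  fit_amps <- succ[succ >= 0.5 * median(succ)]
  med <- median(fit_amps)
  if (max(fit_amps) - min(fit_amps) < 1e-12) {
    q_hat <- fit_amps[1]
  } else {
    grid <- seq(0.4 * med, 1.6 * med, length.out = n_grid)
    L <- vapply(grid, lattice_residual, numeric(1), amps = fit_amps)
    L_min <- min(L)
    i0 <- max(which(L <= L_min * (1 + alias_tol) + 1e-12))
    lo <- grid[max(1L, i0 - 1L)]
    hi <- grid[min(n_grid, i0 + 1L)]
    q_hat <- stats::optimize(lattice_residual, c(lo, hi), amps = fit_amps,
                             tol = 1e-10)$minimum
    if (lattice_residual(grid[i0], fit_amps) <
          lattice_residual(q_hat, fit_amps)) {
      q_hat <- grid[i0]
    }
  }
  k_succ <- pmax(1, round(succ / q_hat))
  per_trial <- integer(cls$n_trials)
  per_trial[cls$trials$success] <- as.integer(k_succ)
  binw <- q_hat / 4
  brks <- seq(0, max(amplitudes, 0) + binw, by = binw)
  h <- graphics::hist(pmax(amplitudes, 0), breaks = brks, plot = FALSE)
  structure(
    list(
      quantal_size_q = q_hat,
      sigma_noise = cls$sigma_noise,
      release_probability_Pr = cls$pr,
      avg_quanta = mean(k_succ),
      max_quanta = as.integer(max(k_succ)),
      per_trial_quanta = per_trial,
      histogram = tibble::tibble(mid = h$mids, count = h$counts),
      n_trials = cls$n_trials,
      n_success = cls$n_success,
      trials = cls$trials
    ),
    class = "quantal_result"
  )
}

#' @export
print.quantal_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<quantal_result> q = %.3f%% dF/F0, Pr = %.3f, ",
      "avg quanta (successes) = %.3f, max = %d\n",
      "  %d/%d successful trials, sigma_noise = %.3g%%\n"
    ),
    x$quantal_size_q, x$release_probability_Pr, x$avg_quanta,
    x$max_quanta, x$n_success, x$n_trials, x$sigma_noise
  ))
  invisible(x)
}
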