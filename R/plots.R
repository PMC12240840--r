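#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_point geom_function scale_fill_viridis_c labs theme_minimal
#'   coord_equal
#' @export
ggplot2::autoplot

#' Plot a pixel-max map
#'
#' @param object A `vq_maxmap`.
#' @param ... Unused.
#' @return A ggplot raster of maximal dF/F0 with physical axes.
#' @export
autoplot.vq_maxmap <- function(object, ...) {
  df <- tibble::tibble(
    x_um = rep((seq_len(ncol(object$values)) - 1) * object$pixel_size,
               each = nrow(object$values)),
    y_um = rep((seq_len(nrow(object$values)) - 1) * object$pixel_size,
               times = ncol(object$values)),
    dff = as.vector(object$values)
  )
  ggplot(df, aes(.data$x_um, .data$y_um, fill = .data$dff)) +
    geom_raster() +
    scale_fill_viridis_c(name = "max dF/F0 (%)") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' Plot a radial profile with its exponential fit
#'
#' @param object A [radial_profile()] tibble.
#' @param fit Optional `spatial_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(.data$r_um, .data$dff_pct)) +
    geom_point(size = 0.8) +
    labs(x = "distance from release centre (um)", y = "max dF/F0 (%)") +
    theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    p <- p + geom_function(
      fun = function(r) fit$p0 * exp(-r / fit$lambda) + fit$offset,
      colour = "red"
    )
  }
  p
}

#' Plot a quantal amplitude histogram
#'
#' Vertical guides mark integer multiples of the estimated quantal size,
#' the equally spaced peaks of the classic analysis.
#'
#' @param object A `quantal_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quantal_result <- function(object, ...) {
  q <- object$quantal_size_q
  guides <- tibble::tibble(x = q * seq_len(max(object$max_quanta, 1)))
  ggplot(object$histogram, aes(.data$mid, .data$count)) +
    geom_col(width = q / 4, fill = "grey40") +
    ggplot2::geom_vline(data = guides, aes(xintercept = .data$x),
                        linetype = 2, colour = "red") +
    labs(x = "amplitude (% dF/F0)", y = "trials") +
    theme_minimal()
}

#' Plot a trial trace
#'
#' @param object A `trial_trace`.
#' @param ... Unused.
#' @return A ggplot of dF/F0 against time.
#' @export
autoplot.trial_trace <- function(object, ...) {
  ggplot(object, aes(.data$time_s, .data$dff_pct)) +
    geom_line() +
    labs(x = "time (s)", y = "dF/F0 (%)") +
    theme_minimal()
}

#' Plot a calibration curve with optional points
#'
#' @param object A `calibration_curve`.
#' @param points Optional calibration points data frame.
#' @param ... Unused.
#' @return A ggplot on log10 concentration.
#' @export
autoplot.calibration_curve <- function(object, points = NULL, ...) {
  rng <- if (!is.null(points)) {
    range(points$concentration_nM[points$concentration_nM > 0])
  } else {
    c(object$ec50 / 100, object$ec50 * 100)
  }
  cc <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
  df <- tibble::tibble(concentration_nM = cc,
                       dff_pct = concentration_to_dff(object, cc))
  p <- ggplot(df, aes(.data$concentration_nM, .data$dff_pct)) +
    geom_line(colour = "red") +
    ggplot2::scale_x_log10() +
    labs(x = "concentration (nM)", y = "dF/F0 (%)") +
    theme_minimal()
  if (!is.null(points)) {
    p <- p + geom_point(data = points,
                        aes(.data$concentration_nM, .data$dff_pct))
  }
  p
}
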