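#' @importFrom rlang %||% abort warn
#' @importFrom stats median mad sd var rnorm rpois rlnorm runif approx coef
#'   dnorm lm pf fitted nls nls.control residuals
NULL

# Robust-scale conversion factor: 1 MAD of a Gaussian = 1.4826 SD.
MAD_TO_SD <- 1.4826

#' Derive a reproducible sub-seed for a named random stream
#'
#' All stochastic stages (quantal draws, shot noise, baseline field, site
#' placement) draw from independent streams derived from one root seed, so
#' that changing e.g. the camera noise realisation never perturbs the
#' sampled quanta.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Evaluate expr under a named stream seed, restoring the caller's RNG state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

# Separable Gaussian blur with edge replication; sigma_px in pixels.
gaussian_blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  w <- max(1L, ceiling(3 * sigma_px))
  kern <- dnorm(seq(-w, w), sd = sigma_px)
  kern <- kern / sum(kern)
  conv1 <- function(v) {
    vp <- c(rep(v[1L], w), v, rep(v[length(v)], w))
    out <- numeric(length(v))
    for (j in seq_along(kern)) {
      out <- out + kern[j] * vp[j:(j + length(v) - 1L)]
    }
    out
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

# Matrix of radial distances (um) from a centre given in um (x, y).
radius_map <- function(nrow, ncol, center_um, pixel_size) {
  x <- (seq_len(ncol) - 1) * pixel_size
  y <- (seq_len(nrow) - 1) * pixel_size
  dx2 <- outer(rep(1, nrow), (x - center_um[1])^2)
  dy2 <- outer((y - center_um[2])^2, rep(1, ncol))
  sqrt(dx2 + dy2)
}

# Pixel (row, col), 1-based, nearest to physical coordinates (x, y) um.
px_of_um <- function(center_um, pixel_size, dim_hw) {
  col <- round(center_um[1] / pixel_size) + 1L
  row <- round(center_um[2] / pixel_size) + 1L
  if (row < 1L || row > dim_hw[1] || col < 1L || col > dim_hw[2]) {
    abort("centre lies outside the image")
  }
  c(row = as.integer(row), col = as.integer(col))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
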