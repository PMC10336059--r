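#' Utilization-distribution area
#'
#' Kernel density estimate of the detections on a regular grid, returning
#' the area of the smallest highest-density region (HDR) that contains at
#' least `prob` of the estimated positional probability mass -- the "area
#' used" (prob = 0.95) and "core area" (prob = 0.50) of open-field tests.
#' Bandwidth is Silverman's rule per axis; the grid spans the arena when one
#' is supplied, otherwise the data range padded by 3 bandwidths. Both are
#' configurable.
#'
#' @param track a [bt_track()] (or a 2-column matrix/data.frame of x, y).
#' @param prob probability mass of the HDR, in (0, 1).
#' @param arena optional [arena_config()] fixing the grid extent.
#' @param bandwidth optional numeric length-2 kernel standard deviations
#'   (px); defaults to Silverman's rule per axis.
#' @param grid_n grid resolution per axis (default 256).
#' @param min_positions minimum number of detections (default 20, the
#'   representativeness filter); fewer raises an insufficient-data error.
#' @return area in squared pixels (number of grid cells in the HDR times
#'   cell area).
#' @export
utilization_area <- function(track, prob, arena = NULL, bandwidth = NULL,
                             grid_n = 256, min_positions = 20) {
  if (inherits(track, "bt_track") || is.data.frame(track)) {
    x <- track$x_px; y <- track$y_px
  } else {
    x <- track[, 1]; y <- track[, 2]
  }
  if (length(prob) != 1 || prob <= 0 || prob >= 1)
    stop("prob must be a single value in (0, 1)")
  n <- length(x)
  if (n < min_positions)
    stop(insufficient_data(sprintf(
      "utilization_area needs at least %d positions (got %d)",
      min_positions, n)))
  if (is.null(bandwidth))
    bandwidth <- c(silverman_bw(x), silverman_bw(y))
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  lims <- if (!is.null(arena)) {
    c(0, arena$width_px, 0, arena$height_px)
  } else {
    c(range(x) + c(-3, 3) * bandwidth[1],
      range(y) + c(-3, 3) * bandwidth[2])
  }
  # MASS::kde2d uses h/4 as the Gaussian sd
  kd <- MASS::kde2d(x, y, h = 4 * bandwidth, n = grid_n, lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  p <- as.vector(kd$z)
  p <- p / sum(p)
  ps <- sort(p, decreasing = TRUE)
  ncells <- which(cumsum(ps) >= prob)[1]
  ncells * cell
}

# Silverman's rule of thumb for one axis (kernel sd in data units)
silverman_bw <- function(v) {
  n <- length(v)
  s <- min(sd(v), IQR(v) / 1.34)
  if (!is.finite(s) || s <= 0) s <- max(sd(v), 1e-3)
  if (!is.finite(s) || s <= 0) s <- 1e-3
  0.9 * s * n^(-1 / 5)
}
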