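#' Arena geometry and calibration
#'
#' Describes the experimental aquarium: its pixel dimensions, the refuge
#' rectangle, optional stimulus points (novel object or conspecific
#' centroid), and the pixel-to-centimetre calibration. All downstream
#' spatial metrics are computed in pixels; [px_to_cm()] converts summaries.
#'
#' @param width_px,height_px arena dimensions in pixels (> 0).
#' @param refuge_region numeric length-4 vector `c(xmin, ymin, xmax, ymax)`
#'   in pixels; must lie inside the arena.
#' @param object_point optional `c(x, y)` of the novel-object centroid (px).
#' @param conspecific_point optional `c(x, y)` of the conspecific centroid (px).
#' @param px_per_cm calibration factor, pixels per centimetre (default 16.7,
#'   i.e. 1 cm = 16.7 px).
#' @return an object of class `arena_config`.
#' @examples
#' arena_config(500, 500, refuge_region = c(0, 200, 60, 300),
#'              object_point = c(250, 480))
#' @export
arena_config <- function(width_px, height_px, refuge_region,
                         object_point = NULL, conspecific_point = NULL,
                         px_per_cm = 16.7) {
  stopifnot(is.numeric(width_px), is.numeric(height_px))
  if (width_px <= 0 || height_px <= 0)
    stop("arena dimensions must be positive")
  if (px_per_cm <= 0) stop("px_per_cm must be positive")
  r <- as.numeric(refuge_region)
  if (length(r) != 4 || r[1] >= r[3] || r[2] >= r[4])
    stop("refuge_region must be c(xmin, ymin, xmax, ymax) with min < max")
  if (r[1] < 0 || r[2] < 0 || r[3] > width_px || r[4] > height_px)
    stop("refuge_region must be contained in the arena")
  chk_pt <- function(p, what) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (length(p) != 2 || any(!is.finite(p)))
      stop(what, " must be a finite (x, y) pair")
    p
  }
  structure(list(width_px = width_px, height_px = height_px,
                 refuge_region = r,
                 object_point = chk_pt(object_point, "object_point"),
                 conspecific_point = chk_pt(conspecific_point,
                                            "conspecific_point"),
                 px_per_cm = px_per_cm),
            class = "arena_config")
}

#' Movement model parameters for trajectory simulation
#'
#' Parameters of the correlated random walk used by [simulate_trajectory()]:
#' exponential step lengths, Von Mises turning angles, and a two-state
#' Markov chain for refuge occupancy (a detection exists exactly when the
#' animal is outside the refuge).
#'
#' @param step_mean_px mean step length per second in pixels (> 0).
#' @param turn_mu_rad Von Mises mean turning angle in radians.
#' @param turn_kappa Von Mises concentration (>= 0; 0 is circular uniform).
#' @param p_enter_refuge,p_exit_refuge per-second transition probabilities
#'   in \[0, 1\].
#' @param duration_s test length in seconds (3600 for 1-h tests, 7200 for the
#'   2-h activity test).
#' @return an object of class `movement_config`.
#' @export
movement_config <- function(step_mean_px = 20, turn_mu_rad = 0,
                            turn_kappa = 1, p_enter_refuge = 0.02,
                            p_exit_refuge = 0.05, duration_s = 3600) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (step_mean_px <= 0) stop("step_mean_px must be positive")
  if (turn_kappa < 0) stop("turn_kappa must be >= 0")
  for (p in c(p_enter_refuge, p_exit_refuge))
    if (p < 0 || p > 1) stop("refuge transition probabilities must be in [0, 1]")
  structure(list(step_mean_px = step_mean_px, turn_mu_rad = turn_mu_rad,
                 turn_kappa = turn_kappa, p_enter_refuge = p_enter_refuge,
                 p_exit_refuge = p_exit_refuge,
                 duration_s = as.integer(duration_s)),
            class = "movement_config")
}

#' Construct a track of per-second detections
#'
#' A track holds the ordered detections of one individual in one test.
#' Seconds with no detection encode refuge occupancy.
#'
#' @param t_s integer seconds (0-based, strictly increasing, < `duration_s`).
#' @param x_px,y_px finite coordinates in pixels.
#' @param duration_s total test duration in seconds.
#' @param id,trial,test labels carried through to metric tables.
#' @return a `data.frame` of class `bt_track` with columns `t_s`, `x_px`,
#'   `y_px` and attributes `duration_s`, `id`, `trial`, `test`.
#' @export
bt_track <- function(t_s, x_px, y_px, duration_s,
                     id = "ind1", trial = 1L, test = "activity") {
  stopifnot(length(t_s) == length(x_px), length(t_s) == length(y_px))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (length(t_s)) {
    if (any(!is.finite(x_px)) || any(!is.finite(y_px)))
      stop("coordinates must be finite")
    if (any(t_s < 0) || any(t_s >= duration_s))
      stop("t_s must satisfy 0 <= t_s < duration_s")
    if (any(diff(t_s) <= 0)) stop("t_s must be strictly increasing")
  }
  structure(data.frame(t_s = as.integer(t_s), x_px = as.numeric(x_px),
                       y_px = as.numeric(y_px)),
            duration_s = as.integer(duration_s),
            id = id, trial = as.integer(trial), test = test,
            class = c("bt_track", "data.frame"))
}

#' @export
print.bt_track <- function(x, ...) {
  cat(sprintf("<bt_track> id=%s trial=%d test=%s: %d detections over %d s\n",
              attr(x, "id"), attr(x, "trial"), attr(x, "test"),
              nrow(x), attr(x, "duration_s")))
  if (nrow(x)) print(head(as.data.frame(x), 5))
  invisible(x)
}
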