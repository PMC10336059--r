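#' Time outside the refuge
#'
#' Each detection corresponds to one second outside the refuge, so the
#' metric is the number of detections.
#'
#' @param track a [bt_track()].
#' @return seconds outside the refuge (integer).
#' @export
time_outside_refuge <- function(track) {
  stopifnot(inherits(track, "bt_track"))
  nrow(track)
}

#' Minimum distance to a stimulus point
#'
#' Minimum Euclidean distance from any detection to the stimulus centroid
#' (novel object or conspecific). If the animal was never detected -- it
#' remained in the refuge for the whole test -- the configured imputation
#' distance is returned instead (250 px for the novel-object test, 350 px
#' for the conspecific test: the average refuge-to-stimulus distances).
#'
#' @param track a [bt_track()].
#' @param point numeric `c(x, y)` stimulus centroid in pixels.
#' @param impute_px distance assigned when there are no detections (> 0).
#' @param per_second logical; if TRUE, undetected seconds each contribute
#'   `impute_px` and the minimum is taken over all seconds (alternative
#'   reading of the imputation rule; default FALSE imputes only fully
#'   undetected tracks).
#' @return minimum distance in pixels.
#' @export
min_distance_to_point <- function(track, point, impute_px, per_second = FALSE) {
  stopifnot(inherits(track, "bt_track"), length(point) == 2)
  if (impute_px <= 0) stop("impute_px must be positive")
  if (nrow(track) == 0) return(impute_px)
  d <- sqrt((track$x_px - point[1])^2 + (track$y_px - point[2])^2)
  if (per_second && nrow(track) < attr(track, "duration_s"))
    return(min(min(d), impute_px))
  min(d)
}

#' Time interacting with a stimulus
#'
#' Number of detected seconds spent within `radius_px` (closed comparison,
#' `<=`) of the stimulus centroid.
#'
#' @param track a [bt_track()].
#' @param point numeric `c(x, y)` stimulus centroid in pixels.
#' @param radius_px interaction radius in pixels (default 100, ~6 cm).
#' @return seconds of interaction (integer).
#' @export
interaction_time <- function(track, point, radius_px = 100) {
  stopifnot(inherits(track, "bt_track"), length(point) == 2)
  if (radius_px <= 0) stop("radius_px must be positive")
  if (nrow(track) == 0) return(0L)
  d2 <- (track$x_px - point[1])^2 + (track$y_px - point[2])^2
  sum(d2 <= radius_px^2)
}

#' Total travelled distance
#'
#' Sum of Euclidean distances between consecutive detections. Detections
#' separated by undetected seconds still form one consecutive pair (no
#' interpolation); set `split_gaps = TRUE` to break the path at gaps
#' instead.
#'
#' @param track a [bt_track()].
#' @param split_gaps logical; if TRUE, pairs spanning a gap in `t_s` are
#'   excluded from the sum.
#' @return distance in pixels.
#' @export
total_distance <- function(track, split_gaps = FALSE) {
  stopifnot(inherits(track, "bt_track"))
  n <- nrow(track)
  if (n < 2) return(0)
  dx <- diff(track$x_px); dy <- diff(track$y_px)
  step <- sqrt(dx^2 + dy^2)
  if (split_gaps) step <- step[diff(track$t_s) == 1L]
  sum(step)
}

#' Turning angles of a trajectory
#'
#' Signed angle in (-pi, pi] between consecutive displacement vectors.
#' Zero-length displacements carry no direction and are skipped. As with
#' [total_distance()], displacements across undetected gaps are kept unless
#' `split_gaps = TRUE`.
#'
#' @param track a [bt_track()].
#' @param split_gaps logical; if TRUE, angles are only formed from pairs of
#'   displacements uninterrupted by detection gaps.
#' @return numeric vector of angles in radians.
#' @export
turning_angles <- function(track, split_gaps = FALSE) {
  stopifnot(inherits(track, "bt_track"))
  if (nrow(track) < 3)
    stop(insufficient_data("turning_angles needs at least 3 detections"))
  dx <- diff(track$x_px); dy <- diff(track$y_px)
  keep <- dx != 0 | dy != 0
  if (split_gaps) keep <- keep & (diff(track$t_s) == 1L)
  dx <- dx[keep]; dy <- dy[keep]
  if (length(dx) < 2) return(numeric(0))
  headings <- atan2(dy, dx)
  wrap_angle(diff(headings))
}

insufficient_data <- function(msg) {
  structure(class = c("bt_insufficient_data", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Convert pixels to centimetres
#'
#' Applies the arena calibration (default 1 cm = 16.7 px).
#'
#' @param value_px length in pixels.
#' @param px_per_cm pixels per centimetre (> 0).
#' @return length in centimetres.
#' @examples
#' px_to_cm(250)  # ~15 cm
#' px_to_cm(33)   # 1.98 cm
#' @export
px_to_cm <- function(value_px, px_per_cm = 16.7) {
  if (px_per_cm <= 0) stop("px_per_cm must be positive")
  value_px / px_per_cm
}

#' Compute the metric set for one track
#'
#' Dispatches the behavioral-test metrics relevant to the test type:
#' \describe{
#'   \item{exploration}{time outside the refuge, minimum distance to the
#'     novel object (250 px imputed when never detected), interaction time
#'     within 100 px.}
#'   \item{sociability}{same three metrics against the conspecific centroid,
#'     with 350 px imputation.}
#'   \item{activity}{time outside, total travelled distance, Von Mises mean
#'     turning angle and concentration, 95\% and 50\% utilization areas.
#'     Activity metrics require at least `min_positions` detections;
#'     otherwise they are returned as `NA` with `insufficient = TRUE`.}
#' }
#'
#' @param track a [bt_track()].
#' @param arena an [arena_config()]; supplies stimulus points and bounds.
#' @param test_type one of `"exploration"`, `"sociability"`, `"activity"`.
#' @param radius_px interaction radius (default 100 px).
#' @param impute_px imputation distance; defaults to 250 (exploration) or
#'   350 (sociability).
#' @param min_positions minimum detections for activity metrics (default 20).
#' @return a named list of class `bt_metricset` including `n_positions`.
#' @export
compute_metricset <- function(track, arena, test_type = attr(track, "test"),
                              radius_px = 100, impute_px = NULL,
                              min_positions = 20) {
  stopifnot(inherits(track, "bt_track"), inherits(arena, "arena_config"))
  n_pos <- nrow(track)
  out <- list(id = attr(track, "id"), trial = attr(track, "trial"),
              test = test_type, n_positions = n_pos,
              time_outside_s = time_outside_refuge(track))
  if (test_type %in% c("exploration", "sociability")) {
    point <- if (test_type == "exploration") arena$object_point else
      arena$conspecific_point
    if (is.null(point))
      stop("arena lacks the stimulus point required for the ", test_type,
           " test")
    if (is.null(impute_px))
      impute_px <- if (test_type == "exploration") 250 else 350
    out$min_distance_px <- min_distance_to_point(track, point, impute_px)
    out$interaction_time_s <- interaction_time(track, point, radius_px)
  } else if (test_type == "activity") {
    if (n_pos >= min_positions) {
      out$total_distance_px <- total_distance(track)
      ang <- turning_angles(track)
      if (length(ang) >= 2) {
        vm <- fit_von_mises(ang)
        out$turn_mu_rad <- vm$mu
        out$turn_kappa <- vm$kappa
      } else {
        out$turn_mu_rad <- NA_real_
        out$turn_kappa <- NA_real_
      }
      out$area95_px2 <- utilization_area(track, 0.95, arena = arena)
      out$area50_px2 <- utilization_area(track, 0.50, arena = arena)
      out$insufficient <- FALSE
    } else {
      out[c("total_distance_px", "turn_mu_rad", "turn_kappa",
            "area95_px2", "area50_px2")] <- NA_real_
      out$insufficient <- TRUE
    }
  } else {
    stop("unknown test_type: ", test_type)
  }
  structure(out, class = "bt_metricset")
}

#' @export
print.bt_metricset <- function(x, ...) {
  cat(sprintf("<bt_metricset> id=%s trial=%d test=%s\n",
              x$id, x$trial, x$test))
  vals <- x[!(names(x) %in% c("id", "trial", "test"))]
  for (nm in names(vals))
    cat(sprintf("  %-18s %s\n", nm, format(vals[[nm]], digits = 6)))
  invisible(x)
}

#' Metric sets for a list of tracks, as a long table
#'
#' @param tracks list of [bt_track()] objects.
#' @param arena an [arena_config()].
#' @param ... passed to [compute_metricset()].
#' @return long `data.frame` with columns `id`, `trial`, `test`, `metric`,
#'   `value`.
#' @export
metrics_long <- function(tracks, arena, ...) {
  rows <- lapply(tracks, function(tr) {
    ms <- compute_metricset(tr, arena, ...)
    num <- ms[vapply(ms, is.numeric, logical(1))]
    num <- num[!(names(num) %in% c("trial"))]
    data.frame(id = ms$id, trial = ms$trial, test = ms$test,
               metric = names(num), value = as.numeric(unlist(num)),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
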