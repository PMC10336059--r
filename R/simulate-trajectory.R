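#' Simulate a per-second tracking trajectory
#'
#' Emulates the output of an automated tracker at 1 Hz: a correlated random
#' walk (exponential step lengths, Von Mises turning angles) interleaved
#' with refuge occupancy governed by a two-state Markov chain. While the
#' animal is inside the refuge no detection is emitted, mirroring the
#' operational equivalence of "not detected" and "in the refuge". Arena
#' walls are reflective; positions never fall inside the refuge rectangle.
#'
#' @param arena an [arena_config()].
#' @param movement a [movement_config()].
#' @param seed integer seed; the trajectory is a deterministic function of
#'   (arena, movement, seed).
#' @param id,trial,test labels attached to the returned track.
#' @param start_inside logical; start the animal inside the refuge
#'   (default TRUE).
#' @return a [bt_track()] with one row per detected (outside-refuge) second.
#' @export
simulate_trajectory <- function(arena, movement, seed = NULL,
                                id = "ind1", trial = 1L, test = "activity",
                                start_inside = TRUE) {
  stopifnot(inherits(arena, "arena_config"), inherits(movement, "movement_config"))
  if (movement$duration_s <= 0) stop("duration_s must be positive")
  if (!is.null(seed)) set.seed(seed)

  dur <- movement$duration_s
  # refuge occupancy: 2-state Markov chain, one step per second
  u_state <- runif(dur)
  inside <- logical(dur)
  state <- start_inside
  p_exit <- movement$p_exit_refuge
  p_enter <- movement$p_enter_refuge
  for (t in seq_len(dur)) {
    inside[t] <- state
    state <- if (state) u_state[t] >= p_exit else u_state[t] < p_enter
  }

  n_out <- sum(!inside)
  if (n_out == 0)
    return(bt_track(integer(0), numeric(0), numeric(0), dur,
                    id = id, trial = trial, test = test))

  r <- arena$refuge_region
  door <- refuge_door(arena)
  # pre-draw all movement randomness (fixed consumption order keeps the
  # trajectory a deterministic function of the seed)
  turns <- rvonmises(n_out, movement$turn_mu_rad, movement$turn_kappa)
  steps <- rexp(n_out, rate = 1 / movement$step_mean_px)
  fresh <- runif(n_out, -pi, pi)

  xs <- numeric(n_out); ys <- numeric(n_out); ts <- integer(n_out)
  k <- 0L
  px <- door[1]; py <- door[2]
  heading <- 0
  prev_inside <- TRUE
  w <- arena$width_px; h <- arena$height_px
  for (t in seq_len(dur)) {
    if (inside[t]) { prev_inside <- TRUE; next }
    k <- k + 1L
    if (prev_inside) {
      # new excursion: leave from the refuge door with a fresh heading
      px <- door[1]; py <- door[2]
      heading <- fresh[k]
    } else {
      heading <- heading + turns[k]
      px <- px + steps[k] * cos(heading)
      py <- py + steps[k] * sin(heading)
      # reflective walls
      px <- px %% (2 * w); if (px > w) px <- 2 * w - px
      py <- py %% (2 * h); if (py > h) py <- 2 * h - py
      # detections never fall inside the refuge: push to the nearest edge
      if (px > r[1] && px < r[3] && py > r[2] && py < r[4]) {
        p <- push_out_of_refuge(c(px, py), r)
        px <- p[1]; py <- p[2]
      }
    }
    ts[k] <- t - 1L; xs[k] <- px; ys[k] <- py
    prev_inside <- FALSE
  }
  bt_track(ts, xs, ys, dur, id = id, trial = trial, test = test)
}

# point just outside the refuge rectangle, on the side facing the arena centre
refuge_door <- function(arena) {
  r <- arena$refuge_region
  cx <- (r[1] + r[3]) / 2; cy <- (r[2] + r[4]) / 2
  ax <- arena$width_px / 2; ay <- arena$height_px / 2
  eps <- 1e-6
  if (abs(ax - cx) >= abs(ay - cy)) {
    x <- if (ax >= cx) r[3] + eps else r[1] - eps
    c(x, cy)
  } else {
    y <- if (ay >= cy) r[4] + eps else r[2] - eps
    c(cx, y)
  }
}

# detections must never fall inside the refuge: project to the nearest edge
push_out_of_refuge <- function(p, r) {
  if (p[1] > r[1] && p[1] < r[3] && p[2] > r[2] && p[2] < r[4]) {
    eps <- 1e-6
    dx_left <- p[1] - r[1]; dx_right <- r[3] - p[1]
    dy_bot <- p[2] - r[2];  dy_top <- r[4] - p[2]
    m <- min(dx_left, dx_right, dy_bot, dy_top)
    if (m == dx_left) p[1] <- r[1] - eps
    else if (m == dx_right) p[1] <- r[3] + eps
    else if (m == dy_bot) p[2] <- r[2] - eps
    else p[2] <- r[4] + eps
  }
  p
}

#' Write / read trajectory CSV
#'
#' Long-format interchange used by the pipeline: columns `id`, `trial`,
#' `test`, `t_s`, `x_px`, `y_px`; missing seconds are undetected (refuge).
#'
#' @param tracks a list of [bt_track()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "bt_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    if (!nrow(tr)) return(NULL)
    data.frame(id = attr(tr, "id"), trial = attr(tr, "trial"),
               test = attr(tr, "test"), t_s = tr$t_s,
               x_px = tr$x_px, y_px = tr$y_px)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(id = character(0), trial = integer(0), test = character(0),
                     t_s = integer(0), x_px = numeric(0), y_px = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param path CSV path to read.
#' @param durations named list/vector mapping test name to duration in
#'   seconds (used to rebuild track attributes).
#' @return a list of [bt_track()] objects, one per (id, trial, test).
#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, durations = c(exploration = 3600,
                                                sociability = 3600,
                                                activity = 7200)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  key <- interaction(df$id, df$trial, df$test, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t_s), ]
    bt_track(d$t_s, d$x_px, d$y_px,
             duration_s = as.integer(durations[[d$test[1]]]),
             id = as.character(d$id[1]), trial = d$trial[1], test = d$test[1])
  })
}
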