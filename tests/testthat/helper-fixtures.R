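# Shared fixtures and independent oracles used across test files.

# random track with optional undetected gaps
random_track <- function(n = 50, duration = 200, seed = NULL,
                         xmax = 500, ymax = 500, ...) {
  if (!is.null(seed)) set.seed(seed)
  ts <- sort(sample.int(duration, n)) - 1L
  bt_track(ts, runif(n, 0, xmax), runif(n, 0, ymax), duration, ...)
}

# brute-force per-row oracles (kept deliberately naive)
oracle_min_distance <- function(track, point) {
  best <- Inf
  for (i in seq_len(nrow(track))) {
    d <- sqrt((track$x_px[i] - point[1])^2 + (track$y_px[i] - point[2])^2)
    if (d < best) best <- d
  }
  best
}

oracle_interaction <- function(track, point, radius) {
  count <- 0L
  for (i in seq_len(nrow(track))) {
    d <- sqrt((track$x_px[i] - point[1])^2 + (track$y_px[i] - point[2])^2)
    if (d <= radius) count <- count + 1L
  }
  count
}

oracle_total_distance <- function(track) {
  tot <- 0
  for (i in seq_len(nrow(track) - 1)) {
    tot <- tot + sqrt((track$x_px[i + 1] - track$x_px[i])^2 +
                        (track$y_px[i + 1] - track$y_px[i])^2)
  }
  tot
}

# atan2-based per-triple turning-angle oracle (skips zero displacements)
oracle_turning_angles <- function(track) {
  xs <- track$x_px; ys <- track$y_px
  heads <- c()
  for (i in seq_len(length(xs) - 1)) {
    dx <- xs[i + 1] - xs[i]; dy <- ys[i + 1] - ys[i]
    if (dx != 0 || dy != 0) heads <- c(heads, atan2(dy, dx))
  }
  if (length(heads) < 2) return(numeric(0))
  a <- diff(heads)
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# one-way ANOVA moment estimators of the variance components, computed
# from balanced group sums (avoids a dense factor design matrix)
anova_components <- function(values, id, k = NULL) {
  id <- as.character(id)
  q <- length(unique(id))
  n <- length(values)
  if (is.null(k)) k <- n / q
  gm <- tapply(values, id, mean)
  msb <- k * sum((gm - mean(values))^2) / (q - 1)
  msw <- sum((values - gm[id])^2) / (n - q)
  v_ind <- max((msb - msw) / k, 0)
  list(v_ind = v_ind, v_e = msw, icc = v_ind / (v_ind + msw))
}

# Rayleigh test p-value for circular uniformity
rayleigh_p <- function(angles) {
  n <- length(angles)
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# leading-eigenvector oracle by power iteration on the correlation matrix
power_iteration_pc1 <- function(mat, n_iter = 2000) {
  S <- stats::cor(mat)
  v <- rep(1, ncol(S))
  for (i in seq_len(n_iter)) {
    v_new <- S %*% v
    v <- v_new / sqrt(sum(v_new^2))
  }
  lambda <- as.numeric(t(v) %*% S %*% v)
  list(vector = as.numeric(v), lambda = lambda,
       varfrac = lambda / sum(diag(S)))
}

# minimal bivariate posterior container for decomposition-only tests
fake_biv_fit <- function(g_draws, r_draws, traits = c("t1", "t2")) {
  structure(list(draws = list(v_ind = g_draws, v_e = r_draws),
                 responses = traits, bivariate = TRUE,
                 constrain_cov = FALSE, dic = 0),
            class = "bt_lmm")
}

tiny_pipeline_config <- function(n_ind = 6L) {
  cfg <- default_pipeline_config()
  cfg$n_individuals <- n_ind
  cfg$movement$durations <- list(exploration = 180L, sociability = 180L,
                                 activity = 300L)
  cfg$movement$p_exit_refuge <- 0.2
  cfg$mcmc$univariate <- list(n_iter = 1500L, burn_in = 500L, thin = 5L)
  cfg$mcmc$bivariate <- list(n_iter = 3000L, burn_in = 1000L, thin = 10L)
  cfg
}
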