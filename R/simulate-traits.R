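#' Configuration for repeated-measures trait simulation
#'
#' Ground-truth generative model for the mixed-model stages:
#' `y_ij = X beta + u_i + e_ij` with `u_i ~ N(0, v_ind)` and
#' `e_ij ~ N(0, v_e)`, so the true adjusted repeatability is
#' `v_ind / (v_ind + v_e)`. Fixed effects are an intercept, a linear trial
#' (learning) effect, a sample (wild vs reared) offset, and a body-length
#' slope. For bivariate generation, `trait_pair_corr = c(r_ind, r_e)` sets
#' the between-individual and residual correlations.
#'
#' @param n_individuals number of individuals.
#' @param n_trials repeated trials per individual (default 4; a warning is
#'   issued below 2 because repeatability is then unidentifiable).
#' @param v_ind between-individual variance (scalar, or length-2 for pairs).
#' @param v_e within-individual (residual) variance (scalar or length-2).
#' @param beta fixed effects `c(intercept, trial, sample_reared, length)`.
#' @param prop_wild proportion of individuals from the wild sample.
#' @param length_mean,length_sd body-length distribution (cm).
#' @param trait_pair_corr optional `c(r_ind_true, r_e_true)` in \[-1, 1\].
#' @param seed integer RNG seed; all sub-streams derive from it.
#' @return an object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(n_individuals = 70, n_trials = 4,
                             v_ind = 0.4, v_e = 0.6,
                             beta = c(intercept = 0, trial = 0,
                                      sample_reared = 0, length = 0),
                             prop_wild = 0.5,
                             length_mean = 10, length_sd = 1,
                             trait_pair_corr = NULL, seed = 1L) {
  if (any(v_ind < 0) || any(v_e <= 0))
    stop("v_ind must be >= 0 and v_e > 0")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (!is.null(trait_pair_corr)) {
    if (length(trait_pair_corr) != 2 || any(abs(trait_pair_corr) > 1))
      stop("trait_pair_corr must be c(r_ind, r_e) with |r| <= 1")
  }
  if (length(beta) != 4) stop("beta must have 4 elements")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_trials = as.integer(n_trials),
                 v_ind = v_ind, v_e = v_e, beta = beta,
                 prop_wild = prop_wild, length_mean = length_mean,
                 length_sd = length_sd, trait_pair_corr = trait_pair_corr,
                 seed = as.integer(seed)),
            class = "trait_sim_config")
}

# individual-level frame shared by both generators
sim_individuals <- function(cfg) {
  n <- cfg$n_individuals
  n_wild <- round(n * cfg$prop_wild)
  data.frame(id = sprintf("SA%03d", seq_len(n)),
             sample = rep(c("wild", "reared"), c(n_wild, n - n_wild)),
             length_cm = rnorm(n, cfg$length_mean, cfg$length_sd))
}

sim_design <- function(cfg, ind) {
  d <- expand.grid(trial = seq_len(cfg$n_trials), id = ind$id,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- merge(d, ind, by = "id", sort = TRUE)
  d <- d[order(d$id, d$trial), ]
  rownames(d) <- NULL
  d$trial_c <- d$trial - mean(d$trial)
  d$length_c <- d$length_cm - mean(d$length_cm)
  d
}

fixed_part <- function(cfg, d) {
  b <- cfg$beta
  b[1] + b[2] * d$trial_c + b[3] * (d$sample == "reared") + b[4] * d$length_c
}

#' Simulate a long-format repeated-measures trait table
#'
#' @param cfg a [trait_sim_config()].
#' @param trait_name label for the `trait` column.
#' @return a `data.frame` with columns `id`, `trial`, `sample`, `length_cm`,
#'   `trial_c`, `length_c` (mean-centered covariates), `trait`, `value`.
#'   Deterministic for a fixed `cfg$seed`.
#' @export
simulate_trait_data <- function(cfg, trait_name = "trait1") {
  stopifnot(inherits(cfg, "trait_sim_config"))
  if (cfg$n_trials < 2)
    warning("n_trials < 2: repeatability is unidentifiable")
  set.seed(cfg$seed)
  ind <- sim_individuals(cfg)
  d <- sim_design(cfg, ind)
  u <- rnorm(cfg$n_individuals, 0, sqrt(cfg$v_ind[1]))
  names(u) <- ind$id
  e <- rnorm(nrow(d), 0, sqrt(cfg$v_e[1]))
  d$trait <- trait_name
  d$value <- fixed_part(cfg, d) + u[d$id] + e
  d
}

#' Simulate a correlated trait pair (long format)
#'
#' Individual effects are drawn from a bivariate normal with correlation
#' `r_ind_true`, residuals with correlation `r_e_true`; marginal variances
#' come from `v_ind` / `v_e` (recycled to length 2).
#'
#' @param cfg a [trait_sim_config()] with `trait_pair_corr` set.
#' @param trait_names labels for the two traits.
#' @return long `data.frame` as in [simulate_trait_data()], two rows per
#'   (id, trial), one per trait.
#' @export
simulate_trait_pair <- function(cfg, trait_names = c("trait1", "trait2")) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  if (is.null(cfg$trait_pair_corr))
    stop("cfg$trait_pair_corr must be set for paired simulation")
  if (cfg$n_trials < 2)
    warning("n_trials < 2: repeatability is unidentifiable")
  set.seed(cfg$seed)
  vi <- rep(cfg$v_ind, length.out = 2)
  ve <- rep(cfg$v_e, length.out = 2)
  r_ind <- cfg$trait_pair_corr[1]; r_e <- cfg$trait_pair_corr[2]
  G <- diag(sqrt(vi)) %*% matrix(c(1, r_ind, r_ind, 1), 2) %*% diag(sqrt(vi))
  R <- diag(sqrt(ve)) %*% matrix(c(1, r_e, r_e, 1), 2) %*% diag(sqrt(ve))
  ind <- sim_individuals(cfg)
  d <- sim_design(cfg, ind)
  U <- rmvnorm2(cfg$n_individuals, G)
  rownames(U) <- ind$id
  E <- rmvnorm2(nrow(d), R)
  mu <- fixed_part(cfg, d)
  long <- rbind(
    transform(d, trait = trait_names[1], value = mu + U[d$id, 1] + E[, 1]),
    transform(d, trait = trait_names[2], value = mu + U[d$id, 2] + E[, 2]))
  long[order(long$id, long$trial, long$trait), , drop = FALSE]
}

# bivariate normal draws via Cholesky (allows semi-definite via eigen fallback)
rmvnorm2 <- function(n, Sigma) {
  L <- tryCatch(t(chol(Sigma)), error = function(e) {
    eg <- eigen(Sigma, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(Sigma))
  })
  t(L %*% matrix(rnorm(2 * n), 2, n))
}

#' Reshape a paired long trait table to wide format
#'
#' One row per (id, trial) with a column per trait, for `cbind()` responses
#' in [bt_lmm()].
#'
#' @param long output of [simulate_trait_pair()] (or any long trait table
#'   with exactly two traits per (id, trial)).
#' @return a wide `data.frame`.
#' @export
traits_to_wide <- function(long) {
  traits <- unique(long$trait)
  base_cols <- intersect(c("id", "trial", "sample", "length_cm",
                           "trial_c", "length_c"), names(long))
  wide <- unique(long[base_cols])
  for (tr in traits) {
    sub <- long[long$trait == tr, c("id", "trial", "value")]
    names(sub)[3] <- tr
    wide <- merge(wide, sub, by = c("id", "trial"), sort = TRUE)
  }
  wide[order(wide$id, wide$trial), , drop = FALSE]
}
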