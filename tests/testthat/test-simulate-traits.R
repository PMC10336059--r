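test_that("with no individual variance, variance of means is v_e / k", {
  cfg <- trait_sim_config(n_individuals = 5000, n_trials = 4,
                          v_ind = 0, v_e = 0.8, seed = 21)
  d <- simulate_trait_data(cfg)
  m <- tapply(d$value, d$id, mean)
  expect_lt(abs(var(m) / (0.8 / 4) - 1), 0.1)
})

test_that("empirical intraclass correlation matches the generative ratio", {
  cfg <- trait_sim_config(n_individuals = 5000, n_trials = 4,
                          v_ind = 0.5, v_e = 0.5, seed = 22)
  d <- simulate_trait_data(cfg)
  est <- anova_components(d$value, d$id)
  expect_lt(abs(est$icc - 0.5), 0.03)
})

test_that("moment estimator recovers R across configurations", {
  grid <- list(c(0.2, 0.8), c(0.5, 0.5), c(1.5, 0.5))
  for (g in grid) {
    cfg <- trait_sim_config(n_individuals = 5000, n_trials = 4,
                            v_ind = g[1], v_e = g[2], seed = 100 + g[1] * 10)
    d <- simulate_trait_data(cfg)
    est <- anova_components(d$value, d$id)
    expect_lt(abs(est$icc - g[1] / (g[1] + g[2])), 0.02)
  }
})

test_that("fixed effects and centering enter the simulated values", {
  cfg <- trait_sim_config(n_individuals = 2000, n_trials = 4,
                          v_ind = 0.1, v_e = 0.1,
                          beta = c(2, 0.5, 1, 0.3), seed = 30)
  d <- simulate_trait_data(cfg)
  expect_equal(mean(d$trial_c), 0)
  expect_equal(mean(d$length_c), 0)
  fit <- stats::lm(value ~ trial_c + length_c + sample, data = d)
  expect_lt(abs(coef(fit)[["trial_c"]] - 0.5), 0.05)
  expect_lt(abs(coef(fit)[["length_c"]] - 0.3), 0.05)
  # sample dummy is alphabetical (reared = reference): wild offset = -1
  expect_lt(abs(coef(fit)[["samplewild"]] + 1), 0.1)
})

test_that("trait simulation is deterministic under a fixed seed", {
  cfg <- trait_sim_config(n_individuals = 40, seed = 5)
  expect_identical(simulate_trait_data(cfg), simulate_trait_data(cfg))
  cfgp <- trait_sim_config(n_individuals = 40, trait_pair_corr = c(0.4, 0.1),
                           seed = 5)
  expect_identical(simulate_trait_pair(cfgp), simulate_trait_pair(cfgp))
})

test_that("single-trial designs warn about unidentifiable repeatability", {
  cfg <- trait_sim_config(n_individuals = 10, n_trials = 1, seed = 1)
  expect_warning(simulate_trait_data(cfg), "unidentifiable")
})

test_that("perfect individual correlation makes mean vectors collinear", {
  cfg <- trait_sim_config(n_individuals = 200, v_ind = 1, v_e = 1e-8,
                          trait_pair_corr = c(1, 0), seed = 40)
  w <- traits_to_wide(simulate_trait_pair(cfg))
  m1 <- tapply(w$trait1, w$id, mean)
  m2 <- tapply(w$trait2, w$id, mean)
  expect_gt(cor(m1, m2), 0.999)
})

test_that("between-individual correlation is recovered after shrinkage", {
  cfg <- trait_sim_config(n_individuals = 2000, n_trials = 4,
                          v_ind = 0.5, v_e = 0.5,
                          trait_pair_corr = c(0.6, 0), seed = 41)
  w <- traits_to_wide(simulate_trait_pair(cfg))
  k <- 4
  m1 <- tapply(w$trait1, w$id, mean); m2 <- tapply(w$trait2, w$id, mean)
  vi1 <- anova_components(w$trait1, w$id)$v_ind
  vi2 <- anova_components(w$trait2, w$id)$v_ind
  # with r_e = 0 the covariance of individual means estimates G12 directly
  r_hat <- cov(m1, m2) / sqrt(vi1 * vi2)
  expect_lt(abs(r_hat - 0.6), 0.05)
})

test_that("a doubly-null pair has no phenotypic correlation", {
  cfg <- trait_sim_config(n_individuals = 2000, n_trials = 4,
                          v_ind = 0.5, v_e = 0.5,
                          trait_pair_corr = c(0, 0), seed = 42)
  w <- traits_to_wide(simulate_trait_pair(cfg))
  expect_lt(abs(cor(w$trait1, w$trait2)), 0.03)
})

test_that("implied phenotypic correlation matches the two-level formula", {
  vi <- c(0.6, 0.3); ve <- c(0.4, 0.9); r_ind <- 0.5; r_e <- 0.3
  cfg <- trait_sim_config(n_individuals = 4000, n_trials = 4,
                          v_ind = vi, v_e = ve,
                          trait_pair_corr = c(r_ind, r_e), seed = 43)
  w <- traits_to_wide(simulate_trait_pair(cfg))
  r_p_expected <- (r_ind * sqrt(vi[1] * vi[2]) + r_e * sqrt(ve[1] * ve[2])) /
    sqrt((vi[1] + ve[1]) * (vi[2] + ve[2]))
  expect_lt(abs(cor(w$trait1, w$trait2) - r_p_expected), 0.03)
})

test_that("invalid pair configurations are rejected", {
  expect_error(trait_sim_config(trait_pair_corr = c(1.2, 0)), "<= 1")
  expect_error(trait_sim_config(v_ind = -1), "v_ind")
  cfg <- trait_sim_config(seed = 1)
  expect_error(simulate_trait_pair(cfg), "trait_pair_corr")
})
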