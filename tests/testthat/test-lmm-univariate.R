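sim_fit <- function(seed, n_id = 70, v_ind = 0.4, v_e = 0.6,
                    beta = c(0, 0.03, 0, 0), mcmc = bt_mcmc(seed = seed)) {
  cfg <- trait_sim_config(n_individuals = n_id, v_ind = v_ind, v_e = v_e,
                          beta = beta, seed = seed)
  d <- simulate_trait_data(cfg)
  bt_lmm(value ~ trial_c + length_c + sample, d, mcmc = mcmc)
}

test_that("the chain is bit-identical under a fixed seed", {
  f1 <- sim_fit(3, n_id = 25, mcmc = bt_mcmc(1500, 500, 5, seed = 8))
  f2 <- sim_fit(3, n_id = 25, mcmc = bt_mcmc(1500, 500, 5, seed = 8))
  expect_identical(f1$draws, f2$draws)
  f3 <- sim_fit(3, n_id = 25, mcmc = bt_mcmc(1500, 500, 5, seed = 9))
  expect_false(identical(f1$draws$v_e, f3$draws$v_e))
})

test_that("posterior recovers the generative variance components", {
  fit <- sim_fit(17)
  expect_gt(mean(fit$draws$v_ind), 0.25)
  expect_lt(mean(fit$draws$v_ind), 0.55)
  s <- summary(fit)
  bci <- s$fixed["trial_c", c("l.BCI", "u.BCI")]
  expect_true(bci[[1]] <= 0.03 && 0.03 <= bci[[2]])
})

test_that("posterior means agree with one-way ANOVA moment estimates", {
  cfg <- trait_sim_config(n_individuals = 200, v_ind = 0.5, v_e = 0.5,
                          seed = 19)
  d <- simulate_trait_data(cfg)
  fit <- bt_lmm(value ~ 1, d, mcmc = bt_mcmc(seed = 4))
  mom <- anova_components(d$value, d$id)
  expect_lt(abs(mean(fit$draws$v_ind) / mom$v_ind - 1), 0.1)
  expect_lt(abs(mean(fit$draws$v_e) / mom$v_e - 1), 0.1)
})

test_that("posterior means agree with REML on balanced data", {
  skip_if_not_installed("lme4")
  cfg <- trait_sim_config(n_individuals = 200, v_ind = 0.4, v_e = 0.6,
                          beta = c(1, 0.1, 0.3, 0), seed = 20)
  d <- simulate_trait_data(cfg)
  fit <- bt_lmm(value ~ trial_c + length_c + sample, d,
                mcmc = bt_mcmc(seed = 5))
  rfit <- lme4::lmer(value ~ trial_c + length_c + sample + (1 | id), d)
  vc <- as.data.frame(lme4::VarCorr(rfit))
  v_ind_reml <- vc$vcov[vc$grp == "id"]
  v_e_reml <- vc$vcov[vc$grp == "Residual"]
  expect_lt(abs(mean(fit$draws$v_ind) / v_ind_reml - 1), 0.1)
  expect_lt(abs(mean(fit$draws$v_e) / v_e_reml - 1), 0.1)
  expect_lt(max(abs(coef(fit) - lme4::fixef(rfit))), 0.05)
})

test_that("repeatability draws respect their bounds", {
  fit <- sim_fit(23, n_id = 30, mcmc = bt_mcmc(2000, 500, 5, seed = 1))
  est <- adjusted_repeatability(fit)
  expect_true(all(est$r_draws >= 0 & est$r_draws <= 1))
  expect_true(all(fit$draws$v_ind > 0))
  expect_true(all(fit$draws$v_e > 0))
  expect_lte(est$bci[1], est$r_mean + 1e-12)
  expect_gte(est$bci[2], est$r_mean - 1e-12)
})

test_that("doubling iterations and thinning leaves the posterior unmoved", {
  f1 <- sim_fit(29, n_id = 40, mcmc = bt_mcmc(6000, 1000, 5, seed = 2))
  f2 <- sim_fit(29, n_id = 40, mcmc = bt_mcmc(12000, 1000, 10, seed = 2))
  expect_lt(abs(mean(f1$draws$v_ind) - mean(f2$draws$v_ind)), 0.05)
  expect_lt(abs(mean(f1$draws$v_e) - mean(f2$draws$v_e)), 0.05)
})

test_that("pMCMC follows the two-sided tail definition", {
  expect_equal(pmcmc(c(-1, 1, 1, 1)), 0.5)
  expect_equal(pmcmc(rep(1, 200)), 1 / 200)      # floored at 1/n
  set.seed(77)
  expect_gt(pmcmc(rnorm(20000)), 0.95)           # symmetric null
  expect_error(pmcmc(1), "at least 2")
})

test_that("degenerate designs are rejected with informative errors", {
  cfg <- trait_sim_config(n_individuals = 20, seed = 2)
  d <- simulate_trait_data(cfg)
  d$dup <- d$trial_c * 2
  expect_error(bt_lmm(value ~ trial_c + dup, d, mcmc = bt_mcmc(seed = 1)),
               "collinear")
  d$const <- 1
  expect_error(bt_lmm(const ~ trial_c, d, mcmc = bt_mcmc(seed = 1)),
               "zero variance")
  one <- d[d$id == d$id[1], ]
  expect_error(bt_lmm(value ~ trial_c, one, mcmc = bt_mcmc(seed = 1)),
               "at least 2 individuals")
})

test_that("model methods are mutually consistent", {
  fit <- sim_fit(31, n_id = 30, mcmc = bt_mcmc(2000, 500, 5, seed = 3))
  expect_equal(length(coef(fit)), 4)
  r <- residuals(fit)
  expect_equal(as.numeric(fit$y), as.numeric(predict(fit) + r))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_output(print(fit), "Bayesian LMM")
  expect_output(print(summary(fit)), "Adjusted repeatability")
})
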