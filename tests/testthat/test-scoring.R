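test_that("perfectly correlated metrics load entirely on PC1", {
  set.seed(51)
  a <- rnorm(50)
  res <- pc1_score(cbind(m1 = a, m2 = 2 * a + 3), "m1")
  expect_equal(res$variance_fraction, 1)
})

test_that("independent equal-variance metrics split the variance evenly", {
  set.seed(52)
  res <- pc1_score(cbind(m1 = rnorm(20000), m2 = rnorm(20000)), "m1")
  expect_lt(abs(res$variance_fraction - 0.5), 0.05)
})

test_that("scores match a power-iteration eigen oracle", {
  set.seed(53)
  for (i in 1:20) {
    p <- sample(3:6, 1)
    n <- sample(30:80, 1)
    base <- matrix(rnorm(n * p), n, p)
    # induce correlation structure
    mat <- base %*% matrix(rnorm(p * p), p, p)
    colnames(mat) <- paste0("m", seq_len(p))
    res <- pc1_score(mat, "m1")
    oracle <- power_iteration_pc1(mat)
    expect_equal(res$variance_fraction, oracle$varfrac, tolerance = 1e-8)
    z <- scale(mat) %*% oracle$vector
    expect_gt(abs(cor(res$scores, z)), 1 - 1e-8)
  }
})

test_that("orientation forces a non-negative correlation with the anchor", {
  set.seed(54)
  for (i in 1:10) {
    mat <- matrix(rnorm(200), 50, 4,
                  dimnames = list(NULL, paste0("m", 1:4)))
    mat[, 1] <- mat[, 1] + rowMeans(mat[, 2:4])
    res <- pc1_score(mat, "m3")
    expect_gte(cor(res$scores, mat[, "m3"]), 0)
    expect_gte(res$loadings[["m3"]], 0)
  }
})

test_that("scores are invariant to affine rescaling of a metric", {
  set.seed(55)
  mat <- matrix(rnorm(300), 75, 4, dimnames = list(NULL, paste0("m", 1:4)))
  mat[, 2] <- mat[, 1] * 0.5 + mat[, 2]
  res1 <- pc1_score(mat, "m1")
  mat2 <- mat
  mat2[, 2] <- mat2[, 2] * 1000 - 7
  res2 <- pc1_score(mat2, "m1")
  expect_equal(res1$scores, res2$scores, tolerance = 1e-8)
  expect_equal(res1$variance_fraction, res2$variance_fraction,
               tolerance = 1e-10)
})

test_that("degenerate inputs are reported by name", {
  mat <- cbind(m1 = rnorm(10), m2 = rep(3, 10))
  expect_error(pc1_score(mat, "m1"), "m2")
  wide <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("m", 1:4)))
  expect_warning(pc1_score(wide, "m1"), "fewer rows")
  expect_error(pc1_score(cbind(m1 = rnorm(10)), "m1"), "at least 2")
})

make_metrics_table <- function(n_id = 8, n_trial = 4, seed = 56) {
  set.seed(seed)
  grid <- expand.grid(id = sprintf("i%02d", 1:n_id), trial = 1:n_trial,
                      stringsAsFactors = FALSE)
  tend <- rnorm(nrow(grid))  # shared tendency making metrics correlate
  rows <- list()
  add <- function(test, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = grid$id, trial = grid$trial, test = test, metric = metric,
      value = value)
  add("exploration", "approaches", round(exp(1 + tend)))
  add("exploration", "time_outside_s", 1800 + 500 * tend + rnorm(nrow(grid), 0, 100))
  add("exploration", "min_distance_px", 200 - 50 * tend + rnorm(nrow(grid), 0, 20))
  add("exploration", "interaction_time_s", pmax(0, 300 + 100 * tend))
  add("sociability", "time_outside_s", 1500 + 400 * tend)
  add("sociability", "min_distance_px", 250 - 60 * tend)
  add("sociability", "interaction_time_s", pmax(0, 200 + 80 * tend))
  add("boldness", "head_latency_s", exp(5 - tend))
  add("boldness", "body_latency_s", exp(5.2 - tend))
  add("boldness", "bite_latency_s", exp(5.5 - tend))
  add("activity", "time_outside_s", 4000 + 800 * tend)
  add("activity", "total_distance_px", 90000 + 20000 * tend)
  add("activity", "turn_mu_rad", rnorm(nrow(grid), 0, 0.1))
  add("activity", "turn_kappa", 1 + 0.3 * tend)
  add("activity", "area95_px2", 150000 + 30000 * tend)
  add("activity", "area50_px2", 40000 + 8000 * tend)
  add("aggressiveness", "approaches", round(exp(2 + tend)))
  do.call(rbind, rows)
}

test_that("axis matrices carry exactly the protocol metric sets", {
  met <- make_metrics_table()
  expl <- prepare_axis_inputs(met, "exploration")
  expect_equal(ncol(expl), 4)
  soc <- prepare_axis_inputs(met, "sociability")
  expect_equal(ncol(soc), 3)
  bold <- prepare_axis_inputs(met, "boldness")
  expect_equal(sort(colnames(bold)),
               sort(c("head_latency_s", "body_latency_s", "bite_latency_s")))
  act <- prepare_axis_inputs(met, "activity")
  expect_equal(ncol(act), 6)
  # negation: min distance flipped so larger = closer approach
  raw <- met[met$test == "exploration" & met$metric == "min_distance_px", ]
  key <- paste(raw$id, raw$trial, sep = ":")
  expect_equal(unname(expl[key, "min_distance_px"]), -raw$value)
  # latencies negated for boldness
  hl <- met[met$test == "boldness" & met$metric == "head_latency_s", ]
  expect_equal(unname(bold[paste(hl$id, hl$trial, sep = ":"),
                           "head_latency_s"]), -hl$value)
})

test_that("missing metrics are reported by name", {
  met <- make_metrics_table()
  met <- met[!(met$test == "activity" & met$metric == "turn_kappa"), ]
  expect_error(prepare_axis_inputs(met, "activity"), "turn_kappa")
  expect_error(prepare_axis_inputs(met, "grooming"), "unknown axis")
})

test_that("the log-shift transform applies only to the two skewed axes", {
  sc <- c(-2, -0.5, 0, 1.5)
  expect_identical(transform_for_lmm(sc, "activity"), sc)
  expect_identical(transform_for_lmm(sc, "boldness"), sc)
  tr <- transform_for_lmm(sc, "exploration")
  expect_equal(attr(tr, "shift"), 3)
  expect_equal(as.numeric(tr), log(sc + 3))
  expect_true(all(diff(tr) > 0))  # monotone
  expect_true(all(is.finite(tr)))
  same <- transform_for_lmm(rep(2, 5), "sociability")
  expect_equal(as.numeric(same), rep(0, 5))
})

test_that("score_axes returns oriented long scores for every axis", {
  met <- make_metrics_table()
  out <- score_axes(met)
  expect_setequal(unique(out$scores$axis),
                  c("exploration", "sociability", "boldness", "activity",
                    "aggressiveness"))
  expect_equal(sum(out$scores$axis == "activity"), 32)
  for (ax in names(out$pca)) {
    expect_gt(out$pca[[ax]]$variance_fraction, 0)
    expect_lte(out$pca[[ax]]$variance_fraction, 1)
  }
  # shared tendency means high variance fraction on the exploration axis
  expect_gt(out$pca$exploration$variance_fraction, 0.5)
})
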