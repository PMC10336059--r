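#' Behavioral-syndrome correlation decomposition
#'
#' Decomposes the phenotypic correlation between two traits into its
#' between-individual and within-individual (residual) levels, per
#' posterior draw of a bivariate fit:
#' \deqn{r_{ind} = G_{12}/\sqrt{G_{11}G_{22}}, \quad
#'       r_e = R_{12}/\sqrt{R_{11}R_{22}}, \quad
#'       r_p = (G_{12}+R_{12})/\sqrt{(G_{11}+R_{11})(G_{22}+R_{22})}}
#' A significant between-individual correlation (`dDIC > 2` against the
#' covariance-constrained refit) is the operational definition of a
#' behavioral syndrome.
#'
#' @param fit a bivariate [bt_lmm()] (unconstrained covariances).
#' @param fit0 the matching fit with `constrain_cov = TRUE`; optional --
#'   without it no `dDIC` is reported.
#' @return an object of class `bt_syndrome`: per-level posterior means,
#'   2.5%/97.5% BCIs, draws, `delta_dic` and `significant` when `fit0` is
#'   given.
#' @export
syndrome_estimate <- function(fit, fit0 = NULL) {
  stopifnot(inherits(fit, "bt_lmm"), fit$bivariate)
  if (fit$constrain_cov)
    stop("fit must be the unconstrained bivariate model")
  g <- fit$draws$v_ind; r <- fit$draws$v_e
  r_ind <- g[, "g12"] / sqrt(g[, "g11"] * g[, "g22"])
  r_e <- r[, "r12"] / sqrt(r[, "r11"] * r[, "r22"])
  r_p <- (g[, "g12"] + r[, "r12"]) /
    sqrt((g[, "g11"] + r[, "r11"]) * (g[, "g22"] + r[, "r22"]))
  summ <- function(x) c(mean = mean(x),
                        unname(quantile(x, c(0.025, 0.975))))
  out <- list(traits = fit$responses,
              r_ind = summ(r_ind), r_e = summ(r_e), r_p = summ(r_p),
              draws = list(r_ind = r_ind, r_e = r_e, r_p = r_p),
              dic_full = fit$dic)
  if (!is.null(fit0)) {
    stopifnot(inherits(fit0, "bt_lmm"), fit0$bivariate, fit0$constrain_cov)
    out$dic_constrained <- fit0$dic
    out$delta_dic <- fit0$dic - fit$dic
    out$significant <- out$delta_dic > 2
  }
  structure(out, class = "bt_syndrome")
}

#' @export
print.bt_syndrome <- function(x, ...) {
  cat(sprintf("Syndrome decomposition: %s -- %s\n",
              x$traits[1], x$traits[2]))
  fmt <- function(nm, s) sprintf("  %-5s %5.2f [%5.2f, %5.2f]\n",
                                 nm, s[1], s[2], s[3])
  cat(fmt("r_ind", x$r_ind), fmt("r_e", x$r_e), fmt("r_p", x$r_p), sep = "")
  if (!is.null(x$delta_dic))
    cat(sprintf("  dDIC (constrained - full): %.2f -> %ssignificant\n",
                x$delta_dic, if (x$significant) "" else "not "))
  invisible(x)
}

#' Fit and test a trait pair for a behavioral syndrome
#'
#' Convenience wrapper: fits the unconstrained bivariate model and the
#' covariance-constrained one, then calls [syndrome_estimate()].
#'
#' @inheritParams bt_lmm
#' @param mcmc MCMC settings; the syndrome-analysis convention is
#'   `bt_mcmc(100000, 10000, 100)`.
#' @return a `bt_syndrome` (with both fits attached as `fit` and `fit0`).
#' @export
bt_syndrome <- function(formula, data, random = ~id,
                        mcmc = bt_mcmc(100000, 10000, 100),
                        prior = bt_prior()) {
  fit <- bt_lmm(formula, data, random = random, mcmc = mcmc, prior = prior)
  fit0 <- bt_lmm(formula, data, random = random, mcmc = mcmc, prior = prior,
                 constrain_cov = TRUE)
  out <- syndrome_estimate(fit, fit0)
  out$fit <- fit
  out$fit0 <- fit0
  out
}

#' F-test for equality of variances between two samples
#'
#' `F` is the ratio of the larger to the smaller sample variance, with a
#' two-sided p-value from the F distribution on `(n - 1, m - 1)` degrees of
#' freedom. Used to compare the spread of per-individual mean trait values
#' between the wild and reared samples.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each), typically
#'   per-individual mean trait values per sample.
#' @return list with `statistic` (F), `df`, `p_value`, and `infinite`
#'   (TRUE when the denominator variance is zero).
#' @examples
#' variance_f_test(c(1, 2, 3), c(2, 4, 6))  # F = 4
#' @export
variance_f_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 values per group")
  va <- var(values_a); vb <- var(values_b)
  if (va >= vb) {
    num <- va; den <- vb; df <- c(length(values_a) - 1, length(values_b) - 1)
  } else {
    num <- vb; den <- va; df <- c(length(values_b) - 1, length(values_a) - 1)
  }
  if (den == 0)
    return(list(statistic = Inf, df = df, p_value = 0, infinite = TRUE))
  f <- num / den
  p <- min(1, 2 * pf(f, df[1], df[2], lower.tail = FALSE))
  list(statistic = f, df = df, p_value = p, infinite = FALSE)
}
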