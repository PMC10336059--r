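#' MCMC run settings
#'
#' Defaults follow the univariate analysis convention: 13,000 iterations,
#' 3,000 burn-in, thinning interval 10 (1,000 retained draws). Bivariate
#' syndrome models conventionally use `bt_mcmc(100000, 10000, 100)`.
#'
#' @param n_iter total iterations.
#' @param burn_in initial iterations discarded (< `n_iter`).
#' @param thin keep-every interval (>= 1).
#' @param seed integer seed making the chain bit-reproducible; `NULL` uses
#'   the current RNG state.
#' @return an object of class `bt_mcmc`.
#' @export
bt_mcmc <- function(n_iter = 13000, burn_in = 3000, thin = 10, seed = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "bt_mcmc")
}

#' Prior specification for the Gibbs sampler
#'
#' Near-flat defaults: fixed effects Gaussian with variance `beta_prior_var`
#' (1e10); univariate variance components inverse-gamma
#' `IG(nu/2, nu*V/2)` with `nu = 0.002`, `V = 1`; bivariate covariance
#' matrices inverse-Wishart with scale `iw_scale` (identity) and degrees of
#' freedom `dim - 1 + nu`.
#'
#' @param beta_prior_var prior variance of each fixed effect.
#' @param nu prior degrees-of-freedom parameter (> 0).
#' @param V univariate prior scale.
#' @param iw_scale 2x2 positive-definite inverse-Wishart scale matrix.
#' @return an object of class `bt_prior`.
#' @export
bt_prior <- function(beta_prior_var = 1e10, nu = 0.002, V = 1,
                     iw_scale = diag(2)) {
  if (beta_prior_var <= 0 || nu <= 0 || V <= 0)
    stop("beta_prior_var, nu and V must be positive")
  iw_scale <- as.matrix(iw_scale)
  ev <- eigen(iw_scale, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("iw_scale must be positive-definite")
  structure(list(beta_prior_var = beta_prior_var, nu = nu, V = V,
                 iw_scale = iw_scale), class = "bt_prior")
}

#' Bayesian linear mixed model with individual random intercepts
#'
#' Fits a Gaussian mixed model by Gibbs sampling with fully conjugate
#' blocks: fixed effects (Gaussian), individual random intercepts
#' (Gaussian), and variance components (scaled inverse-chi-square for
#' univariate responses; inverse-Wishart for the 2x2 between-individual `G`
#' and residual `R` covariance matrices of bivariate responses). A
#' two-column `cbind(y1, y2)` response fits the bivariate model used for
#' behavioral-syndrome decomposition.
#'
#' `random = NULL` drops the random intercept (the constrained model used
#' for repeatability DIC comparison); `constrain_cov = TRUE` fixes the
#' off-diagonals of `G` and `R` at zero (the constrained bivariate model
#' used for syndrome DIC comparison).
#'
#' @param formula model formula, e.g. `score ~ trial_c + length_c + sample`
#'   or `cbind(expl, act) ~ trial_c + sample`. An intercept is always kept.
#' @param data a `data.frame` containing the variables.
#' @param random one-sided formula naming the individual grouping factor
#'   (default `~ id`), or `NULL` for no random effect.
#' @param mcmc a [bt_mcmc()].
#' @param prior a [bt_prior()].
#' @param constrain_cov logical, bivariate only: constrain between- and
#'   within-individual covariances to zero.
#' @return an object of class `bt_lmm` with retained posterior draws
#'   (`$draws`: `beta`, `v_ind`, `v_e`, `deviance`), the DIC decomposition
#'   (`$dic`, `$pd`, `$dbar`), and posterior means used by `predict()` and
#'   `residuals()`.
#' @seealso [adjusted_repeatability()], [repeatability_significance()],
#'   [syndrome_estimate()], [dic()], [pmcmc()]
#' @examples
#' cfg <- trait_sim_config(n_individuals = 30, seed = 42)
#' d <- simulate_trait_data(cfg)
#' fit <- bt_lmm(value ~ trial_c + length_c + sample, d,
#'               mcmc = bt_mcmc(2000, 500, 5, seed = 1))
#' summary(fit)
#' @export
bt_lmm <- function(formula, data, random = ~id,
                   mcmc = bt_mcmc(), prior = bt_prior(),
                   constrain_cov = FALSE) {
  stopifnot(inherits(mcmc, "bt_mcmc"), inherits(prior, "bt_prior"))
  cl <- match.call()
  mf <- model.frame(formula, data)
  Y <- model.response(mf)
  bivariate <- is.matrix(Y)
  if (bivariate && ncol(Y) != 2)
    stop("multivariate responses are limited to 2 traits")
  X <- model.matrix(attr(mf, "terms"), mf)
  if (!"(Intercept)" %in% colnames(X))
    stop("the model must include an intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (bivariate) {
    if (any(apply(Y, 2, var) == 0)) stop("a response has zero variance")
  } else {
    if (var(Y) == 0) stop("response has zero variance")
  }

  include_random <- !is.null(random)
  if (include_random) {
    gvar <- all.vars(random)
    if (length(gvar) != 1)
      stop("random must name exactly one grouping factor")
    fid <- factor(data[[gvar]][match(rownames(mf), rownames(data))])
    if (anyNA(fid)) fid <- factor(data[[gvar]])
    if (length(fid) != nrow(X)) stop("grouping factor length mismatch")
    if (nlevels(fid) < 2) stop("need at least 2 individuals")
    if (max(table(fid)) < 2)
      stop("need repeated measures (>= 2 observations for some individual)")
    id0 <- as.integer(fid) - 1L
    nid <- nlevels(fid)
  } else {
    if (constrain_cov && !bivariate)
      stop("constrain_cov applies to bivariate models only")
    fid <- NULL
    id0 <- integer(nrow(X))
    nid <- 1L
  }

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  if (!bivariate) {
    raw <- gibbs_uni_cpp(as.numeric(Y), X, id0, nid,
                         mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                         prior$beta_prior_var, prior$nu, prior$V,
                         include_random)
    beta <- raw$beta
    colnames(beta) <- colnames(X)
    # DIC: deviance conditional on the random effects, pD = Dbar - D(theta_bar)
    fit_mean <- as.numeric(X %*% raw$beta_mean) +
      if (include_random) raw$u_mean[id0 + 1L] else 0
    dev_hat <- gauss_dev(as.numeric(Y) - fit_mean, raw$ve_mean)
    draws <- list(beta = beta,
                  v_ind = if (include_random) as.numeric(raw$v_ind),
                  v_e = as.numeric(raw$v_e),
                  deviance = as.numeric(raw$deviance))
    responses <- deparse(formula[[2]])
  } else {
    if (constrain_cov && !include_random)
      stop("constrained bivariate model still needs the random term")
    raw <- gibbs_biv_cpp(Y, X, id0, nid,
                         mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                         prior$beta_prior_var, prior$iw_scale,
                         ncol(Y) - 1 + prior$nu, prior$nu, prior$V,
                         constrain_cov)
    beta <- raw$beta
    responses <- colnames(Y)
    if (is.null(responses)) responses <- c("trait1", "trait2")
    colnames(beta) <- paste(rep(responses, each = ncol(X)),
                            rep(colnames(X), 2), sep = ".")
    E <- Y - X %*% raw$beta_mean - raw$u_mean[id0 + 1L, , drop = FALSE]
    dev_hat <- gauss_dev2(E, raw$r_mat_mean)
    draws <- list(beta = beta,
                  v_ind = raw$g, v_e = raw$r,
                  deviance = as.numeric(raw$deviance))
    colnames(draws$v_ind) <- c("g11", "g12", "g22")
    colnames(draws$v_e) <- c("r11", "r12", "r22")
  }

  dbar <- mean(draws$deviance)
  pd <- dbar - dev_hat
  out <- structure(list(
    call = cl, formula = formula, random = random,
    responses = responses, bivariate = bivariate,
    constrain_cov = constrain_cov,
    fixed_names = colnames(X),
    n = nrow(X), n_id = if (include_random) nid else 0L,
    id = fid, X = X, y = Y,
    mcmc = mcmc, prior = prior,
    draws = draws,
    beta_mean = raw$beta_mean, u_mean = if (include_random) raw$u_mean,
    dbar = dbar, pd = pd, dic = dbar + pd),
    class = "bt_lmm")
  out
}

gauss_dev <- function(e, ve) length(e) * log(2 * pi * ve) + sum(e^2) / ve

gauss_dev2 <- function(E, R) {
  Ri <- solve(R)
  nrow(E) * (2 * log(2 * pi) + log(det(R))) + sum((E %*% Ri) * E)
}

#' @export
print.bt_lmm <- function(x, digits = 3, ...) {
  kind <- if (x$bivariate) {
    if (x$constrain_cov) "bivariate (covariances constrained to 0)" else
      "bivariate"
  } else "univariate"
  cat(sprintf("Bayesian LMM (%s), %d obs", kind, x$n))
  if (x$n_id > 0) cat(sprintf(", %d individuals", x$n_id))
  cat(sprintf("\n  response: %s\n", paste(x$responses, collapse = ", ")))
  cat(sprintf("  retained draws: %d  DIC: %.2f (pD = %.2f)\n",
              length(x$draws$deviance), x$dic, x$pd))
  cat("  fixed effects (posterior means):\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.bt_lmm <- function(object, ...) {
  cm <- colMeans(object$draws$beta)
  if (object$bivariate) {
    p <- length(object$fixed_names)
    matrix(cm, ncol = 2, dimnames = list(object$fixed_names,
                                         object$responses))
  } else cm
}

#' @export
summary.bt_lmm <- function(object, ...) {
  b <- object$draws$beta
  fixed <- data.frame(
    post.mean = colMeans(b),
    l.BCI = apply(b, 2, quantile, 0.025),
    u.BCI = apply(b, 2, quantile, 0.975),
    pMCMC = apply(b, 2, pmcmc))
  vc <- if (object$bivariate) {
    g <- object$draws$v_ind; r <- object$draws$v_e
    data.frame(
      post.mean = c(colMeans(g), colMeans(r)),
      l.BCI = c(apply(g, 2, quantile, 0.025), apply(r, 2, quantile, 0.025)),
      u.BCI = c(apply(g, 2, quantile, 0.975), apply(r, 2, quantile, 0.975)),
      row.names = c("G[1,1]", "G[1,2]", "G[2,2]",
                    "R[1,1]", "R[1,2]", "R[2,2]"))
  } else if (!is.null(object$draws$v_ind)) {
    vi <- object$draws$v_ind; ve <- object$draws$v_e
    data.frame(
      post.mean = c(mean(vi), mean(ve)),
      l.BCI = c(quantile(vi, 0.025), quantile(ve, 0.025)),
      u.BCI = c(quantile(vi, 0.975), quantile(ve, 0.975)),
      row.names = c("V_ind", "V_e"))
  } else {
    ve <- object$draws$v_e
    data.frame(post.mean = mean(ve), l.BCI = quantile(ve, 0.025),
               u.BCI = quantile(ve, 0.975), row.names = "V_e")
  }
  rep_est <- if (!object$bivariate && !is.null(object$draws$v_ind))
    adjusted_repeatability(object) else NULL
  structure(list(fixed = fixed, vc = vc, repeatability = rep_est,
                 dic = object$dic, pd = object$pd,
                 responses = object$responses, bivariate = object$bivariate,
                 geweke = geweke_check(object)),
            class = "summary.bt_lmm")
}

#' @export
print.summary.bt_lmm <- function(x, digits = 3, ...) {
  cat("Fixed effects:\n")
  print(round(x$fixed, digits))
  cat("\nVariance components:\n")
  print(round(x$vc, digits))
  if (!is.null(x$repeatability)) {
    cat(sprintf("\nAdjusted repeatability: %.2f [%.2f, %.2f]\n",
                x$repeatability$r_mean, x$repeatability$bci[1],
                x$repeatability$bci[2]))
  }
  cat(sprintf("\nDIC: %.2f (pD = %.2f)\n", x$dic, x$pd))
  bad <- x$geweke[abs(x$geweke) > 2]
  if (length(bad))
    cat("Geweke |z| > 2 for:", paste(names(bad), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.bt_lmm <- function(object, newdata = NULL, re.form = NULL, ...) {
  if (is.null(newdata)) {
    fit <- object$X %*% object$beta_mean
    if (!is.null(object$u_mean) && is.null(re.form)) {
      u <- if (object$bivariate) object$u_mean[as.integer(object$id), ,
                                               drop = FALSE]
      else object$u_mean[as.integer(object$id)]
      fit <- fit + u
    }
  } else {
    tt <- delete.response(terms(object$formula))
    Xn <- model.matrix(tt, model.frame(tt, newdata))
    fit <- Xn %*% object$beta_mean
  }
  if (object$bivariate) {
    colnames(fit) <- object$responses
    fit
  } else as.numeric(fit)
}

#' @export
residuals.bt_lmm <- function(object, ...) {
  r <- object$y - predict(object)
  if (object$bivariate) colnames(r) <- object$responses
  r
}

#' @export
fitted.bt_lmm <- function(object, ...) predict(object)

#' Simulate response data from the fitted posterior
#'
#' Each replicate picks one retained posterior draw, redraws the random
#' intercepts and residuals from it, and returns the implied responses on
#' the original design -- a posterior-predictive simulation.
#'
#' @param object a fitted [bt_lmm()].
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data.frame (univariate: one column per replicate) or a list of
#'   matrices (bivariate).
#' @export
simulate.bt_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(object$draws$deviance)
  picks <- sample.int(k, nsim, replace = TRUE)
  id_idx <- if (!is.null(object$id)) as.integer(object$id)
  if (!object$bivariate) {
    out <- vapply(picks, function(j) {
      mu <- as.numeric(object$X %*% object$draws$beta[j, ])
      if (!is.null(id_idx)) {
        u <- rnorm(object$n_id, 0, sqrt(object$draws$v_ind[j]))
        mu <- mu + u[id_idx]
      }
      mu + rnorm(object$n, 0, sqrt(object$draws$v_e[j]))
    }, numeric(object$n))
    as.data.frame(out)
  } else {
    p <- length(object$fixed_names)
    lapply(picks, function(j) {
      B <- matrix(object$draws$beta[j, ], ncol = 2)
      G <- vech_to_mat(object$draws$v_ind[j, ])
      R <- vech_to_mat(object$draws$v_e[j, ])
      mu <- object$X %*% B
      if (!is.null(id_idx)) mu <- mu + rmvnorm2(object$n_id, G)[id_idx, ]
      out <- mu + rmvnorm2(object$n, R)
      colnames(out) <- object$responses
      out
    })
  }
}

vech_to_mat <- function(v) matrix(c(v[1], v[2], v[2], v[3]), 2)

#' @export
plot.bt_lmm <- function(x, ...) {
  draws <- if (x$bivariate) {
    cbind(x$draws$v_ind, x$draws$v_e)
  } else {
    cbind(V_ind = x$draws$v_ind, V_e = x$draws$v_e)
  }
  op <- graphics::par(mfrow = c(ncol(draws), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(ncol(draws))) {
    graphics::plot(draws[, j], type = "l", xlab = "", col = "grey30",
                   ylab = colnames(draws)[j],
                   main = if (j == 1) "variance-component traces" else "")
  }
  invisible(x)
}

# Geweke convergence diagnostic (first 10% vs last 50% of the chain),
# warning-only use; assumes thinned, weakly autocorrelated draws
geweke_check <- function(object) {
  mats <- list(beta = object$draws$beta)
  if (!is.null(object$draws$v_ind)) mats$v_ind <- object$draws$v_ind
  mats$v_e <- object$draws$v_e
  zs <- c()
  for (nm in names(mats)) {
    m <- as.matrix(mats[[nm]])
    if (is.null(colnames(m)))
      colnames(m) <- if (ncol(m) == 1) nm else paste0(nm, seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      n <- length(v)
      a <- v[seq_len(max(2, floor(0.1 * n)))]
      b <- v[seq.int(floor(0.5 * n) + 1, n)]
      z <- (mean(a) - mean(b)) /
        sqrt(var(a) / length(a) + var(b) / length(b))
      zs[colnames(m)[j]] <- z
    }
  }
  zs
}

#' Deviance information criterion of a fit
#'
#' Spiegelhalter's form `DIC = Dbar + pD`, `pD = Dbar - D(theta_bar)`, at a
#' configurable likelihood focus:
#' \describe{
#'   \item{conditional}{(default) deviance conditional on the random
#'     intercepts -- the convention of MCMC mixed-model software. Used for
#'     the repeatability and syndrome constraint comparisons.}
#'   \item{marginal}{random intercepts integrated out analytically
#'     (`y ~ N(X beta, Vu Z Z' + Ve I)`; univariate fits only). Because the
#'     conditional focus lets the intercepts absorb any between-individual
#'     covariate, fixed-term selection ([backward_reduce()]) uses the
#'     marginal focus, where such terms are visible.}
#' }
#'
#' @param object a fitted [bt_lmm()].
#' @param focus `"conditional"` or `"marginal"`.
#' @return the DIC (numeric scalar) with attributes `pd` and `dbar`.
#' @export
dic <- function(object, focus = c("conditional", "marginal")) {
  stopifnot(inherits(object, "bt_lmm"))
  focus <- match.arg(focus)
  if (focus == "conditional" || is.null(object$draws$v_ind) ||
      object$bivariate) {
    if (focus == "marginal" && object$bivariate)
      stop("marginal DIC is implemented for univariate fits")
    return(structure(object$dic, pd = object$pd, dbar = object$dbar))
  }
  dev <- marginal_deviance(object)
  dbar <- mean(dev$draws)
  pd <- dbar - dev$at_mean
  structure(dbar + pd, pd = pd, dbar = dbar)
}

# marginal Gaussian deviance for a random-intercept model, per draw and at
# the posterior means; uses the closed-form per-individual factorisation of
# V_i = Ve I + Vu J (Woodbury)
marginal_deviance <- function(object) {
  X <- object$X
  y <- as.numeric(object$y)
  id <- as.integer(object$id)
  ni <- tabulate(id)
  n <- length(y); q <- length(ni)
  B <- object$draws$beta
  vu <- object$draws$v_ind
  ve <- object$draws$v_e
  dev_of <- function(Bm, vum, vem) {
    R <- matrix(y, n, length(vem)) - X %*% t(Bm)   # n x k residuals
    S <- rowsum(R, id)                              # q x k group sums
    M <- outer(ni, vum)                             # q x k: n_i * vu_j
    VE <- matrix(vem, q, length(vem), byrow = TRUE)
    logdet <- (n - q) * log(vem) + colSums(log(VE + M))
    quad <- colSums(R^2) / vem -
      colSums(S^2 * matrix(vum, q, length(vum), byrow = TRUE) /
                (VE * (VE + M)))
    n * log(2 * pi) + logdet + quad
  }
  list(draws = dev_of(B, vu, ve),
       at_mean = dev_of(matrix(colMeans(B), 1), mean(vu), mean(ve)))
}

#' MCMC two-sided tail probability
#'
#' `2 * min(P(draw > 0), P(draw < 0))`, floored at `1/n_draws` (a chain can
#' never certify a smaller p).
#'
#' @param draws numeric vector of posterior draws.
#' @return probability in (0, 1\].
#' @export
pmcmc <- function(draws) {
  n <- length(draws)
  if (n < 2) stop("need at least 2 draws")
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  max(p, 1 / n)
}
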