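#' Adjusted repeatability from posterior variance draws
#'
#' Repeatability is the fraction of phenotypic variance attributable to
#' consistent between-individual differences,
#' `R = V_ind / (V_ind + V_e)`, computed per posterior draw after the fixed
#' effects have been controlled ("adjusted"). Reports the posterior mean of
#' the per-draw ratio, the 2.5%/97.5% credibility interval, and also the
#' plug-in ratio of posterior-mean variances (the two summaries differ
#' slightly; both are printed).
#'
#' @param object a fitted univariate [bt_lmm()] with a random term, or a
#'   numeric vector of `V_ind` draws.
#' @param v_e numeric vector of `V_e` draws (when `object` is a vector).
#' @param ... unused.
#' @return an object of class `bt_repeatability`: `r_mean`, `bci`,
#'   `r_plugin`, `r_draws`, `n_draws`.
#' @examples
#' # degenerate single-draw plug-in
#' adjusted_repeatability(0.66, 0.95)  # R = 0.41
#' @export
adjusted_repeatability <- function(object, ...) UseMethod("adjusted_repeatability")

#' @rdname adjusted_repeatability
#' @export
adjusted_repeatability.bt_lmm <- function(object, ...) {
  if (object$bivariate)
    stop("adjusted_repeatability is defined for univariate fits")
  if (is.null(object$draws$v_ind))
    stop("fit has no random term; repeatability undefined")
  adjusted_repeatability.default(object$draws$v_ind, object$draws$v_e)
}

#' @rdname adjusted_repeatability
#' @export
adjusted_repeatability.default <- function(object, v_e, ...) {
  v_ind <- as.numeric(object)
  stopifnot(length(v_ind) == length(v_e), all(v_ind >= 0), all(v_e > 0))
  r <- v_ind / (v_ind + v_e)
  structure(list(r_mean = mean(r),
                 bci = unname(quantile(r, c(0.025, 0.975))),
                 r_plugin = mean(v_ind) / (mean(v_ind) + mean(v_e)),
                 r_draws = r, n_draws = length(r)),
            class = "bt_repeatability")
}

#' @export
print.bt_repeatability <- function(x, ...) {
  cat(sprintf("Adjusted repeatability: %.2f [%.2f, %.2f] (%d draws)\n",
              x$r_mean, x$bci[1], x$bci[2], x$n_draws))
  cat(sprintf("  plug-in ratio of posterior-mean variances: %.2f\n",
              x$r_plugin))
  if (!is.null(x$delta_dic))
    cat(sprintf("  dDIC (constrained - full): %.2f -> %ssignificant\n",
                x$delta_dic, if (x$significant) "" else "not "))
  invisible(x)
}

#' Repeatability with DIC-based significance
#'
#' Fits the full model and the constrained model with the individual random
#' intercept removed; a DIC reduction larger than 2 for the full model
#' (`dDIC = DIC_constrained - DIC_full > 2`) flags the repeatability as
#' significant.
#'
#' @inheritParams bt_lmm
#' @return a `bt_repeatability` augmented with `delta_dic`, `significant`,
#'   `dic_full`, `dic_constrained`, and the two fits (`fit`, `fit0`).
#' @export
repeatability_significance <- function(formula, data, random = ~id,
                                       mcmc = bt_mcmc(), prior = bt_prior()) {
  fit <- bt_lmm(formula, data, random = random, mcmc = mcmc, prior = prior)
  fit0 <- bt_lmm(formula, data, random = NULL, mcmc = mcmc, prior = prior)
  est <- adjusted_repeatability(fit)
  est$dic_full <- fit$dic
  est$dic_constrained <- fit0$dic
  est$delta_dic <- fit0$dic - fit$dic
  est$significant <- est$delta_dic > 2
  est$fit <- fit
  est$fit0 <- fit0
  est
}

#' Backward model reduction by DIC
#'
#' Step-by-step backward elimination of fixed effects: at each step the
#' single term whose removal lowers the DIC the most is dropped; the search
#' stops when no removal lowers the DIC. The intercept and the random term
#' are never removed. Ties within `tie_tol` are broken deterministically in
#' favour of the term listed later in the formula.
#'
#' @inheritParams bt_lmm
#' @param tie_tol DIC difference treated as a tie (default 0.01).
#' @param focus DIC likelihood focus (see [dic()]); the default
#'   `"marginal"` makes between-individual covariates visible to the
#'   selection, which the conditional focus cannot (the random intercepts
#'   absorb them).
#' @return list with `formula` (the reduced formula), `fit` (the final
#'   [bt_lmm()]), and `history` (a data.frame of steps and DICs).
#' @export
backward_reduce <- function(formula, data, random = ~id,
                            mcmc = bt_mcmc(), prior = bt_prior(),
                            tie_tol = 0.01,
                            focus = c("marginal", "conditional")) {
  focus <- match.arg(focus)
  if (is.null(random)) focus <- "conditional"
  terms_now <- attr(terms(formula), "term.labels")
  lhs <- deparse(formula[[2]])
  refit <- function(tl) {
    f <- if (length(tl)) reformulate(tl, response = lhs)
    else as.formula(paste(lhs, "~ 1"))
    environment(f) <- environment(formula)
    fit <- bt_lmm(f, data, random = random, mcmc = mcmc, prior = prior)
    list(fit = fit, dic = as.numeric(dic(fit, focus = focus)))
  }
  cur <- refit(terms_now)
  history <- data.frame(step = 0L, action = "full",
                        formula = deparse(cur$fit$formula), dic = cur$dic)
  step <- 0L
  while (length(terms_now) > 0) {
    cand <- lapply(seq_along(terms_now),
                   function(j) refit(terms_now[-j]))
    improve <- cur$dic - vapply(cand, `[[`, numeric(1), "dic")
    best <- max(improve)
    if (best <= 0) break
    # deterministic tie-break: later-listed term wins
    drop_j <- max(which(improve >= best - tie_tol))
    step <- step + 1L
    dropped <- terms_now[drop_j]
    terms_now <- terms_now[-drop_j]
    cur <- cand[[drop_j]]
    history <- rbind(history, data.frame(
      step = step, action = paste("drop", dropped),
      formula = deparse(cur$fit$formula), dic = cur$dic))
  }
  list(formula = cur$fit$formula, fit = cur$fit, history = history)
}
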