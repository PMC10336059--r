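#' Von Mises random deviates
#'
#' Best–Fisher rejection sampler. With `kappa = 0` angles are uniform on
#' (-pi, pi].
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @references Best, D.J. & Fisher, N.I. (1979) Efficient simulation of the
#'   von Mises distribution. Applied Statistics 28, 152-157.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi)))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nt <- sum(ok)
    if (nt) {
      take <- min(nt, n - got)
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take)] <- sign(u3[idx] - 0.5) * acos(f[idx]) + mu
      got <- got + take
    }
  }
  wrap_angle(out)
}

# wrap to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# ratio I1(kappa)/I0(kappa), numerically safe for large kappa
besselI_ratio <- function(kappa) {
  if (kappa > 700) return(1 - 1 / (2 * kappa) - 1 / (8 * kappa^2))
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Von Mises maximum-likelihood fit for turning angles
#'
#' Circular mean for the direction and ML concentration obtained by
#' inverting the mean-resultant-length equation A1(kappa) = rbar: the
#' closed-form approximation of Fisher (1993) followed by Newton refinement
#' on the Bessel-function ratio. The MLE diverges as rbar -> 1, so kappa is
#' capped at `kappa_ceiling` and flagged.
#'
#' @param angles numeric vector of angles in radians (>= 2 values).
#' @param kappa_ceiling cap for the concentration estimate (default 500).
#' @return list with `mu` (circular mean, radians in (-pi, pi]), `kappa`,
#'   `rbar` (mean resultant length), `n`, and logical `capped`.
#' @export
fit_von_mises <- function(angles, kappa_ceiling = 500) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 2) stop("fit_von_mises needs at least 2 angles")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  if (rbar >= 1 - 1e-12)
    return(list(mu = mu, kappa = kappa_ceiling, rbar = rbar, n = n,
                capped = TRUE))
  # Fisher (1993) piecewise approximation of A1^{-1}
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  k <- max(k, 0)
  # Newton steps on A1(k) - rbar = 0; A1'(k) = 1 - A1/k - A1^2
  for (it in 1:25) {
    if (k <= 0) { k <- 0; break }
    A1 <- besselI_ratio(k)
    dA <- 1 - A1 / k - A1^2
    if (!is.finite(dA) || abs(dA) < 1e-14) break
    step <- (A1 - rbar) / dA
    k_new <- k - step
    if (!is.finite(k_new)) break
    if (k_new < 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * (1 + k)) { k <- k_new; break }
    k <- k_new
  }
  capped <- k > kappa_ceiling
  list(mu = mu, kappa = min(k, kappa_ceiling), rbar = rbar, n = n,
       capped = capped)
}
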