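# Tail probabilities of positive linear combinations of 1-df chi-squares,
# Q ~ sum_j lambda_j chisq_1. Used for the SKAT / SKAT-O null distributions.
#
# Primary route: inversion of the characteristic function (the Imhof-form
# integral, the quantity Davies' algorithm computes), evaluated by a
# vectorized composite Simpson rule with interval doubling until the
# Richardson error estimate meets the tolerance. The truncation point of
# the infinite integral is chosen from an integration-by-parts bound that
# exploits the oscillatory cancellation of the sin term. Equal-weight
# spectra (including the single-eigenvalue case) are evaluated exactly as
# scaled chi-squares. Fallback on non-convergence: Liu-Tang-Zhang moment
# matching to a noncentral chi-square, flagged on the result.

#' Upper tail of a mixture of 1-df chi-squares
#'
#' Computes P(sum_j lambda_j X_j > q) with X_j iid chi-square(1), by
#' characteristic-function inversion with a moment-matching fallback.
#' The default tolerance 1e-6 matches common practice for this inversion;
#' eigenvalues below 1e-7 of the largest are dropped (their contribution
#' is below the tolerance).
#'
#' @param q quantile (scalar).
#' @param lambda positive mixture weights (eigenvalues).
#' @param method `"auto"` (inversion, falling back to moment matching),
#'   `"imhof"`, or `"liu"`.
#' @param abs.tol absolute tolerance for the inversion integral.
#' @return p-value in [0, 1], with attribute `fallback` (logical) marking
#'   whether the moment-matching route was used.
#' @export
pchisq_mixture <- function(q, lambda, method = c("auto", "imhof", "liu"),
                           abs.tol = 1e-6) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  lambda <- lambda[lambda > max(lambda, 0) * 1e-7]
  if (length(lambda) == 0L || q <= 0)
    return(structure(1, fallback = FALSE))
  if (method == "liu")
    return(structure(liu_pvalue(q, lambda), fallback = FALSE))
  # equal weights: exactly a scaled chi-square
  if (diff(range(lambda)) <= max(lambda) * 1e-12)
    return(structure(
      stats::pchisq(q / lambda[1L], df = length(lambda), lower.tail = FALSE),
      fallback = FALSE))
  p <- imhof_pvalue(q, lambda, abs.tol = abs.tol)
  if (is.na(p)) {
    if (method == "imhof") method_error("characteristic-function inversion failed")
    return(structure(liu_pvalue(q, lambda), fallback = TRUE))
  }
  structure(p, fallback = FALSE)
}

# Imhof (1961) representation of the inversion integral:
#   P(Q > q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u)) / (u * rho(u)) du
# with theta(u) = (1/2) sum arctan(lambda_j u) - q u / 2 and
# rho(u) = prod (1 + lambda_j^2 u^2)^(1/4).
imhof_pvalue <- function(q, lambda, abs.tol = 1e-6) {
  s <- max(lambda)
  lam <- lambda / s
  q <- q / s
  m <- length(lam)
  envelope <- function(u) {
    exp(-log(pi * u) - 0.25 * colSums(log1p(outer(lam^2, u^2))))
  }
  # truncation: after integrating the sin term by parts, the tail beyond U
  # is bounded by ~ 4 * envelope(U) / q (theta'(u) -> -q/2 for large u)
  u_try <- 10^seq(0, 9, by = 0.25)
  tail_bound <- envelope(u_try) * (4 / max(q, 0.05) + 1 / u_try)
  iU <- which(tail_bound < abs.tol / 2)
  if (length(iU) == 0L) return(NA_real_)
  U <- u_try[iU[1L]]
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lam, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lam^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lam) - q)  # limit u -> 0
    out
  }
  # grid resolution follows the oscillation count q*U/(4*pi)
  n_cycles <- q * U / (4 * pi) + m / 4 + 1
  N <- 2^min(max(ceiling(log2(n_cycles * 16)), 9), 14)
  simpson <- function(N) {
    h <- U / N
    u <- seq(0, U, length.out = N + 1L)
    f <- numeric(N + 1L)
    # chunked evaluation keeps the outer() workspace bounded for large m
    chunk <- max(1024L, 2^18 %/% m)
    for (i0 in seq(1L, N + 1L, by = chunk)) {
      i1 <- min(i0 + chunk - 1L, N + 1L)
      f[i0:i1] <- integrand(u[i0:i1])
    }
    h / 3 * (f[1L] + f[N + 1L] + 4 * sum(f[seq(2L, N, by = 2L)]) +
               2 * sum(f[seq(3L, N - 1L, by = 2L)]))
  }
  S <- simpson(N)
  repeat {
    N <- N * 2L
    if (N > 2^20) return(NA_real_)
    S2 <- simpson(N)
    err <- abs(S2 - S) / 15
    S <- S2
    if (err < abs.tol / 2) break
  }
  p <- 0.5 + S / pi
  if (p < -1e-4 || p > 1 + 1e-4) return(NA_real_)
  min(max(p, 0), 1)
}

# Tail of a general (signed) quadratic form in iid standard normals,
#   P(sum_r lambda_r chisq_{df_r} > q),
# by the same Imhof inversion with per-term degrees of freedom. Used for
# the exact finite-sample gaussian SKAT p-value, where the event
# {Q / sigma-hat^2 >= t} is equivalent to a signed quadratic form being
# nonnegative (the scale parameter cancels, so the result is pivotal).
pquadform_signed <- function(q, lambda, df) {
  keep <- abs(lambda) > max(abs(lambda)) * 1e-12 & df > 0
  lambda <- lambda[keep]; df <- df[keep]
  if (length(lambda) == 0L) return(if (q < 0) 1 else 0)
  s <- max(abs(lambda))
  lam <- lambda / s
  q <- q / s
  envelope <- function(u)
    exp(-log(pi * u) - 0.25 * colSums(df * log1p(outer(lam^2, u^2))))
  u_try <- 10^seq(-2, 9, by = 0.25)
  tail_bound <- envelope(u_try) * (4 / max(abs(q), 0.05) + 1 / u_try)
  iU <- which(tail_bound < 1e-8)
  if (length(iU) == 0L) return(NA_real_)
  U <- u_try[iU[1L]]
  integrand <- function(u) {
    theta <- 0.5 * colSums(df * atan(outer(lam, u))) - q * u / 2
    rho <- exp(0.25 * colSums(df * log1p(outer(lam^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(df * lam) - q)
    out
  }
  n_cycles <- abs(q) * U / (4 * pi) + sum(df) / 4 + 1
  N <- 2^min(max(ceiling(log2(n_cycles * 16)), 9), 14)
  simpson <- function(N) {
    u <- seq(0, U, length.out = N + 1L)
    f <- integrand(u)
    h <- U / N
    h / 3 * (f[1L] + f[N + 1L] + 4 * sum(f[seq(2L, N, by = 2L)]) +
               2 * sum(f[seq(3L, N - 1L, by = 2L)]))
  }
  S <- simpson(N)
  repeat {
    N <- N * 2L
    if (N > 2^20) return(NA_real_)
    S2 <- simpson(N)
    err <- abs(S2 - S) / 15
    S <- S2
    if (err < 5e-7) break
  }
  p <- 0.5 + S / pi
  if (p < -1e-4 || p > 1 + 1e-4) return(NA_real_)
  min(max(p, 0), 1)
}

# Liu-Tang-Zhang (2009) moment matching, with the modification matching
# skewness when possible, else kurtosis (common SKAT practice).
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  list(mu_q = c1, sigma_q = sqrt(2 * c2),
       mu_x = l + d, sigma_x = sqrt(2) * sqrt(l + 2 * d),
       df = l, ncp = d)
}

liu_pvalue <- function(q, lambda) {
  pp <- liu_params(lambda)
  tstar <- (q - pp$mu_q) / pp$sigma_q
  qx <- tstar * pp$sigma_x + pp$mu_x
  stats::pchisq(qx, df = pp$df, ncp = pp$ncp, lower.tail = FALSE)
}

# Moment-matched quantile: q with P(Q > q) ~= p. Used to map the SKAT-O
# minimum p-value back to per-rho critical values.
liu_quantile <- function(p, lambda) {
  pp <- liu_params(lambda)
  qx <- stats::qchisq(p, df = pp$df, ncp = pp$ncp, lower.tail = FALSE)
  (qx - pp$mu_x) / pp$sigma_x * pp$sigma_q + pp$mu_q
}
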