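# Bivariate copulas (Frank, Plackett, Gauss) used by the sub-modality and
# probability transitions. The discrete construction follows the
# rectangle-difference approach: joint probabilities are differences of the
# copula CDF evaluated at the cumulative margins, and the copula parameter is
# calibrated so the Pearson correlation of the two rank variables under the
# joint pmf matches a requested target.

copula_families <- c("frank", "plackett", "gauss")

# Frank copula CDF for theta > 0, computed in log space so large theta does
# not overflow or lose the tiny survival mass:
# C = -(1/theta) * [log(e^-tu + e^-tv - e^-t(u+v) - e^-t) - log(1 - e^-t)].
frank_cdf_pos <- function(u, v, theta) {
  m <- pmin(theta * u, theta * v)
  s <- exp(m - theta * u) + exp(m - theta * v) -
    exp(m - theta * (u + v)) - exp(m - theta)
  s <- pmax(s, 0)
  out <- -(-m + log(s) - log1p(-exp(-theta))) / theta
  out[s == 0] <- 0
  pmin(pmax(out, 0), pmin(u, v))
}

# Standard bivariate normal CDF by conditioning: integrate phi(x) * Phi((y - rho x)/s).
pbinorm <- function(x, y, rho) {
  s <- sqrt(max(1 - rho^2, 1e-16))
  mapply(function(xi, yi) {
    if (!is.finite(xi) && xi > 0) xi <- 8.5
    if (!is.finite(yi) && yi > 0) yi <- 8.5
    if (xi < -8.5 || yi < -8.5) return(0)
    stats::integrate(function(t) stats::dnorm(t) * stats::pnorm((yi - rho * t) / s),
                     lower = -8.5, upper = min(xi, 8.5),
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, x, y)
}

#' Copula CDF
#'
#' Evaluates C(u, v; theta) for the Frank, Plackett or Gauss family. Values
#' of theta at the independence point (0 for Frank/Gauss, 1 for Plackett)
#' return u*v.
#'
#' @param u,v numeric vectors in [0, 1] (recycled).
#' @param family one of `"frank"`, `"plackett"`, `"gauss"`.
#' @param theta copula parameter: Frank, any real; Plackett, positive;
#'   Gauss, correlation in (-1, 1).
#' @return numeric vector of copula values.
#' @export
copula_cdf <- function(u, v, family, theta) {
  family <- match.arg(family, copula_families)
  u <- pmin(pmax(u, 0), 1); v <- pmin(pmax(v, 0), 1)
  switch(family,
    frank = {
      if (abs(theta) < 1e-10) return(u * v)
      if (theta > 0) frank_cdf_pos(u, v, theta) else
        v - frank_cdf_pos(1 - u, v, -theta) # reflection: Frank(-t) ~ (1-U, V)
    },
    plackett = {
      if (theta <= 0) stopf("plackett theta must be positive")
      if (abs(theta - 1) < 1e-10) return(u * v)
      S <- 1 + (theta - 1) * (u + v)
      (S - sqrt(pmax(S^2 - 4 * theta * (theta - 1) * u * v, 0))) / (2 * (theta - 1))
    },
    gauss = {
      if (abs(theta) >= 1) stopf("gauss theta must lie in (-1, 1)")
      if (abs(theta) < 1e-12) return(u * v)
      pbinorm(stats::qnorm(u), stats::qnorm(v), theta)
    })
}

#' Conditional copula CDF
#'
#' The conditional distribution function of V given U = u,
#' `h(v | u) = dC(u, v)/du`. Used for conditional sampling and for
#' probability-integral-transform diagnostics.
#'
#' @inheritParams copula_cdf
#' @return numeric vector of conditional CDF values in [0, 1].
#' @export
copula_conditional_cdf <- function(v, u, family, theta) {
  family <- match.arg(family, copula_families)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  v <- pmin(pmax(v, 0), 1)
  switch(family,
    frank = {
      if (abs(theta) < 1e-10) return(v)
      if (theta > 0) {
        a <- exp(-theta * u); b <- exp(-theta * v); E <- exp(-theta)
        # h = a(1-b) / (a + b - ab - E); all terms positive for theta > 0
        a * (1 - b) / pmax(a + b - a * b - E, 1e-300)
      } else {
        1 - copula_conditional_cdf(1 - v, u, "frank", -theta)
      }
    },
    plackett = {
      if (theta <= 0) stopf("plackett theta must be positive")
      if (abs(theta - 1) < 1e-10) return(v)
      S <- 1 + (theta - 1) * (u + v)
      0.5 * (1 - (S - 2 * theta * v) /
               sqrt(pmax(S^2 - 4 * theta * (theta - 1) * u * v, 1e-300)))
    },
    gauss = {
      if (abs(theta) >= 1) stopf("gauss theta must lie in (-1, 1)")
      stats::pnorm((stats::qnorm(v) - theta * stats::qnorm(u)) /
                     sqrt(1 - theta^2))
    })
}

#' Sample V conditional on U = u under a copula
#'
#' Draws one v per element of `u` from the conditional law dC(u, v)/du. The
#' Frank and Gauss families use closed-form inverses; Plackett inverts the
#' conditional CDF by vectorized bisection. With uniform `u` the marginal of
#' the output is uniform.
#'
#' @param u numeric vector in [0, 1].
#' @inheritParams copula_cdf
#' @param seed optional integer seed.
#' @return numeric vector in [0, 1], same length as `u`.
#' @export
copula_conditional_sample <- function(u, family, theta, seed = NULL) {
  family <- match.arg(family, copula_families)
  w <- with_seed(seed, stats::runif(length(u)))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  switch(family,
    frank = {
      if (abs(theta) < 1e-10) return(w)
      # inverse conditional: e^{-theta v} = (a(1-w) + wE) / (a(1-w) + w)
      a <- exp(-theta * u); E <- exp(-theta)
      num <- a * (1 - w) + w * E
      den <- a * (1 - w) + w
      pmin(pmax(-(log(num) - log(den)) / theta, 0), 1)
    },
    plackett = {
      if (theta <= 0) stopf("plackett theta must be positive")
      if (abs(theta - 1) < 1e-10) return(w)
      lo <- rep(0, length(u)); hi <- rep(1, length(u))
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        below <- copula_conditional_cdf(mid, u, "plackett", theta) < w
        lo[below] <- mid[below]
        hi[!below] <- mid[!below]
      }
      (lo + hi) / 2
    },
    gauss = {
      if (abs(theta) >= 1) stopf("gauss theta must lie in (-1, 1)")
      z <- stats::qnorm(w)
      stats::pnorm(theta * stats::qnorm(u) + sqrt(1 - theta^2) * z)
    })
}

# -- Spearman's rho of the copula (= Pearson correlation of uniform margins) --

debye <- function(k, x) {
  if (x == 0) return(1)
  (k / x^k) * stats::integrate(function(t) t^k / expm1(t), 0, x,
                               rel.tol = 1e-10)$value
}

copula_spearman <- function(family, theta) {
  family <- match.arg(family, copula_families)
  switch(family,
    frank = {
      if (abs(theta) < 1e-10) return(0)
      s <- sign(theta); th <- abs(theta)
      s * (1 - 12 * (debye(1, th) - debye(2, th)) / th)
    },
    plackett = {
      if (abs(theta - 1) < 1e-10) return(0)
      (theta + 1) / (theta - 1) - 2 * theta * log(theta) / (theta - 1)^2
    },
    gauss = (6 / pi) * asin(theta / 2))
}

# Calibrate theta so that, with uniform margins, cor(U, V) equals `rho`.
copula_theta_for_uniform_corr <- function(family, rho) {
  family <- match.arg(family, copula_families)
  if (abs(rho) >= 1) stopf("target correlation must lie in (-1, 1)")
  if (abs(rho) < 1e-12) return(switch(family, frank = 0, plackett = 1, gauss = 0))
  switch(family,
    gauss = 2 * sin(pi * rho / 6),
    frank = stats::uniroot(function(th) copula_spearman("frank", th) - rho,
                           lower = -300, upper = 300, tol = 1e-10)$root,
    plackett = exp(stats::uniroot(
      function(lt) copula_spearman("plackett", exp(lt)) - rho,
      lower = -35, upper = 35, tol = 1e-10)$root))
}

# -- discrete copula joint ----------------------------------------------------

# Pearson correlation of the two integer rank variables under a joint pmf.
joint_rank_correlation <- function(joint) {
  r1 <- seq_len(nrow(joint)); r2 <- seq_len(ncol(joint))
  p1 <- rowSums(joint); p2 <- colSums(joint)
  m1 <- sum(r1 * p1); m2 <- sum(r2 * p2)
  v1 <- sum(r1^2 * p1) - m1^2; v2 <- sum(r2^2 * p2) - m2^2
  if (v1 <= 1e-15 || v2 <= 1e-15) return(0)
  (as.numeric(r1 %*% joint %*% r2) - m1 * m2) / sqrt(v1 * v2)
}

# Joint pmf from rectangle differences of a copula CDF on cumulative margins.
joint_from_cdf <- function(F1, F2, cdf_fun) {
  C <- outer(c(0, F1), c(0, F2), cdf_fun)
  n1 <- length(F1); n2 <- length(F2)
  J <- C[-1, -1, drop = FALSE] - C[-(n1 + 1), -1, drop = FALSE] -
    C[-1, -(n2 + 1), drop = FALSE] + C[-(n1 + 1), -(n2 + 1), drop = FALSE]
  pmax(J, 0)
}

theta_range <- function(family) {
  switch(family, frank = c(-300, 300), plackett = log(c(1e-14, 1e14)),
         gauss = c(-0.99999, 0.99999))
}

theta_from_par <- function(family, par) if (family == "plackett") exp(par) else par

#' Fit a discrete copula joint to a target rank correlation
#'
#' Couples two pmfs over ranks 1..N1 and 1..N2 into a joint pmf via rectangle
#' differences of a copula CDF evaluated at the cumulative margins, and
#' calibrates the copula parameter so the exact Pearson correlation of the
#' two rank variables under the joint matches `target_correlation`. Targets
#' outside the attainable (Frechet) range for the given margins are clamped
#' to the bound with a warning, never silently.
#'
#' @param margin1,margin2 probability vectors (pmfs over ranks).
#' @param family copula family: `"frank"`, `"plackett"` or `"gauss"`.
#' @param target_correlation requested Pearson correlation in (-1, 1).
#' @return an object of class `discrete_copula_joint`: list with `joint`
#'   (N1 x N2 matrix), `conditional` (rows: P(V = v | U = u)), `fitted_theta`,
#'   `achieved_correlation`, `clamped`.
#' @examples
#' fit_discrete_copula(rep(0.25, 4), rep(0.25, 4), "frank", 0.9)
#' @export
fit_discrete_copula <- function(margin1, margin2, family, target_correlation) {
  family <- match.arg(family, copula_families)
  check_prob_vector(margin1, "margin1")
  check_prob_vector(margin2, "margin2")
  if (abs(target_correlation) >= 1) {
    stopf("target correlation must lie in (-1, 1)")
  }
  finish <- function(joint, theta, clamped = FALSE) {
    cond <- joint / pmax(rowSums(joint), 1e-300)
    structure(list(joint = joint, conditional = cond, fitted_theta = theta,
                   achieved_correlation = joint_rank_correlation(joint),
                   clamped = clamped),
              class = "discrete_copula_joint")
  }
  indep <- outer(margin1, margin2)
  # degenerate margins carry no correlation to match
  degen <- function(p) sum(p > 1e-15) < 2L
  if (degen(margin1) || degen(margin2)) return(finish(indep, NA_real_))
  if (abs(target_correlation) < 1e-12) {
    th0 <- switch(family, frank = 0, plackett = 1, gauss = 0)
    return(finish(indep, th0))
  }
  F1 <- pmin(cumsum(margin1), 1); F2 <- pmin(cumsum(margin2), 1)
  # attainable range under the Frechet-Hoeffding bounds
  j_hi <- joint_from_cdf(F1, F2, function(u, v) pmin(u, v))
  j_lo <- joint_from_cdf(F1, F2, function(u, v) pmax(u + v - 1, 0))
  rho_hi <- joint_rank_correlation(j_hi)
  rho_lo <- joint_rank_correlation(j_lo)
  rng <- theta_range(family)
  rho_at <- function(par) {
    th <- theta_from_par(family, par)
    joint_rank_correlation(joint_from_cdf(F1, F2, function(u, v)
      copula_cdf(u, v, family, th)))
  }
  target <- target_correlation
  clamped <- FALSE
  hi_lim <- rho_at(rng[2]); lo_lim <- rho_at(rng[1])
  if (target >= min(rho_hi, hi_lim)) {
    warning(sprintf(
      "target correlation %.3f exceeds the attainable maximum %.3f for these margins; clamped",
      target, min(rho_hi, hi_lim)))
    return(finish(joint_from_cdf(F1, F2, function(u, v)
      copula_cdf(u, v, family, theta_from_par(family, rng[2]))),
      theta_from_par(family, rng[2]), clamped = TRUE))
  }
  if (target <= max(rho_lo, lo_lim)) {
    warning(sprintf(
      "target correlation %.3f is below the attainable minimum %.3f for these margins; clamped",
      target, max(rho_lo, lo_lim)))
    return(finish(joint_from_cdf(F1, F2, function(u, v)
      copula_cdf(u, v, family, theta_from_par(family, rng[1]))),
      theta_from_par(family, rng[1]), clamped = TRUE))
  }
  root <- stats::uniroot(function(par) rho_at(par) - target,
                         lower = rng[1], upper = rng[2], tol = 1e-9)$root
  theta <- theta_from_par(family, root)
  finish(joint_from_cdf(F1, F2, function(u, v) copula_cdf(u, v, family, theta)),
         theta, clamped)
}

#' @export
print.discrete_copula_joint <- function(x, ...) {
  cat(sprintf("Discrete copula joint %dx%d: theta = %.4g, achieved rho = %.4f%s\n",
              nrow(x$joint), ncol(x$joint), x$fitted_theta,
              x$achieved_correlation, if (x$clamped) " (clamped)" else ""))
  invisible(x)
}
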