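# Marginal distribution families for the synthetic cohort.
#
# Every marginal is specified by (family, mean, sd, lower, upper) and is
# realised through its quantile function applied to a Gaussian-copula
# uniform, so that requested rank dependence and requested marginal
# moments are decoupled:
#   * nbinom  - negative binomial parameterised by (mean, sd); collapses
#               to Poisson when sd^2 <= mean (overdispersion absent);
#   * gamma   - non-negative, right-skewed doses and annual costs;
#   * zigamma - zero-inflated gamma: point mass p_zero at 0, gamma above,
#               with the conditional moments solved so the *overall*
#               mean/sd equal the targets (treatment-year maintenance OCS:
#               most patients discontinue, so an exact zero is needed);
#   * normal  - normal truncated to [lower, upper] (FEV1 and similar
#               near-symmetric positive quantities);
#   * act     - integer Asthma Control Test score on [lower, upper]: a
#               truncated normal, discretised to integers, whose latent
#               (mu, sigma) are solved numerically so the *discrete*
#               marginal hits the requested mean/SD exactly.

marginal_families <- c("nbinom", "gamma", "zigamma", "normal", "act")

validate_marginal <- function(family, mean, sd, lower, upper, p_zero = 0) {
  if (!family %in% marginal_families) {
    stop_prepost("unknown marginal family '", family, "'")
  }
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    stop_prepost("marginal needs finite mean and sd >= 0 (got mean=",
                 mean, ", sd=", sd, ")")
  }
  if (lower >= upper && sd > 0) {
    stop_prepost("degenerate bounds [", lower, ", ", upper,
                 "] with sd > 0 are impossible")
  }
  if (p_zero < 0 || p_zero >= 1) stop_prepost("p_zero must lie in [0, 1)")
  if (family == "zigamma" && p_zero > 0) {
    # conditional variance must stay positive
    if ((sd^2 + mean^2) / (1 - p_zero) - (mean / (1 - p_zero))^2 <= 0) {
      stop_prepost("p_zero = ", p_zero, " is infeasible for mean ", mean,
                   " and sd ", sd)
    }
  }
  invisible(TRUE)
}

# Discrete pmf of a truncated normal rounded to integers lo..hi, with the
# tail mass absorbed into the end points.
act_pmf <- function(mu, sigma, lo, hi) {
  k <- lo:hi
  up <- pnorm((k + 0.5 - mu) / sigma)
  lo_ <- pnorm((k - 0.5 - mu) / sigma)
  p <- up - lo_
  p[1] <- up[1]
  p[length(p)] <- 1 - lo_[length(p)]
  p / sum(p)
}

act_moments <- function(mu, sigma, lo, hi) {
  p <- act_pmf(mu, sigma, lo, hi)
  k <- lo:hi
  m <- sum(k * p)
  v <- sum((k - m)^2 * p)
  c(mean = m, sd = sqrt(v))
}

# Solve for latent (mu, sigma) such that the discretised, clipped normal
# has the requested mean and SD.
act_match_latent <- function(mean, sd, lo, hi) {
  obj <- function(par) {
    mo <- act_moments(par[1], exp(par[2]), lo, hi)
    (mo[["mean"]] - mean)^2 + (mo[["sd"]] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-6) {
    stop_prepost("could not moment-match ACT marginal (mean=", mean,
                 ", sd=", sd, ") on [", lo, ", ", hi, "]")
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Quantile function factory: returns function(u) on (0, 1).
marginal_quantile_fun <- function(family, mean, sd, lower = 0, upper = Inf,
                                  p_zero = 0) {
  validate_marginal(family, mean, sd, lower, upper, p_zero)
  if (sd == 0) return(function(u) rep(mean, length(u)))
  switch(family,
    nbinom = {
      if (sd^2 <= mean) {
        function(u) qpois(u, lambda = mean)
      } else {
        size <- mean^2 / (sd^2 - mean)
        function(u) qnbinom(u, size = size, mu = mean)
      }
    },
    gamma = {
      shape <- (mean / sd)^2
      scale <- sd^2 / mean
      function(u) qgamma(u, shape = shape, scale = scale)
    },
    zigamma = {
      m1 <- mean / (1 - p_zero)
      v1 <- (sd^2 + mean^2) / (1 - p_zero) - m1^2
      shape <- m1^2 / v1
      scale <- v1 / m1
      function(u) {
        out <- numeric(length(u))
        pos <- u > p_zero
        out[pos] <- qgamma((u[pos] - p_zero) / (1 - p_zero),
                           shape = shape, scale = scale)
        out
      }
    },
    normal = {
      plo <- pnorm(lower, mean, sd)
      phi <- pnorm(upper, mean, sd)
      function(u) qnorm(plo + u * (phi - plo), mean, sd)
    },
    act = {
      lat <- act_match_latent(mean, sd, lower, upper)
      cdf <- cumsum(act_pmf(lat$mu, lat$sigma, lower, upper))
      vals <- lower:upper
      function(u) vals[pmin(findInterval(u, cdf) + 1L, length(vals))]
    }
  )
}

# Exact moments of the realised marginal (used for correlation matching).
marginal_moments <- function(family, mean, sd, lower = 0, upper = Inf,
                             p_zero = 0) {
  if (sd == 0) return(c(mean = mean, sd = 0))
  switch(family,
    nbinom = c(mean = mean, sd = if (sd^2 <= mean) sqrt(mean) else sd),
    gamma = c(mean = mean, sd = sd),
    zigamma = c(mean = mean, sd = sd),
    normal = {
      a <- (lower - mean) / sd
      b <- (upper - mean) / sd
      Z <- pnorm(b) - pnorm(a)
      da <- dnorm(a); db <- dnorm(b)
      m <- mean + sd * (da - db) / Z
      aa <- if (is.finite(a)) a * da else 0
      bb <- if (is.finite(b)) b * db else 0
      v <- sd^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
      c(mean = m, sd = sqrt(v))
    },
    act = {
      lat <- act_match_latent(mean, sd, lower, upper)
      act_moments(lat$mu, lat$sigma, lower, upper)
    }
  )
}

# --- Latent-correlation matching (NORTA) ---------------------------------
#
# The Pearson correlation that survives the quantile transforms is
# attenuated relative to the latent Gaussian correlation, noticeably so
# for discrete counts. For requested Pearson targets we solve for the
# latent correlation by quadrature of
# E[F1^{-1}(Phi(Z1)) F2^{-1}(Phi(Z2))] over the bivariate normal. The
# grid is a dense trapezoid rather than Gauss-Hermite because count
# marginals have step quantile functions, for which Gaussian quadrature
# is badly biased; weights are renormalised to sum to one.

norta_cache <- new.env(parent = emptyenv())

norta_grid <- function(n = 601, halfwidth = 7.5) {
  key <- paste0("g", n, "_", halfwidth)
  if (is.null(norta_cache[[key]])) {
    z <- seq(-halfwidth, halfwidth, length.out = n)
    w <- dnorm(z)
    norta_cache[[key]] <- list(z = z, w = w / sum(w))
  }
  norta_cache[[key]]
}

norta_pearson <- function(r, qf1, qf2, m1, s1, m2, s2, gh) {
  # clamp away from 0/1 so extreme grid nodes stay finite; their
  # Gaussian weight is negligible
  punit <- function(z) pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
  z1 <- gh$z
  x1 <- qf1(punit(z1))
  # inner expectation over W for each z1 node: Z2 = r z1 + sqrt(1-r^2) W
  zmat <- outer(r * z1, sqrt(max(0, 1 - r^2)) * gh$z, `+`)
  y <- matrix(qf2(punit(as.vector(zmat))), nrow = length(z1))
  exy <- sum(gh$w * x1 * as.vector(y %*% gh$w))
  (exy - m1 * m2) / (s1 * s2)
}

#' @noRd
norta_match_rho <- function(target, qf1, qf2, m1, s1, m2, s2,
                            cache_key = NULL) {
  if (target == 0) return(0)
  key <- paste("m", cache_key %||% "", target, m1, s1, m2, s2, sep = "_")
  if (!is.null(norta_cache[[key]])) return(norta_cache[[key]])
  gh <- norta_grid()
  f <- function(r) norta_pearson(r, qf1, qf2, m1, s1, m2, s2, gh) - target
  hi <- if (target > 0) 0.9995 else -0.9995
  fhi <- f(hi)
  if ((target > 0 && fhi < 0) || (target < 0 && fhi > 0)) {
    stop_prepost("requested Pearson correlation ", target,
                 " is not attainable for these marginals")
  }
  root <- stats::uniroot(f, sort(c(target * 0.5, hi)), tol = 1e-6)$root
  norta_cache[[key]] <- root
  root
}
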