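# Circular statistics for wind at departure and departure bearings.
# Angles are degrees in [0, 360) at every interface; radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Convert wind u/v components to speed and meteorological direction
#'
#' Uses the meteorological "from" convention: `from_direction` is the compass
#' direction the wind blows FROM (a southwesterly wind is 225 degrees). Note
#' that reanalysis u/v components are "toward" components (u east-positive,
#' v north-positive), hence the 180-degree flip.
#'
#' @param u,v Wind vector components, m/s, east- and north-positive.
#' @return Tibble with `u`, `v`, `speed` (m/s) and `from_direction` (degrees
#'   in [0, 360)).
#' @examples
#' uv_to_wind(1, 1) # southwesterly, 225 degrees, speed sqrt(2)
#' @export
uv_to_wind <- function(u, v) {
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    rlang::abort("Non-finite wind components.")
  }
  tibble::tibble(
    u = u, v = v,
    speed = sqrt(u^2 + v^2),
    from_direction = (rad2deg(atan2(u, v)) + 180) %% 360
  )
}

#' @rdname uv_to_wind
#' @param speed Wind speed, m/s.
#' @param from_direction Meteorological direction the wind blows from, degrees.
#' @return `wind_to_uv()`: tibble with `u`, `v` components.
#' @export
wind_to_uv <- function(speed, from_direction) {
  to <- deg2rad((from_direction + 180) %% 360)
  tibble::tibble(u = speed * sin(to), v = speed * cos(to))
}

#' Circular mean, SD and resultant length of a sample of angles
#'
#' The mean direction is the direction of the vector resultant; the circular
#' SD is sqrt(-2 log R) in radians, converted to degrees, where R is the mean
#' resultant length. With R numerically zero (e.g. antipodal pairs) the mean
#' is undefined and returned as `NA` with `defined = FALSE`.
#'
#' @param angles_deg Angles in degrees.
#' @return One-row tibble: `mean_deg`, `sd_deg`, `resultant_length`, `n`,
#'   `defined`.
#' @export
circular_mean_sd <- function(angles_deg) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  n <- length(angles_deg)
  if (n < 1) rlang::abort("Need at least one angle.")
  a <- deg2rad(angles_deg)
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  defined <- R > 1e-12
  tibble::tibble(
    mean_deg = if (defined) rad2deg(atan2(S, C)) %% 360 else NA_real_,
    sd_deg = if (defined) rad2deg(sqrt(-2 * log(R))) else Inf,
    resultant_length = R,
    n = n,
    defined = defined
  )
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Degenerate concentration `kappa = 0` gives
#' the circular uniform.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in [0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-9) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3 - 0.5)[keep] * acos(f[keep])
    k <- length(theta)
    if (k > 0) {
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  rad2deg(out + mu) %% 360
}

# von Mises negative log-likelihood helper: -sum log f(theta; mu_i, kappa)
# mu_i supplied per observation (radians); A(kappa) = I1/I0 via besselI.
.vm_negll <- function(theta, mu, log_kappa) {
  kappa <- exp(log_kappa)
  -sum(kappa * cos(theta - mu) - log(2 * pi) -
         log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa)
}

#' Watson's two-sample U-squared test of homogeneity
#'
#' Nonparametric test that two samples of angles come from one distribution,
#' computed from the pooled circular order statistics. The p-value is by
#' permutation of group labels by default; `p_method = "band"` instead
#' reports the band implied by asymptotic critical values (the "p > 0.10"
#' reporting style).
#'
#' @param angles_a,angles_b Samples of angles, degrees.
#' @param p_method `"permutation"` or `"band"`.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed for the permutations.
#' @return One-row tibble: `u2`, `p_value` (NA when banded), `p_band`
#'   (character), `n_a`, `n_b`, `method`.
#' @export
watson_u2 <- function(angles_a, angles_b, p_method = c("permutation", "band"),
                      n_perm = 999, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(angles_a) < 8 || length(angles_b) < 8) {
    rlang::abort("Watson's U2 needs at least 8 angles per sample.")
  }
  a <- deg2rad(angles_a %% 360); b <- deg2rad(angles_b %% 360)
  pooled <- c(a, b)
  if (mean(duplicated(signif(pooled, 12))) > 0.2) {
    rlang::warn("Heavy ties among pooled angles; consider jittering.")
  }
  u2 <- .watson_u2_stat(a, b)
  n_a <- length(a); n_b <- length(b)
  if (p_method == "permutation") {
    if (!is.null(seed)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(seed)
    }
    null <- replicate(n_perm, {
      idx <- sample.int(n_a + n_b, n_a)
      .watson_u2_stat(pooled[idx], pooled[-idx])
    })
    p <- (sum(null >= u2) + 1) / (n_perm + 1)
    band <- NA_character_
  } else {
    p <- NA_real_
    # asymptotic critical values for U2 (alpha = 0.10, 0.05, 0.01)
    band <- if (u2 > 0.268) "p < 0.01"
    else if (u2 > 0.187) "p < 0.05"
    else if (u2 > 0.152) "p < 0.10"
    else "p > 0.10"
  }
  tibble::tibble(u2 = u2, p_value = p, p_band = band,
                 n_a = n_a, n_b = n_b, method = p_method)
}

# U2 from the difference d = F_a - F_b between the two empirical CDFs at
# the pooled order statistics, integrated against the pooled empirical
# measure: U2 = n*m/N^2 * sum_k t_k (d_k - dbar)^2, with t_k the tie
# multiplicity. Reduces to the classic rank formula when there are no ties
# and is exactly 0 for identical samples.
.watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  vals <- sort(unique(c(a, b)))
  t_k <- diff(c(0, findInterval(vals, sort(c(a, b)))))
  d <- findInterval(vals, sort(a)) / n - findInterval(vals, sort(b)) / m
  dbar <- sum(t_k * d) / N
  (n * m / N^2) * sum(t_k * (d - dbar)^2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mean departure bearing over the first hours of a trip
#'
#' Circular mean of step headings over the fixes falling within `window_h`
#' hours of the trip's first fix.
#'
#' @param fixes Tibble of one trip's fixes (`timestamp`, `lon`, `lat`),
#'   time-ordered.
#' @param window_h Window after departure, hours.
#' @return Bearing in degrees [0, 360), or `NA` if no step lies in the window.
#' @export
departure_bearing <- function(fixes, window_h = 3) {
  stopifnot(nrow(fixes) >= 2)
  dt <- as.numeric(difftime(fixes$timestamp, fixes$timestamp[1], units = "hours"))
  idx <- which(dt <= window_h)
  idx <- idx[idx < nrow(fixes)]
  if (length(idx) == 0) return(NA_real_)
  moved <- great_circle_km(fixes$lon[idx], fixes$lat[idx],
                           fixes$lon[idx + 1], fixes$lat[idx + 1]) > 1e-6
  idx <- idx[moved]
  if (length(idx) == 0) return(NA_real_)
  headings <- initial_bearing(fixes$lon[idx], fixes$lat[idx],
                              fixes$lon[idx + 1], fixes$lat[idx + 1])
  circular_mean_sd(headings)$mean_deg
}

# ---- von Mises circular regression --------------------------------------

#' Circular-circular regression of one angle on another
#'
#' Models the response direction as von Mises with mean
#' `mu + 2 atan(bc cos x + bs sin x)` where `x` is the predictor angle; fits
#' by maximum likelihood and tests each of the cosine and sine components
#' with a likelihood-ratio test (optionally by permutation of the predictor).
#'
#' @param response_deg,predictor_deg Angles in degrees.
#' @param p_method `"lrt"` (default) or `"permutation"`.
#' @param n_perm Permutations when `p_method = "permutation"`.
#' @param seed Optional seed for permutations.
#' @return Object of class `circ_fit`; see [tidy.circ_fit()].
#' @export
circ_circ_regression <- function(response_deg, predictor_deg,
                                 p_method = c("lrt", "permutation"),
                                 n_perm = 199, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(response_deg) == 0) rlang::abort("Empty response.")
  if (length(response_deg) != length(predictor_deg)) {
    rlang::abort("response and predictor lengths differ.")
  }
  if (length(response_deg) < 5) rlang::abort("Need at least 5 observations.")
  x <- deg2rad(predictor_deg)
  X <- cbind(cos(x), sin(x))
  fit <- .vm_reg_fit(deg2rad(response_deg), X)
  pvals <- .vm_reg_component_p(deg2rad(response_deg), X, fit, p_method,
                               n_perm, seed)
  structure(list(
    type = "circular-circular",
    coefficients = c(mu_deg = rad2deg(fit$mu) %% 360,
                     beta_cos = fit$beta[1], beta_sin = fit$beta[2]),
    kappa = fit$kappa, logLik = -fit$negll, n = length(response_deg),
    p_values = c(cos = pvals[1], sin = pvals[2]), p_method = p_method
  ), class = "circ_fit")
}

#' Circular-linear regression of an angle on a scalar covariate
#'
#' Same von Mises framework as [circ_circ_regression()] with mean direction
#' `mu + 2 atan(beta z)` for a centred scalar covariate `z`.
#'
#' @param response_deg Angles in degrees.
#' @param predictor Numeric covariate.
#' @inheritParams circ_circ_regression
#' @return Object of class `circ_fit`.
#' @export
circ_lin_regression <- function(response_deg, predictor,
                                p_method = c("lrt", "permutation"),
                                n_perm = 199, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(response_deg) < 5) rlang::abort("Need at least 5 observations.")
  if (length(response_deg) != length(predictor)) {
    rlang::abort("response and predictor lengths differ.")
  }
  z <- predictor - mean(predictor)
  sdz <- stats::sd(z)
  if (sdz > 0) z <- z / sdz
  X <- cbind(z)
  fit <- .vm_reg_fit(deg2rad(response_deg), X)
  pvals <- .vm_reg_component_p(deg2rad(response_deg), X, fit, p_method,
                               n_perm, seed)
  structure(list(
    type = "circular-linear",
    coefficients = c(mu_deg = rad2deg(fit$mu) %% 360, slope = fit$beta[1]),
    kappa = fit$kappa, logLik = -fit$negll, n = length(response_deg),
    p_values = c(slope = pvals[1]), p_method = p_method
  ), class = "circ_fit")
}

# ML fit of theta ~ VM(mu + 2 atan(X beta), kappa). Parameters
# (mu via cos/sin embedding is avoided: mu direct, beta free, log kappa).
.vm_reg_fit <- function(theta, X) {
  p <- ncol(X)
  nll <- function(par) {
    mu <- par[1]; beta <- par[2:(1 + p)]; log_kappa <- par[2 + p]
    eta <- drop(X %*% beta)
    .vm_negll(theta, mu + 2 * atan(eta), log_kappa)
  }
  # init: circular mean of response, zero slopes, moment kappa
  cm <- atan2(mean(sin(theta)), mean(cos(theta)))
  R <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  k0 <- max(0.1, min(50, R * (2 - R^2) / (1 - R^2)))
  par0 <- c(cm, rep(0, p), log(k0))
  opt <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(mu = opt$par[1], beta = opt$par[2:(1 + p)],
       kappa = exp(opt$par[2 + p]), negll = opt$value, X = X)
}

# LRT (chisq df 1 per component) or permutation p for each column of X.
.vm_reg_component_p <- function(theta, X, fit, p_method, n_perm, seed) {
  p <- ncol(X)
  if (p_method == "lrt") {
    vapply(seq_len(p), function(j) {
      Xr <- X[, -j, drop = FALSE]
      if (ncol(Xr) > 0) {
        r <- .vm_reg_fit(theta, Xr)
      } else {
        # mean-only model
        nll0 <- function(par) .vm_negll(theta, par[1], par[2])
        cm <- atan2(mean(sin(theta)), mean(cos(theta)))
        o <- stats::optim(c(cm, log(1)), nll0, method = "BFGS",
                          control = list(reltol = 1e-10))
        r <- list(negll = o$value)
      }
      lr <- 2 * (r$negll - fit$negll)
      stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }, numeric(1))
  } else {
    if (!is.null(seed)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(seed)
    }
    obs <- abs(fit$beta)
    null_ge <- matrix(0L, n_perm, p)
    for (i in seq_len(n_perm)) {
      Xp <- X[sample.int(nrow(X)), , drop = FALSE]
      fp <- .vm_reg_fit(theta, Xp)
      null_ge[i, ] <- as.integer(abs(fp$beta) >= obs)
    }
    (colSums(null_ge) + 1) / (n_perm + 1)
  }
}

#' @export
print.circ_fit <- function(x, ...) {
  cat("von Mises", x$type, "regression\n")
  cat("  n =", x$n, " kappa =", signif(x$kappa, 4),
      " logLik =", signif(x$logLik, 6), "\n")
  cat("  coefficients:\n")
  print(signif(x$coefficients, 4))
  cat("  p-values (", x$p_method, "):\n", sep = "")
  print(signif(x$p_values, 4))
  invisible(x)
}

#' Tidy a circular regression fit
#'
#' @param x A `circ_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per model term.
#' @exportS3Method generics::tidy
tidy.circ_fit <- function(x, ...) {
  terms <- names(x$coefficients)
  pv <- rep(NA_real_, length(terms))
  if (x$type == "circular-circular") {
    pv[match(c("beta_cos", "beta_sin"), terms)] <- x$p_values[c("cos", "sin")]
  } else {
    pv[match("slope", terms)] <- x$p_values["slope"]
  }
  tibble::tibble(term = terms, estimate = unname(x$coefficients),
                 p.value = pv)
}

#' Glance at a circular regression fit
#'
#' @inheritParams tidy.circ_fit
#' @return One-row tibble with fit-level summaries.
#' @exportS3Method generics::glance
glance.circ_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, logLik = x$logLik, nobs = x$n,
                 p_method = x$p_method)
}
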