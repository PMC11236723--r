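#' Circular statistics utilities
#'
#' Minimal circular-statistics toolbox used by the tuning and alignment
#' modules: circular mean and resultant, angular deviation, the Rayleigh
#' uniformity test, the two-sample Watson-Williams test, and a von Mises
#' sampler. Angles are radians unless a function says otherwise.
#'
#' @name circstats
NULL

#' Wrap angles to [0, 2*pi) (radians) or [0, 360) (degrees)
#' @param x angles
#' @param degrees logical; if TRUE wrap to [0, 360)
#' @export
wrap_angle <- function(x, degrees = FALSE) {
  period <- if (degrees) 360 else 2 * pi
  out <- x %% period
  out[out < 0] <- out[out < 0] + period
  out
}

#' Circular mean direction
#' @param x angles (rad)
#' @param w optional non-negative weights
#' @return mean direction in [0, 2*pi).
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  wrap_angle(atan2(sum(w * sin(x)), sum(w * cos(x))))
}

#' Mean resultant length
#' @param x angles (rad)
#' @return resultant length in [0, 1].
#' @export
circ_r <- function(x) {
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}

#' Circular angular deviation, sqrt(2 (1 - R))
#' @param x angles (rad)
#' @return angular deviation (rad), in [0, sqrt(2)].
#' @export
circ_angular_deviation <- function(x) {
  sqrt(2 * (1 - circ_r(x)))
}

#' Rayleigh test of circular uniformity
#'
#' Large-sample approximation
#' \code{p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))} with
#' \code{Rn = n R}. For very small samples (\code{n < 10}) a Monte-Carlo
#' p-value (uniform resampling of the resultant) is available.
#'
#' @param x angles (rad)
#' @param method \code{"approx"} or \code{"mc"}
#' @param n_mc Monte-Carlo replicates for \code{method = "mc"}
#' @return list with \code{r} (resultant), \code{statistic} (\code{n r^2})
#'   and \code{p_value}.
#' @export
rayleigh_test <- function(x, method = c("approx", "mc"), n_mc = 10000) {
  method <- match.arg(method)
  n <- length(x)
  r <- circ_r(x)
  z <- n * r^2
  if (method == "approx") {
    p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  } else {
    rs <- vapply(seq_len(n_mc), function(i) circ_r(stats::runif(n, 0, 2 * pi)), 0)
    p <- (sum(rs >= r) + 1) / (n_mc + 1)
  }
  list(r = r, statistic = z, p_value = min(1, p))
}

#' Estimate von Mises concentration from a mean resultant length
#'
#' Standard piecewise approximation to the inverse of A1(kappa) = I1/I0.
#' @param r mean resultant length in [0, 1)
#' @return concentration kappa >= 0.
#' @export
kappa_from_r <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Sample from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' @param n sample size
#' @param mu mean direction (rad)
#' @param kappa concentration (>= 0); 0 gives the circular uniform
#' @return angles in [0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rho <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + rho * z) / (rho + z)
    c0 <- kappa * (rho - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- wrap_angle(mu + sign(u3 - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

#' Two-sample Watson-Williams test for equal mean directions
#'
#' Classical F-approximation with the 1 + 3/(8 kappa) correction, where kappa
#' is estimated from the pooled within-sample resultant. The test assumes
#' reasonably concentrated samples (pooled resultant >= 0.45); below that a
#' caveat flag is set and the F statistic is still reported.
#'
#' @param x,y angle samples (rad)
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{critical_value} (F at alpha = 0.05) and \code{low_concentration}.
#' @export
watson_williams_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  R1 <- n1 * circ_r(x)
  R2 <- n2 * circ_r(y)
  R <- N * circ_r(c(x, y))
  rw <- (R1 + R2) / N
  kappa <- kappa_from_r(min(rw, 0.999999))
  corr <- 1 + 3 / (8 * kappa)
  Fstat <- corr * (N - 2) * (R1 + R2 - R) / (N - R1 - R2)
  Fstat <- max(0, Fstat)
  df1 <- 1; df2 <- N - 2
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       critical_value = stats::qf(0.95, df1, df2),
       low_concentration = rw < 0.45)
}
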