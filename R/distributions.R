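# Circular (von Mises) and gamma helpers shared by the trajectory generator
# and the movement HMM. Kept internal; exported surface lives in the module
# files.

#' von Mises log-density
#'
#' @param theta angles (rad)
#' @param mu mean direction (rad)
#' @param kappa concentration (>= 0); kappa = 0 is the circular uniform
#' @return log-density values
#' @keywords internal
dvonmises_log <- function(theta, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  # log besselI with expon.scaled to stay finite at large kappa
  kappa * cos(theta - mu) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

#' von Mises sampler (Best & Fisher rejection method)
#'
#' @param n number of draws
#' @param mu mean direction (rad)
#' @param kappa concentration; `Inf` returns `mu` exactly, 0 is uniform
#' @return angles in (-pi, pi]
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  if (is.infinite(kappa)) {
    return(rep(wrap_angle(mu), n))
  }
  if (kappa == 0) {
    return(runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

#' Wrap angles into (-pi, pi]
#' @keywords internal
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Inverse of the mean-resultant-length function A1(kappa) = I1/I0
#'
#' Best & Fisher approximation, the standard estimator for the von Mises
#' concentration from a resultant length in [0, 1).
#' @keywords internal
a1inv <- function(R) {
  if (R < 0) R <- 0
  if (R >= 0.999999) return(1e6)
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

#' Weighted von Mises maximum-likelihood estimate
#'
#' @param theta angles; `w` nonnegative weights
#' @return list(mu, kappa)
#' @keywords internal
fit_vonmises_weighted <- function(theta, w) {
  sw <- sum(w)
  C <- sum(w * cos(theta)) / sw
  S <- sum(w * sin(theta)) / sw
  mu <- atan2(S, C)
  R <- sqrt(C^2 + S^2)
  list(mu = mu, kappa = a1inv(R))
}

#' Weighted gamma maximum-likelihood estimate
#'
#' Newton iteration on log(shape) for the profile score
#' log(k) - digamma(k) = log(wmean) - wmeanlog; scale = wmean / shape.
#' Falls back to the moment estimator if the score is degenerate
#' (near-constant data).
#' @param x positive observations; `w` nonnegative weights
#' @return list(shape, scale, mean, sd)
#' @keywords internal
fit_gamma_weighted <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  mlog <- sum(w * log(x)) / sw
  s <- log(m) - mlog              # >= 0 by Jensen
  if (!is.finite(s) || s <= 1e-12) {
    # nearly degenerate: huge shape, tiny scale
    v <- max(sum(w * (x - m)^2) / sw, 1e-12)
    shape <- m^2 / v
  } else {
    shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka init
    for (i in 1:50) {
      num <- log(shape) - digamma(shape) - s
      den <- 1 / shape - trigamma(shape)
      step <- num / den
      shape_new <- shape - step
      if (shape_new <= 0) shape_new <- shape / 2
      if (abs(shape_new - shape) < 1e-10 * shape) {
        shape <- shape_new
        break
      }
      shape <- shape_new
    }
  }
  scale <- m / shape
  list(shape = shape, scale = scale, mean = m, sd = sqrt(shape) * scale)
}
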