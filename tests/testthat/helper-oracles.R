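# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (explicit enumeration, direct density
# formulas) rather than calling the package's own code paths.

# von Mises density computed directly from its definition
oracle_dvm <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
}

# per-time-step emission density for a (step, angle) pair under state k;
# missing angles contribute only the step density
oracle_emission <- function(step, angle, fit, k) {
  shape <- (fit$step_mean[k] / fit$step_sd[k])^2
  scale <- fit$step_sd[k]^2 / fit$step_mean[k]
  d <- dgamma(step, shape = shape, scale = scale)
  if (is.finite(angle)) d <- d * oracle_dvm(angle, fit$angle_mean[k], fit$angle_kappa[k])
  d
}

# all K^T hidden paths as rows
all_paths <- function(K, T) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

# total likelihood by explicit summation over every hidden path
oracle_hmm_lik <- function(fit, s) {
  K <- length(fit$step_mean)
  T <- nrow(s)
  paths <- all_paths(K, T)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    lik <- fit$delta[path[1]] * oracle_emission(s$step_mm[1], s$angle_rad[1], fit, path[1])
    for (t in 2:T) {
      lik <- lik * fit$transition[path[t - 1], path[t]] *
        oracle_emission(s$step_mm[t], s$angle_rad[t], fit, path[t])
    }
    total <- total + lik
  }
  total
}

# most probable path by explicit enumeration (ties -> first in row order,
# which with expand.grid is the lexicographically smallest path)
oracle_viterbi <- function(fit, s) {
  K <- length(fit$step_mean)
  T <- nrow(s)
  paths <- all_paths(K, T)
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    ll <- log(fit$delta[path[1]]) +
      log(oracle_emission(s$step_mm[1], s$angle_rad[1], fit, path[1]))
    for (t in 2:T) {
      ll <- ll + log(fit$transition[path[t - 1], path[t]]) +
        log(oracle_emission(s$step_mm[t], s$angle_rad[t], fit, path[t]))
    }
    if (ll > best + 1e-12) { best <- ll; arg <- path }
  }
  unname(arg)
}

# a parameter-set stand-in shaped like a kx_hmm_fit, for decoding/likelihood
make_fitlike <- function(transition, delta, step_mean, step_sd, angle_mean,
                         angle_kappa) {
  list(n_states = nrow(transition), transition = transition, delta = delta,
       step_mean = step_mean, step_sd = step_sd,
       step_shape = (step_mean / step_sd)^2, step_scale = step_sd^2 / step_mean,
       angle_mean = angle_mean, angle_kappa = angle_kappa)
}

# small random step/angle series
random_series <- function(T, seed) {
  set.seed(seed)
  tibble::tibble(step_mm = rgamma(T, 2, 2),
                 angle_rad = runif(T, -pi, pi))
}

# straight-line trajectory builder from explicit positions
traj_from_xy <- function(x, y, dt = 1, larva_id = "L1") {
  out <- tibble::tibble(larva_id = larva_id,
                        t_s = seq_along(x) * dt - dt,
                        x_mm = x, y_mm = y, period = 1L, light = 1L)
  attr(out, "dt") <- dt
  out
}
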