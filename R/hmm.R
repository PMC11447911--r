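# Three-state (slow/medium/fast) movement HMM on step-length / turning-angle
# series: gamma + von Mises emissions, conditionally independent given the
# state; one shared parameter set across larvae treated as independent
# chains; EM (Baum-Welch) with multiple jittered restarts. The forward,
# backward and Viterbi recursions are in compiled code (src/hmm_core.cpp).

#' Step/turn series for HMM fitting
#'
#' Converts one or more trajectories into per-larva step-length (mm) and
#' turning-angle (rad) series. The first step of a series has no defined
#' turning angle (NA); zero-length displacements give NA angles as well.
#'
#' @param traj trajectory tibble (single or multi-larva).
#' @return named list of tibbles (`step_mm`, `angle_rad`), one per larva.
#' @export
hmm_series <- function(traj) {
  out <- list()
  for (id in unique(traj$larva_id)) {
    tr <- traj[traj$larva_id == id, , drop = FALSE]
    dx <- diff(tr$x_mm); dy <- diff(tr$y_mm)
    step <- sqrt(dx^2 + dy^2)
    n <- length(step)
    ang <- rep(NA_real_, n)
    if (n >= 2) {
      h <- atan2(dy, dx)
      h[step == 0] <- NA
      a <- wrap_angle(diff(h))
      ang[-1] <- a
    }
    out[[id]] <- tibble(step_mm = step, angle_rad = ang)
  }
  out
}

as_series_list <- function(series) {
  if (is.data.frame(series)) {
    if (all(c("x_mm", "y_mm") %in% names(series))) return(hmm_series(series))
    return(list(series))
  }
  series
}

# log emission matrix (T x K); NA angles contribute only the step density
log_emissions <- function(s, step_shape, step_scale, angle_mu, angle_kappa) {
  K <- length(step_shape)
  Tt <- nrow(s)
  B <- matrix(0, Tt, K)
  ok <- is.finite(s$angle_rad)
  for (k in seq_len(K)) {
    B[, k] <- dgamma(s$step_mm, shape = step_shape[k], scale = step_scale[k],
                     log = TRUE)
    B[ok, k] <- B[ok, k] +
      dvonmises_log(s$angle_rad[ok], angle_mu[k], angle_kappa[k])
  }
  B
}

moment_init <- function(steps, angles, K, jitter_sd) {
  q <- quantile(steps, probs = seq(0, 1, length.out = K + 1))
  grp <- cut(steps, breaks = unique(q), include.lowest = TRUE,
             labels = FALSE)
  if (length(unique(grp)) < K) grp <- sample.int(K, length(steps), replace = TRUE)
  m <- tapply(steps, grp, mean)
  s <- tapply(steps, grp, sd)
  m <- as.numeric(m)[seq_len(K)]
  s <- as.numeric(s)[seq_len(K)]
  s[!is.finite(s) | s <= 0] <- m[!is.finite(s) | s <= 0] / 2
  m <- m * exp(rnorm(K, 0, jitter_sd))
  s <- s * exp(rnorm(K, 0, jitter_sd))
  o <- order(m)
  A <- matrix(0.2 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.8 else 1
  list(step_mean = m[o], step_sd = s[o],
       angle_mu = rep(0, K),
       angle_kappa = exp(rnorm(K, 0, jitter_sd)),
       A = A, delta = rep(1 / K, K))
}

#' Fit the movement HMM by Baum-Welch EM
#'
#' Maximum-likelihood fit of a K-state HMM with gamma step-length and
#' von Mises turning-angle emissions, pooled across larvae (shared
#' parameters, independent chains). The best of `n_restarts` jittered
#' moment-based initializations (by final log-likelihood) is returned, with
#' states relabelled so step-length means increase (slow < medium < fast).
#'
#' @param series a trajectory tibble, a single step/angle tibble, or a list
#'   of step/angle tibbles (`step_mm`, `angle_rad`) as from [hmm_series()].
#' @param n_states number of movement states (default 3).
#' @param n_restarts EM restarts (default 10).
#' @param seed integer seed controlling initialization jitter.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter EM iteration cap; hitting it flags non-convergence and
#'   returns the best iterate.
#' @param step_floor small positive value replacing zero step lengths
#'   (gamma support); the number floored is recorded in the fit.
#' @return object of class `kx_hmm_fit`: transition matrix, initial
#'   distribution, per-state step mean/sd (and gamma shape/scale), angle
#'   mean/concentration, log-likelihood trace, convergence flag.
#' @export
fit_movement_hmm <- function(series, n_states = 3, n_restarts = 10,
                             seed = 1, tol = 1e-6, max_iter = 500,
                             step_floor = 1e-6) {
  series <- as_series_list(series)
  if (!length(series)) stop("no series supplied")
  K <- n_states
  for (s in series) {
    if (nrow(s) < K) stop("each series needs at least n_states observations")
    if (any(!is.finite(s$step_mm))) stop("non-finite step lengths")
  }
  n_floored <- 0L
  series <- lapply(series, function(s) {
    z <- s$step_mm < step_floor
    n_floored <<- n_floored + sum(z)
    s$step_mm[z] <- step_floor
    s
  })
  all_steps <- unlist(lapply(series, `[[`, "step_mm"))
  all_angles <- unlist(lapply(series, `[[`, "angle_rad"))
  all_angles <- all_angles[is.finite(all_angles)]
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- moment_init(all_steps, all_angles, K,
                        jitter_sd = if (r == 1) 0 else 0.3)
    fit <- em_run(series, init, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # canonical ordering: slow < medium < fast by step mean
  o <- order(best$step_mean)
  fit <- list(
    n_states = K,
    transition = best$A[o, o, drop = FALSE],
    delta = best$delta[o],
    step_mean = best$step_mean[o], step_sd = best$step_sd[o],
    step_shape = best$step_shape[o], step_scale = best$step_scale[o],
    angle_mean = best$angle_mu[o], angle_kappa = best$angle_kappa[o],
    loglik = best$loglik, loglik_trace = best$trace,
    converged = best$converged, n_iter = best$n_iter,
    n_restarts = n_restarts, n_series = length(series),
    n_floored_steps = n_floored
  )
  dimnames(fit$transition) <- list(state_names(K), state_names(K))
  class(fit) <- "kx_hmm_fit"
  fit
}

state_names <- function(K) {
  if (K == 3) c("slow", "medium", "fast") else paste0("state", seq_len(K))
}

em_run <- function(series, init, tol, max_iter) {
  K <- length(init$step_mean)
  A <- init$A; delta <- init$delta
  step_mean <- init$step_mean; step_sd <- init$step_sd
  angle_mu <- init$angle_mu; angle_kappa <- init$angle_kappa
  trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    step_shape <- (step_mean / step_sd)^2
    step_scale <- step_sd^2 / step_mean
    log_A <- log(A); log_pi <- log(delta)
    ll <- 0
    xi_tot <- matrix(0, K, K)
    delta_acc <- numeric(K)
    gam_list <- vector("list", length(series))
    for (i in seq_along(series)) {
      B <- log_emissions(series[[i]], step_shape, step_scale, angle_mu,
                         angle_kappa)
      fb <- .fb_cpp(log_pi, log_A, B)
      ll <- ll + fb$loglik
      xi_tot <- xi_tot + fb$xi_sum
      delta_acc <- delta_acc + fb$gamma[1, ]
      gam_list[[i]] <- fb$gamma
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    if (K > 1) {
      rs <- rowSums(xi_tot)
      A <- xi_tot / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- 1 / K
    }
    delta <- delta_acc / sum(delta_acc)
    gam <- do.call(rbind, gam_list)
    steps <- unlist(lapply(series, `[[`, "step_mm"))
    angles <- unlist(lapply(series, `[[`, "angle_rad"))
    ok <- is.finite(angles)
    for (k in seq_len(K)) {
      w <- gam[, k]
      gf <- fit_gamma_weighted(steps, w)
      step_mean[k] <- gf$mean; step_sd[k] <- gf$sd
      vf <- fit_vonmises_weighted(angles[ok], w[ok])
      angle_mu[k] <- vf$mu; angle_kappa[k] <- min(vf$kappa, 1e4)
    }
  }
  list(A = A, delta = delta, step_mean = step_mean, step_sd = step_sd,
       step_shape = (step_mean / step_sd)^2, step_scale = step_sd^2 / step_mean,
       angle_mu = angle_mu, angle_kappa = angle_kappa,
       loglik = trace[length(trace)], trace = trace,
       converged = converged, n_iter = length(trace))
}

#' Forward log-likelihood of series under a fit (or parameter set)
#'
#' @param fit a `kx_hmm_fit` or a list with the same parameter fields.
#' @param series as in [fit_movement_hmm()].
#' @export
hmm_loglik <- function(fit, series) {
  series <- as_series_list(series)
  step_shape <- if (!is.null(fit$step_shape)) fit$step_shape else (fit$step_mean / fit$step_sd)^2
  step_scale <- if (!is.null(fit$step_scale)) fit$step_scale else fit$step_sd^2 / fit$step_mean
  delta <- if (!is.null(fit$delta)) fit$delta else stationary_dist(fit$transition)
  ll <- 0
  for (s in series) {
    B <- log_emissions(s, step_shape, step_scale, fit$angle_mean, fit$angle_kappa)
    ll <- ll + .fb_cpp(log(delta), log(fit$transition), B)$loglik
  }
  ll
}

#' Viterbi decoding of the most probable state path
#'
#' Ties are broken deterministically toward the lower (slower) state index.
#'
#' @param fit a `kx_hmm_fit`.
#' @param series as in [fit_movement_hmm()].
#' @return list with `paths` (list of integer vectors, one per series) and
#'   `occupancy` (fraction of steps decoded into each state).
#' @export
decode_states <- function(fit, series) {
  series <- as_series_list(series)
  if (!length(series)) stop("no series supplied")
  for (s in series) {
    if (!nrow(s) || all(!is.finite(s$step_mm) & !is.finite(s$angle_rad))) {
      stop("series lacks usable emissions")
    }
  }
  step_shape <- fit$step_shape; step_scale <- fit$step_scale
  paths <- lapply(series, function(s) {
    B <- log_emissions(s, step_shape, step_scale, fit$angle_mean, fit$angle_kappa)
    as.integer(.viterbi_cpp(log(fit$delta), log(fit$transition), B))
  })
  occ <- tabulate(unlist(paths), nbins = fit$n_states)
  list(paths = paths, occupancy = occ / sum(occ))
}

# circular variance of a fitted von Mises: 1 - I1(kappa)/I0(kappa)
vm_circ_var <- function(kappa) {
  1 - besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' HMM behavior endpoints from a fitted model
#'
#' Emits the HMM endpoint rows used in treatment comparisons: per-state
#' staying probabilities P(i -> i), all transition probabilities P(i -> j),
#' per-state step-length mean and variation (sd), and per-state turning-angle
#' mean and variation (circular variance of the fitted von Mises).
#'
#' @param fit a `kx_hmm_fit`.
#' @param group optional label attached to every row.
#' @return tibble `endpoint, value` (plus `group` if given).
#' @export
hmm_behavior_endpoints <- function(fit, group = NULL) {
  K <- fit$n_states
  nm <- state_names(K)
  rows <- list()
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      label <- if (i == j) sprintf("stay_prob_%s", nm[i]) else
        sprintf("trans_prob_%s_to_%s", nm[i], nm[j])
      rows[[length(rows) + 1]] <- tibble(endpoint = label,
                                         value = fit$transition[i, j])
    }
  }
  for (i in seq_len(K)) {
    rows[[length(rows) + 1]] <- tibble(
      endpoint = c(sprintf("step_length_mean_%s", nm[i]),
                   sprintf("step_length_sd_%s", nm[i]),
                   sprintf("turn_angle_mean_%s", nm[i]),
                   sprintf("turn_angle_var_%s", nm[i])),
      value = c(fit$step_mean[i], fit$step_sd[i],
                fit$angle_mean[i], vm_circ_var(fit$angle_kappa[i]))
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(group)) out$group <- group
  out
}

#' @export
print.kx_hmm_fit <- function(x, ...) {
  cat(sprintf("Movement HMM fit: %d states, %d series, loglik %.2f (%s, %d EM iterations)\n",
              x$n_states, x$n_series, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("Transition matrix:\n")
  print(round(x$transition, 4))
  cat("Step length mean (mm):", signif(x$step_mean, 4), "\n")
  cat("Step length sd   (mm):", signif(x$step_sd, 4), "\n")
  cat("Turn angle kappa     :", signif(x$angle_kappa, 4), "\n")
  invisible(x)
}
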