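# Synthetic generators for every pipeline input: multi-state movement
# trajectories, alternating light/dark (VMR-style) trajectories, feeding-assay
# event records, and negative-binomial count matrices with planted
# fold-changes. These define the statistical structure the downstream
# analyses assume, so the whole chain is testable without raw assay data.

#' Movement-HMM parameter set
#'
#' Parameters of a K-state hidden Markov model of larval swimming: a
#' row-stochastic transition matrix, per-state gamma step-length laws
#' (mean and sd, in mm per frame) and per-state von Mises turning-angle laws
#' (mean direction and concentration). States are ordered slow < medium <
#' fast by mean step length.
#'
#' @param transition K x K row-stochastic matrix of per-frame transition
#'   probabilities.
#' @param step_mean,step_sd per-state mean and sd of the gamma step-length
#'   law (mm per frame). `step_sd = 0` gives a deterministic step. Means must
#'   be strictly increasing with state index.
#' @param angle_mean,angle_kappa per-state mean direction (rad) and
#'   concentration of the von Mises turning-angle law. `angle_kappa = Inf`
#'   gives deterministic turns.
#' @param dt frame interval in seconds (default 1/30 s, a typical tracking
#'   frame rate).
#' @return An object of class `kx_hmm_params`.
#' @examples
#' p <- hmm_params()            # default 3-state slow/medium/fast model
#' p$transition
#' @export
hmm_params <- function(transition = default_transition_3(),
                       step_mean = c(0.08, 0.35, 1.1),
                       step_sd = c(0.06, 0.20, 0.55),
                       angle_mean = c(0, 0, 0),
                       angle_kappa = c(0.5, 2, 8),
                       dt = 1 / 30) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  if (ncol(transition) != K) stop("transition matrix must be square")
  if (any(transition < 0)) stop("transition probabilities must be >= 0")
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("each transition row must sum to 1 (got ", paste(signif(rs, 6), collapse = ", "), ")")
  }
  for (v in list(step_mean, step_sd, angle_mean, angle_kappa)) {
    if (length(v) != K) stop("emission parameter vectors must have length K = ", K)
  }
  if (any(step_mean <= 0)) stop("step means must be > 0")
  if (any(step_sd < 0)) stop("step sds must be >= 0")
  if (K > 1 && any(diff(step_mean) <= 0)) {
    stop("step means must be strictly increasing with state index (slow < medium < fast)")
  }
  if (any(angle_kappa < 0)) stop("angle concentrations must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(
    list(n_states = K, transition = transition,
         step_mean = step_mean, step_sd = step_sd,
         angle_mean = angle_mean, angle_kappa = angle_kappa, dt = dt),
    class = "kx_hmm_params"
  )
}

#' Default 3-state transition matrix (diagonally dominant)
#' @keywords internal
#' @export
default_transition_3 <- function() {
  matrix(c(0.85, 0.12, 0.03,
           0.10, 0.80, 0.10,
           0.05, 0.15, 0.80),
         nrow = 3, byrow = TRUE)
}

#' Stationary distribution of a row-stochastic matrix
#' @keywords internal
stationary_dist <- function(A) {
  K <- nrow(A)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Simulate one larval movement trajectory from a movement HMM
#'
#' Draws a hidden state chain from `params$transition` (started at its
#' stationary distribution), then a gamma step length and von Mises turn
#' angle per frame, and integrates headings into 2-D positions. The returned
#' table has `n_steps + 1` rows: the starting position plus one position per
#' step; column `state` carries the hidden state that generated the arriving
#' displacement (the first row repeats the first state).
#'
#' @param params a [hmm_params()] object.
#' @param n_steps number of movement steps (>= 1).
#' @param seed integer seed; same params + seed reproduce the trajectory
#'   exactly.
#' @param larva_id identifier attached to every row.
#' @param origin length-2 starting position (mm).
#' @param heading0 initial heading (rad); `NULL` draws it uniformly.
#' @return A tibble with columns `larva_id, t_s, x_mm, y_mm, period, light,
#'   state` and attribute `dt`.
#' @examples
#' tr <- gen_trajectory(hmm_params(), n_steps = 100, seed = 1)
#' total_distance(tr)
#' @export
gen_trajectory <- function(params, n_steps, seed = NULL, larva_id = "L1",
                           origin = c(0, 0), heading0 = NULL) {
  stopifnot(inherits(params, "kx_hmm_params"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  K <- params$n_states
  states <- integer(n_steps)
  states[1] <- sample.int(K, 1, prob = stationary_dist(params$transition))
  if (n_steps > 1) {
    for (t in 2:n_steps) {
      states[t] <- sample.int(K, 1, prob = params$transition[states[t - 1], ])
    }
  }
  steps <- numeric(n_steps)
  turns <- numeric(n_steps)
  for (k in seq_len(K)) {
    idx <- which(states == k)
    if (!length(idx)) next
    m <- params$step_mean[k]; s <- params$step_sd[k]
    steps[idx] <- if (s == 0) m else rgamma(length(idx), shape = (m / s)^2, scale = s^2 / m)
    turns[idx] <- rvonmises(length(idx), params$angle_mean[k], params$angle_kappa[k])
  }
  h0 <- if (is.null(heading0)) runif(1, -pi, pi) else heading0
  headings <- wrap_angle(h0 + cumsum(turns))
  x <- origin[1] + c(0, cumsum(steps * cos(headings)))
  y <- origin[2] + c(0, cumsum(steps * sin(headings)))
  out <- tibble(
    larva_id = larva_id,
    t_s = seq(0, n_steps) * params$dt,
    x_mm = x, y_mm = y,
    period = 1L, light = 1L,
    state = c(states[1], states)
  )
  attr(out, "dt") <- params$dt
  out
}

#' Assay period design
#'
#' Ordered, non-overlapping time periods of an assay record, each labelled
#' light or dark. Intervals are half-open `[start, end)` on a 0-based clock.
#'
#' @param label period labels (coerced to character).
#' @param start_s,end_s period bounds in seconds, `start_s < end_s`,
#'   non-overlapping in order.
#' @param light logical/0-1 flag per period.
#' @param assay one of `"vmr"`, `"locomotion"`, `"feeding"`.
#' @return A tibble of class `kx_period_design`.
#' @export
period_design <- function(label, start_s, end_s, light,
                          assay = c("vmr", "locomotion", "feeding")) {
  assay <- match.arg(assay)
  n <- length(label)
  stopifnot(length(start_s) == n, length(end_s) == n, length(light) == n)
  if (any(end_s <= start_s)) stop("each period must have start < end")
  o <- order(start_s)
  if (any(start_s[o][-1] < end_s[o][-n])) stop("periods must not overlap")
  out <- tibble(label = as.character(label), start_s = start_s[o],
                end_s = end_s[o], light = as.integer(light)[o])
  attr(out, "assay") <- assay
  class(out) <- c("kx_period_design", class(out))
  out
}

#' Default visual-motor-response (VMR) design
#'
#' Five equal periods alternating dark-light-dark-light-dark, the layout of
#' an assay whose light periods are the 2nd and 4th.
#'
#' @param period_s seconds per period.
#' @export
vmr_design <- function(period_s = 60) {
  period_design(label = as.character(1:5),
                start_s = (0:4) * period_s,
                end_s = (1:5) * period_s,
                light = c(0L, 1L, 0L, 1L, 0L),
                assay = "vmr")
}

#' Simulate a VMR-style trajectory with alternating light regimes
#'
#' Emits movement from `light_params` during light periods and `dark_params`
#' during dark periods; position and heading are continuous across period
#' boundaries while the hidden chain restarts at its stationary distribution
#' (regime changes are treated as exogenous resets). Every emitted point
#' carries its period label and light flag.
#'
#' @param light_params,dark_params [hmm_params()] objects; must share `dt`.
#' @param design a [period_design()]; defaults to [vmr_design()].
#' @param seed integer seed.
#' @param larva_id identifier attached to every row.
#' @return A tibble as in [gen_trajectory()], with true per-step states.
#' @export
gen_vmr_trajectory <- function(light_params, dark_params,
                               design = vmr_design(), seed = NULL,
                               larva_id = "L1") {
  stopifnot(inherits(light_params, "kx_hmm_params"),
            inherits(dark_params, "kx_hmm_params"),
            inherits(design, "kx_period_design"))
  if (light_params$dt != dark_params$dt) stop("light and dark params must share dt")
  if (!is.null(seed)) set.seed(seed)
  dt <- light_params$dt
  pos <- c(0, 0)
  heading <- runif(1, -pi, pi)
  pieces <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    p <- if (design$light[i] == 1L) light_params else dark_params
    n_steps <- floor((design$end_s[i] - design$start_s[i]) / dt)
    seg <- gen_trajectory(p, n_steps, seed = NULL, larva_id = larva_id,
                          origin = pos, heading0 = heading)
    # heading of the last step for continuity
    dx <- diff(utils::tail(seg$x_mm, 2)); dy <- diff(utils::tail(seg$y_mm, 2))
    if (dx != 0 || dy != 0) heading <- atan2(dy, dx)
    pos <- c(seg$x_mm[nrow(seg)], seg$y_mm[nrow(seg)])
    seg$t_s <- design$start_s[i] + seg$t_s
    seg$period <- i
    seg$light <- design$light[i]
    # drop the duplicated joint point for all but the first piece
    pieces[[i]] <- if (i == 1) seg else seg[-1, ]
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "dt") <- dt
  attr(out, "design") <- design
  out
}

#' Feeding-assay parameter set
#'
#' @param encounter_rate prey encounters per minute (>= 0).
#' @param p_attempt probability an encountered prey is attacked.
#' @param p_capture probability an attempted prey is captured.
#' @param reaction_distance `c(mean, sd)` in mm of the (zero-truncated
#'   normal) reaction distance.
#' @param handling_time `c(mean, sd)` in seconds of the (zero-truncated
#'   normal) handling time per captured prey.
#' @return An object of class `kx_feeding_params`.
#' @export
feeding_params <- function(encounter_rate = 2, p_attempt = 0.6,
                           p_capture = 0.5,
                           reaction_distance = c(4, 1),
                           handling_time = c(5, 1.5)) {
  stopifnot(encounter_rate >= 0,
            p_attempt >= 0, p_attempt <= 1,
            p_capture >= 0, p_capture <= 1)
  if (reaction_distance[1] <= 0 || handling_time[1] <= 0) stop("means must be > 0")
  if (reaction_distance[2] < 0 || handling_time[2] < 0) stop("sds must be >= 0")
  structure(list(encounter_rate = encounter_rate, p_attempt = p_attempt,
                 p_capture = p_capture, reaction_distance = reaction_distance,
                 handling_time = handling_time),
            class = "kx_feeding_params")
}

# exact inverse-CDF draw from N(mean, sd) truncated to (0, Inf)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Simulate feeding-assay event records for one larva
#'
#' Encounter count is Poisson(`encounter_rate * duration_min`); each
#' encounter is attacked with probability `p_attempt` and, if attacked,
#' captured with probability `p_capture`. Reaction distance is drawn per
#' encounter; handling time per captured prey (NA otherwise).
#'
#' @param params a [feeding_params()] object.
#' @param duration_min assay duration in minutes (> 0).
#' @param seed integer seed.
#' @param larva_id identifier.
#' @return A tibble with columns `larva_id, event_idx, attempted, captured,
#'   reaction_distance_mm, handling_time_s` (zero rows if no encounters).
#' @export
gen_feeding_events <- function(params, duration_min, seed = NULL,
                               larva_id = "L1") {
  stopifnot(inherits(params, "kx_feeding_params"))
  if (duration_min <= 0) stop("duration_min must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, params$encounter_rate * duration_min)
  if (n == 0) {
    return(tibble(larva_id = character(), event_idx = integer(),
                  attempted = integer(), captured = integer(),
                  reaction_distance_mm = numeric(), handling_time_s = numeric()))
  }
  attempted <- rbinom(n, 1, params$p_attempt)
  captured <- ifelse(attempted == 1, rbinom(n, 1, params$p_capture), 0L)
  ht <- rep(NA_real_, n)
  ht[captured == 1] <- rtruncnorm_pos(sum(captured), params$handling_time[1],
                                      params$handling_time[2])
  tibble(
    larva_id = larva_id, event_idx = seq_len(n),
    attempted = as.integer(attempted), captured = as.integer(captured),
    reaction_distance_mm = rtruncnorm_pos(n, params$reaction_distance[1],
                                          params$reaction_distance[2]),
    handling_time_s = ht
  )
}

#' Specification for a synthetic RNA-seq count simulation
#'
#' Two-group negative-binomial counts with a fraction of genes carrying a
#' planted log2 fold-change (half up, half down).
#'
#' @param n_genes,n_per_group dimensions of the simulated experiment.
#' @param baseline_mean expected count of a null gene.
#' @param dispersion NB dispersion (1/size); shared across genes unless
#'   `per_gene_dispersion` is TRUE, in which case per-gene dispersions are
#'   drawn around this value.
#' @param de_fraction fraction of genes with a planted effect, in \[0, 1\].
#' @param log2_fc planted absolute log2 fold-change.
#' @param per_gene_dispersion draw a per-gene dispersion (lognormal around
#'   `dispersion`) instead of a shared one.
#' @param seed integer seed.
#' @return An object of class `kx_count_spec`.
#' @export
count_sim_spec <- function(n_genes = 2000, n_per_group = 6,
                           baseline_mean = 100, dispersion = 0.2,
                           de_fraction = 0.1, log2_fc = 1,
                           per_gene_dispersion = FALSE, seed = 1L) {
  stopifnot(n_genes >= 1, n_per_group >= 2, baseline_mean > 0,
            dispersion > 0, de_fraction >= 0, de_fraction <= 1)
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 de_fraction = de_fraction, log2_fc = log2_fc,
                 per_gene_dispersion = per_gene_dispersion,
                 seed = as.integer(seed)),
            class = "kx_count_spec")
}

#' Simulate a gene x sample count matrix with planted fold-changes
#'
#' The first `round(de_fraction * n_genes)` genes carry the planted effect in
#' the second group: the first half up (`+log2_fc`), the second half down.
#'
#' @param spec a [count_sim_spec()].
#' @param groups length-2 character vector of group labels.
#' @return list with `counts` (integer matrix, genes x samples), `design`
#'   (tibble: sample, treatment) and `truth` (tibble: gene, is_de, direction
#'   in -1/0/+1).
#' @export
gen_counts <- function(spec, groups = c("ctrl", "trt")) {
  stopifnot(inherits(spec, "kx_count_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes; n <- spec$n_per_group
  n_de <- round(spec$de_fraction * G)
  direction <- integer(G)
  if (n_de > 0) {
    n_up <- ceiling(n_de / 2)
    direction[seq_len(n_de)] <- c(rep(1L, n_up), rep(-1L, n_de - n_up))
  }
  disp <- if (spec$per_gene_dispersion) {
    spec$dispersion * exp(rnorm(G, 0, 0.5))
  } else rep(spec$dispersion, G)
  mu1 <- rep(spec$baseline_mean, G)
  mu2 <- spec$baseline_mean * 2^(direction * spec$log2_fc)
  counts <- matrix(0L, G, 2 * n)
  for (g in seq_len(G)) {
    counts[g, ] <- c(rnbinom(n, mu = mu1[g], size = 1 / disp[g]),
                     rnbinom(n, mu = mu2[g], size = 1 / disp[g]))
  }
  rownames(counts) <- sprintf("gene%05d", seq_len(G))
  colnames(counts) <- c(sprintf("%s_%d", groups[1], seq_len(n)),
                        sprintf("%s_%d", groups[2], seq_len(n)))
  list(
    counts = counts,
    design = tibble(sample = colnames(counts),
                    treatment = rep(groups, each = n)),
    truth = tibble(gene = rownames(counts),
                   is_de = direction != 0L,
                   direction = direction)
  )
}
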