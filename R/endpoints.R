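# Per-larva behavior endpoints: distance, swimming bouts, step length,
# turning angle, startle and feeding metrics, evaluated overall and per assay
# period. Time is 0-based; windows and periods are half-open [start, end).

traj_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- median(diff(traj$t_s))
  dt
}

window_rows <- function(traj, window) {
  if (is.null(window)) return(traj)
  traj[traj$t_s >= window[1] & traj$t_s < window[2], , drop = FALSE]
}

#' Total distance traveled
#'
#' Sum of consecutive Euclidean displacements of one larva's positions,
#' optionally restricted to a half-open time window `[start, end)`.
#' Fewer than 2 positions in the window yields `NA` (undefined), not 0.
#'
#' @param traj single-larva trajectory tibble (`t_s, x_mm, y_mm`).
#' @param window optional `c(start_s, end_s)`.
#' @return distance in mm, or `NA_real_`.
#' @export
total_distance <- function(traj, window = NULL) {
  tr <- window_rows(traj, window)
  if (nrow(tr) < 2) return(NA_real_)
  sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
}

#' Per-frame step lengths (mm) and speeds (mm/s)
#'
#' @param traj single-larva trajectory.
#' @return tibble with `t_s` (arrival time), `step_mm`, `speed_mm_s`.
#' @export
step_lengths <- function(traj) {
  if (nrow(traj) < 2) {
    return(tibble(t_s = numeric(), step_mm = numeric(), speed_mm_s = numeric()))
  }
  dt <- traj_dt(traj)
  step <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  tibble(t_s = traj$t_s[-1], step_mm = step, speed_mm_s = step / dt)
}

#' Detect swimming bouts
#'
#' A bout is a maximal interval with speed >= `speed_threshold`; pauses
#' shorter than `min_pause` between two moving stretches are merged into the
#' surrounding bout. Each step occupies the interval ending at its arrival
#' time.
#'
#' @param traj single-larva trajectory.
#' @param speed_threshold mm/s.
#' @param min_pause seconds; pauses shorter than this do not break a bout.
#' @return tibble of bouts (`start_s`, `end_s`, `duration_s`); zero rows if
#'   the larva never moves above threshold.
#' @export
detect_bouts <- function(traj, speed_threshold = 5, min_pause = 0.2) {
  sl <- step_lengths(traj)
  if (nrow(sl) == 0) {
    return(tibble(start_s = numeric(), end_s = numeric(), duration_s = numeric()))
  }
  dt <- traj_dt(traj)
  moving <- sl$speed_mm_s >= speed_threshold
  r <- rle(moving)
  # merge interior pauses shorter than min_pause
  if (length(r$lengths) > 2) {
    for (i in seq(2, length(r$values) - 1)) {
      if (!r$values[i] && r$lengths[i] * dt < min_pause) r$values[i] <- TRUE
    }
  }
  moving2 <- inverse.rle(r)
  r2 <- rle(moving2)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1
  keep <- which(r2$values)
  if (!length(keep)) {
    return(tibble(start_s = numeric(), end_s = numeric(), duration_s = numeric()))
  }
  start_s <- sl$t_s[starts[keep]] - dt   # departure time of the first step
  end_s <- sl$t_s[ends[keep]]
  tibble(start_s = start_s, end_s = end_s, duration_s = end_s - start_s)
}

#' Bout summary endpoints
#'
#' @param bouts output of [detect_bouts()].
#' @param record_duration_s duration of the analysed record, for the
#'   per-second bout frequency.
#' @return named list: `bout_count`, `bout_freq_per_s`, `bout_duration_mean_s`
#'   (`NA` if no bouts), `total_time_swimming_s`.
#' @export
bout_stats <- function(bouts, record_duration_s) {
  n <- nrow(bouts)
  list(
    bout_count = n,
    bout_freq_per_s = n / record_duration_s,
    bout_duration_mean_s = if (n) mean(bouts$duration_s) else NA_real_,
    total_time_swimming_s = sum(bouts$duration_s)
  )
}

#' Signed turning angles of a trajectory
#'
#' Angle between consecutive displacement vectors, in (-pi, pi], computed as
#' atan2(cross, dot). Steps with zero displacement yield no angle; the count
#' of skipped angles is returned as attribute `n_skipped`.
#'
#' @param traj single-larva trajectory with >= 3 positions.
#' @return numeric vector of angles (rad).
#' @export
turning_angles <- function(traj) {
  if (nrow(traj) < 3) stop("turning angles need >= 3 positions")
  dx <- diff(traj$x_mm); dy <- diff(traj$y_mm)
  nz <- dx != 0 | dy != 0
  dxm <- dx[nz]; dym <- dy[nz]
  n <- length(dxm)
  if (n < 2) {
    out <- numeric(0)
    attr(out, "n_skipped") <- sum(!nz)
    return(out)
  }
  v1x <- dxm[-n]; v1y <- dym[-n]
  v2x <- dxm[-1]; v2y <- dym[-1]
  out <- atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
  attr(out, "n_skipped") <- sum(!nz)
  out
}

#' Circular mean and circular variance of an angle series
#'
#' The "mean" and "variation" turning-angle endpoints: circular mean
#' atan2(mean sin, mean cos) and circular variance 1 - R (resultant length),
#' which respects the wrap-around of angles.
#'
#' @param theta angles (rad).
#' @return list(mean, var); `NA`s for an empty series.
#' @export
circular_summary <- function(theta) {
  if (!length(theta)) return(list(mean = NA_real_, var = NA_real_))
  C <- mean(cos(theta)); S <- mean(sin(theta))
  list(mean = atan2(S, C), var = 1 - sqrt(C^2 + S^2))
}

#' Startle magnitude around a light transition
#'
#' Distance traveled in the `window` seconds after `transition_time` minus
#' the distance in the equal window before it (both half-open); positive
#' values mean a movement burst at the transition, negative values a freeze.
#'
#' @param traj single-larva trajectory.
#' @param transition_time seconds; must lie inside the record.
#' @param window seconds.
#' @return mm (may be negative).
#' @export
startle_magnitude <- function(traj, transition_time, window = 2) {
  t0 <- min(traj$t_s); t1 <- max(traj$t_s)
  if (transition_time < t0 || transition_time > t1) {
    stop("transition_time outside the record")
  }
  if (transition_time - window < t0 || transition_time + window > t1) {
    stop("startle window extends beyond the record")
  }
  # closed windows on positions: the displacements then partition
  # (t - w, t] and (t, t + w]
  dist_closed <- function(a, b) {
    tr <- traj[traj$t_s >= a & traj$t_s <= b, , drop = FALSE]
    if (nrow(tr) < 2) return(NA_real_)
    sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
  }
  dist_closed(transition_time, transition_time + window) -
    dist_closed(transition_time - window, transition_time)
}

#' Feeding-assay endpoints
#'
#' The five feeding endpoints from one larva's event records: capture
#' attempts (count), capture probability (captures/attempts), capture
#' attempt ratio (attempts/encounters), mean reaction distance and mean
#' handling time. Ratio endpoints with an empty denominator are `NA`.
#'
#' @param events event tibble from [gen_feeding_events()] (one larva).
#' @return tibble with columns `endpoint`, `value`.
#' @export
feeding_endpoints <- function(events) {
  enc <- nrow(events)
  att <- sum(events$attempted)
  cap <- sum(events$captured)
  tibble(
    endpoint = c("capture_attempts", "capture_probability",
                 "capture_attempt_ratio", "reaction_distance_mm",
                 "handling_time_s"),
    value = c(att,
              if (att > 0) cap / att else NA_real_,
              if (enc > 0) att / enc else NA_real_,
              if (enc > 0) mean(events$reaction_distance_mm) else NA_real_,
              if (cap > 0) mean(events$handling_time_s, na.rm = TRUE) else NA_real_)
  )
}

swim_endpoints_window <- function(traj, window, speed_threshold, min_pause) {
  tr <- window_rows(traj, window)
  dur <- if (is.null(window)) diff(range(traj$t_s)) else window[2] - window[1]
  if (nrow(tr) < 2) {
    vals <- rep(NA_real_, 10)
  } else {
    bouts <- detect_bouts(tr, speed_threshold, min_pause)
    bs <- bout_stats(bouts, dur)
    sl <- step_lengths(tr)
    ang <- if (nrow(tr) >= 3) turning_angles(tr) else numeric(0)
    cs <- circular_summary(ang)
    vals <- c(total_distance(tr), bs$total_time_swimming_s, bs$bout_count,
              bs$bout_freq_per_s, bs$bout_duration_mean_s,
              mean(sl$step_mm), sd(sl$step_mm), cs$mean, cs$var, NA_real_)
  }
  tibble(
    endpoint = c("total_distance_mm", "total_time_swimming_s", "bout_count",
                 "bout_freq_per_s", "bout_duration_mean_s", "step_length_mean_mm",
                 "step_length_sd_mm", "turn_angle_mean_rad", "turn_angle_var",
                 "startle_magnitude_mm"),
    value = vals
  )
}

#' Behavior endpoint table
#'
#' Evaluates the swimming endpoint catalogue (and, for VMR designs, startle
#' magnitude at each period transition) for every larva, overall and per
#' period, and/or the feeding endpoints from event records. Long format:
#' one row per (larva, endpoint, period).
#'
#' @param traj trajectory tibble, possibly multi-larva (grouped by
#'   `larva_id`); `NULL` to skip swimming endpoints.
#' @param events feeding event tibble, possibly multi-larva; `NULL` to skip.
#' @param design optional [period_design()]; when given, per-period endpoint
#'   rows are added (period = the period label) next to `period = "overall"`.
#' @param speed_threshold,min_pause bout-detection settings (mm/s, s).
#' @param startle_window seconds for the startle endpoint at period
#'   transitions (VMR designs only).
#' @return tibble `larva_id, endpoint, period, value`.
#' @export
endpoint_table <- function(traj = NULL, events = NULL, design = NULL,
                           speed_threshold = 5, min_pause = 0.2,
                           startle_window = 2) {
  out <- list()
  if (!is.null(traj)) {
    for (id in unique(traj$larva_id)) {
      tr <- traj[traj$larva_id == id, , drop = FALSE]
      attr(tr, "dt") <- attr(traj, "dt")
      tab <- swim_endpoints_window(tr, NULL, speed_threshold, min_pause)
      tab$period <- "overall"
      rows <- list(tab)
      if (!is.null(design)) {
        for (i in seq_len(nrow(design))) {
          ptab <- swim_endpoints_window(tr, c(design$start_s[i], design$end_s[i]),
                                        speed_threshold, min_pause)
          ptab$period <- design$label[i]
          if (i > 1 && identical(attr(design, "assay"), "vmr")) {
            ptab$value[ptab$endpoint == "startle_magnitude_mm"] <-
              tryCatch(startle_magnitude(tr, design$start_s[i], startle_window),
                       error = function(e) NA_real_)
          }
          rows[[length(rows) + 1]] <- ptab
        }
      }
      tab <- dplyr::bind_rows(rows)
      tab$larva_id <- id
      out[[length(out) + 1]] <- tab
    }
  }
  if (!is.null(events) && nrow(events)) {
    for (id in unique(events$larva_id)) {
      fe <- feeding_endpoints(events[events$larva_id == id, , drop = FALSE])
      fe$period <- "overall"
      fe$larva_id <- id
      out[[length(out) + 1]] <- fe
    }
  }
  if (!length(out)) {
    return(tibble(larva_id = character(), endpoint = character(),
                  period = character(), value = numeric()))
  }
  dplyr::bind_rows(out)[, c("larva_id", "endpoint", "period", "value")]
}
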