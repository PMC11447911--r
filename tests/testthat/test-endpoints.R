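# Behavior endpoint extraction: distance, bouts, angles, startle, feeding.

test_that("total distance handles degenerate, analytic and random paths", {
  still <- traj_from_xy(rep(1, 10), rep(2, 10))
  expect_equal(total_distance(still), 0)

  tri <- traj_from_xy(c(0, 3, 3), c(0, 0, 4))
  expect_equal(total_distance(tri), 7)            # 3-4-5 triangle

  expect_true(is.na(total_distance(traj_from_xy(1, 1))))

  set.seed(9)
  x <- cumsum(rnorm(1000)); y <- cumsum(rnorm(1000))
  tr <- traj_from_xy(x, y)
  brute <- 0
  for (i in 2:1000) brute <- brute + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  expect_equal(total_distance(tr), brute)
})

test_that("bout detection finds, merges and counts movement intervals", {
  dt <- 0.1
  mk <- function(speeds) {     # build a trajectory with given per-step speeds
    traj_from_xy(c(0, cumsum(speeds * dt)), rep(0, length(speeds) + 1), dt = dt)
  }
  # always above threshold: one bout spanning the record
  b <- detect_bouts(mk(rep(10, 50)), speed_threshold = 5, min_pause = 0.2)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 50 * dt)

  # move - long pause - move: two bouts
  b2 <- detect_bouts(mk(c(rep(10, 10), rep(0, 10), rep(10, 10))),
                     speed_threshold = 5, min_pause = 0.2)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$duration_s, c(1, 1))

  # pause shorter than min_pause is merged
  b3 <- detect_bouts(mk(c(rep(10, 10), 0, rep(10, 10))),
                     speed_threshold = 5, min_pause = 0.2)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$duration_s, 2.1)

  # never moving
  b4 <- detect_bouts(mk(rep(0, 30)), speed_threshold = 5, min_pause = 0.2)
  expect_equal(nrow(b4), 0)
  expect_equal(bout_stats(b4, 3)$total_time_swimming_s, 0)
  expect_equal(bout_stats(b4, 3)$bout_count, 0)
})

test_that("turning angles match geometry and an independent oracle", {
  line <- traj_from_xy(0:10, rep(0, 11))
  expect_true(all(turning_angles(line) == 0))

  square <- traj_from_xy(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(abs(as.numeric(turning_angles(square))), rep(pi / 2, 3))

  set.seed(3)
  x <- cumsum(rnorm(500)); y <- cumsum(rnorm(500))
  got <- turning_angles(traj_from_xy(x, y))
  # oracle: acos of normalized dot, signed by the cross product
  dx <- diff(x); dy <- diff(y)
  n <- length(dx)
  oracle <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    v1 <- c(dx[i], dy[i]); v2 <- c(dx[i + 1], dy[i + 1])
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
    s <- sign(v1[1] * v2[2] - v1[2] * v2[1])
    oracle[i] <- if (s == 0) ang else s * ang
  }
  expect_equal(as.numeric(got), oracle, tolerance = 1e-10)

  # zero-length displacement: angle skipped, not fabricated
  paused <- traj_from_xy(c(0, 1, 1, 2), c(0, 0, 0, 0))
  a <- turning_angles(paused)
  expect_equal(length(a), 1)
  expect_equal(attr(a, "n_skipped"), 1)
})

test_that("startle magnitude is a post-minus-pre window distance", {
  dt <- 0.5
  same <- traj_from_xy(cumsum(rep(1, 21)), rep(0, 21), dt = dt)
  expect_equal(startle_magnitude(same, transition_time = 5, window = 2), 0)

  # still before the transition, 5 mm of travel after
  x <- c(rep(0, 11), cumsum(rep(1.25, 10)))
  burst <- traj_from_xy(x, rep(0, 21), dt = dt)
  expect_equal(startle_magnitude(burst, transition_time = 5, window = 2), 5)

  expect_error(startle_magnitude(same, transition_time = 9.5, window = 2),
               "window")
  expect_error(startle_magnitude(same, transition_time = 50, window = 2),
               "outside")
})

test_that("feeding endpoints follow their defining ratios", {
  mk_events <- function(enc, att, cap) {
    tibble::tibble(larva_id = "L1", event_idx = seq_len(enc),
                   attempted = rep(c(1L, 0L), c(att, enc - att)),
                   captured = rep(c(1L, 0L), c(cap, enc - cap)),
                   reaction_distance_mm = rep(4, enc),
                   handling_time_s = ifelse(seq_len(enc) <= cap, 5, NA))
  }
  perfect <- feeding_endpoints(mk_events(10, 10, 10))
  v <- setNames(perfect$value, perfect$endpoint)
  expect_equal(v[["capture_attempts"]], 10)
  expect_equal(v[["capture_probability"]], 1)
  expect_equal(v[["capture_attempt_ratio"]], 1)

  partial <- feeding_endpoints(mk_events(8, 4, 1))
  v <- setNames(partial$value, partial$endpoint)
  expect_equal(v[["capture_attempt_ratio"]], 0.5)
  expect_equal(v[["capture_probability"]], 0.25)

  none <- feeding_endpoints(mk_events(5, 0, 0))
  v <- setNames(none$value, none$endpoint)
  expect_true(is.na(v[["capture_probability"]]))

  # events simulated at known p recover p within a binomial CI
  ev <- gen_feeding_events(feeding_params(encounter_rate = 3000, p_attempt = 1,
                                          p_capture = 0.6), 1, seed = 4)
  v <- setNames(feeding_endpoints(ev)$value, feeding_endpoints(ev)$endpoint)
  expect_lt(abs(v[["capture_probability"]] - 0.6),
            3 * sqrt(0.6 * 0.4 / nrow(ev)))
})

test_that("endpoint table composes per-larva, per-period single calls", {
  p <- hmm_params()
  des <- vmr_design(period_s = 2)
  tr1 <- gen_vmr_trajectory(p, p, des, seed = 1, larva_id = "A")
  tr2 <- gen_vmr_trajectory(p, p, des, seed = 2, larva_id = "B")
  both <- dplyr::bind_rows(tr1, tr2)
  attr(both, "dt") <- attr(tr1, "dt")
  tab <- endpoint_table(traj = both, design = des)

  expect_setequal(unique(tab$period), c("overall", as.character(1:5)))
  expect_equal(nrow(tab), 2 * 10 * 6)      # larvae x endpoints x (overall+5)

  # compositional check against a direct single-larva, single-window call
  got <- tab$value[tab$larva_id == "A" & tab$endpoint == "total_distance_mm" &
                     tab$period == "3"]
  expect_equal(got, total_distance(tr1, c(des$start_s[3], des$end_s[3])))
  got_all <- tab$value[tab$larva_id == "B" & tab$endpoint == "total_distance_mm" &
                         tab$period == "overall"]
  expect_equal(got_all, total_distance(tr2))
})

test_that("endpoints are invariant to rigid motion and consistent across periods", {
  p <- hmm_params()
  des <- vmr_design(period_s = 2)
  tr <- gen_vmr_trajectory(p, p, des, seed = 11)
  th <- 0.7
  rot <- tr
  rot$x_mm <- cos(th) * tr$x_mm - sin(th) * tr$y_mm + 12
  rot$y_mm <- sin(th) * tr$x_mm + cos(th) * tr$y_mm - 3
  expect_equal(total_distance(rot), total_distance(tr))
  expect_equal(abs(turning_angles(rot)), abs(turning_angles(tr)), tolerance = 1e-9)
  expect_equal(detect_bouts(rot, 5, 0.2), detect_bouts(tr, 5, 0.2), tolerance = 1e-9)

  # per-period distances sum to the overall distance within one-step slack
  per <- vapply(1:5, function(i) total_distance(tr, c(des$start_s[i], des$end_s[i])), 0)
  overall <- total_distance(tr)
  expect_lte(sum(per), overall + 1e-9)
  max_step <- max(step_lengths(tr)$step_mm)
  expect_lt(overall - sum(per), 5 * max_step)

  # total time swimming never exceeds the record duration
  bs <- bout_stats(detect_bouts(tr, 5, 0.2), diff(range(tr$t_s)))
  expect_lte(bs$total_time_swimming_s, diff(range(tr$t_s)) + 1e-9)
})
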