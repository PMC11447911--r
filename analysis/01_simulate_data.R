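#!/usr/bin/env Rscript
# Simulate every input the pipeline consumes, for the five-treatment,
# two-population design: free-swimming locomotion trajectories, alternating
# light/dark (VMR) trajectories, feeding-assay event records, and brain
# expression count matrices with planted fold-changes whose relative sizes
# mirror the design's expected contrast strengths (population >> reference
# PCB > PCB-vs-PCB > MeHg > tolerant PCB).
#
# Outputs under results/sim/.

suppressMessages({library(killitox); library(dplyr)})
set.seed(101)
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

n_larvae <- 8

# per-treatment movement models: PCB slows the reference population
# (smaller fast-state steps, more dwell in slow), mildly alters the
# tolerant one; MeHg nudges dwell in medium/fast upward
base_T <- default_transition_3()
tweak <- function(p_slow_stay = 0, fast_step = 1) {
  Tm <- base_T
  Tm[1, 1] <- Tm[1, 1] + p_slow_stay
  Tm[1, 2:3] <- Tm[1, 2:3] * (1 - Tm[1, 1]) / sum(Tm[1, 2:3])
  hmm_params(transition = Tm, step_mean = c(0.08, 0.35, 1.1 * fast_step))
}
movement <- list(
  "SCO-Ctrl" = tweak(),
  "SCO-MeHg" = tweak(p_slow_stay = -0.03),
  "SCO-PCB"  = tweak(p_slow_stay = 0.06, fast_step = 0.8),
  "NBH-Ctrl" = tweak(p_slow_stay = 0.02),
  "NBH-PCB"  = tweak(p_slow_stay = 0.05, fast_step = 0.9)
)

# feeding models: handling time up under PCB everywhere; MeHg improves
# capture probability and reaction distance
feeding <- list(
  "SCO-Ctrl" = feeding_params(),
  "SCO-MeHg" = feeding_params(p_capture = 0.58, reaction_distance = c(4.4, 1)),
  "SCO-PCB"  = feeding_params(p_capture = 0.42, handling_time = c(8, 1.5),
                              reaction_distance = c(3.6, 1)),
  "NBH-Ctrl" = feeding_params(p_capture = 0.55, reaction_distance = c(4.3, 1)),
  "NBH-PCB"  = feeding_params(p_capture = 0.52, handling_time = c(5.5, 1.5),
                              reaction_distance = c(4.0, 1))
)

loco <- list(); vmr <- list(); feed <- list()
des <- vmr_design(period_s = 30)
for (trt in names(movement)) {
  for (i in seq_len(n_larvae)) {
    id <- sprintf("%s_L%02d", trt, i)
    s <- sum(utf8ToInt(id))
    tr <- gen_trajectory(movement[[trt]], 2400, seed = s, larva_id = id)
    tr$treatment <- trt
    loco[[id]] <- tr
    tv <- gen_vmr_trajectory(movement[[trt]],
                             tweak(p_slow_stay = -0.02),  # dark: more active
                             design = des, seed = s + 1, larva_id = id)
    tv$treatment <- trt
    vmr[[id]] <- tv
    fe <- gen_feeding_events(feeding[[trt]], duration_min = 10, seed = s + 2,
                             larva_id = id)
    if (nrow(fe)) fe$treatment <- trt
    feed[[id]] <- fe
  }
}
write.csv(bind_rows(loco), "results/sim/trajectories_locomotion.csv", row.names = FALSE)
write.csv(bind_rows(vmr), "results/sim/trajectories_vmr.csv", row.names = FALSE)
write.csv(bind_rows(feed), "results/sim/feeding_events.csv", row.names = FALSE)
cat("simulated", length(loco), "locomotion and", length(vmr), "VMR trajectories,",
    sum(sapply(feed, nrow)), "feeding events\n")

# counts per planned comparison; planted fractions mirror the relative
# contrast strengths of the design
plan <- comparison_plan()
de_fracs <- c(0.005, 0.024, 0.20, 0.013, 0.002)
for (i in seq_len(nrow(plan))) {
  x <- gen_counts(count_sim_spec(n_genes = 2000, n_per_group = 6,
                                 de_fraction = de_fracs[i], log2_fc = 1.5,
                                 seed = 300 + i),
                  groups = c(plan$first[i], plan$second[i]))
  slug <- gsub("[^A-Za-z0-9]", "_", plan$comparison[i])
  write.table(x$counts, sprintf("results/sim/counts_%s.tsv", slug),
              sep = "\t", quote = FALSE)
  write.table(x$design, sprintf("results/sim/design_%s.tsv", slug),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$truth, sprintf("results/sim/truth_%s.tsv", slug),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("counts for %-22s: %d genes, %d planted\n", plan$comparison[i],
              nrow(x$counts), sum(x$truth$is_de)))
}
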