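# Trend calling: behavior comparisons, NB differential expression, BH,
# multiplicity arithmetic, gene-set over-representation.

two_arm_data <- function(m1, m2, n = 20, sd = 1, seed = 1,
                         arms = c("SCO-Ctrl", "SCO-PCB")) {
  set.seed(seed)
  tibble::tibble(
    endpoint = "ep",
    treatment = rep(arms, each = n),
    value = c(rnorm(n, m1, sd), rnorm(n, m2, sd)))
}

test_that("behavior trend calls are antisymmetric under pair reversal", {
  d <- two_arm_data(10, 13, seed = 2)
  plan_fwd <- comparison_plan(first = "SCO-Ctrl", second = "SCO-PCB")
  plan_rev <- comparison_plan(first = "SCO-PCB", second = "SCO-Ctrl")
  fwd <- compare_behavior(d, plan_fwd, seed = 7)
  rev <- compare_behavior(d, plan_rev, seed = 7)
  expect_equal(fwd$estimate, -rev$estimate)
  expect_equal(fwd$lo, -rev$hi)
  expect_equal(fwd$hi, -rev$lo)
  expect_equal(fwd$call, "Pos")
  expect_equal(rev$call, "Neg")
})

test_that("a 5-SD shift is called Pos essentially always", {
  plan <- comparison_plan(first = "SCO-Ctrl", second = "SCO-PCB")
  calls <- vapply(1:20, function(s) {
    compare_behavior(two_arm_data(10, 15, n = 20, sd = 1, seed = s),
                     plan, seed = s)$call
  }, "")
  expect_true(all(calls == "Pos"))
})

test_that("degenerate zero-variance equal arms give NS with a warning", {
  d <- tibble::tibble(endpoint = "ep",
                      treatment = rep(c("A", "B"), each = 5),
                      value = rep(3, 10))
  plan <- comparison_plan(first = "A", second = "B")
  expect_warning(res <- compare_behavior(d, plan), "degenerate")
  expect_equal(res$call, "NS")
})

test_that("welch fallback and log transform behave like the main path", {
  d <- two_arm_data(10, 14, seed = 3)
  plan <- comparison_plan(first = "SCO-Ctrl", second = "SCO-PCB")
  expect_equal(compare_behavior(d, plan, method = "welch")$call, "Pos")
  expect_equal(compare_behavior(d, plan, transform = "log", seed = 1)$call, "Pos")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  # min_{j>=i} p_(j) * m / j with m = 4:
  # (0.01,0.02,0.03,0.04) -> (0.04, 0.04, 0.04, 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  q <- bh_adjust(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.5)))  # NA excluded from m
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH q-values dominate p and are monotone in sorted p", {
  set.seed(4)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    # the adjustment is a monotone operator: re-adjusting never shrinks
    expect_true(all(bh_adjust(q) >= q - 1e-12))
    # equal p-values are fixed points of the adjustment
    expect_equal(bh_adjust(rep(p[1], 10)), rep(p[1], 10))
  }
})

test_that("expected chance significances follow alpha x m", {
  expect_equal(expected_false_positives(0.05, 83), 4.15)
  expect_equal(expected_false_positives(0.1, 40), 4.0)
  expect_error(expected_false_positives(0, 10))
  expect_error(expected_false_positives(0.05, 0))
})

test_that("DE log-fold-changes negate under a group-label swap", {
  x <- gen_counts(count_sim_spec(n_genes = 60, n_per_group = 4, log2_fc = 1.5,
                                 de_fraction = 0.3, seed = 8))
  fwd <- de_test(x$counts, x$design, groups = c("ctrl", "trt"))
  rev <- de_test(x$counts, x$design, groups = c("trt", "ctrl"))
  expect_equal(fwd$table$estimate, -rev$table$estimate, tolerance = 1e-8)
  swapped <- ifelse(fwd$table$call == "Pos", "Neg",
                    ifelse(fwd$table$call == "Neg", "Pos", "NS"))
  expect_equal(rev$table$call, swapped)
})

test_that("planted fold-changes are detected with high power", {
  x <- gen_counts(count_sim_spec(n_genes = 300, n_per_group = 6,
                                 baseline_mean = 100, log2_fc = 2,
                                 de_fraction = 0.1, seed = 12))
  de <- de_test(x$counts, x$design)
  tab <- dplyr::left_join(de$table, x$truth, by = "gene")
  expect_gte(mean(tab$call[tab$is_de] != "NS"), 0.8)
  # planted direction is recovered on the called genes
  called <- tab[tab$is_de & tab$call != "NS", ]
  expect_true(all(ifelse(called$direction == 1, "Pos", "Neg") == called$call))
})

test_that("all-zero and low-count genes are filtered, not tested", {
  x <- gen_counts(count_sim_spec(n_genes = 40, n_per_group = 4, seed = 3))
  x$counts[5, ] <- 0L
  x$counts[9, ] <- c(rep(0L, 7), 1L)
  de <- de_test(x$counts, x$design)
  expect_setequal(de$filtered, c("gene00005", "gene00009"))
  expect_false(any(de$table$gene %in% de$filtered))
})

test_that("NB fold-change estimates agree with edgeR on a shared fixture", {
  skip_if_not_installed("edgeR")
  x <- gen_counts(count_sim_spec(n_genes = 150, n_per_group = 6, log2_fc = 2,
                                 de_fraction = 0.2, seed = 21))
  de <- de_test(x$counts, x$design)
  y <- edgeR::DGEList(counts = x$counts,
                      group = factor(x$design$treatment, c("ctrl", "trt")))
  y <- edgeR::estimateDisp(y, model.matrix(~group, data = list(group = y$samples$group)))
  et <- edgeR::exactTest(y)
  common <- intersect(de$table$gene, rownames(et$table))
  r <- cor(de$table$estimate[match(common, de$table$gene)],
           et$table[common, "logFC"])
  expect_gt(r, 0.97)
  # strong planted genes are found by both routes
  strong <- x$truth$gene[x$truth$is_de]
  edger_called <- rownames(et$table)[p.adjust(et$table$PValue, "BH") < 0.05]
  both <- intersect(strong, de$table$gene[de$table$call != "NS"])
  expect_gt(length(intersect(both, edger_called)) / length(strong), 0.8)
})

test_that("gene-set over-representation matches the exact hypergeometric tail", {
  calls <- tibble::tibble(gene = paste0("g", 1:20),
                          call = rep(c("Pos", "NS"), c(6, 14)))
  sets <- list(hit_heavy = paste0("g", c(1, 2, 3, 4, 15)),
               everything = paste0("g", 1:20))
  res <- gene_set_test(calls, sets)
  pos <- res[res$direction == "Pos", ]
  # oracle: P(X >= 4), X ~ Hypergeom(N=20, K=6 hits, n=5 drawn)
  tail_p <- sum(vapply(4:5, function(k) {
    choose(6, k) * choose(14, 5 - k) / choose(20, 5)
  }, 0))
  expect_equal(pos$p[pos$set == "hit_heavy"], tail_p, tolerance = 1e-12)
  expect_equal(pos$p[pos$set == "everything"], 1)

  # a set holding exactly the Pos genes is the most enriched possible
  sets2 <- c(sets, list(exact_hits = paste0("g", 1:6)))
  res2 <- gene_set_test(calls, sets2)
  pos2 <- res2[res2$direction == "Pos", ]
  expect_equal(pos2$set[which.min(pos2$p)], "exact_hits")

  # empty-after-intersection sets are skipped
  sets3 <- list(alien = c("zz1", "zz2"))
  expect_equal(nrow(gene_set_test(calls, sets3)), 0)
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst set\tg1\tg2\tg3",
               "setB\tsecond set\tg2\tg4"), path)
  gmt <- read_gmt(path)
  expect_equal(gmt$set, c("setA", "setB"))
  expect_equal(gmt$genes[[1]], c("g1", "g2", "g3"))
  expect_equal(gmt$description[2], "second set")
})
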