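#!/usr/bin/env Rscript
# Group genes and behavior endpoints by identical trend pattern across the
# five ordered comparisons, and match genes to behaviors whose patterns are
# identical ("original") or exactly sign-flipped ("opposite").
#
# Writes results/pattern_groups.tsv and results/gene_behavior_matches.tsv.

suppressMessages({library(killitox); library(dplyr)})
plan <- comparison_plan()

beh <- read.csv("results/behavior_trends.tsv", sep = "\t")
genes <- read.csv("results/gene_trends.tsv", sep = "\t")

bv <- encode_trend_vector(beh, plan, kind = "behavior")
gv <- encode_trend_vector(genes |> rename(id = gene), plan, kind = "gene")
cat("eligible behavior endpoints:", sum(bv$eligible), "of", nrow(bv), "\n")
cat("eligible genes:", sum(gv$eligible), "of", nrow(gv), "\n")

groups <- group_by_pattern(bind_rows(bv, gv))
groups_out <- groups |> mutate(ids = sapply(ids, paste, collapse = ";"))
write.table(groups_out, "results/pattern_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("distinct non-null patterns:", nrow(groups), "; largest group:",
    groups$n[1], "members (", groups$pattern[1], ")\n")

matches <- match_gene_behavior(gv, bv, allow_opposite = TRUE)
write.table(matches, "results/gene_behavior_matches.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("gene-behavior matches:", sum(matches$type == "original"), "original,",
    sum(matches$type == "opposite"), "opposite\n")
if (nrow(matches)) {
  cat("most shared pattern among matches:",
      names(sort(table(matches$pattern), decreasing = TRUE))[1], "\n")
}
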