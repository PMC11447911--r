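#!/usr/bin/env Rscript
# Call Pos/Neg/NS trends across the five ordered treatment comparisons:
# behavior endpoints (including the decoded per-larva HMM endpoints) through
# the Bayesian two-arm comparison, genes through per-gene negative binomial
# models at FDR 0.05, and direction-aware gene-set over-representation.
#
# Writes results/behavior_trends.tsv, results/gene_trends.tsv,
# results/gene_set_enrichment.tsv.

suppressMessages({library(killitox); library(dplyr)})
plan <- comparison_plan()

## behavior ------------------------------------------------------------------
eps <- read.csv("results/endpoints.tsv", sep = "\t")
hmm_eps <- read.csv("results/hmm_larva_endpoints.tsv", sep = "\t")
hmm_eps$period <- "overall"; hmm_eps$assay <- "hmm"
all_eps <- bind_rows(eps, hmm_eps) |>
  mutate(endpoint = paste(assay, endpoint, period, sep = "."))
beh <- compare_behavior(all_eps |> select(endpoint, treatment, value),
                        plan, seed = 17)
write.table(beh, "results/behavior_trends.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("behavior trend calls:\n")
print(table(beh$call))
m <- length(unique(beh$id)) * nrow(plan)
cat(sprintf("expected by chance at alpha 0.05 over %d tests: %.2f\n",
            m, expected_false_positives(0.05, m)))

## genes ---------------------------------------------------------------------
gene_rows <- list()
for (i in seq_len(nrow(plan))) {
  slug <- gsub("[^A-Za-z0-9]", "_", plan$comparison[i])
  counts <- as.matrix(read.csv(sprintf("results/sim/counts_%s.tsv", slug),
                               sep = "\t", check.names = FALSE))
  design <- read.csv(sprintf("results/sim/design_%s.tsv", slug), sep = "\t")
  de <- de_test(counts, design, groups = c(plan$first[i], plan$second[i]))
  tab <- de$table
  tab$comparison <- plan$comparison[i]
  gene_rows[[i]] <- tab
  cat(sprintf("%-22s: %d genes called (%d filtered)\n", plan$comparison[i],
              sum(tab$call != "NS"), length(de$filtered)))
}
genes <- bind_rows(gene_rows)
write.table(genes, "results/gene_trends.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## gene sets -----------------------------------------------------------------
gmt <- read_gmt(system.file("extdata", "brain_gene_sets_synthetic.gmt",
                            package = "killitox"))
gs_rows <- list()
for (i in seq_len(nrow(plan))) {
  calls <- genes |> filter(comparison == plan$comparison[i])
  gs <- gene_set_test(calls, gmt)
  if (nrow(gs)) { gs$comparison <- plan$comparison[i]; gs_rows[[i]] <- gs }
}
gs <- bind_rows(gs_rows)
write.table(gs, "results/gene_set_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("gene sets nominally enriched (p < 0.05):", sum(gs$p < 0.05), "of",
    nrow(gs), "set x direction x comparison tests\n")
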