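# Pos/Neg/NS trend calling across the ordered treatment comparisons:
# a Bayesian two-arm comparison for behavior endpoints, per-gene negative
# binomial models with BH false-discovery control for expression, and
# direction-aware gene-set over-representation.

#' The ordered treatment comparison plan
#'
#' Defaults to the five comparisons of the two-population design: the MeHg
#' contrast in the reference population, and the four PCB126/population
#' contrasts. Trend signs are read as second-minus-first.
#'
#' @param first,second equal-length character vectors of treatment labels.
#' @return tibble of class `kx_plan` (`comparison, first, second`).
#' @export
comparison_plan <- function(
    first = c("SCO-Ctrl", "SCO-Ctrl", "SCO-Ctrl", "SCO-PCB", "NBH-Ctrl"),
    second = c("SCO-MeHg", "SCO-PCB", "NBH-Ctrl", "NBH-PCB", "NBH-PCB")) {
  stopifnot(length(first) == length(second))
  if (any(first == second)) stop("a comparison must involve two distinct treatments")
  key <- paste(first, second, sep = "|")
  if (anyDuplicated(key)) stop("duplicate comparison pairs")
  out <- tibble(comparison = paste(first, "vs", second),
                first = first, second = second)
  class(out) <- c("kx_plan", class(out))
  out
}

transform_fun <- function(transform) {
  switch(transform,
         identity = list(f = identity, inv = identity),
         log = list(f = log, inv = exp),
         logit = list(f = function(p) log(p / (1 - p)),
                      inv = function(x) 1 / (1 + exp(-x))),
         stop("unknown transform: ", transform))
}

# deterministic small seed from strings, stable across sessions
seed_from_strings <- function(base, ...) {
  s <- paste(..., collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147480009
  as.integer((base + h) %% 2147480009)
}

bayes_arm_draws <- function(y, n_draws) {
  n <- length(y)
  ybar <- mean(y); s <- sd(y)
  if (!is.finite(s) || s == 0) return(rep(ybar, n_draws))
  ybar + (s / sqrt(n)) * stats::rt(n_draws, df = n - 1)
}

#' Trend calls for behavior endpoints across a comparison plan
#'
#' For each endpoint and each planned comparison, the two arms are modelled
#' on the chosen transform scale as normal with unknown mean and variance
#' under Jeffreys priors; the posterior of each arm mean is a scaled t, and
#' the treatment difference (second minus first) is summarised by Monte
#' Carlo. A comparison is significant when the central credible interval
#' excludes 0; the Pos/Neg direction is read from the back-transformed arm
#' means. `method = "welch"` replaces the posterior with a Welch t-test of
#' the same level (fast path for large simulation loops).
#'
#' Arm draws are keyed to (endpoint, sorted arm labels), so reversing a
#' comparison exactly negates the estimate and interval and swaps Pos/Neg.
#'
#' @param data tibble with columns `endpoint`, `treatment`, `value`.
#' @param plan a [comparison_plan()].
#' @param transform `"identity"`, `"log"` or `"logit"` (analysis scale).
#' @param level credible/confidence level (default 0.95).
#' @param method `"bayes"` (default) or `"welch"`.
#' @param n_draws Monte Carlo draws per arm for the Bayesian method.
#' @param seed integer; controls all Monte Carlo draws.
#' @return tibble: `id, comparison, estimate, lo, hi, call` with
#'   `call` in Pos/Neg/NS; estimate on the transform scale.
#' @export
compare_behavior <- function(data, plan = comparison_plan(),
                             transform = "identity", level = 0.95,
                             method = c("bayes", "welch"),
                             n_draws = 8000, seed = 1) {
  method <- match.arg(method)
  tf <- transform_fun(transform)
  alpha <- 1 - level
  out <- list()
  for (ep in unique(data$endpoint)) {
    d <- data[data$endpoint == ep, , drop = FALSE]
    for (i in seq_len(nrow(plan))) {
      a1 <- plan$first[i]; a2 <- plan$second[i]
      y1 <- d$value[d$treatment == a1]
      y2 <- d$value[d$treatment == a2]
      y1 <- y1[is.finite(y1)]; y2 <- y2[is.finite(y2)]
      if (length(y1) < 2 || length(y2) < 2) {
        out[[length(out) + 1]] <- tibble(id = ep, comparison = plan$comparison[i],
                                         estimate = NA_real_, lo = NA_real_,
                                         hi = NA_real_, call = "NS")
        next
      }
      t1 <- tf$f(y1); t2 <- tf$f(y2)
      if (sd(t1) == 0 && sd(t2) == 0 && mean(t1) == mean(t2)) {
        warning("degenerate arms (zero variance, equal means) for ", ep,
                " / ", plan$comparison[i], ": NS")
        out[[length(out) + 1]] <- tibble(id = ep, comparison = plan$comparison[i],
                                         estimate = 0, lo = 0, hi = 0, call = "NS")
        next
      }
      if (method == "bayes") {
        arms <- sort(c(a1, a2))
        set.seed(seed_from_strings(seed, ep, arms[1], arms[2]))
        draws <- list(bayes_arm_draws(tf$f(d$value[d$treatment == arms[1] &
                                                     is.finite(d$value)]), n_draws),
                      bayes_arm_draws(tf$f(d$value[d$treatment == arms[2] &
                                                     is.finite(d$value)]), n_draws))
        names(draws) <- arms
        dd <- draws[[a2]] - draws[[a1]]
        est <- mean(t2) - mean(t1)
        qs <- quantile(dd, c(alpha / 2, 1 - alpha / 2), names = FALSE)
        lo <- qs[1]; hi <- qs[2]
        sig <- lo > 0 || hi < 0
      } else {
        tt <- stats::t.test(t2, t1, conf.level = level)
        est <- mean(t2) - mean(t1)
        lo <- tt$conf.int[1]; hi <- tt$conf.int[2]
        sig <- tt$p.value < alpha
      }
      bt2 <- tf$inv(mean(t2)); bt1 <- tf$inv(mean(t1))
      call <- if (!sig || bt2 == bt1) "NS" else if (bt2 > bt1) "Pos" else "Neg"
      out[[length(out) + 1]] <- tibble(id = ep, comparison = plan$comparison[i],
                                       estimate = est, lo = lo, hi = hi,
                                       call = call)
    }
  }
  dplyr::bind_rows(out)
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up BH q-values; NA/NaN p-values are excluded from the number of
#' tests and returned as NA.
#'
#' @param p p-values in \[0, 1\] (NAs allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Expected number of chance significances
#'
#' The back-of-envelope multiplicity count `alpha * m`: how many of `m`
#' independent tests would be called significant at level `alpha` if nothing
#' were real (e.g. 0.05 x 83 = 4.15 for a full behavior endpoint battery).
#'
#' @param alpha per-test significance level, in (0, 1).
#' @param m number of tests (>= 1).
#' @export
expected_false_positives <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha * m
}

# Two-stage per-gene NB fit. Stage 1 (MASS::glm.nb, ML dispersion) gives the
# mean structure; stage 2 re-estimates the dispersion from df-corrected
# Pearson residuals (plain ML dispersion is biased low at a handful of
# samples per group, which inflates the Wald statistic) and refits with the
# dispersion held fixed. The Wald statistic is referred to t with the
# residual df.
fit_nb_gene <- function(y, grp, loglib) {
  f1 <- tryCatch(suppressWarnings(MASS::glm.nb(y ~ grp + offset(loglib))),
                 error = function(e) NULL)
  if (is.null(f1)) {
    f1 <- suppressWarnings(stats::glm(y ~ grp + offset(loglib),
                                      family = stats::poisson()))
  }
  mu <- stats::fitted(f1)
  n <- length(y); p <- 2
  pearson_gap <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - (n - p)
  a <- if (pearson_gap(0) <= 0) 0 else {
    tryCatch(stats::uniroot(pearson_gap, c(1e-8, 100))$root,
             error = function(e) 100)
  }
  fam <- if (a < 1e-6) stats::poisson() else MASS::negative.binomial(theta = 1 / a)
  f2 <- suppressWarnings(stats::glm(y ~ grp + offset(loglib), family = fam))
  co <- summary(f2, dispersion = 1)$coefficients
  tval <- co[2, 1] / co[2, 2]
  c(est = co[2, 1], se = co[2, 2], p = 2 * stats::pt(-abs(tval), df = n - p))
}

#' Per-gene negative binomial differential expression with trend calls
#'
#' Fits, for every gene passing a minimum-count filter, a negative binomial
#' GLM with log link and log library-size offset; the per-gene dispersion is
#' estimated in two stages (ML for the mean structure, then df-corrected
#' Pearson residuals, which keeps the test calibrated at a handful of
#' samples per group). The group coefficient is tested by a Wald test
#' against a t reference with the residual df, p-values are adjusted by
#' Benjamini-Hochberg, and genes are called Pos/Neg by the sign of the log2
#' fold-change at `q < fdr` (NS otherwise).
#'
#' @param counts integer gene x sample matrix (rownames = gene ids).
#' @param design tibble with `sample`, `treatment` matching the columns.
#' @param groups optional length-2 vector ordering the comparison as
#'   (first, second); defaults to the order of appearance. The log2
#'   fold-change is second over first.
#' @param fdr false discovery rate for calling (default 0.05).
#' @param min_count_mean genes with mean count below this are excluded and
#'   reported, not tested.
#' @param level Wald interval level for `lo`/`hi`.
#' @return list of class `kx_de_result`: `table` (gene, estimate = log2 FC,
#'   lo, hi, p, q, call), `filtered` (excluded gene ids), `fdr`.
#' @export
de_test <- function(counts, design, groups = NULL, fdr = 0.05,
                    min_count_mean = 1, level = 0.95) {
  stopifnot(ncol(counts) == nrow(design))
  design <- design[match(colnames(counts), design$sample), ]
  if (is.null(groups)) groups <- unique(design$treatment)
  stopifnot(length(groups) == 2, all(design$treatment %in% groups))
  grp <- factor(design$treatment, levels = groups)
  if (any(table(grp) < 2)) stop("need >= 2 samples per group")
  loglib <- log(colSums(counts))
  keep <- rowMeans(counts) >= min_count_mean
  filtered <- rownames(counts)[!keep]
  tested <- which(keep)
  res <- matrix(NA_real_, length(tested), 3,
                dimnames = list(NULL, c("est", "se", "p")))
  for (i in seq_along(tested)) {
    res[i, ] <- fit_nb_gene(as.numeric(counts[tested[i], ]), grp, loglib)
  }
  q <- bh_adjust(res[, "p"])
  l2 <- res[, "est"] / log(2)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  call <- ifelse(is.na(q) | q >= fdr, "NS", ifelse(l2 > 0, "Pos", "Neg"))
  out <- list(
    table = tibble(gene = rownames(counts)[tested],
                   estimate = l2,
                   lo = (res[, "est"] - zc * res[, "se"]) / log(2),
                   hi = (res[, "est"] + zc * res[, "se"]) / log(2),
                   p = res[, "p"], q = q, call = call),
    filtered = filtered,
    groups = groups,
    fdr = fdr
  )
  class(out) <- "kx_de_result"
  out
}

#' @export
print.kx_de_result <- function(x, ...) {
  cat(sprintf("NB differential expression: %d genes tested, %d filtered, FDR %.3g\n",
              nrow(x$table), length(x$filtered), x$fdr))
  print(table(x$table$call))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, member genes.
#'
#' @param path GMT file path.
#' @return tibble: `set`, `description`, `genes` (list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    set = vapply(parts, `[`, "", 1),
    description = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Direction-aware gene-set over-representation
#'
#' Hypergeometric over-representation of Pos-called (and separately
#' Neg-called) genes in each set, BH-adjusted across sets within each
#' direction. Sets with no member in the universe are skipped.
#'
#' @param calls tibble with `gene` and `call` (Pos/Neg/NS) for the tested
#'   universe (one comparison).
#' @param gene_sets tibble as from [read_gmt()], or a named list of gene
#'   vectors.
#' @param universe optional character vector; defaults to `calls$gene`.
#' @return tibble: `set, description, direction, n_set, n_hits, overlap, p, q`.
#' @export
gene_set_test <- function(calls, gene_sets, universe = NULL) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- tibble(set = names(gene_sets),
                        description = "",
                        genes = unname(gene_sets))
  }
  if (is.null(universe)) universe <- unique(calls$gene)
  calls <- calls[calls$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  out <- list()
  for (dir in c("Pos", "Neg")) {
    hits <- unique(calls$gene[calls$call == dir])
    n_hits <- length(hits)
    for (i in seq_len(nrow(gene_sets))) {
      members <- intersect(gene_sets$genes[[i]], universe)
      if (!length(members)) next
      k <- length(intersect(members, hits))
      p <- phyper(k - 1, n_hits, N - n_hits, length(members),
                  lower.tail = FALSE)
      out[[length(out) + 1]] <- tibble(
        set = gene_sets$set[i], description = gene_sets$description[i],
        direction = dir, n_set = length(members), n_hits = n_hits,
        overlap = k, p = p)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) {
    res <- dplyr::group_by(res, .data$direction)
    res <- dplyr::mutate(res, q = bh_adjust(.data$p))
    res <- dplyr::ungroup(res)
  }
  res
}
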