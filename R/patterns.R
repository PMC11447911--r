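# Trend-pattern concordance: encode each endpoint's or gene's Pos/Neg/NS
# calls across the ordered comparison plan as a sign vector, group ids with
# identical vectors, and match genes to behaviors whose vectors are
# identical ("original") or exactly sign-flipped ("opposite").

#' Encode trend calls as a sign vector over the comparison plan
#'
#' Deterministic mapping Pos -> +1, Neg -> -1, NS -> 0, ordered by the plan;
#' comparisons with no call are 0. An all-zero vector is flagged ineligible
#' for pattern matching (nothing significant to match on).
#'
#' @param calls tibble with `id` (or `gene`), `comparison`, `call`.
#' @param plan a [comparison_plan()].
#' @param kind `"behavior"` or `"gene"`, carried through to matching.
#' @return tibble of class `kx_trend_vectors`: `id, kind, pattern`
#'   (character like `"0,+,-,0,0"`), `signs` (list of integer vectors),
#'   `eligible`.
#' @export
encode_trend_vector <- function(calls, plan, kind = c("behavior", "gene")) {
  kind <- match.arg(kind)
  if (!"id" %in% names(calls) && "gene" %in% names(calls)) {
    calls$id <- calls$gene
  }
  dup <- calls[, c("id", "comparison")]
  if (anyDuplicated(dup)) {
    d <- calls[duplicated(dup) | duplicated(dup, fromLast = TRUE), ]
    if (any(tapply(d$call, paste(d$id, d$comparison), function(x) length(unique(x))) > 1)) {
      stop("conflicting duplicate calls for one (id, comparison)")
    }
    calls <- calls[!duplicated(dup), ]
  }
  ids <- unique(calls$id)
  sign_of <- c(Pos = 1L, Neg = -1L, NS = 0L)
  out <- lapply(ids, function(id) {
    d <- calls[calls$id == id, ]
    v <- integer(nrow(plan))
    m <- match(plan$comparison, d$comparison)
    got <- !is.na(m)
    v[got] <- sign_of[d$call[m[got]]]
    v
  })
  tibble(
    id = ids, kind = kind,
    pattern = vapply(out, pattern_string, ""),
    signs = out,
    eligible = vapply(out, function(v) any(v != 0L), TRUE)
  )
}

pattern_string <- function(v) {
  paste(c("-", "0", "+")[v + 2L], collapse = ",")
}

#' Group ids by identical trend vector
#'
#' Exact-equality partition of eligible vectors; groups ordered by
#' decreasing size, ties broken lexicographically by pattern.
#'
#' @param vectors tibble from [encode_trend_vector()] (rows from several
#'   calls can be bound together).
#' @return tibble: `pattern, n, ids` (list column).
#' @export
group_by_pattern <- function(vectors) {
  v <- vectors[vectors$eligible, , drop = FALSE]
  if (!nrow(v)) return(tibble(pattern = character(), n = integer(), ids = list()))
  sp <- split(v$id, v$pattern)
  out <- tibble(pattern = names(sp),
                n = lengths(sp),
                ids = unname(sp))
  out[order(-out$n, out$pattern), ]
}

negate_pattern <- function(v) -v

#' Match genes to behaviors by trend pattern
#'
#' Pairs every eligible gene vector with every eligible behavior vector
#' whose calls agree on ALL plan positions, zeros included ("original"
#' match), or are exactly sign-flipped ("opposite", when `allow_opposite`).
#' `relaxed = TRUE` instead requires agreement only on positions where at
#' least one side is non-zero and neither side conflicts (a significant call
#' on one side may pair with NS on the other).
#'
#' @param gene_vectors,behavior_vectors tibbles from [encode_trend_vector()].
#' @param allow_opposite include sign-flipped matches.
#' @param relaxed significant-positions-only matching (default FALSE:
#'   strict full-pattern equality).
#' @return tibble: `gene, behavior, pattern, type` with type in
#'   original/opposite.
#' @export
match_gene_behavior <- function(gene_vectors, behavior_vectors,
                                allow_opposite = TRUE, relaxed = FALSE) {
  g <- gene_vectors[gene_vectors$eligible, , drop = FALSE]
  b <- behavior_vectors[behavior_vectors$eligible, , drop = FALSE]
  if (!nrow(g) || !nrow(b)) {
    return(tibble(gene = character(), behavior = character(),
                  pattern = character(), type = character()))
  }
  compatible <- function(v, w) {
    nz <- v != 0L & w != 0L
    all(v[nz] == w[nz]) && any(nz)
  }
  out <- list()
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(b))) {
      vg <- g$signs[[i]]; vb <- b$signs[[j]]
      orig <- if (relaxed) compatible(vg, vb) else identical(vg, vb)
      opp <- allow_opposite &&
        (if (relaxed) compatible(vg, negate_pattern(vb)) else
           identical(vg, negate_pattern(vb)))
      if (orig) {
        out[[length(out) + 1]] <- tibble(gene = g$id[i], behavior = b$id[j],
                                         pattern = g$pattern[i],
                                         type = "original")
      }
      if (opp && !(orig && all(vg == 0L))) {
        out[[length(out) + 1]] <- tibble(gene = g$id[i], behavior = b$id[j],
                                         pattern = g$pattern[i],
                                         type = "opposite")
      }
    }
  }
  if (!length(out)) {
    return(tibble(gene = character(), behavior = character(),
                  pattern = character(), type = character()))
  }
  dplyr::bind_rows(out)
}
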