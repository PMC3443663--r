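# Functional representation analysis: EASE score with BH FDR.

#' EASE and Fisher enrichment scores for one biological theme
#'
#' The one-sided Fisher exact test asks whether the hit list (e.g. a miRNA's
#' target genes) over-represents the theme's genes within the universe. The
#' EASE score is the conservative variant in which the observed
#' hits-in-theme count is reduced by one (floored at zero) before computing
#' the same upper-tail probability, which penalizes themes supported by a
#' single gene; `ease_p >= fisher_p` always.
#'
#' @param hit_genes,theme_genes character vectors, subsets of `universe`.
#' @param universe character vector of all candidate genes.
#' @return A list with `ease_p`, `fisher_p`, and `counts` (named: `overlap`,
#'   `hits`, `theme`, `universe`).
#' @export
ease_score <- function(hit_genes, theme_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  hit_genes <- unique(as.character(hit_genes))
  theme_genes <- unique(as.character(theme_genes))
  if (length(setdiff(hit_genes, universe)) ||
      length(setdiff(theme_genes, universe)))
    stop("hit and theme genes must be contained in the universe")
  a <- length(intersect(hit_genes, theme_genes))
  counts <- c(overlap = a, hits = length(hit_genes),
              theme = length(theme_genes), universe = length(universe))
  if (length(hit_genes) == 0L)
    return(list(ease_p = 1, fisher_p = 1, counts = counts))
  tail_p <- function(q) {
    stats::phyper(q - 1L, counts[["theme"]],
                  counts[["universe"]] - counts[["theme"]],
                  counts[["hits"]], lower.tail = FALSE)
  }
  list(ease_p = min(1, tail_p(max(a - 1L, 0L))),
       fisher_p = min(1, tail_p(a)),
       counts = counts)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up adjusted values (monotone, capped at 1), used as the "global FDR"
#' across all themes of one enrichment analysis.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of a hit list across a theme collection
#'
#' Runs [ease_score()] for every theme and attaches the BH-adjusted EASE
#' p-values.
#'
#' @param hit_genes character vector of hit genes.
#' @param themes a [target_set_collection()] read from a theme GMT file
#'   (theme id -> gene set).
#' @param universe character vector of candidate genes (typically the
#'   expression matrix gene set). Theme genes outside the universe are
#'   dropped before testing.
#' @return A data frame with columns `theme`, `overlap`, `hits`, `theme_size`,
#'   `fisher_p`, `ease_p`, `bh_fdr`.
#' @export
enrich_themes <- function(hit_genes, themes, universe) {
  stopifnot(inherits(themes, "TargetSetCollection"))
  universe <- unique(as.character(universe))
  hit_genes <- intersect(unique(as.character(hit_genes)), universe)
  rows <- lapply(names(themes$targets), function(id) {
    th <- intersect(themes$targets[[id]], universe)
    if (length(th) == 0L)
      return(data.frame(theme = id, overlap = 0L, hits = length(hit_genes),
                        theme_size = 0L, fisher_p = 1, ease_p = 1))
    es <- ease_score(hit_genes, th, universe)
    data.frame(theme = id, overlap = es$counts[["overlap"]],
               hits = es$counts[["hits"]], theme_size = es$counts[["theme"]],
               fisher_p = es$fisher_p, ease_p = es$ease_p)
  })
  out <- do.call(rbind, rows)
  out$bh_fdr <- bh_adjust(out$ease_p)
  out
}
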