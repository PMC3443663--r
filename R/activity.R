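# Per-miRNA activity scoring on the ranked expression-change vector,
# permutation null, empirical p-values and the permutation FDR ratio.

# Run expr with a private, seeded RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Signed running-sum extremum for a target set at (sorted, 1-based) rank
# positions `pos` on a vector of length N. Walking ranks 1..N the sum gains
# sqrt((N-m)/m) at a target and loses sqrt(m/(N-m)) elsewhere; candidates for
# the extremum are the values at each target rank, just before each target
# rank, and the endpoint (always 0). D is the candidate of largest absolute
# value; on a magnitude tie the extremum attained at the smallest rank wins.
# Returns AS = -D.
.as_from_positions <- function(pos, N) {
  m <- length(pos)
  up <- sqrt((N - m) / m)
  down <- sqrt(m / (N - m))
  i <- seq_len(m)
  gaps <- (pos - i) * down
  at_hit <- i * up - gaps          # running sum at rank pos_i
  at_pre <- at_hit - up            # running sum at rank pos_i - 1
  vals <- c(at_hit, at_pre[pos > 1L], 0)
  ranks <- c(pos, pos[pos > 1L] - 1L, N)
  vmax <- max(vals); vmin <- min(vals)
  rmax <- min(ranks[vals == vmax]); rmin <- min(ranks[vals == vmin])
  d <- if (abs(vmax) > abs(vmin)) vmax
       else if (abs(vmax) < abs(vmin)) vmin
       else if (rmax <= rmin) vmax else vmin
  -d
}

#' Activity score of one miRNA on an expression change vector
#'
#' Measures how skewed the miRNA's predicted targets are on the ranked
#' expression-change vector with a weighted Kolmogorov-Smirnov-style running
#' sum: walking the vector from the largest to the smallest change, the sum
#' increases by `sqrt((N-m)/m)` at each of the `m` target genes and decreases
#' by `sqrt(m/(N-m))` at each of the other `N-m` genes. `D` is the running-sum
#' value of largest absolute magnitude (magnitude ties resolved toward the
#' extremum attained at the smallest rank) and the activity score is
#' `AS = -D`, so that targets concentrated at the bottom of the vector
#' (down-regulated in the case condition, i.e. repressed) give a positive
#' score: positive AS means inferred activation, negative AS means silencing.
#'
#' @param cv an `ExpressionChangeVector` from [rank_expression_changes()].
#' @param target_genes character vector of target gene ids; only genes present
#'   in the vector are used.
#' @return The activity score (numeric scalar) with attribute `m_used`, the
#'   number of target genes found in the vector. `NA` (with a warning) if no
#'   target gene is present.
#' @export
activity_score <- function(cv, target_genes) {
  stopifnot(inherits(cv, "ExpressionChangeVector"))
  N <- nrow(cv)
  pos <- sort(match(unique(target_genes), cv$gene_id))
  pos <- pos[!is.na(pos)]
  m <- length(pos)
  if (m == 0L) {
    warning("no target genes present in the change vector; miRNA skipped")
    return(structure(NA_real_, m_used = 0L))
  }
  if (m == N)
    stop("target set covers the entire change vector (m = N); score undefined")
  structure(.as_from_positions(pos, N), m_used = m)
}

#' Null activity scores from gene-label permutations
#'
#' Builds the null distribution NS(x, k): for each of `K` random permutations
#' of the gene labels of the expression matrix (one shared permutation per k
#' for all miRNAs), the change vector is rebuilt and every miRNA is re-scored.
#' Because the per-gene statistic depends only on that gene's row, permuting
#' gene labels and recomputing the vector is equivalent to permuting which
#' gene occupies which rank; the implementation exploits this and permutes
#' the gene-to-rank assignment directly.
#'
#' @param em an [expression_matrix()].
#' @param case_label,comparator_label the contrast, as in
#'   [rank_expression_changes()].
#' @param targets a [target_set_collection()].
#' @param K number of permutations (default 1000).
#' @param seed integer seed; results are fully reproducible for a fixed seed.
#' @return An object of class `NullScores`: list with `ns` (miRNAs x K matrix
#'   of null scores, rows named by miRNA; miRNAs with no target gene in the
#'   matrix are dropped with a warning), `K`, `seed`.
#' @export
permutation_null <- function(em, case_label, comparator_label, targets,
                             K = 1000L, seed) {
  stopifnot(inherits(em, "ExpressionMatrix"),
            inherits(targets, "TargetSetCollection"))
  if (K < 1L) stop("K must be >= 1")
  if (missing(seed)) stop("a seed is required for the permutation null")
  cv <- rank_expression_changes(em, case_label, comparator_label)
  N <- nrow(cv)
  idx <- lapply(targets$targets, function(g) {
    p <- match(unique(g), cv$gene_id)
    p[!is.na(p)]
  })
  keep <- lengths(idx) >= 1L & lengths(idx) < N
  if (any(!keep))
    warning("miRNA(s) with no usable target genes skipped: ",
            paste(names(idx)[!keep], collapse = ", "))
  idx <- idx[keep]
  ns <- matrix(NA_real_, nrow = length(idx), ncol = K,
               dimnames = list(names(idx), NULL))
  .with_seed(seed, {
    for (k in seq_len(K)) {
      # rank position of each original gene slot under this permutation
      rank_of <- sample.int(N)
      for (x in seq_along(idx))
        ns[x, k] <- .as_from_positions(sort.int(rank_of[idx[[x]]]), N)
    }
  })
  structure(list(ns = ns, K = as.integer(K), seed = seed),
            class = "NullScores")
}

#' @export
print.NullScores <- function(x, ...) {
  cat(sprintf("NullScores: %d miRNAs x %d permutations (seed %s)\n",
              nrow(x$ns), x$K, format(x$seed)))
  invisible(x)
}

#' Empirical permutation p-value for one activity score
#'
#' Two-sided on the absolute score, with the usual +1 pseudocount so that
#' p is never zero: `p = (1 + #\{k : |NS(x,k)| >= |AS|\}) / (K + 1)`.
#'
#' @param as_score observed activity score.
#' @param null_row numeric vector of the miRNA's K null scores.
#' @return p-value in (0, 1\].
#' @export
empirical_p <- function(as_score, null_row) {
  K <- length(null_row)
  if (K < 1L) stop("null_row must have length >= 1")
  (1 + sum(abs(null_row) >= abs(as_score))) / (K + 1)
}

#' Permutation-based FDR estimate at a score threshold
#'
#' For a threshold `AS* >= 0` the estimate is the ratio of the percentage of
#' all null scores NS(x, k) that are `>= 0` and also `>= AS*`, divided by the
#' percentage of observed scores AS(x) that are `>= 0` and also `>= AS*`;
#' mirrored with `<=` for `AS* < 0`. The ratio is capped at 1, and degenerate
#' cases (no observed or null score on the relevant side of zero) return 1
#' with a warning (conservative).
#'
#' @param as_scores numeric vector of observed activity scores.
#' @param null a `NullScores` object (or a bare numeric matrix of null
#'   scores).
#' @param as_star the score threshold AS*.
#' @return FDR estimate in \[0, 1\].
#' @export
estimate_fdr <- function(as_scores, null, as_star) {
  ns <- if (inherits(null, "NullScores")) null$ns else null
  ns <- as.numeric(ns)
  as_scores <- as.numeric(as_scores)
  if (!is.finite(as_star)) stop("as_star must be finite")
  if (as_star >= 0) {
    ns_side <- ns[ns >= 0]; as_side <- as_scores[as_scores >= 0]
    num_hits <- sum(ns_side >= as_star); den_hits <- sum(as_side >= as_star)
  } else {
    ns_side <- ns[ns <= 0]; as_side <- as_scores[as_scores <= 0]
    num_hits <- sum(ns_side <= as_star); den_hits <- sum(as_side <= as_star)
  }
  if (length(ns_side) == 0L || length(as_side) == 0L || den_hits == 0L) {
    warning("FDR undefined at as_star = ", format(as_star),
            " (empty side); returning 1")
    return(1)
  }
  min(1, (num_hits / length(ns_side)) / (den_hits / length(as_side)))
}

#' Score every miRNA and attach permutation p-values and FDR estimates
#'
#' The main entry point of the activity analysis: ranks genes by differential
#' change between the two conditions, scores every target set, builds the
#' shared permutation null, and attaches to each miRNA its empirical p-value
#' and the FDR estimate at its own score.
#'
#' @inheritParams permutation_null
#' @param p_threshold,fdr_threshold thresholds used for the direction call
#'   column (see [call_deregulated()]).
#' @return A data frame of class `ActivityResult` with columns `mirna_id`,
#'   `m_used`, `as_score`, `p_value`, `fdr`, `call`, plus attributes `null`
#'   (the `NullScores`) and `change_vector`.
#' @export
mirna_activity <- function(em, case_label, comparator_label, targets,
                           K = 1000L, seed, p_threshold = 0.005,
                           fdr_threshold = 0.01) {
  cv <- rank_expression_changes(em, case_label, comparator_label)
  null <- permutation_null(em, case_label, comparator_label, targets,
                           K = K, seed = seed)
  ids <- rownames(null$ns)
  as_scores <- numeric(length(ids))
  m_used <- integer(length(ids))
  for (i in seq_along(ids)) {
    s <- activity_score(cv, targets$targets[[ids[i]]])
    as_scores[i] <- as.numeric(s)
    m_used[i] <- attr(s, "m_used")
  }
  p <- vapply(seq_along(ids),
              function(i) empirical_p(as_scores[i], null$ns[i, ]), 0)
  fdr <- vapply(as_scores, function(a) estimate_fdr(as_scores, null, a), 0)
  call <- ifelse(p <= p_threshold & fdr <= fdr_threshold,
                 ifelse(as_scores > 0, "activated",
                        ifelse(as_scores < 0, "silenced", "none")),
                 "none")
  res <- data.frame(mirna_id = ids, m_used = m_used, as_score = as_scores,
                    p_value = p, fdr = fdr, call = call,
                    stringsAsFactors = FALSE)
  structure(res, null = null, change_vector = cv,
            case = case_label, comparator = comparator_label,
            class = c("ActivityResult", "data.frame"))
}

#' Call activated and silenced miRNAs at p and FDR thresholds
#'
#' @param results an `ActivityResult` data frame (or any data frame with
#'   columns `mirna_id`, `as_score`, `p_value`, `fdr`).
#' @param p_threshold,fdr_threshold thresholds in (0, 1\].
#' @return A list with elements `activated` and `silenced`, each a character
#'   vector of miRNA ids sorted by decreasing `|AS|`.
#' @export
call_deregulated <- function(results, p_threshold = 0.005,
                             fdr_threshold = 0.01) {
  stopifnot(all(c("mirna_id", "as_score", "p_value", "fdr") %in% names(results)))
  if (p_threshold <= 0 || p_threshold > 1 || fdr_threshold <= 0 || fdr_threshold > 1)
    stop("thresholds must lie in (0, 1]")
  hit <- results$p_value <= p_threshold & results$fdr <= fdr_threshold
  pick <- function(side) {
    r <- results[hit & side, , drop = FALSE]
    r$mirna_id[order(-abs(r$as_score), r$mirna_id, method = "radix")]
  }
  list(activated = pick(results$as_score > 0),
       silenced = pick(results$as_score < 0))
}

#' Write an activity results table
#'
#' Tab-separated `mirna_id, m_used, as_score, p_value, fdr, call` with
#' provenance comments recording the contrast, K and seed.
#'
#' @param results an `ActivityResult` from [mirna_activity()].
#' @param path output path.
#' @return Invisibly, `results`.
#' @export
write_activity_table <- function(results, path) {
  stopifnot(inherits(results, "ActivityResult"))
  null <- attr(results, "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(sprintf("case=%s; comparator=%s; K=%d; seed=%s",
                                 attr(results, "case"),
                                 attr(results, "comparator"),
                                 null$K, format(null$seed))), con)
  utils::write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results)
}

#' Write a null-score matrix
#'
#' @param null a `NullScores` object.
#' @param path output path.
#' @return Invisibly, `null`.
#' @export
write_null_scores <- function(null, path) {
  stopifnot(inherits(null, "NullScores"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(sprintf("K=%d; seed=%s", null$K, format(null$seed))), con)
  tab <- data.frame(mirna_id = rownames(null$ns), null$ns,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[-1L] <- paste0("perm", seq_len(null$K))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(null)
}
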