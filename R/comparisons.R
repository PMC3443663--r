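# Cross-phenotype set logic and supporting statistics.

#' Construct a deregulation profile for one condition contrast
#'
#' @param condition free-text label for the contrast (e.g.
#'   `"LEIO vs normal"`).
#' @param activated,silenced character vectors of miRNA ids; must be disjoint.
#' @param universe character vector of all miRNAs evaluated in the analysis
#'   (those with at least one usable target gene).
#' @return An object of class `DeregulationProfile`.
#' @export
deregulation_profile <- function(condition, activated, silenced, universe) {
  activated <- unique(as.character(activated))
  silenced <- unique(as.character(silenced))
  universe <- unique(as.character(universe))
  both <- intersect(activated, silenced)
  if (length(both))
    stop("miRNA(s) both activated and silenced: ", paste(both, collapse = ", "))
  out <- setdiff(c(activated, silenced), universe)
  if (length(out))
    stop("deregulated miRNA(s) outside the universe: ",
         paste(out, collapse = ", "))
  structure(list(condition = condition, activated = activated,
                 silenced = silenced, universe = universe),
            class = "DeregulationProfile")
}

#' @export
print.DeregulationProfile <- function(x, ...) {
  cat(sprintf("DeregulationProfile '%s': %d activated, %d silenced of %d evaluated\n",
              x$condition, length(x$activated), length(x$silenced),
              length(x$universe)))
  invisible(x)
}

#' One-sided overlap test between two gene/miRNA sets
#'
#' Upper-tail hypergeometric probability of observing an overlap at least as
#' large as `|A` \eqn{\cap} `B|` when drawing `|B|` items from a universe
#' containing `|A|` marked items — equivalent to a one-sided Fisher exact
#' test on the 2x2 membership table.
#'
#' @param setA,setB character vectors, both subsets of `universe`.
#' @param universe character vector defining the sampling frame.
#' @return A list with `overlap` (count) and `p_value`.
#' @export
overlap_test <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop("both sets must be contained in the universe")
  if (length(universe) == 0L) stop("universe must be non-empty")
  q <- length(intersect(setA, setB))
  p <- stats::phyper(q - 1L, length(setA), length(universe) - length(setA),
                     length(setB), lower.tail = FALSE)
  list(overlap = q, p_value = p)
}

#' Subtype-specific deregulated miRNAs
#'
#' For each profile, the miRNAs deregulated in a given direction in that
#' condition and in no other profile — the condition-unique activity pattern.
#'
#' @param profiles list of two or more [deregulation_profile()] objects
#'   sharing a common universe.
#' @return A named list (one element per condition) of lists with `activated`
#'   and `silenced` unique sets.
#' @export
subtype_specific <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  stopifnot(all(vapply(profiles, inherits, TRUE, "DeregulationProfile")))
  u <- profiles[[1L]]$universe
  same <- vapply(profiles, function(p) setequal(p$universe, u), TRUE)
  if (!all(same)) stop("profiles have differing universes")
  out <- lapply(seq_along(profiles), function(i) {
    others <- profiles[-i]
    list(activated = setdiff(profiles[[i]]$activated,
                             unlist(lapply(others, `[[`, "activated"))),
         silenced = setdiff(profiles[[i]]$silenced,
                            unlist(lapply(others, `[[`, "silenced"))))
  })
  names(out) <- vapply(profiles, `[[`, "", "condition")
  out
}

#' Pathway-switching miRNAs between two contrasts
#'
#' miRNAs activated in the pathway-active contrast and silenced in the
#' pathway-inactive contrast — candidates for reversing their activity upon
#' transition to the pathway-active state. The hypergeometric overlap p-value
#' for the intersection (against the common universe) is reported alongside.
#'
#' @param profile_active [deregulation_profile()] for the pathway-active
#'   contrast.
#' @param profile_inactive [deregulation_profile()] for the pathway-inactive
#'   contrast (same universe).
#' @return A list with `switching` (character vector), `overlap` and
#'   `p_value` (from [overlap_test()]).
#' @export
ras_switching <- function(profile_active, profile_inactive) {
  stopifnot(inherits(profile_active, "DeregulationProfile"),
            inherits(profile_inactive, "DeregulationProfile"))
  if (!setequal(profile_active$universe, profile_inactive$universe))
    stop("profiles have differing universes")
  sw <- intersect(profile_active$activated, profile_inactive$silenced)
  ov <- overlap_test(profile_active$activated, profile_inactive$silenced,
                     profile_active$universe)
  list(switching = sw, overlap = ov$overlap, p_value = ov$p_value)
}

#' Partition samples by pathway activation probability
#'
#' @param probabilities a [pathway_probabilities()] vector.
#' @param cutoff minimum probability for a predicted-active call; the cutoff
#'   is inclusive (a probability exactly at the cutoff counts as active).
#'   Default 0.8.
#' @return A list with `active` and `inactive` character vectors of sample
#'   ids.
#' @export
threshold_pathway <- function(probabilities, cutoff = 0.8) {
  stopifnot(inherits(probabilities, "PathwayProbabilities"))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  p <- as.numeric(probabilities)
  list(active = names(probabilities)[p >= cutoff],
       inactive = names(probabilities)[p < cutoff])
}

#' One-tailed Welch t-test between two sample groups
#'
#' Heteroskedastic (Welch) t-test with Welch-Satterthwaite degrees of
#' freedom, one-tailed. Used to test whether e.g. miRNA-processing-machinery
#' transcripts are down-regulated in pathway-active tumors.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param alternative `"a_less_than_b"` (default) or `"a_greater_than_b"`.
#' @return A list with `t`, `df`, `p_value`.
#' @export
welch_one_tailed <- function(group_a, group_b,
                             alternative = c("a_less_than_b",
                                             "a_greater_than_b")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      warning("both groups constant and equal; p = 0.5 by convention")
      return(list(t = 0, df = NA_real_, p_value = 0.5))
    }
    # constant groups with different means: direction decides
    p <- if ((mean(group_a) < mean(group_b)) ==
             (alternative == "a_less_than_b")) 0 else 1
    return(list(t = if (p == 0) -Inf else Inf, df = NA_real_, p_value = p))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = if (alternative == "a_less_than_b")
                        "less" else "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Average-linkage hierarchical clustering with correlation distance
#'
#' Agglomerative clustering with unweighted average inter-cluster distance
#' (UPGMA: the mean of all cross-pair distances), the linkage used by the
#' BRB ArrayTools profile clustering, on a 1 - Pearson correlation distance
#' (or a user-supplied distance matrix). Ties in the minimum inter-cluster
#' distance are broken toward the lexicographically smallest item index pair
#' so the merge order is deterministic.
#'
#' @param x numeric matrix (items in rows) or a `dist` object / square
#'   distance matrix.
#' @param distance `"one_minus_pearson"` (default; requires matrix input) or
#'   `"precomputed"`.
#' @return An object of class `hclust` (merge matrix, heights, order,
#'   labels), usable with [stats::cutree()], `plot()` and
#'   [dendrogram_newick()]. Non-monotone merge heights (possible since
#'   correlation distance is not metric) are reported via a warning, not an
#'   error.
#' @export
cluster_average_linkage <- function(x, distance = c("one_minus_pearson",
                                                    "precomputed")) {
  distance <- match.arg(distance)
  if (distance == "one_minus_pearson") {
    if (!is.matrix(x)) stop("matrix input required for correlation distance")
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance item(s) under correlation distance: ",
           paste(rownames(x)[sds == 0], collapse = ", "))
    d <- 1 - stats::cor(t(x))
    labels <- rownames(x)
  } else {
    d <- as.matrix(if (inherits(x, "dist")) x else stats::as.dist(x))
    labels <- rownames(d)
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)             # hclust convention: negative = singleton
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    best <- min(sub)
    # smallest (i, j) pair among ties, i < j in original index order
    hits <- which(sub == best, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- idx[hits[1L, 1L]]; j <- idx[hits[1L, 2L]]
    merge[s, ] <- sort(c(node[i], node[j]))
    height[s] <- best
    # UPGMA update: average over all cross pairs = size-weighted mean
    others <- setdiff(idx, c(i, j))
    d[i, others] <- d[others, i] <-
      (size[i] * d[i, others] + size[j] * d[j, others]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    node[i] <- s
  }
  if (any(diff(height) < -1e-8))
    warning("non-monotone merge heights (correlation distance is not metric)")
  hc <- list(merge = merge, height = height, order = .hclust_order(merge),
             labels = labels, method = "average",
             dist.method = distance, call = match.call())
  class(hc) <- "hclust"
  hc
}

# Leaf order by left-to-right traversal of the merge tree.
.hclust_order <- function(merge) {
  walk <- function(k) {
    if (k < 0L) return(-k)
    c(walk(merge[k, 1L]), walk(merge[k, 2L]))
  }
  walk(nrow(merge))
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from merge heights (each child branch spans the gap
#' between its own height, 0 for leaves, and its parent's merge height).
#'
#' @param hc an `hclust` object, e.g. from [cluster_average_linkage()].
#' @param path optional file path; when given, the string is also written
#'   there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
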