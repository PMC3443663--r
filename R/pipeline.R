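# Orchestration: discovery and switch analyses over one expression cohort.

#' Full discovery run for one condition contrast
#'
#' Chains the pipeline stages: optional virtual-reference normalization,
#' batch adjustment (when more than one batch is present), expression-change
#' ranking, activity scoring with permutation p-values and FDR estimates, and
#' deregulation calls. When `out_dir` is given, the change vector, the
#' activity table and the deregulation profile are written there as
#' tab-separated files with provenance comments.
#'
#' @param em an [expression_matrix()].
#' @param targets a [target_set_collection()].
#' @param case_label,comparator_label phenotype labels of the contrast.
#' @param K permutations (default 1000); values below 100 log a warning but
#'   run.
#' @param seed integer seed (required).
#' @param p_threshold,fdr_threshold call thresholds (defaults 0.005 / 0.01).
#' @param normalize `"none"` (default; values already normalized/log-scale)
#'   or `"dasl"` for virtual-reference intensity scaling.
#' @param out_dir optional output directory (created if absent).
#' @return A list with `results` (the `ActivityResult`), `profile` (a
#'   [deregulation_profile()]) and `calls`.
#' @export
run_discovery <- function(em, targets, case_label, comparator_label,
                          K = 1000L, seed, p_threshold = 0.005,
                          fdr_threshold = 0.01,
                          normalize = c("none", "dasl"), out_dir = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"),
            inherits(targets, "TargetSetCollection"))
  if (missing(seed)) stop("a seed is required")
  normalize <- match.arg(normalize)
  if (K < 100L)
    warning("K = ", K, " permutations is low for discovery; ",
            "p-value resolution is 1/", K + 1)
  if (normalize == "dasl") em <- dasl_normalize(em)
  if (length(unique(em$batch)) > 1L) em <- batch_adjust(em)
  results <- mirna_activity(em, case_label, comparator_label, targets,
                            K = K, seed = seed, p_threshold = p_threshold,
                            fdr_threshold = fdr_threshold)
  calls <- call_deregulated(results, p_threshold, fdr_threshold)
  condition <- paste(case_label, "vs", comparator_label)
  profile <- deregulation_profile(condition, calls$activated, calls$silenced,
                                  results$mirna_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    safe <- gsub("[^A-Za-z0-9_.-]", "_", condition)
    write_change_vector(attr(results, "change_vector"),
                        file.path(out_dir, paste0(safe, ".change_vector.tsv")))
    write_activity_table(results,
                         file.path(out_dir, paste0(safe, ".activity.tsv")))
    write_profile(profile, file.path(out_dir, paste0(safe, ".profile.tsv")))
  }
  list(results = results, profile = profile, calls = calls)
}

#' Write a deregulation profile
#'
#' Tab-separated `mirna_id, direction` rows plus provenance comments
#' recording the condition and universe size.
#'
#' @param profile a [deregulation_profile()].
#' @param path output path.
#' @return Invisibly, `profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "DeregulationProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(sprintf("condition=%s; universe=%d",
                                 profile$condition,
                                 length(profile$universe))), con)
  tab <- data.frame(
    mirna_id = c(profile$activated, profile$silenced),
    direction = rep(c("activated", "silenced"),
                    c(length(profile$activated), length(profile$silenced))),
    stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' Pathway-switch analysis
#'
#' Partitions the case samples by pathway activation probability at the
#' given cutoff, runs one discovery contrast per partition (pathway-active vs
#' comparator, pathway-inactive vs comparator) and intersects the calls:
#' miRNAs activated in the active contrast and silenced in the inactive one
#' are reported as switching, with the hypergeometric overlap p-value. When
#' either partition has fewer than two samples the analysis is skipped with a
#' warning.
#'
#' @param em an [expression_matrix()]; samples named in `probabilities` are
#'   partitioned, all others keep their phenotype (the comparator samples).
#' @param targets a [target_set_collection()].
#' @param probabilities a [pathway_probabilities()] vector covering the case
#'   samples.
#' @param comparator_label phenotype label of the comparator samples.
#' @param cutoff pathway-activation probability cutoff (inclusive; default
#'   0.8).
#' @inheritParams run_discovery
#' @return A list with `switching`, `overlap`, `p_value`, `profiles` (the two
#'   [deregulation_profile()]s) and `partition`; or a list with
#'   `skipped = TRUE` and a `reason` when a partition is degenerate.
#' @export
run_switch_analysis <- function(em, targets, probabilities,
                                comparator_label = "normal", cutoff = 0.8,
                                K = 1000L, seed, p_threshold = 0.005,
                                fdr_threshold = 0.01, out_dir = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"),
            inherits(probabilities, "PathwayProbabilities"))
  if (missing(seed)) stop("a seed is required")
  unknown <- setdiff(names(probabilities), colnames(em$values))
  if (length(unknown))
    stop("probability sample(s) absent from the matrix: ",
         paste(unknown, collapse = ", "))
  part <- threshold_pathway(probabilities, cutoff)
  if (length(part$active) < 2L || length(part$inactive) < 2L) {
    warning("pathway partition degenerate (",
            length(part$active), " active / ",
            length(part$inactive), " inactive samples); analysis skipped")
    return(list(skipped = TRUE,
                reason = "degenerate pathway partition",
                partition = part))
  }
  phen <- em$phenotype
  phen[part$active] <- "pathway_active"
  phen[part$inactive] <- "pathway_inactive"
  em2 <- expression_matrix(em$values, em$batch, phen)
  run_act <- run_discovery(em2, targets, "pathway_active", comparator_label,
                           K = K, seed = seed, p_threshold = p_threshold,
                           fdr_threshold = fdr_threshold, out_dir = out_dir)
  run_ina <- run_discovery(em2, targets, "pathway_inactive", comparator_label,
                           K = K, seed = seed + 1L, p_threshold = p_threshold,
                           fdr_threshold = fdr_threshold, out_dir = out_dir)
  # universe = miRNAs scored in both contrasts
  u <- intersect(run_act$profile$universe, run_ina$profile$universe)
  pa <- deregulation_profile(run_act$profile$condition,
                             intersect(run_act$profile$activated, u),
                             intersect(run_act$profile$silenced, u), u)
  pi_ <- deregulation_profile(run_ina$profile$condition,
                              intersect(run_ina$profile$activated, u),
                              intersect(run_ina$profile$silenced, u), u)
  sw <- ras_switching(pa, pi_)
  list(switching = sw$switching, overlap = sw$overlap, p_value = sw$p_value,
       profiles = list(active = pa, inactive = pi_), partition = part,
       skipped = FALSE)
}
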