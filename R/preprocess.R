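# Normalization, batch adjustment and the ranked expression-change vector.

#' Virtual-reference scaling of bead-array intensities
#'
#' Scales every sample by the ratio of the average intensity of a virtual
#' reference sample (the mean of the per-sample mean intensities) to the
#' average intensity of that sample, the normalization applied to
#' background-subtracted DASL bead-array data. After scaling, every sample
#' has the same mean intensity, and the operation is idempotent.
#'
#' @param em an [expression_matrix()] of non-negative intensities.
#' @return The scaled `ExpressionMatrix`.
#' @export
dasl_normalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (any(em$values < 0))
    stop("dasl_normalize expects non-negative intensities")
  sample_means <- colMeans(em$values)
  zero <- names(sample_means)[sample_means == 0]
  if (length(zero))
    stop("sample(s) with zero mean intensity: ", paste(zero, collapse = ", "))
  ref <- mean(sample_means)
  em$values <- sweep(em$values, 2L, ref / sample_means, `*`)
  em
}

#' Location/scale batch adjustment across datasets
#'
#' Removes non-biological between-dataset variation with a transparent
#' per-gene location/scale match: within each batch, every gene's values are
#' shifted so the within-batch mean equals the unweighted mean of the batch
#' means, and rescaled so the within-batch standard deviation equals the
#' pooled (root-mean) within-batch standard deviation. Genes with zero
#' variance inside a batch are shifted only. The adjustment is isolated
#' behind this one function so an alternative (e.g. empirical-Bayes
#' shrinkage) can be swapped in.
#'
#' @param em an [expression_matrix()]; every batch must contain at least two
#'   samples.
#' @return The adjusted `ExpressionMatrix`.
#' @export
batch_adjust <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  batches <- split(colnames(em$values), em$batch)
  small <- names(batches)[lengths(batches) < 2L]
  if (length(small))
    stop("batch(es) with fewer than 2 samples: ", paste(small, collapse = ", "))
  if (length(batches) == 1L) return(em)
  v <- em$values
  means <- vapply(batches, function(s) rowMeans(v[, s, drop = FALSE]),
                  numeric(nrow(v)))
  vars <- vapply(batches, function(s) {
    x <- v[, s, drop = FALSE]
    rowSums((x - rowMeans(x))^2) / (length(s) - 1L)
  }, numeric(nrow(v)))
  if (!is.matrix(means)) {   # single-gene matrix: vapply drops dimensions
    means <- matrix(means, 1L, dimnames = list(NULL, names(batches)))
    vars <- matrix(vars, 1L, dimnames = list(NULL, names(batches)))
  }
  grand <- rowMeans(means)
  pooled_sd <- sqrt(rowMeans(vars))
  for (b in names(batches)) {
    s <- batches[[b]]
    sd_b <- sqrt(vars[, b])
    scale <- ifelse(sd_b > 0 & pooled_sd > 0, pooled_sd / sd_b, 1)
    v[, s] <- (v[, s, drop = FALSE] - means[, b]) * scale + grand
  }
  em$values <- v
  em
}

# Per-gene Welch t statistics, vectorized over genes. Genes with zero
# variance in both groups get statistic 0 (no rankable evidence).
.welch_t_rows <- function(values, case_cols, comp_cols) {
  xc <- values[, case_cols, drop = FALSE]
  xn <- values[, comp_cols, drop = FALSE]
  n1 <- ncol(xc); n2 <- ncol(xn)
  m1 <- rowMeans(xc); m2 <- rowMeans(xn)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1L)
  v2 <- rowSums((xn - m2)^2) / (n2 - 1L)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  t
}

#' Rank genes by differential expression between two conditions
#'
#' Computes a per-gene Welch t statistic (case minus comparator) and orders
#' all genes by decreasing statistic — the expression change vector on which
#' miRNA activity is scored. Ties are broken by ascending gene id (C-locale)
#' so the ranking is deterministic across platforms. Genes with zero variance
#' in both groups get statistic 0.
#'
#' @param em an [expression_matrix()].
#' @param case_label,comparator_label phenotype labels defining the contrast;
#'   each must cover at least two samples.
#' @return An object of class `ExpressionChangeVector`: a data frame with
#'   columns `gene_id` and `statistic`, sorted by decreasing statistic, with
#'   attributes `case`, `comparator` and `statistic_name`.
#' @export
rank_expression_changes <- function(em, case_label, comparator_label) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  case_cols <- names(em$phenotype)[em$phenotype == case_label]
  comp_cols <- names(em$phenotype)[em$phenotype == comparator_label]
  if (length(case_cols) < 2L)
    stop("condition '", case_label, "' has fewer than 2 samples")
  if (length(comp_cols) < 2L)
    stop("condition '", comparator_label, "' has fewer than 2 samples")
  t <- .welch_t_rows(em$values, case_cols, comp_cols)
  gene_id <- rownames(em$values)
  ord <- order(-t, gene_id, method = "radix")
  structure(data.frame(gene_id = gene_id[ord], statistic = t[ord],
                       stringsAsFactors = FALSE),
            case = case_label, comparator = comparator_label,
            statistic_name = "welch_t",
            class = c("ExpressionChangeVector", "data.frame"))
}

#' Write an expression change vector
#'
#' Two tab-separated columns (`gene_id`, `statistic`) preceded by provenance
#' comment lines recording the contrast.
#'
#' @param cv an `ExpressionChangeVector` from [rank_expression_changes()].
#' @param path output path.
#' @return Invisibly, `cv`.
#' @export
write_change_vector <- function(cv, path) {
  stopifnot(inherits(cv, "ExpressionChangeVector"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(sprintf("case=%s; comparator=%s; statistic=%s",
                                 attr(cv, "case"), attr(cv, "comparator"),
                                 attr(cv, "statistic_name"))), con)
  utils::write.table(as.data.frame(cv), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cv)
}
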