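#' Construct an expression matrix with sample annotations
#'
#' The central evidence container of the pipeline: a genes x samples matrix of
#' (log-scale) expression intensities together with a batch label and a
#' phenotype label for every sample. All downstream operations
#' ([dasl_normalize()], [batch_adjust()], [rank_expression_changes()]) consume
#' and return this class. Values are assumed to be on a log scale already; the
#' pipeline never exponentiates.
#'
#' @param values numeric matrix, rows = genes, columns = samples; dimnames
#'   required and unique; all entries finite.
#' @param batch named character vector mapping every sample to a batch label.
#' @param phenotype named character vector mapping every sample to a class
#'   label (e.g. a tumor subtype or `"normal"`).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `batch`, `phenotype`.
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2, dimnames = list(paste0("G", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, batch = c(s1 = "b1", s2 = "b1"),
#'                         phenotype = c(s1 = "tumor", s2 = "normal"))
#' @export
expression_matrix <- function(values, batch, phenotype) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'values' must have row (gene) and column (sample) names")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  batch <- .check_sample_map(batch, sample_ids, "batch")
  phenotype <- .check_sample_map(phenotype, sample_ids, "phenotype")
  structure(list(values = values, batch = batch, phenotype = phenotype),
            class = "ExpressionMatrix")
}

.check_sample_map <- function(map, sample_ids, what) {
  if (is.null(names(map)))
    stop("'", what, "' must be a named vector (names = sample ids)")
  missing <- setdiff(sample_ids, names(map))
  if (length(missing))
    stop("sample(s) missing from ", what, " annotation: ",
         paste(missing, collapse = ", "))
  stats::setNames(as.character(map[sample_ids]), sample_ids)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  batches:   ", paste(unique(x$batch), collapse = ", "), "\n")
  cat("  phenotypes:", paste(unique(x$phenotype), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by samples
#'
#' @param em an [expression_matrix()].
#' @param samples character vector of sample ids to keep (order preserved).
#' @return An `ExpressionMatrix` restricted to `samples`.
#' @export
subset_samples <- function(em, samples) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  missing <- setdiff(samples, colnames(em$values))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  expression_matrix(em$values[, samples, drop = FALSE],
                    em$batch[samples], em$phenotype[samples])
}

#' Construct a collection of per-miRNA target gene sets
#'
#' Holds the sequence-based side of the activity inference: for each miRNA the
#' set of genes predicted to carry binding sites (e.g. miRanda or TargetScan
#' predictions read from a GMT file). Target genes need not all be present in
#' a given expression matrix; the intersection is taken at analysis time.
#'
#' @param targets named list; one character vector of gene ids per miRNA.
#'   Duplicate genes within a set are collapsed (first occurrence kept).
#' @param scores optional named list parallel to `targets` giving per-gene
#'   binding scores (named numeric vectors).
#' @param descriptions optional named character vector of free-text
#'   descriptions (the second GMT column).
#' @return An object of class `TargetSetCollection`.
#' @export
target_set_collection <- function(targets, scores = NULL, descriptions = NULL) {
  if (!is.list(targets) || is.null(names(targets)))
    stop("'targets' must be a named list of character vectors")
  dup <- unique(names(targets)[duplicated(names(targets))])
  if (length(dup))
    stop("duplicate miRNA identifier(s): ", paste(dup, collapse = ", "))
  targets <- lapply(targets, function(g) unique(as.character(g)))
  empty <- names(targets)[lengths(targets) == 0L]
  if (length(empty))
    stop("empty target set(s): ", paste(empty, collapse = ", "))
  if (!is.null(scores)) {
    if (!all(names(scores) %in% names(targets)))
      stop("'scores' contains miRNAs absent from 'targets'")
  }
  structure(list(targets = targets, scores = scores,
                 descriptions = descriptions),
            class = "TargetSetCollection")
}

#' @export
print.TargetSetCollection <- function(x, ...) {
  sz <- lengths(x$targets)
  cat(sprintf("TargetSetCollection: %d miRNAs, target-set sizes %d-%d (median %g)\n",
              length(x$targets), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' @export
length.TargetSetCollection <- function(x) length(x$targets)

#' Construct per-sample pathway activation probabilities
#'
#' A thin validated wrapper around a named numeric vector of probabilities
#' that a signaling pathway (e.g. RAS) is active in each sample, as produced
#' by an external classifier. Consumed by [threshold_pathway()].
#'
#' @param p named numeric vector, values in \[0, 1\].
#' @return An object of class `PathwayProbabilities` (a named numeric vector).
#' @export
pathway_probabilities <- function(p) {
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("probabilities must be named by sample id")
  p <- stats::setNames(as.numeric(p), names(p))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  structure(p, class = "PathwayProbabilities")
}

#' Construct a set of miRNA precursor sequences
#'
#' Precursor hairpins are the mapping reference for small-RNA reads. RNA
#' alphabet (U) is normalized to DNA (T) internally so the mapper operates on
#' a single alphabet; whether each input sequence used U is remembered so that
#' writing the set back out reproduces the original alphabet.
#'
#' @param sequences named character vector of nucleotide sequences over
#'   A/C/G/T/U (case-insensitive).
#' @return An object of class `PrecursorSet`: a named character vector of
#'   upper-case DNA sequences with a logical attribute `rna` recording which
#'   inputs used the RNA alphabet.
#' @export
precursor_set <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("precursor sequences must be named by miRNA id")
  dup <- unique(names(sequences)[duplicated(names(sequences))])
  if (length(dup))
    stop("duplicate precursor identifier(s): ", paste(dup, collapse = ", "))
  s <- toupper(as.character(sequences))
  if (any(!nzchar(s)))
    stop("empty precursor sequence(s): ",
         paste(names(sequences)[!nzchar(s)], collapse = ", "))
  bad <- grepl("[^ACGTU]", s)
  if (any(bad))
    stop("invalid characters in precursor(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  rna <- grepl("U", s, fixed = TRUE)
  s <- gsub("U", "T", s, fixed = TRUE)
  structure(stats::setNames(s, names(sequences)),
            rna = stats::setNames(rna, names(sequences)),
            class = "PrecursorSet")
}

#' @export
print.PrecursorSet <- function(x, ...) {
  cat(sprintf("PrecursorSet: %d precursors, lengths %d-%d\n",
              length(unclass(x)), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Construct a set of small-RNA sequencing reads
#'
#' @param read_id character vector of unique read identifiers.
#' @param sequence character vector of read sequences over A/C/G/T/N.
#' @param quality character vector of Phred+33 quality strings, one character
#'   per base.
#' @return An object of class `ReadSet`: a data frame with columns `read_id`,
#'   `sequence`, `quality`.
#' @export
read_set <- function(read_id, sequence, quality) {
  read_id <- as.character(read_id)
  sequence <- toupper(as.character(sequence))
  quality <- as.character(quality)
  if (length(read_id) != length(sequence) || length(sequence) != length(quality))
    stop("read_id, sequence and quality must have equal length")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("invalid characters in read(s): ",
         paste(read_id[bad], collapse = ", "))
  mism <- nchar(sequence) != nchar(quality)
  if (any(mism))
    stop("quality/sequence length mismatch for read(s): ",
         paste(read_id[mism], collapse = ", "))
  structure(data.frame(read_id = read_id, sequence = sequence,
                       quality = quality, stringsAsFactors = FALSE),
            class = c("ReadSet", "data.frame"))
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads, lengths %s\n", nrow(x),
              if (nrow(x)) paste(range(nchar(x$sequence)), collapse = "-") else "-"))
  invisible(x)
}
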