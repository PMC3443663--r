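# Readers/writers for the plain-text formats the pipeline touches.
# All tabular outputs are tab-separated with a header row; lines starting
# with '#' are provenance comments and are skipped on read.

.provenance <- function(...) {
  extra <- paste(c(...), collapse = "; ")
  sprintf("# miract %s%s",
          as.character(utils::packageVersion("miract")),
          if (nzchar(extra)) paste0("; ", extra) else "")
}

#' Read an expression matrix and its sample annotation
#'
#' The matrix file is tab-separated: first column gene id, remaining columns
#' one per sample. The annotation file is tab-separated with the sample id in
#' its first column and (at least) a batch and a phenotype column.
#'
#' @param path path to the expression table.
#' @param annotation_path path to the sample annotation table.
#' @param batch_column,phenotype_column names of the annotation columns
#'   holding batch and phenotype labels.
#' @return An [expression_matrix()]. Row and column order follow the file.
#' @export
read_expression_table <- function(path, annotation_path,
                                  batch_column = "batch",
                                  phenotype_column = "phenotype") {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression table needs a gene-id column plus >=1 sample column")
  gene_ids <- as.character(tab[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  for (col in c(batch_column, phenotype_column))
    if (!col %in% names(ann))
      stop("annotation file lacks column '", col, "'")
  sample_ids <- as.character(ann[[1L]])
  expression_matrix(values,
                    batch = stats::setNames(as.character(ann[[batch_column]]), sample_ids),
                    phenotype = stats::setNames(as.character(ann[[phenotype_column]]), sample_ids))
}

#' Write an expression matrix and its sample annotation
#'
#' @param em an [expression_matrix()].
#' @param path,annotation_path output paths for the matrix and annotation.
#' @param comment optional extra provenance recorded in the header comment.
#' @return Invisibly, `em`.
#' @export
write_expression_table <- function(em, path, annotation_path, comment = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(.provenance(comment), con)
  tab <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = colnames(em$values),
                    batch = unname(em$batch),
                    phenotype = unname(em$phenotype),
                    stringsAsFactors = FALSE)
  con2 <- file(annotation_path, "w")
  on.exit(close(con2), add = TRUE)
  writeLines(.provenance(comment), con2)
  utils::write.table(ann, con2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(em)
}

#' Read miRNA target sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a line are collapsed; line order is preserved.
#'
#' @param path path to the GMT file.
#' @return A [target_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  targets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(targets) <- ids
  target_set_collection(targets, descriptions = stats::setNames(desc, ids))
}

#' Write a target set collection as GMT
#'
#' @param tsc a [target_set_collection()].
#' @param path output path.
#' @return Invisibly, `tsc`.
#' @export
write_gmt <- function(tsc, path) {
  stopifnot(inherits(tsc, "TargetSetCollection"))
  desc <- tsc$descriptions
  lines <- vapply(names(tsc$targets), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, tsc$targets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(tsc)
}

#' Read precursor sequences from a FASTA file
#'
#' Sequences are upper-cased and U is normalized to T internally; the
#' original alphabet is remembered so [write_fasta()] round-trips it.
#'
#' @param path path to the FASTA file.
#' @return A [precursor_set()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  precursor_set(stats::setNames(as.character(set),
                                sub("\\s.*$", "", names(set))))
}

#' Write precursor sequences as FASTA
#'
#' @param ps a [precursor_set()].
#' @param path output path.
#' @return Invisibly, `ps`.
#' @export
write_fasta <- function(ps, path) {
  stopifnot(inherits(ps, "PrecursorSet"))
  seqs <- unclass(ps)
  rna <- attr(ps, "rna")
  out <- ifelse(rna[names(seqs)], gsub("T", "U", seqs, fixed = TRUE), seqs)
  writeLines(paste0(">", names(seqs), "\n", out), path)
  invisible(ps)
}

#' Read small-RNA reads from a FASTQ file (Phred+33)
#'
#' @param path path to the FASTQ file.
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ file has ", length(lines), " lines, not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  bad <- !startsWith(ids, "@")
  if (any(bad))
    stop("malformed FASTQ header at line ", idx[which(bad)[1L]])
  ids <- sub("\\s.*$", "", substring(ids, 2L))
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism))
    stop("quality/sequence length mismatch for read(s): ",
         paste(ids[mism], collapse = ", "))
  read_set(ids, seqs, quals)
}

#' Write small-RNA reads as FASTQ (Phred+33)
#'
#' @param rs a [read_set()].
#' @param path output path.
#' @return Invisibly, `rs`.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "ReadSet"))
  writeLines(paste0("@", rs$read_id, "\n", rs$sequence, "\n+\n", rs$quality),
             path)
  invisible(rs)
}

#' Read per-sample pathway activation probabilities
#'
#' Tab-separated, two columns: sample id, probability.
#'
#' @param path path to the table.
#' @return A [pathway_probabilities()] vector.
#' @export
read_pathway_probabilities <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  pathway_probabilities(stats::setNames(as.numeric(tab[[2L]]),
                                        as.character(tab[[1L]])))
}

#' Write per-sample pathway activation probabilities
#'
#' @param p a [pathway_probabilities()] vector.
#' @param path output path.
#' @return Invisibly, `p`.
#' @export
write_pathway_probabilities <- function(p, path) {
  stopifnot(inherits(p, "PathwayProbabilities"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(), con)
  utils::write.table(data.frame(sample_id = names(p), probability = as.numeric(p)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}
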