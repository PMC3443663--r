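# Small-RNA sequencing side: trimming, <=1-base-difference mapping to
# precursor hairpins, read-count quantification, alteration flagging, QC.

#' Trim reads to their leading bases
#'
#' Retains the leading `keep_length` bases of each read (sequence and quality
#' truncated in step) — the mature-miRNA-sized prefix of a longer sequencing
#' read whose 3' end runs into adaptor. Reads already shorter than
#' `keep_length` pass through unchanged; their number is reported in the
#' `n_short` attribute and a message.
#'
#' @param reads a [read_set()].
#' @param keep_length number of leading bases to retain (default 21, the
#'   typical mature miRNA length).
#' @return A `ReadSet` with attribute `n_short`.
#' @export
trim_reads <- function(reads, keep_length = 21L) {
  stopifnot(inherits(reads, "ReadSet"))
  if (keep_length < 1L) stop("keep_length must be >= 1")
  short <- nchar(reads$sequence) < keep_length
  if (any(short))
    message(sum(short), " read(s) shorter than ", keep_length,
            " bases passed through untrimmed")
  out <- read_set(reads$read_id,
                  substr(reads$sequence, 1L, keep_length),
                  substr(reads$quality, 1L, keep_length))
  attr(out, "n_short") <- sum(short)
  out
}

# Longest common prefix / suffix length of two equal-orientation char vectors.
.lcp <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}
.lcs <- function(a, b) .lcp(rev(a), rev(b))

#' Map one read to precursor sequences allowing at most one base difference
#'
#' A read maps to a precursor wherever it matches a substring exactly or with
#' a single difference: one substitution, one base missing from the read
#' relative to the precursor (`deletion_in_read`, the "one gap" case) or one
#' extra base in the read (`insertion_in_read`). All best mappings are
#' returned: if the read matches exactly anywhere, only exact mappings are
#' reported; otherwise all one-difference mappings are. U in the read is
#' accepted and normalized to T.
#'
#' @param read_sequence a single read sequence (character scalar).
#' @param precursors a [precursor_set()].
#' @param min_length minimum read length accepted (default 10).
#' @return A data frame with columns `mirna_id`, `class` (one of `exact`,
#'   `substitution`, `deletion_in_read`, `insertion_in_read`) and `offset`
#'   (1-based start within the precursor); zero rows if unmapped.
#' @export
map_read <- function(read_sequence, precursors, min_length = 10L) {
  stopifnot(inherits(precursors, "PrecursorSet"))
  r_str <- gsub("U", "T", toupper(read_sequence), fixed = TRUE)
  L <- nchar(r_str)
  if (L < min_length)
    stop("read shorter than the minimum mappable length (", min_length, ")")
  r <- strsplit(r_str, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (id in names(unclass(precursors))) {
    p <- strsplit(unclass(precursors)[[id]], "", fixed = TRUE)[[1L]]
    Lp <- length(p)
    # exact and single-substitution windows (length L)
    if (Lp >= L) {
      for (o in seq_len(Lp - L + 1L)) {
        mism <- sum(p[o:(o + L - 1L)] != r)
        if (mism == 0L)
          rows[[length(rows) + 1L]] <- list(id, "exact", o)
        else if (mism == 1L)
          rows[[length(rows) + 1L]] <- list(id, "substitution", o)
      }
    }
    # one base of the precursor window absent from the read (length L + 1)
    if (Lp >= L + 1L) {
      for (o in seq_len(Lp - L)) {
        w <- p[o:(o + L)]
        if (.lcp(r, w) + .lcs(r, w) >= L)
          rows[[length(rows) + 1L]] <- list(id, "deletion_in_read", o)
      }
    }
    # one extra base in the read relative to the window (length L - 1)
    if (L >= 2L && Lp >= L - 1L) {
      for (o in seq_len(Lp - L + 2L)) {
        w <- p[o:(o + L - 2L)]
        if (.lcp(r, w) + .lcs(r, w) >= L - 1L)
          rows[[length(rows) + 1L]] <- list(id, "insertion_in_read", o)
      }
    }
  }
  out <- data.frame(mirna_id = vapply(rows, `[[`, "", 1L),
                    class = vapply(rows, `[[`, "", 2L),
                    offset = vapply(rows, function(x) as.integer(x[[3L]]), 0L),
                    stringsAsFactors = FALSE)
  if (any(out$class == "exact"))
    out <- out[out$class == "exact", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a whole read set against the precursors
#'
#' @param reads a [read_set()].
#' @inheritParams map_read
#' @return A named list (one element per read id) of [map_read()] results.
#' @export
map_reads <- function(reads, precursors, min_length = 10L) {
  stopifnot(inherits(reads, "ReadSet"))
  out <- lapply(reads$sequence, map_read, precursors = precursors,
                min_length = min_length)
  names(out) <- reads$read_id
  out
}

#' Per-miRNA read counts at 0 and <=1 base differences
#'
#' Each read contributes one count to every miRNA it best-maps to
#' (multi-mapping reads are counted once per miRNA, a choice recorded in the
#' output attribute `multimapped`); `count_exact` increments only when the
#' best mappings to that miRNA are exact.
#'
#' @param mappings output of [map_reads()].
#' @param precursors the [precursor_set()] mapped against (defines the row
#'   set; miRNAs with no reads get zero counts).
#' @return A data frame `mirna_id, count_le1, count_exact` with attribute
#'   `multimapped` (number of reads mapping to more than one miRNA).
#' @export
quantify <- function(mappings, precursors) {
  stopifnot(inherits(precursors, "PrecursorSet"))
  ids <- names(unclass(precursors))
  le1 <- stats::setNames(integer(length(ids)), ids)
  exact <- le1
  multi <- 0L
  for (m in mappings) {
    if (nrow(m) == 0L) next
    hit <- unique(m$mirna_id)
    if (length(hit) > 1L) multi <- multi + 1L
    le1[hit] <- le1[hit] + 1L
    ex <- unique(m$mirna_id[m$class == "exact"])
    exact[ex] <- exact[ex] + 1L
  }
  structure(data.frame(mirna_id = ids, count_le1 = unname(le1),
                       count_exact = unname(exact), stringsAsFactors = FALSE),
            multimapped = multi)
}

#' Flag potential miRNA sequence alterations across samples
#'
#' A miRNA is flagged when, in every provided sample/replicate, it is
#' supported by at least `min_reads` reads at one base difference or less
#' while having zero exact-match reads — the count signature of a consistent
#' single-base alteration. A miRNA absent from a sample (zero reads) is not
#' flagged. Without genome-wide exclusion of other loci these remain
#' *potential* alterations.
#'
#' @param counts data frame with columns `mirna_id`, `sample`, `count_le1`,
#'   `count_exact` (long format; one row per miRNA per sample/replicate).
#' @param min_reads minimum supporting `count_le1` per sample (default 10).
#' @return A data frame `mirna_id, n_samples, min_count_le1, max_count_exact,
#'   flagged`, one row per miRNA.
#' @export
flag_alterations <- function(counts, min_reads = 10L) {
  need <- c("mirna_id", "sample", "count_le1", "count_exact")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$count_exact > counts$count_le1))
    stop("count_exact exceeds count_le1 for some row")
  samples <- unique(counts$sample)
  if (length(samples) < 1L) stop("need at least one sample")
  full <- expand.grid(mirna_id = unique(counts$mirna_id), sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- merge(full, counts[, need], by = c("mirna_id", "sample"),
                all.x = TRUE)
  full$count_le1[is.na(full$count_le1)] <- 0L
  full$count_exact[is.na(full$count_exact)] <- 0L
  agg <- do.call(rbind, lapply(split(full, full$mirna_id), function(g) {
    data.frame(mirna_id = g$mirna_id[1L], n_samples = nrow(g),
               min_count_le1 = min(g$count_le1),
               max_count_exact = max(g$count_exact),
               flagged = all(g$count_le1 >= min_reads) &&
                 all(g$count_exact == 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$mirna_id, method = "radix"), , drop = FALSE]
}

#' Implied base-call accuracy from a mean Phred score
#'
#' `100 * (1 - 10^(-q/10))` percent: a mean quality of 30 implies 99.9%
#' base-call accuracy.
#'
#' @param mean_q mean Phred quality score (>= 0).
#' @return Percent accuracy.
#' @export
phred_mean_accuracy <- function(mean_q) {
  if (any(mean_q < 0)) stop("mean Phred score must be non-negative")
  100 * (1 - 10^(-mean_q / 10))
}

#' Mean Phred quality of a read set
#'
#' @param reads a [read_set()] with Phred+33 qualities.
#' @return Mean per-base Phred score across all reads.
#' @export
mean_phred <- function(reads) {
  stopifnot(inherits(reads, "ReadSet"))
  q <- unlist(lapply(reads$quality, function(s) utf8ToInt(s) - 33L))
  mean(q)
}
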