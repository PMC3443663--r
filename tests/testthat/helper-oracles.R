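# Independent oracles used across tests. These deliberately use the dumbest
# possible formulation (explicit loops, exhaustive enumeration) so they stay
# independent of the package's vectorized implementations.

# Change vector with a prescribed gene order (statistics descending).
toy_change_vector <- function(gene_ids) {
  structure(data.frame(gene_id = gene_ids,
                       statistic = seq(length(gene_ids), 1),
                       stringsAsFactors = FALSE),
            case = "case", comparator = "comparator",
            statistic_name = "welch_t",
            class = c("ExpressionChangeVector", "data.frame"))
}

# Brute-force permutation FDR: literal loops over every (x, k) pair.
brute_fdr <- function(as_scores, ns, as_star) {
  ns_side <- c(); num <- 0
  for (x in seq_len(nrow(ns))) for (k in seq_len(ncol(ns))) {
    v <- ns[x, k]
    if (as_star >= 0 && v >= 0) {
      ns_side <- c(ns_side, v); if (v >= as_star) num <- num + 1
    }
    if (as_star < 0 && v <= 0) {
      ns_side <- c(ns_side, v); if (v <= as_star) num <- num + 1
    }
  }
  as_side <- c(); den <- 0
  for (a in as_scores) {
    if (as_star >= 0 && a >= 0) {
      as_side <- c(as_side, a); if (a >= as_star) den <- den + 1
    }
    if (as_star < 0 && a <= 0) {
      as_side <- c(as_side, a); if (a <= as_star) den <- den + 1
    }
  }
  if (length(ns_side) == 0 || length(as_side) == 0 || den == 0) return(1)
  min(1, (num / length(ns_side)) / (den / length(as_side)))
}

# Exhaustive hypergeometric upper-tail probability by direct tail summation.
tail_sum_p <- function(q, size_a, size_b, size_u) {
  total <- 0
  for (i in seq(q, min(size_a, size_b))) {
    if (i < 0) next
    total <- total + choose(size_a, i) * choose(size_u - size_a, size_b - i)
  }
  total / choose(size_u, size_b)
}

# Exhaustive single-edit-neighborhood read mapper: for every precursor
# substring, enumerate its whole edit-distance-<=1 relationship with the read
# by explicit string surgery, then apply the exact-beats-one-difference rule.
oracle_map_read <- function(read, precursors) {
  read <- gsub("U", "T", toupper(read), fixed = TRUE)
  L <- nchar(read)
  delete_each <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i)
      paste0(substr(s, 1, i - 1), substring(s, i + 1)), "")
  }
  rows <- list()
  add <- function(id, cls, off)
    rows[[length(rows) + 1L]] <<- data.frame(mirna_id = id, class = cls,
                                             offset = off,
                                             stringsAsFactors = FALSE)
  for (id in names(unclass(precursors))) {
    p <- unclass(precursors)[[id]]
    Lp <- nchar(p)
    for (o in seq_len(max(Lp - L + 1, 0))) {
      w <- substr(p, o, o + L - 1)
      if (w == read) add(id, "exact", o)
      else if (sum(strsplit(w, "")[[1]] != strsplit(read, "")[[1]]) == 1)
        add(id, "substitution", o)
    }
    for (o in seq_len(max(Lp - L, 0))) {
      w <- substr(p, o, o + L)
      if (read %in% delete_each(w)) add(id, "deletion_in_read", o)
    }
    if (L >= 2) for (o in seq_len(max(Lp - L + 2, 0))) {
      w <- substr(p, o, o + L - 2)
      if (w %in% delete_each(read)) add(id, "insertion_in_read", o)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), class = character(),
               offset = integer(), stringsAsFactors = FALSE)
  if (any(out$class == "exact")) out <- out[out$class == "exact", ]
  rownames(out) <- NULL
  out
}

# Canonical string form of a mapping table for set comparison.
mapping_key <- function(m) sort(paste(m$mirna_id, m$class, m$offset))

# Small expression matrix fixture.
toy_matrix <- function(values, batch = NULL, phenotype = NULL) {
  samples <- colnames(values)
  if (is.null(batch)) batch <- stats::setNames(rep("b1", ncol(values)), samples)
  if (is.null(phenotype))
    phenotype <- stats::setNames(rep("tumor", ncol(values)), samples)
  expression_matrix(values, batch, phenotype)
}
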