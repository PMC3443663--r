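# Seeded generators emulating the statistical structure of a two-condition
# expression study with miRNA-driven target repression, and of small-RNA
# sequencing reads from precursor hairpins.

#' Specification of a synthetic expression study
#'
#' Defines the design of a simulated two-condition cohort: baseline
#' log-intensities around 8, Gaussian noise, per-miRNA target sets drawn
#' without replacement (independently across miRNAs, so sets may overlap as
#' real prediction sets do), a planted shift of target genes in the case
#' samples for selected miRNAs, optional per-batch offsets, and an optional
#' pathway-switch program. Defaults mirror a desk-scale version of an
#' integrated discovery cohort: 2000 genes, 100 miRNAs, 50 targets each,
#' 20 case and 20 comparator samples, effect size 1.5 noise SDs.
#'
#' @param n_genes,n_mirnas,targets_per_mirna design dimensions.
#' @param n_case,n_comparator samples per condition.
#' @param effect_size planted shift of target genes in case samples, in units
#'   of `noise_sd` (>= 0). Activated miRNAs repress their targets (shift
#'   `-effect_size * noise_sd`); silenced miRNAs de-repress (`+`).
#' @param noise_sd Gaussian noise standard deviation on the log scale.
#' @param baseline mean baseline log-intensity.
#' @param n_activated,n_silenced numbers of planted activated/silenced
#'   miRNAs (the first `n_activated` and next `n_silenced` generated miRNAs).
#' @param batch_offsets named numeric vector of additive per-batch offsets;
#'   samples are assigned to batches cyclically within each condition.
#' @param n_switch if > 0, the cohort gains a third sample group: case
#'   samples are split into pathway-active and pathway-inactive halves
#'   (`n_case` each) and the first `n_switch` miRNAs *after* the planted ones
#'   follow a switch program — targets repressed in pathway-active samples
#'   and de-repressed in pathway-inactive samples.
#' @param seed integer seed (required).
#' @return A `SimulationSpec` list.
#' @export
sim_spec <- function(n_genes = 2000L, n_mirnas = 100L,
                     targets_per_mirna = 50L, n_case = 20L,
                     n_comparator = 20L, effect_size = 1.5, noise_sd = 1,
                     baseline = 8, n_activated = 0L, n_silenced = 0L,
                     batch_offsets = c(b1 = 0), n_switch = 0L, seed) {
  if (missing(seed)) stop("a seed is required")
  if (targets_per_mirna > n_genes)
    stop("targets_per_mirna exceeds n_genes")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (n_activated + n_silenced + n_switch > n_mirnas)
    stop("more planted miRNAs than n_mirnas")
  if (any(c(n_genes, n_mirnas, targets_per_mirna, n_case, n_comparator) < 1L))
    stop("design counts must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 targets_per_mirna = as.integer(targets_per_mirna),
                 n_case = as.integer(n_case),
                 n_comparator = as.integer(n_comparator),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline = baseline,
                 n_activated = as.integer(n_activated),
                 n_silenced = as.integer(n_silenced),
                 batch_offsets = batch_offsets,
                 n_switch = as.integer(n_switch),
                 seed = seed),
            class = "SimulationSpec")
}

.pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a synthetic expression study
#'
#' Draws baseline values `Normal(baseline, noise_sd)`, plants the
#' miRNA-driven target shifts described in [sim_spec()], adds batch offsets,
#' and (for switch designs) emits pathway activation probabilities that
#' separate the active (drawn from U(0.85, 0.99)) and inactive (U(0.05, 0.6))
#' case samples. Fully reproducible from the spec's seed.
#'
#' @param spec a [sim_spec()].
#' @return A list with `expression` (an [expression_matrix()]; phenotypes are
#'   `"tumor"`/`"normal"`), `targets` (a [target_set_collection()]), `truth`
#'   (data frame `mirna_id, status` with status in
#'   activated/silenced/switch/null, plus attribute `target_overlap`, the
#'   fraction of targeted genes targeted by more than one miRNA), and
#'   `probabilities` (a [pathway_probabilities()] over the case samples, or
#'   `NULL` when `n_switch == 0`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  .with_seed(spec$seed, {
    genes <- .pad_ids("g", spec$n_genes)
    mirnas <- .pad_ids("mir", spec$n_mirnas)
    switch_mode <- spec$n_switch > 0L
    n_tumor <- if (switch_mode) 2L * spec$n_case else spec$n_case
    samples <- c(.pad_ids("T", n_tumor), .pad_ids("N", spec$n_comparator))
    phenotype <- stats::setNames(rep(c("tumor", "normal"),
                                     c(n_tumor, spec$n_comparator)), samples)
    active_samples <- if (switch_mode) samples[seq_len(spec$n_case)] else
      samples[phenotype == "tumor"]
    inactive_samples <- if (switch_mode)
      samples[spec$n_case + seq_len(spec$n_case)] else character(0)

    values <- matrix(stats::rnorm(spec$n_genes * length(samples),
                                  spec$baseline, spec$noise_sd),
                     nrow = spec$n_genes,
                     dimnames = list(genes, samples))
    targets <- lapply(seq_len(spec$n_mirnas), function(i)
      sample(genes, spec$targets_per_mirna))
    names(targets) <- mirnas

    status <- rep("null", spec$n_mirnas)
    status[seq_len(spec$n_activated)] <- "activated"
    status[spec$n_activated + seq_len(spec$n_silenced)] <- "silenced"
    status[spec$n_activated + spec$n_silenced + seq_len(spec$n_switch)] <- "switch"

    shift <- spec$effect_size * spec$noise_sd
    tumor_samples <- samples[phenotype == "tumor"]
    for (i in seq_len(spec$n_mirnas)) {
      tg <- targets[[i]]
      if (status[i] == "activated")
        values[tg, tumor_samples] <- values[tg, tumor_samples] - shift
      else if (status[i] == "silenced")
        values[tg, tumor_samples] <- values[tg, tumor_samples] + shift
      else if (status[i] == "switch") {
        values[tg, active_samples] <- values[tg, active_samples] - shift
        values[tg, inactive_samples] <- values[tg, inactive_samples] + shift
      }
    }

    batch_labels <- names(spec$batch_offsets)
    batch <- stats::setNames(
      unlist(lapply(split(samples, phenotype[samples]), function(s)
        stats::setNames(rep_len(batch_labels, length(s)), s)),
        use.names = FALSE),
      unlist(lapply(split(samples, phenotype[samples]), identity),
             use.names = FALSE))
    batch <- batch[samples]
    values <- values + rep(spec$batch_offsets[batch], each = spec$n_genes)

    probabilities <- NULL
    if (switch_mode) {
      p <- c(stats::runif(length(active_samples), 0.85, 0.99),
             stats::runif(length(inactive_samples), 0.05, 0.60))
      probabilities <- pathway_probabilities(
        stats::setNames(p, c(active_samples, inactive_samples)))
    }

    targeted <- table(unlist(targets))
    truth <- data.frame(mirna_id = mirnas, status = status,
                        stringsAsFactors = FALSE)
    attr(truth, "target_overlap") <- mean(targeted > 1L)

    list(expression = expression_matrix(values, batch, phenotype),
         targets = target_set_collection(targets),
         truth = truth,
         probabilities = probabilities)
  })
}

#' Generate random precursor hairpin sequences
#'
#' Uniform-random DNA of the given length — a stand-in reference for
#' exercising the mapper; no attempt is made to emulate real hairpin
#' structure or base composition.
#'
#' @param n number of precursors.
#' @param length precursor length (default 70).
#' @param seed integer seed.
#' @return A [precursor_set()] with ids `mirp01, mirp02, ...`.
#' @export
simulate_precursors <- function(n, length = 70L, seed) {
  if (missing(seed)) stop("a seed is required")
  .with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), "")
    precursor_set(stats::setNames(seqs, .pad_ids("mirp", n)))
  })
}

.apply_edit <- function(window, edit) {
  pos <- edit$position
  if (pos < 1L || pos > nchar(window))
    stop("edit position ", pos, " outside the read window")
  switch(edit$type,
         delete = paste0(substr(window, 1L, pos - 1L),
                         substring(window, pos + 1L)),
         substitute = {
           orig <- substr(window, pos, pos)
           if (identical(orig, edit$base))
             stop("substitution at position ", pos,
                  " does not change the base")
           paste0(substr(window, 1L, pos - 1L), edit$base,
                  substring(window, pos + 1L))
         },
         insert = paste0(substr(window, 1L, pos - 1L), edit$base,
                         substring(window, pos)),
         stop("unknown edit type: ", edit$type))
}

#' Generate small-RNA reads from precursor windows
#'
#' Emits the leading `window` bases of each precursor as reads; miRNAs listed
#' in `altered` emit only edited reads carrying the specified single-base
#' change, reproducing the count signature of a sequence alteration
#' (one-difference reads only, zero exact). Per-base qualities are drawn from
#' a discretized Normal(`mean_q`, 2) clipped to \[2, 41\], Phred+33 encoded.
#'
#' @param precursors a [precursor_set()].
#' @param reads_per_mirna reads emitted per precursor (default 10).
#' @param altered named list (by miRNA id) of edits, each a list with
#'   `position`, `type` (`"delete"`, `"substitute"`, `"insert"`) and, for
#'   substitute/insert, `base`.
#' @param mean_q mean Phred quality (default 30).
#' @param window number of leading precursor bases per read (default 21).
#' @param seed integer seed.
#' @return A list with `reads` (a [read_set()]) and `truth` (data frame
#'   `read_id, mirna_id, edited`).
#' @export
simulate_reads <- function(precursors, reads_per_mirna = 10L, altered = list(),
                           mean_q = 30, window = 21L, seed) {
  stopifnot(inherits(precursors, "PrecursorSet"))
  if (missing(seed)) stop("a seed is required")
  unknown <- setdiff(names(altered), names(unclass(precursors)))
  if (length(unknown))
    stop("altered miRNA(s) not in the precursor set: ",
         paste(unknown, collapse = ", "))
  .with_seed(seed, {
    ids <- names(unclass(precursors))
    recs <- lapply(ids, function(id) {
      w <- substr(unclass(precursors)[[id]], 1L, window)
      edited <- id %in% names(altered)
      if (edited) w <- .apply_edit(w, altered[[id]])
      data.frame(read_id = sprintf("%s_r%03d", id, seq_len(reads_per_mirna)),
                 mirna_id = id, sequence = w, edited = edited,
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    qual <- vapply(nchar(recs$sequence), function(n) {
      q <- pmin(pmax(round(stats::rnorm(n, mean_q, 2)), 2L), 41L)
      intToUtf8(q + 33L)
    }, "")
    list(reads = read_set(recs$read_id, recs$sequence, qual),
         truth = recs[, c("read_id", "mirna_id", "edited")])
  })
}
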