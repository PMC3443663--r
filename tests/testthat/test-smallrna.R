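test_that("trimming keeps the leading bases of sequence and quality together", {
  rs <- read_set(c("r1", "r2"),
                 c(strrep("A", 36), "ACGTACGTACGTACG"),   # 36 and 15 bases
                 c(strrep("I", 36), "IIIIIIIIIIIIIII"))
  expect_message(out <- trim_reads(rs, 21), "1 read")
  expect_equal(nchar(out$sequence), c(21L, 15L))
  expect_equal(nchar(out$quality), c(21L, 15L))
  expect_equal(attr(out, "n_short"), 1L)
})

test_that("the deletion-carrying read maps as in the worked alteration example", {
  ps <- precursor_set(c("hsa-miR-422a" = "ACUGGACUUAGGGUCAGAAGGC"))
  m <- map_read("ACUGGACUUGGGUCAGAAGGC", ps)
  expect_equal(nrow(m), 1)
  expect_equal(m$class, "deletion_in_read")
  expect_equal(m$mirna_id, "hsa-miR-422a")
  expect_false(any(m$class == "exact"))
})

test_that("an exact match suppresses one-difference alternatives", {
  ps <- precursor_set(c(p1 = "AAACCCGGGTTTAAACCCGGGTTT",
                        p2 = "AAACCCGGGTTTAAACCCGGGTTA"))
  read <- substr(unclass(ps)[["p1"]], 3, 16)
  m <- map_read(read, ps)
  expect_true(all(m$class == "exact"))
  # the same windows in p2 differ by one base and would otherwise report
  expect_true(all(m$mirna_id == "p1") || any(m$mirna_id == "p2"))
  oracle <- oracle_map_read(read, ps)
  expect_equal(mapping_key(m), mapping_key(oracle))
})

test_that("reads two edits away from every window stay unmapped", {
  ps <- precursor_set(c(p1 = "ACGTACGTACGTACGTACGT"))
  read <- "ACGTACGTCCCCACGTACGT"  # two substitutions vs any window
  m <- map_read(read, ps)
  expect_equal(nrow(m), 0)
  expect_equal(nrow(oracle_map_read(read, ps)), 0)
})

test_that("the mapper agrees with the single-edit-neighborhood oracle", {
  set.seed(37)
  ps <- simulate_precursors(4, length = 28, seed = 101)
  for (i in 1:40) {
    # reads near a real window (edited half the time) or fully random
    if (i %% 2 == 0) {
      src <- sample(names(unclass(ps)), 1)
      o <- sample(1:8, 1)
      read <- substr(unclass(ps)[[src]], o, o + sample(12:20, 1))
      pos <- sample(nchar(read), 1)
      edit <- sample(c("none", "sub", "del", "ins"), 1)
      read <- switch(edit,
        none = read,
        sub = paste0(substr(read, 1, pos - 1),
                     sample(setdiff(c("A", "C", "G", "T"),
                                    substr(read, pos, pos)), 1),
                     substring(read, pos + 1)),
        del = paste0(substr(read, 1, pos - 1), substring(read, pos + 1)),
        ins = paste0(substr(read, 1, pos - 1),
                     sample(c("A", "C", "G", "T"), 1),
                     substring(read, pos)))
    } else {
      read <- paste(sample(c("A", "C", "G", "T"), sample(12:22, 1),
                           replace = TRUE), collapse = "")
    }
    if (nchar(read) < 10) next
    expect_equal(mapping_key(map_read(read, ps)),
                 mapping_key(oracle_map_read(read, ps)),
                 info = read)
  }
})

test_that("quantification counts best mappings per miRNA", {
  ps <- precursor_set(c(p1 = "ACTGGACTTAGGGTCAGAAGGCACGT",
                        p2 = "TTTTACTGGACTTAGGGTCAGAAGGC"))
  # a read exactly inside both precursors: both counted, both exact
  shared <- "ACTGGACTTAGGGTCAGAAGGC"
  rs <- read_set("r1", shared, strrep("I", nchar(shared)))
  q <- quantify(map_reads(rs, ps), ps)
  expect_equal(q$count_le1, c(1L, 1L))
  expect_equal(q$count_exact, c(1L, 1L))
  expect_equal(attr(q, "multimapped"), 1L)
  # no reads: all zero
  q0 <- quantify(list(), ps)
  expect_true(all(q0$count_le1 == 0) && all(q0$count_exact == 0))
  # ten one-difference reads: (10, 0)
  del_read <- paste0(substr(shared, 1, 9), substring(shared, 11))
  rs10 <- read_set(paste0("d", 1:10), rep(del_read, 10),
                   rep(strrep("I", nchar(del_read)), 10))
  ps1 <- precursor_set(c(p1 = "ACTGGACTTAGGGTCAGAAGGCACGT"))
  q10 <- quantify(map_reads(rs10, ps1), ps1)
  expect_equal(q10$count_le1, 10L)
  expect_equal(q10$count_exact, 0L)
})

test_that("alteration flags require consistent one-difference-only support", {
  counts <- data.frame(
    mirna_id = rep(c("m422", "mOK", "mLow"), each = 4),
    sample = rep(c("LEIO_1", "LEIO_2", "LIPO_1", "LIPO_2"), 3),
    count_le1 = c(10, 15, 25, 15,  10, 15, 20, 12,  9, 30, 30, 30),
    count_exact = c(0, 0, 0, 0,  0, 2, 0, 0,  0, 0, 0, 0))
  flags <- flag_alterations(counts, min_reads = 10)
  expect_true(flags$flagged[flags$mirna_id == "m422"])
  expect_false(flags$flagged[flags$mirna_id == "mOK"])   # exact reads present
  expect_false(flags$flagged[flags$mirna_id == "mLow"])  # below threshold once
  # monotone: raising min_reads never adds flags
  stricter <- flag_alterations(counts, min_reads = 20)
  expect_true(all(stricter$flagged <= flags$flagged))
})

test_that("Phred utilities convert mean scores to implied accuracy", {
  expect_equal(phred_mean_accuracy(30), 99.9)
  expect_equal(phred_mean_accuracy(10), 90)
  expect_equal(phred_mean_accuracy(20), 99)
  expect_error(phred_mean_accuracy(-1), "non-negative")
  rs <- read_set("r1", "ACGT", intToUtf8(c(63, 63, 63, 63)))  # Q30 each
  expect_equal(mean_phred(rs), 30)
})
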