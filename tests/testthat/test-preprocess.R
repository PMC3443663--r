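test_that("virtual-reference scaling equalizes sample means", {
  m <- matrix(c(1, 3, 2, 6), 2, 2,
              dimnames = list(c("G1", "G2"), c("s1", "s2")))
  em <- toy_matrix(m)
  out <- dasl_normalize(em)
  # reference mean 3; factors 1.5 and 0.75
  expect_equal(unname(out$values[, "s1"]), c(1.5, 4.5))
  expect_equal(unname(out$values[, "s2"]), c(1.5, 4.5))
  expect_equal(unname(colMeans(out$values)), c(3, 3))
  # idempotent
  expect_equal(dasl_normalize(out)$values, out$values)
})

test_that("virtual-reference scaling identities and errors", {
  single <- toy_matrix(matrix(c(1, 3), 2, 1,
                              dimnames = list(c("G1", "G2"), "s1")))
  expect_equal(dasl_normalize(single)$values, single$values)
  flat <- toy_matrix(matrix(5, 2, 3,
                            dimnames = list(c("G1", "G2"),
                                            c("s1", "s2", "s3"))))
  expect_equal(dasl_normalize(flat)$values, flat$values)
  zero <- toy_matrix(matrix(c(1, 1, 0, 0), 2, 2,
                            dimnames = list(c("G1", "G2"), c("s1", "s2"))))
  expect_error(dasl_normalize(zero), "s2")
})

test_that("batch adjustment matches the hand-worked location example", {
  m <- matrix(c(0, 2, 10, 12), 1, 4,
              dimnames = list("G1", paste0("s", 1:4)))
  em <- expression_matrix(m,
                          batch = c(s1 = "b1", s2 = "b1", s3 = "b2", s4 = "b2"),
                          phenotype = setNames(rep("t", 4), paste0("s", 1:4)))
  out <- batch_adjust(em)
  expect_equal(unname(out$values[1, ]), c(5, 7, 5, 7))
})

test_that("batch adjustment equalizes per-gene batch means and is safe", {
  set.seed(7)
  m <- matrix(rnorm(40, 8), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("s", 1:10)))
  batch <- setNames(rep(c("b1", "b2"), each = 5), colnames(m))
  em <- expression_matrix(m, batch, setNames(rep("t", 10), colnames(m)))
  out <- batch_adjust(em)
  for (g in rownames(m)) {
    m1 <- mean(out$values[g, batch == "b1"])
    m2 <- mean(out$values[g, batch == "b2"])
    expect_equal(m1, m2, tolerance = 1e-10)
    expect_equal(sd(out$values[g, batch == "b1"]),
                 sd(out$values[g, batch == "b2"]), tolerance = 1e-10)
  }
  # single batch: identity
  em1 <- toy_matrix(m)
  expect_equal(batch_adjust(em1)$values, m)
  # batch of size 1: error
  bad <- expression_matrix(m, setNames(c("b1", rep("b2", 9)), colnames(m)),
                           setNames(rep("t", 10), colnames(m)))
  expect_error(batch_adjust(bad), "b1")
})

test_that("pure batch offsets are removed from a null cohort", {
  sp <- sim_spec(n_genes = 200, n_mirnas = 10, targets_per_mirna = 10,
                 effect_size = 0, batch_offsets = c(b1 = 0, b2 = 3),
                 seed = 5)
  sim <- simulate_expression(sp)
  out <- batch_adjust(sim$expression)
  diffs <- vapply(rownames(out$values), function(g) {
    mean(out$values[g, out$batch == "b1"]) -
      mean(out$values[g, out$batch == "b2"])
  }, 0)
  expect_lt(max(abs(diffs)), 1e-10)
})

test_that("change vector ranks by Welch t with deterministic ties", {
  m <- rbind(
    up   = c(5, 5.1, 4.9, 1, 1.1, 0.9),   # strongly up in case
    flat = c(3, 3.1, 2.9, 3, 3.1, 2.9),
    down = c(1, 1.1, 0.9, 5, 5.1, 4.9))
  colnames(m) <- paste0("s", 1:6)
  em <- expression_matrix(m, setNames(rep("b1", 6), colnames(m)),
                          setNames(rep(c("case", "ctrl"), each = 3),
                                   colnames(m)))
  cv <- rank_expression_changes(em, "case", "ctrl")
  expect_equal(cv$gene_id, c("up", "flat", "down"))
  # per-gene statistics agree with stats::t.test (independent route)
  for (g in rownames(m)) {
    expected <- t.test(m[g, 1:3], m[g, 4:6])$statistic
    expect_equal(cv$statistic[cv$gene_id == g], unname(expected),
                 tolerance = 1e-12)
  }
  # ties break by ascending gene id
  m2 <- rbind(b = c(1, 2, 1, 2), a = c(1, 2, 1, 2), c = c(1, 2, 1, 2))
  colnames(m2) <- paste0("s", 1:4)
  em2 <- expression_matrix(m2, setNames(rep("b1", 4), colnames(m2)),
                           setNames(rep(c("x", "y"), each = 2), colnames(m2)))
  cv2 <- rank_expression_changes(em2, "x", "y")
  expect_equal(cv2$gene_id, c("a", "b", "c"))
  expect_equal(cv2$statistic, c(0, 0, 0))
})

test_that("ranking is invariant to column order and per-gene constants", {
  set.seed(11)
  m <- matrix(rnorm(60, 8), 6, 10,
              dimnames = list(paste0("G", 1:6), paste0("s", 1:10)))
  phen <- setNames(rep(c("case", "ctrl"), each = 5), colnames(m))
  em <- expression_matrix(m, setNames(rep("b1", 10), colnames(m)), phen)
  cv <- rank_expression_changes(em, "case", "ctrl")
  shuf <- sample(colnames(m))
  em2 <- expression_matrix(m[, shuf], setNames(rep("b1", 10), shuf),
                           phen[shuf])
  expect_equal(rank_expression_changes(em2, "case", "ctrl"), cv)
  m3 <- m; m3["G3", ] <- m3["G3", ] + 100
  em3 <- expression_matrix(m3, setNames(rep("b1", 10), colnames(m)), phen)
  expect_equal(rank_expression_changes(em3, "case", "ctrl")$gene_id,
               cv$gene_id)
  # a condition with < 2 samples is rejected
  expect_error(rank_expression_changes(em, "case", "missing"),
               "fewer than 2")
})

test_that("change vectors serialize with their contrast metadata", {
  cv <- toy_change_vector(c("g1", "g2", "g3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_change_vector(cv, path)
  lines <- readLines(path)
  expect_match(lines[1], "case")
  tab <- read.delim(path, comment.char = "#")
  expect_equal(tab$gene_id, cv$gene_id)
})
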