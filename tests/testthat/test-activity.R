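test_that("activity score matches the closed-form running-sum examples", {
  cv <- toy_change_vector(paste0("g", 1:10))
  # targets at the top: running sum peaks at +2*sqrt(8/2) = +4, AS = -4
  expect_equal(as.numeric(activity_score(cv, c("g1", "g2"))), -4)
  # mirror: targets at the bottom
  expect_equal(as.numeric(activity_score(cv, c("g9", "g10"))), 4)
  # magnitude tie between -2 (rank 4) and +2 (rank 6): smallest rank wins
  expect_equal(as.numeric(activity_score(cv, c("g5", "g6"))), 2)
  expect_equal(attr(activity_score(cv, c("g1", "g2")), "m_used"), 2L)
})

test_that("activity score handles missing and degenerate target sets", {
  cv <- toy_change_vector(paste0("g", 1:10))
  expect_warning(s <- activity_score(cv, c("zz1", "zz2")), "skipped")
  expect_true(is.na(s))
  expect_error(activity_score(cv, paste0("g", 1:10)), "m = N")
  # genes absent from the vector are ignored, not counted
  s2 <- activity_score(cv, c("g1", "g2", "zz"))
  expect_equal(as.numeric(s2), -4)
  expect_equal(attr(s2, "m_used"), 2L)
})

test_that("activity score depends only on gene ranks, not magnitudes", {
  cv <- toy_change_vector(paste0("g", 1:20))
  cv2 <- cv
  cv2$statistic <- exp(cv$statistic / 3)  # different monotone scale
  for (tg in list(c("g1", "g5"), c("g3", "g9", "g17"), paste0("g", 15:19)))
    expect_equal(as.numeric(activity_score(cv, tg)),
                 as.numeric(activity_score(cv2, tg)))
})

test_that("reversing the change vector negates scores (up to magnitude ties)", {
  set.seed(42)
  genes <- paste0("g", sprintf("%03d", 1:100))
  cv <- toy_change_vector(genes)
  cv_rev <- toy_change_vector(rev(genes))
  flipped <- 0
  for (rep in 1:50) {
    tg <- sample(genes, sample(3:20, 1))
    a <- as.numeric(activity_score(cv, tg))
    b <- as.numeric(activity_score(cv_rev, tg))
    expect_equal(abs(a), abs(b), tolerance = 1e-12)
    if (isTRUE(all.equal(b, -a))) flipped <- flipped + 1
  }
  # sign flips except in the rare exact magnitude-tie configuration
  expect_gte(flipped, 45)
})

test_that("permutation null is reproducible and centered under the null", {
  sp <- sim_spec(n_genes = 300, n_mirnas = 15, targets_per_mirna = 15,
                 n_case = 8, n_comparator = 8, effect_size = 0, seed = 3)
  sim <- simulate_expression(sp)
  n1 <- permutation_null(sim$expression, "tumor", "normal", sim$targets,
                         K = 200, seed = 99)
  n2 <- permutation_null(sim$expression, "tumor", "normal", sim$targets,
                         K = 200, seed = 99)
  expect_identical(n1$ns, n2$ns)
  expect_equal(dim(n1$ns), c(15L, 200L))
  # running-sum statistic is symmetric under random placement
  mc_se <- apply(n1$ns, 1, sd) / sqrt(200)
  expect_true(all(abs(rowMeans(n1$ns)) < 4 * mc_se + 0.05))
})

test_that("empirical p-values follow the pseudocounted two-sided definition", {
  expect_equal(empirical_p(5, c(0, 0, 0)), 1 / 4)
  expect_equal(empirical_p(0, c(0.5, -1, 2)), 1)
  expect_equal(empirical_p(2, c(-3, 1, 2, -1)), 3 / 5)
})

test_that("FDR ratio matches its worked examples and stays in [0, 1]", {
  ns <- rbind(c(1, -1), c(0.5, -0.5))
  expect_equal(estimate_fdr(c(2, 1), ns, 1), 0.5)
  expect_equal(estimate_fdr(c(2, 1), ns, 2), 0)
  # null identical to observed (single identity permutation): FDR = 1
  as_obs <- c(0.5, 1.5, -2)
  expect_equal(estimate_fdr(as_obs, matrix(as_obs, ncol = 1), 0.5), 1)
  # empty relevant side is conservative
  expect_warning(f <- estimate_fdr(c(1, 2), matrix(c(1, 2), 2), -1),
                 "returning 1")
  expect_equal(f, 1)
})

test_that("FDR ratio agrees with brute-force enumeration on random instances", {
  set.seed(123)
  for (i in 1:100) {
    nx <- sample(2:10, 1); nk <- sample(1:20, 1)
    as_scores <- round(rnorm(nx), 2)
    ns <- matrix(round(rnorm(nx * nk), 2), nx, nk)
    as_star <- sample(c(as_scores, round(rnorm(1), 2)), 1)
    expect_equal(suppressWarnings(estimate_fdr(as_scores, ns, as_star)),
                 suppressWarnings(brute_fdr(as_scores, ns, as_star)),
                 tolerance = 1e-12)
  }
})

test_that("deregulation calls apply thresholds and sort by |AS|", {
  res <- data.frame(mirna_id = c("m1", "m2", "m3", "m4"),
                    as_score = c(3, -5, 2, -1),
                    p_value = c(0.001, 0.002, 0.5, 0.001),
                    fdr = c(0.005, 0.002, 0.001, 0.2))
  calls <- call_deregulated(res, 0.005, 0.01)
  expect_equal(calls$activated, "m1")
  expect_equal(calls$silenced, "m2")
  allp1 <- res; allp1$p_value <- 1
  expect_equal(call_deregulated(allp1, 0.005, 0.01),
               list(activated = character(0), silenced = character(0)))
  expect_error(call_deregulated(res, 0, 0.01), "thresholds")
})

test_that("tightening the FDR threshold can only shrink the call lists", {
  sp <- sim_spec(n_genes = 500, n_mirnas = 30, targets_per_mirna = 20,
                 n_case = 10, n_comparator = 10, n_activated = 3,
                 n_silenced = 3, seed = 21)
  sim <- simulate_expression(sp)
  res <- mirna_activity(sim$expression, "tumor", "normal", sim$targets,
                        K = 100, seed = 22, fdr_threshold = 0.05)
  strict <- call_deregulated(res, 0.05, 0.01)
  loose <- call_deregulated(res, 0.05, 0.05)
  expect_true(all(strict$activated %in% loose$activated))
  expect_true(all(strict$silenced %in% loose$silenced))
})

test_that("activity and null tables serialize with provenance", {
  sp <- sim_spec(n_genes = 200, n_mirnas = 8, targets_per_mirna = 10,
                 n_case = 5, n_comparator = 5, seed = 31)
  sim <- simulate_expression(sp)
  res <- mirna_activity(sim$expression, "tumor", "normal", sim$targets,
                        K = 50, seed = 32)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(res, path)
  expect_match(readLines(path, n = 1), "seed=32")
  tab <- read.delim(path, comment.char = "#")
  expect_equal(tab$mirna_id, res$mirna_id)
  npath <- withr::local_tempfile(fileext = ".tsv")
  write_null_scores(attr(res, "null"), npath)
  ntab <- read.delim(npath, comment.char = "#")
  expect_equal(dim(ntab), c(8L, 51L))
})
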