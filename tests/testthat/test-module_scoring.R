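test_that("gene binning splits ranked means into balanced bins", {
  m <- toy_lognorm(rep(c(0, 1, 2, 3), each = 3), 3, 4)
  bins <- bin_genes(m, 2)
  expect_identical(unname(bins), c(1L, 1L, 2L, 2L))

  # all-equal means: any balanced assignment, sizes differ by <= 1
  eqm <- toy_lognorm(1, 4, 7)
  b2 <- bin_genes(eqm, 3)
  expect_lte(diff(range(table(b2))), 1L)

  # 1000 random genes: balance and monotone bin means
  set.seed(31)
  big <- toy_lognorm(runif(20 * 1000), 20, 1000)
  b3 <- bin_genes(big, 24)
  expect_lte(diff(range(table(b3))), 1L)
  means <- Matrix::colMeans(big$counts)
  bin_means <- tapply(means, b3, mean)
  expect_true(all(diff(bin_means) > 0))

  expect_error(bin_genes(eqm, 100), "exceeds")
  expect_error(bin_genes(count_matrix(matrix(1, 2, 2,
    dimnames = list(c("a", "b"), c("g1", "g2")))), 1), "lognorm")
})

test_that("score is exactly zero when controls match the program by construction", {
  # every gene constant at the same value: program mean == control mean
  m <- toy_lognorm(2.5, 6, 30)
  sc <- score_program(m, c("g01", "g02"), n_bins = 1, n_ctrl_per_gene = 28,
                      seed = 4)
  expect_equal(sc$score, rep(0, 6))
})

test_that("a printed toy score equals the hand-computed mean difference", {
  # 6 genes x 3 cells; n_bins = 1 and n_ctrl = all non-program genes makes
  # the control pool deterministic: the score is mean(prog) - mean(others)
  vals <- matrix(c(1, 2, 3,
                   2, 4, 6,
                   0, 1, 0,
                   1, 1, 1,
                   5, 3, 2,
                   2, 2, 4), nrow = 3, ncol = 6,
                 dimnames = list(c("c1", "c2", "c3"), sprintf("g%02d", 1:6)))
  m <- count_matrix(vals, layer = "lognorm")
  sc <- score_program(m, c("g01", "g02"), n_bins = 1, n_ctrl_per_gene = 4,
                      seed = 1)
  hand <- rowMeans(vals[, 1:2]) - rowMeans(vals[, 3:6])
  expect_equal(sc$score, unname(hand), tolerance = 1e-15)
})

test_that("scores are invariant to adding a constant to the matrix", {
  set.seed(12)
  base <- matrix(runif(15 * 40, 0, 4), 15, 40,
                 dimnames = list(sprintf("c%02d", 1:15),
                                 sprintf("g%02d", 1:40)))
  m1 <- count_matrix(base, layer = "lognorm")
  m2 <- count_matrix(base + 7.3, layer = "lognorm")
  s1 <- score_program(m1, c("g03", "g17"), n_bins = 4, n_ctrl_per_gene = 5,
                      seed = 2)
  s2 <- score_program(m2, c("g03", "g17"), n_bins = 4, n_ctrl_per_gene = 5,
                      seed = 2)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("score_program matches the naive dense reimplementation exactly", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(10:50, 1); g <- sample(20:50, 1)
    mat <- matrix(round(runif(n * g, 0, 5), 3), n, g,
                  dimnames = list(sprintf("c%03d", seq_len(n)),
                                  sprintf("g%03d", seq_len(g))))
    genes <- sample(colnames(mat), 4)
    m <- count_matrix(mat, layer = "lognorm")
    got <- suppressWarnings(
      score_program(m, genes, n_bins = 5, n_ctrl_per_gene = 3, seed = s))
    want <- suppressWarnings(oracle_score(mat, genes, 5, 3, seed = s))
    expect_equal(got$score, want, tolerance = 1e-12)
  }
})

test_that("scoring guards its preconditions", {
  m <- toy_lognorm(1, 3, 10)
  expect_error(score_program(m, c("nope1", "nope2"), n_bins = 2,
                             n_ctrl_per_gene = 2), "none of the program genes")
  expect_warning(score_program(m, c("g01", "nope"), n_bins = 2,
                               n_ctrl_per_gene = 2, seed = 1), "dropped")
  raw <- random_counts(3, 10, seed = 1)
  expect_error(score_program(raw, "g0001", n_bins = 2, n_ctrl_per_gene = 2),
               "lognorm")
  # undersized bin falls back to replacement with a warning
  expect_warning(score_program(m, "g01", n_bins = 2, n_ctrl_per_gene = 50,
                               seed = 1), "replacement")
})

test_that("the default calling rule separates a strong program nearly perfectly", {
  sim <- simulate_expression(expression_sim_spec(
    n_cells = 1200, n_genes = 800, n_program_genes = 40,
    program_log2fc = 2, program_fraction = 0.05, seed = 21))
  norm <- normalize_counts(sim$matrix, norm_dialect("visium"))
  sc <- suppressWarnings(
    score_program(norm, sim$program_genes, seed = 1, program_name = "ISG"))
  calls <- call_isgt(sc, sim$cells, rule = "sd:3")
  truth <- merge(calls, sim$cells, by = "cell_id")
  tpos <- truth[truth$is_T & truth$truth_is_program_positive, ]
  tneg <- truth[truth$is_T & !truth$truth_is_program_positive, ]
  expect_gte(mean(tpos$is_isgt), 0.9)   # sensitivity
  expect_gte(mean(!tneg$is_isgt), 0.9)  # specificity
})

test_that("degenerate calling rules behave as documented", {
  scores <- data.frame(cell_id = sprintf("c%d", 1:6), program = "ISG",
                       score = rep(1.5, 6))
  cells <- data.frame(cell_id = sprintf("c%d", 1:6),
                      sample_id = "s1", is_T = rep(c(TRUE, FALSE), 3))
  expect_false(any(call_isgt(scores, cells, "sd:3")$is_isgt))
  expect_true(all(call_isgt(scores, cells, "abs:-Inf")$is_isgt))
  expect_error(call_isgt(scores, cells, "nonsense"), "rule")
})

test_that("per-sample ISG-T frequencies handle counts and missing T cells", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:16),
    sample_id = rep(c("s1", "s2"), c(14, 2)),
    is_T = c(rep(TRUE, 12), FALSE, FALSE, FALSE, FALSE))
  calls <- data.frame(cell_id = cells$cell_id,
                      is_isgt = c(rep(TRUE, 3), rep(FALSE, 13)))
  fr <- isgt_frequency(calls, cells)
  expect_equal(fr$frequency[fr$sample_id == "s1"], 0.25)  # 3 of 12 T cells
  expect_true(is.na(fr$frequency[fr$sample_id == "s2"]))  # zero T cells
  expect_identical(fr$n_T, c(12L, 0L))
})

test_that("estimated cohort frequency recovers the simulated truth fraction", {
  freqs <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_expression(expression_sim_spec(
      n_cells = 500, n_genes = 500, n_program_genes = 40,
      program_log2fc = 2, program_fraction = 0.05, seed = 500 + s),
      sample_id = sprintf("s%02d", s))
    norm <- normalize_counts(sim$matrix, norm_dialect("visium"))
    sc <- suppressWarnings(
      score_program(norm, sim$program_genes, seed = 1))
    fr <- isgt_frequency(call_isgt(sc, sim$cells), sim$cells)
    freqs[s] <- fr$frequency
  }
  expect_lt(abs(mean(freqs) - 0.05), 0.03)
})

test_that("mean program score rises strictly with the simulated fold change", {
  mean_pos_score <- function(log2fc, seed = 77) {
    sim <- simulate_expression(expression_sim_spec(
      n_cells = 600, n_genes = 500, n_program_genes = 40,
      program_log2fc = log2fc, program_fraction = 0.1, seed = seed))
    norm <- normalize_counts(sim$matrix, norm_dialect("visium"))
    sc <- suppressWarnings(score_program(norm, sim$program_genes, seed = 1))
    mean(sc$score[sim$cells$truth_is_program_positive])
  }
  ms <- vapply(c(0, 0.5, 1, 2), mean_pos_score, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("the program-vs-rest contrast is robust to the control-gene seed", {
  sim <- simulate_expression(expression_sim_spec(
    n_cells = 800, n_genes = 600, n_program_genes = 40,
    program_log2fc = 1, program_fraction = 0.1, seed = 13))
  norm <- normalize_counts(sim$matrix, norm_dialect("visium"))
  pos <- sim$cells$truth_is_program_positive
  for (s in 1:10) {
    sc <- suppressWarnings(score_program(norm, sim$program_genes, seed = s))
    p <- wilcox.test(sc$score[pos], sc$score[!pos])$p.value
    expect_lt(p, 1e-6)
  }
})
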