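test_that("hand-placed geometries give the forced distances", {
  inst <- make_map(c(0, 3, 10), c(0, 4, 0), c("other", "focal", "focal"))
  rec <- nearest_focal_distances(inst$map, inst$cells, "focal")
  expect_equal(rec$d_min_um, 5.0)    # 3-4-5 triangle

  co <- make_map(c(1, 1), c(2, 2), c("other", "focal"))
  expect_equal(nearest_focal_distances(co$map, co$cells, "focal")$d_min_um, 0)
})

test_that("distances equal the brute-force double loop", {
  inst <- random_instance(1000, 50, seed = 55)
  rec <- nearest_focal_distances(inst$map, inst$cells, "focal")
  is_f <- inst$cells$cell_type == "focal"
  want <- oracle_nearest(inst$map$x_um[!is_f], inst$map$y_um[!is_f],
                         inst$map$x_um[is_f], inst$map$y_um[is_f])
  expect_equal(rec$d_min_um, want, tolerance = 1e-9)
})

test_that("samples are isolated and focal-free samples are skipped", {
  a <- random_instance(50, 5, seed = 1, sample_id = "sA")
  b <- random_instance(40, 4, seed = 2, sample_id = "sB")
  nofocal <- make_map(c(1, 2), c(1, 2), c("other", "other"), sample_id = "sC")

  rec_a <- nearest_focal_distances(a$map, a$cells, "focal")
  both <- nearest_focal_distances(rbind(a$map, b$map, nofocal$map),
                                  rbind(a$cells, b$cells, nofocal$cells),
                                  "focal")
  sub_a <- both[both$sample_id == "sA", ]
  expect_equal(sub_a$d_min_um[match(rec_a$cell_id, sub_a$cell_id)],
               rec_a$d_min_um)
  expect_identical(attr(both, "skipped_samples"), "sC")
  expect_false("sC" %in% both$sample_id)

  expect_error(nearest_focal_distances(nofocal$map, nofocal$cells, "focal"),
               "absent from every sample")
})

test_that("distances are equivariant to scaling and invariant to rigid motion", {
  inst <- random_instance(200, 20, seed = 77)
  base <- nearest_focal_distances(inst$map, inst$cells, "focal")

  sc <- inst; sc$map$x_um <- sc$map$x_um * 2.5; sc$map$y_um <- sc$map$y_um * 2.5
  rec_sc <- nearest_focal_distances(sc$map, sc$cells, "focal")
  expect_equal(rec_sc$d_min_um, base$d_min_um * 2.5, tolerance = 1e-12)

  th <- 0.9
  rot <- inst
  rot$map$x_um <- cos(th) * inst$map$x_um - sin(th) * inst$map$y_um + 500
  rot$map$y_um <- sin(th) * inst$map$x_um + cos(th) * inst$map$y_um - 120
  rec_rot <- nearest_focal_distances(rot$map, rot$cells, "focal")
  expect_equal(rec_rot$d_min_um, base$d_min_um, tolerance = 1e-9)
})

test_that("median aggregation matches forced arithmetic and a brute-force recount", {
  rec <- data.frame(cell_id = sprintf("c%d", 1:4),
                    sample_id = c("s1", "s1", "s1", "s2"),
                    cell_type = "pDC", lineage = "non_lymphocyte",
                    condition = NA, d_min_um = c(1, 1, 9, 3))
  pooled <- median_distance_by_type(rec, "pooled_cells")
  expect_equal(pooled$median_um, 2)      # median of {1,1,9,3}
  mosm <- median_distance_by_type(rec, "median_of_sample_medians")
  expect_equal(mosm$median_um, 2)        # median of {1, 3}

  one <- rec[1:3, ]; one$d_min_um <- c(1, 2, 3)
  expect_equal(median_distance_by_type(one, "pooled_cells")$median_um, 2)

  # random records against scalar recomputation
  set.seed(91)
  rr <- data.frame(cell_id = sprintf("c%03d", 1:120),
                   sample_id = sample(c("s1", "s2", "s3"), 120, TRUE),
                   cell_type = sample(c("PT", "EC", "MAC"), 120, TRUE),
                   lineage = "non_lymphocyte", condition = NA,
                   d_min_um = runif(120, 0, 300))
  got_p <- median_distance_by_type(rr, "pooled_cells")
  got_m <- median_distance_by_type(rr, "median_of_sample_medians")
  for (ty in unique(rr$cell_type)) {
    v <- rr$d_min_um[rr$cell_type == ty]
    expect_equal(got_p$median_um[got_p$cell_type == ty], median(v))
    sm <- vapply(split(rr$d_min_um[rr$cell_type == ty],
                       rr$sample_id[rr$cell_type == ty]), median, 1)
    expect_equal(got_m$median_um[got_m$cell_type == ty], median(sm))
  }
})

test_that("neighbour ranking orders types within lineage and reports ties", {
  med <- data.frame(cell_type = c("pDC", "PT", "Tn", "B"),
                    lineage = c("non_lymphocyte", "non_lymphocyte",
                                "lymphocyte", "lymphocyte"),
                    median_um = c(10, 40, 25, 25), n_cells = c(5, 5, 5, 5))
  net <- rank_neighbors(med, "ISG-T")
  nodes <- net$nodes
  nl <- nodes[nodes$lineage == "non_lymphocyte", ]
  expect_identical(nl$cell_type[nl$rank == 1L], "pDC")
  expect_false(any(nl$tied))
  ly <- nodes[nodes$lineage == "lymphocyte", ]
  expect_identical(ly$cell_type, c("B", "Tn"))  # tie broken by name
  expect_true(all(ly$tied))
  # ranks are a permutation within each class
  expect_identical(sort(nl$rank), seq_len(nrow(nl)))
  expect_identical(sort(ly$rank), seq_len(nrow(ly)))
})

test_that("clustered cohorts put the parent type at rank 1", {
  specs <- list(disease = tissue_sim_spec(attraction_sigma_um = 30))
  co <- simulate_cohort(specs, n_samples_per_condition = 10, base_seed = 40)
  rec <- nearest_focal_distances(co$map, co$cells, "ISG-T")
  rank1 <- 0L
  for (s in unique(rec$sample_id)) {
    med <- median_distance_by_type(rec[rec$sample_id == s, ], "pooled_cells")
    net <- rank_neighbors(med, "ISG-T")
    nl <- net$nodes[net$nodes$lineage == "non_lymphocyte", ]
    if (nl$cell_type[nl$rank == 1L] == "pDC") rank1 <- rank1 + 1L
  }
  expect_gte(rank1, 9L)
})

test_that("condition comparisons match the closed-form test statistics", {
  # three forced groups
  rec <- data.frame(cell_id = sprintf("c%d", 1:9),
                    sample_id = "s", cell_type = "pDC",
                    lineage = "non_lymphocyte",
                    condition = rep(c("a", "b", "c"), each = 3),
                    d_min_um = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  cmp <- compare_conditions(rec, "pDC", "anova_tukey")
  want <- oracle_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(cmp$statistic, want$F, tolerance = 1e-10)
  expect_equal(cmp$p_value, want$p, tolerance = 1e-10)
  for (i in seq_len(nrow(cmp$pairwise))) {
    pair <- strsplit(cmp$pairwise$comparison[i], "-")[[1]]
    g <- split(rec$d_min_um, rec$condition)
    expect_equal(cmp$pairwise$p_adj[i],
                 oracle_tukey_p(mean(g[[pair[1]]]), mean(g[[pair[2]]]),
                                3, 3, want$mse, 3, want$df),
                 tolerance = 1e-8)
  }

  # two identical groups: F = 0 and Tukey p -> 1
  same <- data.frame(cell_id = sprintf("c%d", 1:6), sample_id = "s",
                     cell_type = "pDC", lineage = "non_lymphocyte",
                     condition = rep(c("a", "b"), each = 3),
                     d_min_um = c(2, 5, 9, 2, 5, 9))
  cmp0 <- compare_conditions(same, "pDC", "anova_tukey")
  expect_equal(cmp0$statistic, 0, tolerance = 1e-12)
  expect_equal(min(cmp0$pairwise$p_adj), 1, tolerance = 1e-9)
})

test_that("two-group tests agree with enumeration and closed forms", {
  rec <- data.frame(cell_id = sprintf("c%d", 1:9),
                    sample_id = "s", cell_type = "pDC", lineage = "other",
                    condition = rep(c("ctl", "dis"), c(4, 5)),
                    d_min_um = c(12.1, 15.3, 9.8, 20.2, 3.1, 5.7, 2.2, 7.9, 4.4))
  a <- rec$d_min_um[1:4]; b <- rec$d_min_um[5:9]

  mw <- compare_conditions(rec, "pDC", "mann_whitney")
  expect_equal(mw$p_value, oracle_ranksum(a, b), tolerance = 1e-10)
  wx <- compare_conditions(rec, "pDC", "wilcoxon")
  expect_equal(wx$p_value, mw$p_value)

  wt <- compare_conditions(rec, "pDC", "welch_t")
  want <- oracle_welch(a, b)
  expect_equal(wt$statistic, want$t, tolerance = 1e-10)
  expect_equal(wt$p_value, want$p, tolerance = 1e-10)

  expect_error(compare_conditions(rec[1:5, ], "pDC", "welch_t"), ">= 2")
})

test_that("degenerate zero-variance groups report a missing p with reason", {
  rec <- data.frame(cell_id = sprintf("c%d", 1:6), sample_id = "s",
                    cell_type = "pDC", lineage = "other",
                    condition = rep(c("a", "b"), each = 3),
                    d_min_um = rep(4, 6))
  cmp <- compare_conditions(rec, "pDC", "anova_tukey")
  expect_true(is.na(cmp$p_value))
  expect_match(cmp$reason, "zero variance")
})

test_that("pearson wrapper matches the closed form and the exact-line case", {
  x <- c(1, 2, 3, 4, 5)
  exact <- pearson_test(x, 2 * x + 1)
  expect_equal(exact$r, 1)

  set.seed(8)
  u <- rnorm(20); v <- 0.6 * u + rnorm(20)
  got <- pearson_test(u, v)
  want <- oracle_pearson(u, v)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
})

test_that("network serialization and plotting run cleanly", {
  med <- data.frame(cell_type = c("pDC", "PT"), lineage = "non_lymphocyte",
                    median_um = c(10, 40), n_cells = c(4, 4))
  net <- rank_neighbors(med, "ISG-T")
  path <- withr::local_tempfile(fileext = ".json")
  write_proximity_network(net, path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(payload$focal_type, "ISG-T")
  expect_identical(payload$nodes$cell_type, c("pDC", "PT"))
  pdf(NULL)
  expect_silent(plot(net))
  dev.off()
})
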