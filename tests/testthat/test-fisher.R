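test_that("build_contingency performs exact set algebra", {
  tab <- build_contingency(as.character(1:3), as.character(2:4),
                           as.character(1:10))
  expect_equal(tab[c("a", "b", "c", "d")],
               list(a = 2L, b = 1L, c = 1L, d = 6L))
  expect_equal(tab$universe_size, 10L)

  disjoint <- build_contingency(c("1", "2"), c("3", "4"),
                                as.character(1:10))
  expect_equal(disjoint$a, 0L)

  sat <- build_contingency(as.character(1:5), as.character(1:5),
                           as.character(1:5))
  expect_equal(sat[c("a", "b", "c", "d")],
               list(a = 5L, b = 0L, c = 0L, d = 0L))

  # inputs are intersected with the universe first
  clipped <- build_contingency(c("1", "99"), c("1", "98"),
                               as.character(1:10))
  expect_equal(clipped$a + clipped$b + clipped$c + clipped$d, 10L)

  expect_error(build_contingency("1", "2", character(0)),
               class = "ct_error_config")
})

test_that("fisher_greater returns exactly 1 for zero overlap", {
  tab <- build_contingency(c("1", "2"), c("3", "4"), as.character(1:10))
  expect_identical(fisher_greater(tab), 1)
})

test_that("fisher_greater equals enumeration on the worked 5/5/5/85 table", {
  tab <- structure(list(a = 5L, b = 5L, c = 5L, d = 85L,
                        universe_size = 100L), class = "contingency_table")
  expect_equal(fisher_greater(tab), oracle_hyper_tail(5, 5, 5, 85),
               tolerance = 1e-12)
})

test_that("fisher_greater agrees with stats::fisher.test on random tables", {
  set.seed(31)
  for (rep in 1:50) {
    cells <- as.integer(rmultinom(1, sample(20:200, 1), rep(1, 4)))
    tab <- structure(list(a = cells[1], b = cells[2], c = cells[3],
                          d = cells[4], universe_size = sum(cells)),
                     class = "contingency_table")
    ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(fisher_greater(tab), ft$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_greater is monotone in the overlap at fixed margins", {
  # margins: 10 markers, 15 set genes, universe 60
  for (a in 0:9) {
    t1 <- structure(list(a = a, b = 10 - a, c = 15 - a, d = 35 + a,
                         universe_size = 60L), class = "contingency_table")
    t2 <- structure(list(a = a + 1, b = 9 - a, c = 14 - a, d = 36 + a,
                         universe_size = 60L), class = "contingency_table")
    expect_gte(fisher_greater(t1), fisher_greater(t2))
  }
})

test_that("bh_adjust reproduces hand-applied step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.5)), class = "ct_error_config")
  expect_error(bh_adjust(c(0.1, -0.2)), class = "ct_error_config")
})

test_that("fisher_per_cluster ranks the matching cell type first", {
  rl <- make_ranked(sprintf("g%02d", 1:10), seq(10, 1))
  recs <- data.frame(
    tissue = "blood",
    cell_type = rep(c("match", "decoy"), each = 10),
    gene = c(rl$genes, paste0("x", 1:10)),
    stringsAsFactors = FALSE)
  gsc <- gene_set_collection(recs)
  res <- fisher_per_cluster(rl, gsc)
  expect_equal(res$cell_type[res$rank == 1], "match")
  expect_lt(res$pvalue[res$cell_type == "match"],
            res$pvalue[res$cell_type == "decoy"])
})

test_that("identical gene sets tie and break by cell type name", {
  rl <- make_ranked(sprintf("g%02d", 1:10), seq(10, 1))
  recs <- data.frame(
    tissue = "blood",
    cell_type = rep(c("zeta", "alpha"), each = 5),
    gene = rep(rl$genes[1:5], 2),
    stringsAsFactors = FALSE)
  gsc <- gene_set_collection(recs)
  res <- fisher_per_cluster(rl, gsc)
  expect_equal(res$pvalue[1], res$pvalue[2])
  expect_equal(res$cell_type, c("alpha", "zeta"))
})

test_that("fisher ordering agrees with an independent recomputation", {
  set.seed(77)
  for (rep in 1:10) {
    sc <- synthetic_scenario(n_cell_types = 5, marker_overlap_frac = 0.3,
                             noise_frac = 0.4, seed = rep)
    truth <- simulate_truth(sc)
    rl <- build_ranked_list(truth$marker_table, "2")
    res <- fisher_per_cluster(rl, truth$database)
    # recompute p and padj from scratch and re-sort with the documented keys
    universe <- union(collection_universe(truth$database), rl$genes)
    p_ind <- vapply(res$cell_type, function(ct) {
      oracle_hyper_tail_from_sets(rl$genes, truth$database$sets[[ct]],
                                  universe)
    }, numeric(1))
    expect_equal(res$pvalue, unname(p_ind), tolerance = 1e-10)
    expect_equal(res$padj, oracle_bh(res$pvalue), tolerance = 1e-12)
    ord <- order(res$padj, -res$overlap_score, -res$a, res$cell_type,
                 method = "radix")
    expect_equal(ord, seq_len(nrow(res)))
  }
})

test_that("the overlap score is the mean expression score of overlapping markers", {
  rl <- make_ranked(c("a", "b", "c"), c(3, 2, 1))
  gsc <- gene_set_collection(data.frame(
    tissue = "blood", cell_type = "ct", gene = c("a", "c", "zz"),
    stringsAsFactors = FALSE))
  res <- fisher_per_cluster(rl, gsc)
  expect_equal(res$overlap_score, mean(c(3, 1)))
})
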