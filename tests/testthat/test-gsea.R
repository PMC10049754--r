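ranked10 <- make_ranked(sprintf("g%02d", 1:10), seq(10, 1))

test_that("a set containing only the top-ranked gene reaches ES = 1", {
  es <- enrichment_score(ranked10, "g01")
  expect_identical(es$ES, 1)
  expect_equal(es$peak, 1L)
  expect_equal(es$set_size_used, 1L)
})

test_that("a set containing only the bottom-ranked gene reaches ES = -1", {
  # nine misses of 1/(N - N_H) = 1/9 each accumulate to -1 at position 9
  es <- enrichment_score(ranked10, "g10")
  expect_equal(es$ES, -1)
  expect_equal(es$peak, 9L)
  oracle <- oracle_enrichment_score(ranked10$genes, ranked10$scores, "g10")
  expect_equal(es$ES, oracle$ES)
})

test_that("the running sum starts at position 1 and returns to zero", {
  es <- enrichment_score(ranked10, c("g03", "g07"))
  expect_length(es$running_sum, 10)
  expect_lt(abs(es$running_sum[10]), 1e-9)
})

test_that("vectorized ES matches the naive double-loop oracle on random instances", {
  set.seed(101)
  for (rep in 1:200) {
    N <- sample(5:50, 1)
    genes <- sprintf("g%03d", sample(500, N))
    scores <- rnorm(N)
    rl <- make_ranked(genes, scores)
    set <- sample(genes, sample(1:min(10, N - 1), 1))
    p <- sample(c(0, 0.5, 1, 2), 1)
    es <- enrichment_score(rl, set, weight_exponent = p)
    oracle <- oracle_enrichment_score(rl$genes, rl$scores, set, p = p)
    expect_equal(es$ES, oracle$ES, tolerance = 1e-12)
    expect_equal(es$running_sum, oracle$running_sum, tolerance = 1e-12)
    expect_lte(abs(es$ES), 1)
    expect_lt(abs(es$running_sum[N]), 1e-9)
  }
})

test_that("ES is invariant to positive rescaling of scores at weight 1", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:30)
  scores <- runif(30, 0.1, 4)
  rl <- make_ranked(genes, scores)
  rl_scaled <- make_ranked(genes, scores * 37.5)
  set <- sample(genes, 6)
  expect_equal(enrichment_score(rl, set)$ES,
               enrichment_score(rl_scaled, set)$ES, tolerance = 1e-12)
})

test_that("all-zero member scores fall back to the unweighted statistic", {
  rl <- make_ranked(sprintf("g%02d", 1:6), c(3, 2, 1, 0, 0, 0))
  es <- enrichment_score(rl, c("g04", "g05"))
  oracle <- oracle_enrichment_score(rl$genes, rl$scores, c("g04", "g05"),
                                    p = 0)
  expect_equal(es$ES, oracle$ES)
})

test_that("an empty intersection yields the set-skipped signal, full coverage errors", {
  expect_null(enrichment_score(ranked10, c("x1", "x2")))
  expect_error(enrichment_score(ranked10, ranked10$genes),
               class = "ct_error_config")
})

test_that("the permutation null is reproducible and bounded", {
  cfg <- gsea_config(nperm = 200, seed = 99)
  n1 <- permutation_null(ranked10, 3, cfg)
  n2 <- permutation_null(ranked10, 3, cfg)
  expect_identical(n1, n2)
  expect_length(n1, 200)
  expect_true(all(abs(n1) <= 1))

  # boundary set size N - 1
  nb <- permutation_null(ranked10, 9, cfg)
  expect_true(all(is.finite(nb)) && all(abs(nb) <= 1))
  expect_error(permutation_null(ranked10, 10, cfg),
               class = "ct_error_config")
})

test_that("null ES over symmetric random scores is centred at zero", {
  # averaged over score draws as well as set draws: for a single fixed
  # ranked list the weighted null need not be centred, but marginally over
  # symmetric scores the ES distribution is symmetric
  set.seed(17)
  genes <- sprintf("g%03d", 1:40)
  es_vals <- vapply(1:2000, function(b) {
    rl <- make_ranked(genes, rnorm(40))
    enrichment_score(rl, sample(genes, 8))$ES
  }, numeric(1))
  se <- sd(es_vals) / sqrt(length(es_vals))
  expect_lt(abs(mean(es_vals)), 3 * se)

  # with the unweighted statistic the null is symmetric even conditionally
  # on one ranked list
  rl <- make_ranked(genes, rnorm(40))
  null0 <- permutation_null(rl, 8, gsea_config(weight_exponent = 0,
                                               nperm = 2000, seed = 4))
  se0 <- sd(null0) / sqrt(length(null0))
  expect_lt(abs(mean(null0)), 3 * se0)
})

test_that("the permutation null leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(permutation_null(ranked10, 3, gsea_config(nperm = 100, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("gsea_per_cluster ranks a genuinely enriched set first", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:50)
  rl <- make_ranked(genes, seq(50, 1))
  recs <- data.frame(
    tissue = "blood",
    cell_type = rep(c("true_type", "decoy"), each = 5),
    gene = c(rl$genes[1:5], rl$genes[46:50]),
    stringsAsFactors = FALSE)
  gsc <- gene_set_collection(recs)
  res <- gsea_per_cluster(rl, gsc, gsea_config(nperm = 1000, seed = 7))
  expect_equal(res$cell_type[res$rank == 1], "true_type")
  expect_lt(res$pvalue[res$cell_type == "true_type"],
            res$pvalue[res$cell_type == "decoy"])
})

test_that("with a single candidate set padj equals the raw p", {
  rl <- make_ranked(sprintf("g%02d", 1:20), seq(20, 1))
  gsc <- gene_set_collection(data.frame(
    tissue = "blood", cell_type = "only", gene = rl$genes[1:4],
    stringsAsFactors = FALSE))
  res <- gsea_per_cluster(rl, gsc, gsea_config(nperm = 200, seed = 2))
  expect_equal(res$padj, res$pvalue)
})

test_that("permutation p-values respect the 1/(nperm+1) floor and padj >= p", {
  sc <- synthetic_scenario(n_cell_types = 4, marker_overlap_frac = 0.3,
                           seed = 21)
  truth <- simulate_truth(sc)
  rep_g <- annotate_clusters(truth$marker_table, truth$database,
                             test = "gsea",
                             config = gsea_config(nperm = 100, seed = 21))
  res <- rep_g$results
  expect_true(all(res$pvalue >= 1 / 101))
  expect_true(all(res$padj >= res$pvalue))
})

test_that("score_type pos ranks negatively enriched sets after positive ones", {
  rl <- make_ranked(sprintf("g%02d", 1:30), seq(30, 1))
  recs <- data.frame(
    tissue = "blood",
    cell_type = rep(c("bottom_set", "top_set"), each = 4),
    gene = c(rl$genes[27:30], rl$genes[1:4]),
    stringsAsFactors = FALSE)
  gsc <- gene_set_collection(recs)
  res_pos <- gsea_per_cluster(rl, gsc, gsea_config(nperm = 200, seed = 5,
                                                   score_type = "pos"))
  # the bottom set has strongly negative ES; under pos it must rank last
  expect_equal(res_pos$cell_type[res_pos$rank == nrow(res_pos)], "bottom_set")
  expect_lt(res_pos$ES[res_pos$cell_type == "bottom_set"], 0)
})

test_that("candidates outside the set-size bounds yield an empty result with a warning", {
  # a singleton set falls below the default min_set_size of 2
  gsc <- gene_set_collection(data.frame(
    tissue = "blood", cell_type = "singleton", gene = "g01",
    stringsAsFactors = FALSE))
  expect_warning(res <- gsea_per_cluster(ranked10, gsc, gsea_config()),
                 "no candidate")
  expect_equal(nrow(res), 0)
})

test_that("database genes absent from the marker list pad the walk at score 0", {
  # the full marker list lies inside the candidate set: without padding the
  # walk would have no non-member genes and the candidate would be skipped
  gsc <- gene_set_collection(data.frame(
    tissue = "blood",
    cell_type = rep(c("covering", "other"), c(12, 5)),
    gene = c(ranked10$genes, paste0("z", 1:2), paste0("y", 1:5)),
    stringsAsFactors = FALSE))
  res <- gsea_per_cluster(ranked10, gsc, gsea_config(nperm = 200, seed = 3))
  expect_equal(res$cell_type[res$rank == 1], "covering")
  expect_equal(res$ES[res$cell_type == "covering"], 1)
  expect_equal(res$set_size_used[res$cell_type == "covering"], 12L)
})
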