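# Independent reference implementations used to check the package's
# vectorized code paths.  Each is written as a direct transcription of the
# defining formula (naive loops, explicit binomial coefficients) and shares
# no code with the implementation under test.

# Running-sum enrichment score by naive per-position re-summation:
# at every position i, re-sum the weighted hit mass and the miss count
# from scratch (O(N^2)).
oracle_enrichment_score <- function(genes, scores, gene_set, p = 1) {
  N <- length(genes)
  member <- genes %in% gene_set
  N_H <- sum(member)
  if (N_H == 0 || N_H >= N) stop("oracle requires 1 <= N_H < N")
  w <- abs(scores)^p
  N_R <- sum(w[member])
  if (N_R == 0) {
    w <- rep(1, N)
    N_R <- N_H
  }
  rs <- numeric(N)
  for (i in seq_len(N)) {
    p_hit <- 0
    n_miss <- 0
    for (j in seq_len(i)) {
      if (member[j]) p_hit <- p_hit + w[j] / N_R else n_miss <- n_miss + 1
    }
    rs[i] <- p_hit - n_miss / (N - N_H)
  }
  best <- 1
  for (i in seq_len(N)) {
    # earliest peak, tolerating ulp-level rounding on exact ties
    if (abs(rs[i]) > abs(rs[best]) + 1e-9) best <- i
  }
  list(ES = rs[best], running_sum = rs)
}

# Hypergeometric upper tail by explicit binomial-coefficient enumeration.
oracle_hyper_tail <- function(a, b, c, d) {
  n <- a + b + c + d
  n_draw <- a + b
  n_set <- a + c
  if (a == 0) return(1)
  k <- a:min(n_draw, n_set)
  sum(choose(n_set, k) * choose(n - n_set, n_draw - k)) / choose(n, n_draw)
}

# Benjamini-Hochberg step-up, transcribed from the defining formula:
# padj_(i) = min_{j >= i} min(1, m * p_(j) / j) over the sorted order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Build a ranked_gene_list directly (bypassing marker tables) for unit tests.
make_ranked <- function(genes, scores, cluster = "c1") {
  ord <- order(-scores, genes, method = "radix")
  structure(list(cluster = cluster, genes = genes[ord], scores = scores[ord]),
            class = "ranked_gene_list")
}

# Write a small marker database TSV and return its path.
write_db_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("species\ttissue\tcell_type\tgene",
               vapply(rows, paste, character(1), collapse = "\t")),
             path)
  path
}

# Write a marker CSV and return its path.
write_marker_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("gene,cluster,score", lines), path)
  path
}

# Minimal hand-built annotation_report for the plot-table units.
fake_report <- function(per_cluster, test = "fisher") {
  rows <- lapply(names(per_cluster), function(cl) {
    df <- per_cluster[[cl]]
    data.frame(cluster = cl, rank = seq_len(nrow(df)),
               cell_type = df$cell_type, pvalue = df$padj, padj = df$padj,
               stringsAsFactors = FALSE)
  })
  structure(list(results = do.call(rbind, rows), test = test,
                 config = gsea_config(), min_set_size = 2,
                 clusters = names(per_cluster), unassigned = character(0)),
            class = "annotation_report")
}

# Hypergeometric tail computed from raw sets (independent set algebra).
oracle_hyper_tail_from_sets <- function(markers, gene_set, universe) {
  m <- intersect(markers, universe)
  s <- intersect(gene_set, universe)
  a <- length(intersect(m, s))
  oracle_hyper_tail(a, length(m) - a, length(s) - a,
                    length(universe) - length(m) - length(s) + a)
}
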