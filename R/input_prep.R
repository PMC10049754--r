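#' Read a per-cluster marker table
#'
#' Reads the standard differential-expression output consumed by the
#' annotation engines: a CSV with header columns `gene`, `cluster` and
#' `score`, one row per cluster-specific marker gene.  `score` is the
#' ranking statistic from the upstream DE analysis (typically the log2 fold
#' change of the gene in the cluster versus all other clusters); `gene` may
#' hold Entrez IDs or symbols.  Extra columns are ignored.
#'
#' Rows with a non-finite or unparseable score are dropped with a warning.
#' When `symbol_map` is supplied the gene column is converted to Entrez IDs
#' via [convert_symbols()] and rows whose symbol has no mapping are dropped,
#' again with a warning.
#'
#' @param path Path to the marker CSV.
#' @param symbol_map Optional named vector symbol -> Entrez ID (see
#'   [load_symbol_map()]).
#' @return A `marker_table`: data frame with character columns `gene`,
#'   `cluster` and numeric `score`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("gene,cluster,score", "930,1,2.5", "931,1,1.2", "100,2,0.8"), f)
#' read_marker_table(f)
#' @export
read_marker_table <- function(path, symbol_map = NULL) {
  if (!file.exists(path)) {
    ct_stop(sprintf("marker table not found: %s", path), "ct_error_io")
  }
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("gene", "cluster", "score")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    ct_stop(sprintf("marker table is missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "ct_error_schema")
  }
  tab <- raw[, required, drop = FALSE]
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- !is.finite(score) | !nzchar(trimws(tab$gene)) |
    !nzchar(trimws(tab$cluster))
  if (any(bad)) {
    ct_warn(sprintf("marker table: dropped %d row(s) with non-finite score or empty fields",
                    sum(bad)))
  }
  tab <- tab[!bad, , drop = FALSE]
  tab$score <- score[!bad]
  if (!is.null(symbol_map)) {
    hit <- tab$gene %in% names(symbol_map)
    if (any(!hit)) {
      ct_warn(sprintf("marker table: dropped %d row(s) whose gene symbol has no Entrez mapping",
                      sum(!hit)))
    }
    tab <- tab[hit, , drop = FALSE]
    tab$gene <- unname(symbol_map[tab$gene])
  }
  if (nrow(tab) == 0) {
    ct_stop("marker table has no usable rows after filtering",
            "ct_error_empty")
  }
  rownames(tab) <- NULL
  marker_table(tab)
}

#' Construct a marker table from a data frame
#'
#' Validates and normalises an in-memory marker table (columns `gene`,
#' `cluster`, `score`) into the class the annotation functions expect.
#'
#' @param df Data frame with columns `gene`, `cluster`, `score`.
#' @return A `marker_table` data frame.
#' @export
marker_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene", "cluster", "score") %in% names(df)))
  out <- data.frame(gene = as.character(df$gene),
                    cluster = as.character(df$cluster),
                    score = as.numeric(df$score),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$score))) {
    ct_stop("marker_table scores must be finite", "ct_error_config")
  }
  if (any(!nzchar(out$cluster)) || any(!nzchar(out$gene))) {
    ct_stop("marker_table gene and cluster labels must be non-empty",
            "ct_error_config")
  }
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Cluster labels present in a marker table
#' @param table A `marker_table`.
#' @return Character vector of unique cluster labels, in order of first
#'   appearance.
#' @export
marker_clusters <- function(table) {
  unique(as.character(table$cluster))
}

#' Build the ranked gene list for one cluster
#'
#' Extracts one cluster's markers and produces the deterministic ranked
#' list the enrichment engines consume: duplicate genes are collapsed
#' keeping the maximum score, genes are sorted by score descending, and
#' ties are broken by gene identifier ascending so repeated runs give
#' byte-identical rankings.
#'
#' @param table A `marker_table`.
#' @param cluster Cluster label present in `table`.
#' @return A `ranked_gene_list`: list with `cluster`, `genes` (character,
#'   unique) and `scores` (numeric, non-increasing, parallel to `genes`).
#' @examples
#' tab <- marker_table(data.frame(gene = c("g1", "g2", "g1"),
#'                                cluster = "1", score = c(2, 3, 1)))
#' build_ranked_list(tab, "1")
#' @export
build_ranked_list <- function(table, cluster) {
  stopifnot(inherits(table, "marker_table"))
  cluster <- as.character(cluster)
  rows <- table[table$cluster == cluster, , drop = FALSE]
  if (nrow(rows) == 0) {
    ct_stop(sprintf("cluster '%s' not present in marker table", cluster),
            "ct_error_lookup")
  }
  # max-collapse duplicates, then order by (score desc, gene asc)
  best <- tapply(rows$score, rows$gene, max)
  genes <- names(best)
  scores <- as.numeric(best)
  ord <- order(-scores, genes, method = "radix")
  structure(list(cluster = cluster,
                 genes = genes[ord],
                 scores = scores[ord]),
            class = "ranked_gene_list")
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat(sprintf("ranked_gene_list: cluster '%s', %d genes, score range [%g, %g]\n",
              x$cluster, length(x$genes), min(x$scores), max(x$scores)))
  invisible(x)
}
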