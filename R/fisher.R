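#' Build the 2x2 contingency table for one cell type
#'
#' Cross-classifies the genes of a background universe by membership in the
#' cluster's marker list and in a candidate cell type's gene set.  Both
#' input sets are first intersected with the universe, so the four cells
#' always sum to the universe size.
#'
#' @param markers Character vector: the cluster's marker gene IDs.
#' @param gene_set Character vector: the candidate cell type's gene IDs.
#' @param universe Character vector: the background gene universe
#'   (non-empty).
#' @return A `contingency_table` list with integer cells `a` (markers in
#'   set), `b` (markers outside set), `c` (set genes not markers), `d`
#'   (neither) and `universe_size`.
#' @examples
#' build_contingency(as.character(1:3), as.character(2:4), as.character(1:10))
#' @export
build_contingency <- function(markers, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    ct_stop("contingency universe is empty", "ct_error_config")
  }
  m <- intersect(unique(as.character(markers)), universe)
  s <- intersect(unique(as.character(gene_set)), universe)
  a <- length(intersect(m, s))
  b <- length(m) - a
  cc <- length(s) - a
  d <- length(universe) - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d,
                 universe_size = length(universe)),
            class = "contingency_table")
}

#' One-sided Fisher's exact test (over-representation)
#'
#' Upper-tail hypergeometric probability of observing at least `a` marker
#' genes inside the candidate set, given the table margins: the classic
#' over-representation p-value used in gene-set enrichment.  The tail is
#' accumulated in log space so tables drawn from universes of up to ~1e5
#' genes evaluate without underflow.
#'
#' @param table A `contingency_table` from [build_contingency()].
#' @return p-value in (0, 1]; exactly 1 when `a = 0`.
#' @export
fisher_greater <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a
  if (a == 0) {
    return(1)
  }
  n_set <- table$a + table$c        # white balls: genes in the set
  n_out <- table$b + table$d        # black balls: genes outside the set
  n_draw <- table$a + table$b       # draws: the cluster's markers
  k <- a:min(n_draw, n_set)
  logs <- stats::dhyper(k, n_set, n_out, n_draw, log = TRUE)
  mx <- max(logs)
  p <- exp(mx + log(sum(exp(logs - mx))))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values;
#' adjusted values are returned in the input order.
#'
#' @param pvalues Numeric vector with all values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) {
    return(numeric(0))
  }
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    ct_stop("p-values must all lie in [0, 1]", "ct_error_config")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher over-representation annotation of one cluster
#'
#' Runs the one-sided Fisher's exact test of the cluster's marker genes
#' against every candidate cell type in the collection.  The background
#' universe is the union of all genes in the (tissue-filtered) collection
#' and the cluster's own markers, so the test is self-contained and stable
#' across runs.  Raw p-values are Benjamini-Hochberg adjusted across the
#' cell types tested within the cluster.
#'
#' Because identical tables give identical p-values, the expression scores
#' of the overlapping markers act as a secondary ranking key: rows sort by
#' adjusted p ascending, then mean score of the overlap descending, then
#' overlap size descending, then cell type ascending.
#'
#' @param ranked A `ranked_gene_list`.
#' @param collection A [gene_set_collection].
#' @param min_set_size Minimum number of genes a cell type must have inside
#'   the universe to be tested.
#' @return Data frame with columns `cluster`, `rank`, `cell_type`, `a`,
#'   `b`, `c`, `d`, `pvalue`, `padj`, `overlap_score`; zero rows (with a
#'   warning) if no cell type could be tested.
#' @export
fisher_per_cluster <- function(ranked, collection, min_set_size = 2) {
  stopifnot(inherits(ranked, "ranked_gene_list"),
            inherits(collection, "gene_set_collection"))
  universe <- union(collection_universe(collection), ranked$genes)
  sizes <- vapply(collection$sets,
                  function(s) length(intersect(s, universe)), integer(1))
  testable <- sizes >= min_set_size
  if (!any(testable)) {
    ct_warn(sprintf("cluster '%s': no candidate cell type meets min_set_size=%d",
                    ranked$cluster, min_set_size))
    return(empty_fisher_frame())
  }
  score_of <- stats::setNames(ranked$scores, ranked$genes)
  types <- names(collection$sets)[testable]
  rows <- lapply(types, function(ct) {
    set <- collection$sets[[ct]]
    tab <- build_contingency(ranked$genes, set, universe)
    overlap <- intersect(ranked$genes, set)
    ov_score <- if (length(overlap) == 0) 0 else mean(score_of[overlap])
    data.frame(cluster = ranked$cluster, cell_type = ct,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               pvalue = fisher_greater(tab),
               overlap_score = ov_score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$pvalue)
  ord <- order(res$padj, -res$overlap_score, -res$a, res$cell_type,
               method = "radix")
  res <- res[ord, c("cluster", "cell_type", "a", "b", "c", "d",
                    "pvalue", "padj", "overlap_score")]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("cluster", "rank", "cell_type", "a", "b", "c", "d",
          "pvalue", "padj", "overlap_score")]
}

empty_fisher_frame <- function() {
  data.frame(cluster = character(0), rank = integer(0),
             cell_type = character(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), pvalue = numeric(0),
             padj = numeric(0), overlap_score = numeric(0),
             stringsAsFactors = FALSE)
}
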