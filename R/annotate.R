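#' Annotate all clusters of a marker table
#'
#' The main entry point: for each cluster in the marker table a ranked gene
#' list is built and tested against the candidate cell types of the
#' (typically tissue-filtered) collection with either the preranked GSEA
#' engine or the Fisher over-representation engine.  Clusters for which no
#' cell type could be tested are recorded as unassigned rather than
#' dropped.
#'
#' @param table A `marker_table` (see [read_marker_table()]).
#' @param collection A [gene_set_collection].
#' @param test `"gsea"` or `"fisher"`.
#' @param config A [gsea_config()]; used by the GSEA engine (its
#'   `min_set_size` is also applied by the Fisher engine unless
#'   `min_set_size` is given).
#' @param min_set_size Optional override of the minimum set size for the
#'   Fisher engine.
#' @param min_score Optional lower bound on the expression score; rows
#'   below it are dropped before ranking (useful to restrict annotation to
#'   up-regulated markers).
#' @return An `annotation_report`: list with `results` (one data frame of
#'   ranked candidates over all clusters), `test`, `config`, `clusters`
#'   (every input cluster) and `unassigned`.
#' @examples
#' sc <- synthetic_scenario(n_cell_types = 3, seed = 42)
#' truth <- simulate_truth(sc)
#' rep <- annotate_clusters(truth$marker_table, truth$database, test = "fisher")
#' hard_classify(rep)
#' @export
annotate_clusters <- function(table, collection,
                              test = c("gsea", "fisher"),
                              config = gsea_config(),
                              min_set_size = NULL,
                              min_score = NULL) {
  stopifnot(inherits(table, "marker_table"),
            inherits(collection, "gene_set_collection"),
            inherits(config, "gsea_config"))
  test <- match.arg(test)
  if (!is.null(min_score)) {
    keep <- table$score >= min_score
    if (!any(keep)) {
      ct_stop(sprintf("no marker rows with score >= %g", min_score),
              "ct_error_empty")
    }
    table <- marker_table(table[keep, , drop = FALSE])
  }
  clusters <- marker_clusters(table)
  mss <- if (is.null(min_set_size)) config$min_set_size else as.integer(min_set_size)
  per_cluster <- lapply(clusters, function(cl) {
    ranked <- build_ranked_list(table, cl)
    if (test == "gsea") {
      gsea_per_cluster(ranked, collection, config)
    } else {
      fisher_per_cluster(ranked, collection, min_set_size = mss)
    }
  })
  n_rows <- vapply(per_cluster, nrow, integer(1))
  unassigned <- clusters[n_rows == 0]
  if (length(unassigned) > 0) {
    ct_msg(sprintf("unassigned cluster(s): %s",
                   paste(unassigned, collapse = ", ")))
  }
  results <- do.call(rbind, per_cluster[n_rows > 0])
  if (is.null(results)) {
    results <- if (test == "gsea") empty_gsea_frame() else empty_fisher_frame()
  }
  structure(list(results = results,
                 test = test,
                 config = config,
                 min_set_size = mss,
                 clusters = clusters,
                 unassigned = unassigned),
            class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("annotation_report: %d cluster(s), test=%s, %d unassigned\n",
              length(x$clusters), x$test, length(x$unassigned)))
  hard <- hard_classify(x)
  for (cl in names(hard)) {
    cat(sprintf("  cluster %s -> %s\n", cl, hard[[cl]]))
  }
  invisible(x)
}

#' Sentinel label for clusters with no testable candidate
#' @export
UNASSIGNED_LABEL <- "unassigned"

report_candidates <- function(report, cluster) {
  res <- report$results
  res[res$cluster == cluster, , drop = FALSE]
}

#' Hard classification: the single most significant cell type per cluster
#'
#' @param report An `annotation_report`.
#' @return Named character vector, cluster -> cell type (or the
#'   `"unassigned"` sentinel).
#' @export
hard_classify <- function(report) {
  stopifnot(inherits(report, "annotation_report"))
  out <- vapply(report$clusters, function(cl) {
    cand <- report_candidates(report, cl)
    if (nrow(cand) == 0) UNASSIGNED_LABEL else cand$cell_type[cand$rank == 1]
  }, character(1))
  stats::setNames(out, report$clusters)
}

#' Soft classification: the top-k candidate cell types per cluster
#'
#' The first element of each cluster's list always equals the hard label,
#' so soft classification can only improve the chance that the true label
#' is reported.
#'
#' @param report An `annotation_report`.
#' @param k Maximum number of candidates per cluster (default 5).
#' @return Named list, cluster -> character vector of at most `k` cell
#'   types in ranking order (the sentinel `"unassigned"` for clusters with
#'   no candidates).
#' @export
soft_classify <- function(report, k = 5) {
  stopifnot(inherits(report, "annotation_report"), k >= 1)
  out <- lapply(report$clusters, function(cl) {
    cand <- report_candidates(report, cl)
    if (nrow(cand) == 0) {
      UNASSIGNED_LABEL
    } else {
      cand$cell_type[order(cand$rank)][seq_len(min(k, nrow(cand)))]
    }
  })
  stats::setNames(out, report$clusters)
}

clip_neglog10 <- function(padj, cap = 10) {
  v <- -log10(padj)
  pmin(pmax(v, 0), cap)
}

#' Dot-plot summary table
#'
#' One row per (cluster, top-k candidate); `size_value` encodes
#' significance as `-log10(padj)` clipped to \[0, 10\], so within a cluster
#' the most significant cell type gets the largest dot.
#'
#' @param report An `annotation_report`.
#' @param k Number of top candidates per cluster (default 5).
#' @return Data frame with columns `cluster`, `cell_type`, `rank`,
#'   `size_value`.
#' @export
dotplot_data <- function(report, k = 5) {
  stopifnot(inherits(report, "annotation_report"), k >= 1)
  res <- report$results
  keep <- res$rank <= k
  out <- data.frame(cluster = res$cluster[keep],
                    cell_type = res$cell_type[keep],
                    rank = res$rank[keep],
                    size_value = clip_neglog10(res$padj[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bar-plot table for one cluster
#'
#' Candidate cell types of one cluster with significance encoded as bar
#' length (`-log10(padj)` clipped to \[0, 10\]); at most `max_candidates`
#' rows, and exactly the first row flagged as the hard label.
#'
#' @param report An `annotation_report`.
#' @param cluster Cluster label present in the report.
#' @param max_candidates Maximum number of rows (default 10).
#' @return Data frame with columns `cell_type`, `bar_value`,
#'   `is_hard_label`.
#' @export
barplot_data <- function(report, cluster, max_candidates = 10) {
  stopifnot(inherits(report, "annotation_report"), max_candidates >= 1)
  cluster <- as.character(cluster)
  if (!cluster %in% report$clusters) {
    ct_stop(sprintf("cluster '%s' not present in the report", cluster),
            "ct_error_lookup")
  }
  cand <- report_candidates(report, cluster)
  cand <- cand[order(cand$rank), , drop = FALSE]
  cand <- utils::head(cand, max_candidates)
  out <- data.frame(cell_type = cand$cell_type,
                    bar_value = clip_neglog10(cand$padj),
                    is_hard_label = seq_len(nrow(cand)) == 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render the dot-plot summary
#'
#' Thin ggplot2 layer over [dotplot_data()]; the table, not the image, is
#' the tested surface.
#'
#' @param report An `annotation_report`.
#' @param k Top candidates per cluster.
#' @return A ggplot object.
#' @export
plot_annotation_dots <- function(report, k = 5) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    ct_stop("ggplot2 is required for plotting", "ct_error_config")
  }
  d <- dotplot_data(report, k)
  ggplot2::ggplot(d, ggplot2::aes(x = cluster, y = cell_type,
                                  size = size_value)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_continuous(limits = c(0, 10)) +
    ggplot2::labs(x = "Cluster", y = "Candidate cell type",
                  size = "-log10 adj. p") +
    ggplot2::theme_minimal()
}

#' Render the per-cluster bar plot
#'
#' Thin ggplot2 layer over [barplot_data()].
#'
#' @param report An `annotation_report`.
#' @param cluster Cluster label.
#' @param max_candidates Maximum bars shown.
#' @return A ggplot object.
#' @export
plot_cluster_bars <- function(report, cluster, max_candidates = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    ct_stop("ggplot2 is required for plotting", "ct_error_config")
  }
  d <- barplot_data(report, cluster, max_candidates)
  d$cell_type <- factor(d$cell_type, levels = rev(d$cell_type))
  ggplot2::ggplot(d, ggplot2::aes(x = bar_value, y = cell_type,
                                  fill = is_hard_label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 adj. p", y = NULL,
                  title = sprintf("Cluster %s", cluster)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
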