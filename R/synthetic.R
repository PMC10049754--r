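#' Define a synthetic annotation scenario
#'
#' Describes a ground-truthed benchmark: a marker database of
#' `n_cell_types` gene sets plus, for each cluster, a reported marker table
#' that mixes genuine markers of the cluster's true cell type with decoy
#' genes.  The scenario emulates the marker-table structure produced by
#' upstream clustering + differential expression on a PBMC-like dataset of
#' eight cell types, without simulating cells themselves: the ranked
#' marker list is the sufficient statistic the annotation engines consume.
#'
#' Reported true-marker scores are drawn uniformly on \[1, 3\] and decoy
#' scores uniformly on \[0.1, 0.8\], so genuine markers stochastically
#' dominate the noise as in a real log-fold-change ranking.
#'
#' @param n_cell_types Number of cell types / clusters (default 8, a
#'   PBMC-like panel).
#' @param markers_per_type Database markers per cell type (default 20).
#' @param marker_overlap_frac Fraction of each set shared with the next
#'   cell type, emulating hard-to-distinguish related subtypes (e.g. T-cell
#'   subsets); must leave every pair of sets distinct.
#' @param n_markers_reported Markers reported per cluster in the DE table
#'   (default 20).
#' @param noise_frac Fraction of each cluster's reported markers drawn
#'   from decoy genes unrelated to any cell type (default 0.2).
#' @param n_decoy_genes Size of the decoy gene pool (default 200).
#' @param cells_per_cluster Integer scalar or vector of length
#'   `n_cell_types`: cluster sizes used for per-cell accuracy weighting
#'   (default 200, i.e. 1600 cells over 8 clusters).
#' @param seed Integer seed; all simulation randomness flows from it.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_cell_types = 8,
                               markers_per_type = 20,
                               marker_overlap_frac = 0,
                               n_markers_reported = 20,
                               noise_frac = 0.2,
                               n_decoy_genes = 200,
                               cells_per_cluster = 200,
                               seed = 1) {
  stopifnot(n_cell_types >= 1, markers_per_type >= 1,
            marker_overlap_frac >= 0, marker_overlap_frac < 1,
            n_markers_reported >= 1,
            noise_frac >= 0, noise_frac < 1,
            n_decoy_genes >= 1,
            all(cells_per_cluster >= 1),
            length(cells_per_cluster) %in% c(1L, n_cell_types))
  if (length(cells_per_cluster) == 1) {
    cells_per_cluster <- rep(cells_per_cluster, n_cell_types)
  }
  structure(list(n_cell_types = as.integer(n_cell_types),
                 markers_per_type = as.integer(markers_per_type),
                 marker_overlap_frac = marker_overlap_frac,
                 n_markers_reported = as.integer(n_markers_reported),
                 noise_frac = noise_frac,
                 n_decoy_genes = as.integer(n_decoy_genes),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 true_score_range = c(1, 3),
                 noise_score_range = c(0.1, 0.8),
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

synthetic_type_names <- function(K) {
  sprintf("type_%02d", seq_len(K))
}

#' Simulate a marker database with known structure
#'
#' Builds `n_cell_types` gene sets of `markers_per_type` synthetic gene
#' tokens over a synthetic universe.  Adjacent cell types share
#' `floor(marker_overlap_frac * markers_per_type)` genes, emulating related
#' subtypes whose marker panels overlap; with zero overlap the sets are
#' pairwise disjoint.  All records carry species `"human"` and tissue
#' `"blood"` so the tissue-filter step of the real pipeline can be
#' exercised.  The construction is deterministic given the scenario.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [gene_set_collection].
#' @export
simulate_database <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  K <- scenario$n_cell_types
  m <- scenario$markers_per_type
  s <- floor(scenario$marker_overlap_frac * m)
  # interior types give s genes to each neighbour; the shares must fit in
  # the set and the sets must stay pairwise distinct
  n_shared_blocks <- max(K - 1, 0)
  if (s > 0 && ((K >= 2 && s >= m) || (K >= 3 && 2 * s > m))) {
    ct_stop("marker_overlap_frac too large to keep adjacent gene sets distinct",
            "ct_error_config")
  }
  core_sizes <- vapply(seq_len(K), function(i) {
    m - s * ((i > 1) + (i < K)) * (K > 1)
  }, numeric(1))
  n_genes <- sum(core_sizes) + s * n_shared_blocks * (s > 0)
  # assign tokens in shuffled order: real marker panels are not contiguous
  # in gene-identifier space, so set membership must not correlate with
  # the lexicographic order of the synthetic universe
  tokens <- ct_with_seed(scenario$seed,
                         sample(sprintf("g%05d", seq_len(n_genes))))
  nxt <- 1
  take <- function(n) {
    if (n == 0) return(character(0))
    out <- tokens[nxt:(nxt + n - 1)]
    nxt <<- nxt + n
    out
  }
  shared <- if (s > 0 && K > 1) {
    lapply(seq_len(K - 1), function(i) take(s))
  } else {
    rep(list(character(0)), max(K - 1, 0))
  }
  sets <- lapply(seq_len(K), function(i) {
    left <- if (i > 1) shared[[i - 1]] else character(0)
    right <- if (i < K) shared[[i]] else character(0)
    c(left, take(core_sizes[i]), right)
  })
  names(sets) <- synthetic_type_names(K)
  records <- data.frame(
    tissue = "blood",
    cell_type = rep(names(sets), vapply(sets, length, integer(1))),
    gene = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  gene_set_collection(records, species = "human",
                      source_name = "synthetic")
}

#' Simulate per-cluster marker tables with known truth
#'
#' For each cluster `i` (true cell type `i`) the reported marker table
#' contains `n_markers_reported` rows: a fraction `noise_frac` are decoy
#' genes absent from every database set, the rest are sampled without
#' replacement from the true cell type's marker set.  True markers get
#' scores uniform on \[1, 3\], decoys uniform on \[0.1, 0.8\]; rows are
#' shuffled so downstream ranking does the work.  Deterministic under the
#' scenario seed.
#'
#' @param truth_db A [gene_set_collection] from [simulate_database()].
#' @param scenario The same [synthetic_scenario()].
#' @return A `synthetic_truth` list: `database`, `marker_table`,
#'   `true_label` (cluster -> cell type), `cells_per_cluster` and the
#'   scenario.
#' @export
simulate_markers <- function(truth_db, scenario) {
  stopifnot(inherits(truth_db, "gene_set_collection"),
            inherits(scenario, "synthetic_scenario"))
  K <- scenario$n_cell_types
  types <- synthetic_type_names(K)
  stopifnot(all(types %in% names(truth_db$sets)))
  n_rep <- scenario$n_markers_reported
  n_noise <- round(scenario$noise_frac * n_rep)
  n_true <- n_rep - n_noise
  if (n_true > scenario$markers_per_type) {
    ct_stop(sprintf("cannot report %d true markers from sets of size %d",
                    n_true, scenario$markers_per_type), "ct_error_config")
  }
  if (n_noise > scenario$n_decoy_genes) {
    ct_stop("decoy pool smaller than the number of noise markers requested",
            "ct_error_config")
  }
  decoys <- sprintf("decoy%05d", seq_len(scenario$n_decoy_genes))
  tr <- scenario$true_score_range
  nr <- scenario$noise_score_range
  tab <- ct_with_seed(scenario$seed, {
    rows <- lapply(seq_len(K), function(i) {
      true_genes <- sample(truth_db$sets[[types[i]]], n_true)
      noise_genes <- sample(decoys, n_noise)
      df <- data.frame(
        gene = c(true_genes, noise_genes),
        cluster = as.character(i),
        score = c(stats::runif(n_true, tr[1], tr[2]),
                  stats::runif(n_noise, nr[1], nr[2])),
        stringsAsFactors = FALSE)
      df[sample.int(nrow(df)), , drop = FALSE]
    })
    do.call(rbind, rows)
  })
  rownames(tab) <- NULL
  structure(list(database = truth_db,
                 marker_table = marker_table(tab),
                 true_label = stats::setNames(types, as.character(seq_len(K))),
                 cells_per_cluster = stats::setNames(scenario$cells_per_cluster,
                                                     as.character(seq_len(K))),
                 scenario = scenario),
            class = "synthetic_truth")
}

#' Simulate database and marker tables in one call
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `synthetic_truth` (see [simulate_markers()]).
#' @export
simulate_truth <- function(scenario) {
  simulate_markers(simulate_database(scenario), scenario)
}

#' Per-cell annotation accuracy against known truth
#'
#' A cluster is correctly annotated when its hard label equals the true
#' label (`mode = "hard"`) or when the true label appears among the top-k
#' soft candidates (`mode = "soft"`).  Every cell of a correctly annotated
#' cluster counts as correct, so accuracy is the cell-count-weighted
#' fraction of correct clusters: correct cells divided by total cells.
#' A cluster missing from the report counts as incorrect (with a message).
#'
#' @param truth A `synthetic_truth`.
#' @param report An `annotation_report` covering the truth's clusters.
#' @param mode `"hard"` or `"soft"`.
#' @param k Top-k for soft mode (default 5).
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_accuracy <- function(truth, report, mode = c("hard", "soft"),
                              k = 5) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(report, "annotation_report"))
  mode <- match.arg(mode)
  clusters <- names(truth$true_label)
  missing <- setdiff(clusters, report$clusters)
  if (length(missing) > 0) {
    ct_msg(sprintf("cluster(s) absent from report, counted incorrect: %s",
                   paste(missing, collapse = ", ")))
  }
  labels <- if (mode == "hard") {
    as.list(hard_classify(report))
  } else {
    soft_classify(report, k)
  }
  correct <- vapply(clusters, function(cl) {
    if (!cl %in% report$clusters) return(FALSE)
    truth$true_label[[cl]] %in% labels[[cl]]
  }, logical(1))
  cells <- truth$cells_per_cluster[clusters]
  sum(cells[correct]) / sum(cells)
}
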