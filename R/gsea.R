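#' Configuration for the preranked GSEA engine
#'
#' @param weight_exponent Exponent applied to the absolute ranking score
#'   when weighting the running sum; `1` is the classic weighted statistic,
#'   `0` reduces to the unweighted Kolmogorov-Smirnov form.
#' @param nperm Number of gene-label permutations for the null
#'   distribution (at least 100).
#' @param seed Integer seed controlling the permutation null.
#' @param score_type `"pos"` treats the marker list as up-regulated markers
#'   and ranks cell types with negative enrichment after all non-negative
#'   ones; `"std"` keeps fully signed behaviour.
#' @param min_set_size,max_set_size Bounds on the number of set genes
#'   present in the ranked list for a cell type to be tested.  Singleton
#'   sets trivially reach the maximal enrichment score, hence the default
#'   lower bound of 2.
#' @return A `gsea_config` list.
#' @export
gsea_config <- function(weight_exponent = 1, nperm = 1000, seed = 1,
                        score_type = c("pos", "std"),
                        min_set_size = 2, max_set_size = 500) {
  score_type <- match.arg(score_type)
  stopifnot(is.numeric(weight_exponent), length(weight_exponent) == 1,
            weight_exponent >= 0,
            is.numeric(nperm), length(nperm) == 1, nperm >= 100,
            is.numeric(seed), length(seed) == 1,
            min_set_size >= 1, min_set_size <= max_set_size)
  structure(list(weight_exponent = weight_exponent,
                 nperm = as.integer(nperm),
                 seed = as.integer(seed),
                 score_type = score_type,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size)),
            class = "gsea_config")
}

# Earliest position of the maximal |running sum|.  Exact ties (e.g. -0.5
# then +0.5 on a short list) can differ by an ulp after cumsum, so the
# comparison tolerates 1e-9 — far below the smallest genuine gap between
# distinct deviations, which is at least 1/(N * (N - N_H)).
es_peak <- function(running) {
  which(abs(running) >= max(abs(running)) - 1e-9)[1]
}

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
ct_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Weighted running-sum enrichment score
#'
#' Computes the preranked enrichment score of a gene set against a ranked
#' gene list.  With `N` ranked genes of which `N_H` belong to the set, the
#' running sum at position `i` is the hit mass accumulated so far minus the
#' miss mass: hits contribute `|r_j|^p / N_R` (where `N_R` is the total
#' weighted hit mass and `p` the weight exponent), misses contribute
#' `1 / (N - N_H)`.  The walk therefore starts accruing at position 1 and
#' returns to 0 at position `N`.  The enrichment score is the running-sum
#' element of maximal absolute value (earliest position on ties), a
#' weighted Kolmogorov-Smirnov-like statistic in `[-1, 1]`.
#'
#' If every set member has score 0 the weighted hit mass is degenerate and
#' the computation falls back to `weight_exponent = 0` for that set.
#'
#' @param ranked A `ranked_gene_list` (see [build_ranked_list()]).
#' @param gene_set Character vector of gene identifiers.
#' @param weight_exponent Non-negative exponent on the absolute score.
#' @return `NULL` if the set does not intersect the ranked list (the
#'   set-skipped signal); otherwise a list with `ES`, `running_sum`
#'   (length `N`), `set_size_used` (`N_H`) and `peak` (argmax position).
#' @examples
#' rl <- build_ranked_list(marker_table(
#'   data.frame(gene = paste0("g", 1:10), cluster = "1", score = 10:1)), "1")
#' enrichment_score(rl, c("g1", "g2"))$ES
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"),
            weight_exponent >= 0)
  N <- length(ranked$genes)
  member <- ranked$genes %in% gene_set
  N_H <- sum(member)
  if (N_H == 0) {
    return(NULL)
  }
  if (N_H >= N) {
    ct_stop("gene set covers the whole ranked list; enrichment is undefined without at least one non-member",
            "ct_error_config")
  }
  w <- abs(ranked$scores)^weight_exponent
  N_R <- sum(w[member])
  if (N_R == 0) {
    # all member scores are exactly zero: unweighted fallback
    w <- rep(1, N)
    N_R <- N_H
  }
  inc <- rep.int(-1 / (N - N_H), N)
  inc[member] <- w[member] / N_R
  running <- cumsum(inc)
  peak <- es_peak(running)
  list(ES = running[peak],
       running_sum = running,
       set_size_used = N_H,
       peak = peak)
}

#' Permutation null distribution of the enrichment score
#'
#' Draws `nperm` gene sets of the given size uniformly without replacement
#' from the ranked universe (gene-label permutation, the standard preranked
#' null) and computes the enrichment score of each.  The draw is seeded
#' from `config$seed` offset by `set_size`, so nulls for different set
#' sizes are independent yet the whole vector is reproducible; the caller's
#' RNG state is left untouched.
#'
#' @param ranked A `ranked_gene_list`.
#' @param set_size Size of the null sets; must be at most `N - 1`.
#' @param config A [gsea_config()].
#' @return Numeric vector of `nperm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, config = gsea_config()) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  N <- length(ranked$genes)
  set_size <- as.integer(set_size)
  if (set_size < 1 || set_size > N - 1) {
    ct_stop(sprintf("null set size must be in [1, N-1]; got %d with N=%d",
                    set_size, N), "ct_error_config")
  }
  w <- abs(ranked$scores)^config$weight_exponent
  miss <- -1 / (N - set_size)
  ct_with_seed(config$seed + set_size, {
    vapply(seq_len(config$nperm), function(b) {
      idx <- sample.int(N, set_size)
      w_hit <- w[idx]
      N_R <- sum(w_hit)
      inc <- rep.int(miss, N)
      inc[idx] <- if (N_R == 0) 1 / set_size else w_hit / N_R
      running <- cumsum(inc)
      running[es_peak(running)]
    }, numeric(1))
  })
}

# Sign-conditional permutation p and normalized ES.
# p = (1 + #{null of same sign with |null| >= |obs|}) / (1 + #{null of same sign});
# NES = ES / mean(|null| of same sign), NA if no same-sign nulls exist.
gsea_p_nes <- function(es, null_es) {
  same <- if (es >= 0) null_es >= 0 else null_es < 0
  n_same <- sum(same)
  p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + n_same)
  nes <- if (n_same == 0) NA_real_ else es / mean(abs(null_es[same]))
  list(p = p, NES = nes)
}

# Extend a ranked list with universe genes absent from it, at score 0.
# Zero-score padding merges into the ordering between positive and negative
# scores (ties broken by gene ID), so the walk stays well defined even when
# every reported marker belongs to one candidate set.
augment_ranked <- function(ranked, universe) {
  extra <- setdiff(universe, ranked$genes)
  if (length(extra) == 0) {
    return(ranked)
  }
  genes <- c(ranked$genes, sort(extra))
  scores <- c(ranked$scores, rep(0, length(extra)))
  ord <- order(-scores, genes, method = "radix")
  structure(list(cluster = ranked$cluster, genes = genes[ord],
                 scores = scores[ord]),
            class = "ranked_gene_list")
}

#' Preranked GSEA annotation of one cluster
#'
#' Tests every candidate cell type in the collection against the cluster's
#' ranked marker list.  As in the Fisher branch, the background universe is
#' the union of the collection's genes and the cluster's markers: database
#' genes missing from the marker list are appended at score 0, which keeps
#' the running sum defined even when the entire marker list lies inside a
#' candidate set (the strongest possible annotation evidence, which would
#' otherwise leave no non-member genes to walk over).  Cell types whose set
#' intersects the universe in fewer than `min_set_size` or more than
#' `max_set_size` genes, or covers the whole universe, are skipped.  For
#' each tested cell type the enrichment score, a sign-conditional
#' permutation p-value, the normalized enrichment score and the
#' Benjamini-Hochberg adjusted p-value (across the cell types tested
#' within this cluster) are reported.
#'
#' Null enrichment scores are shared across cell types with the same
#' intersection size, so the permutation cost scales with the number of
#' distinct set sizes rather than the number of cell types.
#'
#' Ordering of the result: with `score_type = "pos"` all non-negatively
#' enriched cell types precede negatively enriched ones; within that,
#' rows sort by adjusted p ascending, raw p ascending, `|NES|` descending
#' and cell type ascending, which makes the ranking deterministic.
#'
#' @param ranked A `ranked_gene_list`.
#' @param collection A [gene_set_collection].
#' @param config A [gsea_config()].
#' @return Data frame with columns `cluster`, `rank`, `cell_type`, `ES`,
#'   `NES`, `pvalue`, `padj`, `set_size_used`; zero rows (with a warning)
#'   if no cell type could be tested.
#' @export
gsea_per_cluster <- function(ranked, collection, config = gsea_config()) {
  stopifnot(inherits(ranked, "ranked_gene_list"),
            inherits(collection, "gene_set_collection"))
  ranked <- augment_ranked(ranked, collection_universe(collection))
  N <- length(ranked$genes)
  sizes <- vapply(collection$sets,
                  function(s) sum(ranked$genes %in% s), integer(1))
  testable <- sizes >= config$min_set_size & sizes <= config$max_set_size &
    sizes < N
  if (!any(testable)) {
    ct_warn(sprintf("cluster '%s': no candidate cell type intersects the ranked list within the set-size bounds",
                    ranked$cluster))
    return(empty_gsea_frame())
  }
  types <- names(collection$sets)[testable]
  null_cache <- new.env(parent = emptyenv())
  rows <- lapply(types, function(ct) {
    es <- enrichment_score(ranked, collection$sets[[ct]],
                           config$weight_exponent)
    key <- as.character(es$set_size_used)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- permutation_null(ranked, es$set_size_used, config)
    }
    pn <- gsea_p_nes(es$ES, null_cache[[key]])
    data.frame(cluster = ranked$cluster, cell_type = ct,
               ES = es$ES, NES = pn$NES, pvalue = pn$p,
               set_size_used = es$set_size_used,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$pvalue)
  neg_last <- if (config$score_type == "pos") res$ES < 0 else rep(FALSE, nrow(res))
  abs_nes <- abs(res$NES)
  abs_nes[is.na(abs_nes)] <- -Inf  # undefined NES sorts last within a p tie
  ord <- order(neg_last, res$padj, res$pvalue, -abs_nes, res$cell_type,
               method = "radix")
  res <- res[ord, c("cluster", "cell_type", "ES", "NES", "pvalue", "padj",
                    "set_size_used")]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("cluster", "rank", "cell_type", "ES", "NES", "pvalue", "padj",
          "set_size_used")]
}

empty_gsea_frame <- function() {
  data.frame(cluster = character(0), rank = integer(0),
             cell_type = character(0), ES = numeric(0), NES = numeric(0),
             pvalue = numeric(0), padj = numeric(0),
             set_size_used = integer(0), stringsAsFactors = FALSE)
}
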