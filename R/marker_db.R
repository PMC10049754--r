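#' Load a cell-marker gene-set database
#'
#' Reads a long-format marker database (one row per species/tissue/cell
#' type/gene record, as distributed by curated marker resources such as
#' CellMarker, PanglaoDB or Clustermole once reduced to a common dialect)
#' and builds a [gene_set_collection] for one species.
#'
#' The file must be UTF-8, tab-separated, with a header row containing at
#' least the columns `species`, `tissue`, `cell_type` and `gene`.  Gene
#' identifiers are kept as text tokens, so both Entrez IDs and plain gene
#' symbols work; a database keyed by symbols can be used end-to-end as long
#' as the marker table uses the same key space.
#'
#' Rows not matching `species` are dropped, duplicated (cell type, gene)
#' pairs are collapsed, and the number of retained and dropped rows is
#' reported via [message()].
#'
#' @param path Path to the database TSV.
#' @param species Either `"human"` or `"mouse"`.
#' @param source_name Optional label recording where the records came from;
#'   defaults to the file name.
#' @return A [gene_set_collection].
#' @seealso [filter_by_tissue()], [gene_set_collection()]
#' @examples
#' db <- system.file("extdata", "mini_marker_db.tsv", package = "celltyper")
#' gsc <- load_marker_db(db, species = "human")
#' gsc
#' @export
load_marker_db <- function(path, species = c("human", "mouse"),
                           source_name = basename(path)) {
  species <- match.arg(species)
  if (!file.exists(path)) {
    ct_stop(sprintf("database file not found: %s", path), "ct_error_io")
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("species", "tissue", "cell_type", "gene")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    ct_stop(sprintf("database is missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "ct_error_schema")
  }
  n_total <- nrow(raw)
  keep <- raw$species == species &
    nzchar(trimws(raw$tissue)) &
    nzchar(trimws(raw$cell_type)) &
    nzchar(trimws(raw$gene))
  recs <- raw[keep, c("tissue", "cell_type", "gene"), drop = FALSE]
  ct_msg(sprintf("database '%s': %d/%d rows retained for species '%s' (%d dropped)",
                 source_name, nrow(recs), n_total, species,
                 n_total - nrow(recs)))
  if (nrow(recs) == 0) {
    ct_stop(sprintf("no records for species '%s' in %s", species, path),
            "ct_error_empty")
  }
  gene_set_collection(records = recs, species = species,
                      source_name = source_name)
}

#' Construct a gene-set collection from marker records
#'
#' A `gene_set_collection` maps each cell type to the unique set of gene
#' identifiers reported as its markers, together with the tissues the
#' contributing records were observed in.  It is the priori-defined gene-set
#' universe against which cluster marker lists are tested.  Duplicate
#' (tissue, cell type, gene) records are collapsed; cell types with no
#' genes are never stored.
#'
#' @param records Data frame with character columns `tissue`, `cell_type`,
#'   `gene`.
#' @param species Species label (`"human"` or `"mouse"`).
#' @param source_name Provenance label.
#' @return An object of class `gene_set_collection` with components:
#'   \describe{
#'     \item{sets}{named list, cell type -> character vector of unique gene IDs}
#'     \item{tissues}{named list, cell type -> tissues contributing records}
#'     \item{records}{the deduplicated long-format records}
#'     \item{species, source}{labels}
#'     \item{n_records}{number of deduplicated records}
#'   }
#' @export
gene_set_collection <- function(records, species = "human",
                                source_name = "unknown") {
  stopifnot(is.data.frame(records),
            all(c("tissue", "cell_type", "gene") %in% names(records)))
  records <- unique(records[, c("tissue", "cell_type", "gene")])
  records <- records[order(records$cell_type, records$tissue, records$gene), ,
                     drop = FALSE]
  rownames(records) <- NULL
  sets <- lapply(split(records$gene, records$cell_type),
                 function(g) sort(unique(g)))
  tissues <- lapply(split(records$tissue, records$cell_type),
                    function(t) sort(unique(t)))
  keep <- vapply(sets, length, integer(1)) > 0
  structure(list(sets = sets[keep],
                 tissues = tissues[keep],
                 records = records,
                 species = species,
                 source = source_name,
                 n_records = nrow(records)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d cell types, %d records, species=%s, source=%s\n",
              length(x$sets), x$n_records, x$species, x$source))
  sizes <- vapply(x$sets, length, integer(1))
  if (length(sizes) > 0) {
    cat(sprintf("  set sizes: min=%d median=%g max=%d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' All gene identifiers in a collection
#'
#' @param collection A [gene_set_collection].
#' @return Sorted character vector of the union of all gene sets.
#' @export
collection_universe <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sort(unique(unlist(collection$sets, use.names = FALSE)))
}

#' Restrict a collection to tissues matching keywords
#'
#' Retains database records whose tissue label contains any of the supplied
#' keywords.  Matching is a case-insensitive substring test by default (so
#' the keyword `"blood"` retains e.g. `"peripheral blood"`, `"blood
#' vessel"`, `"umbilical cord blood"` and `"venous blood"`); set
#' `exact = TRUE` for whole-label matching.  Cell types left with no
#' surviving records are removed.  The operation is idempotent.
#'
#' @param collection A [gene_set_collection].
#' @param keywords Character vector of tissue keywords (non-empty).
#' @param exact Require the whole tissue label to equal a keyword
#'   (case-insensitively) instead of substring containment.
#' @return A filtered [gene_set_collection].
#' @examples
#' db <- system.file("extdata", "mini_marker_db.tsv", package = "celltyper")
#' gsc <- load_marker_db(db, species = "human")
#' filter_by_tissue(gsc, "blood")
#' @export
filter_by_tissue <- function(collection, keywords, exact = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    ct_stop("at least one non-empty tissue keyword is required",
            "ct_error_config")
  }
  kw <- tolower(keywords)
  t_low <- tolower(collection$records$tissue)
  if (exact) {
    keep <- t_low %in% kw
  } else {
    keep <- Reduce(`|`, lapply(kw, function(k) grepl(k, t_low, fixed = TRUE)))
  }
  recs <- collection$records[keep, , drop = FALSE]
  if (nrow(recs) == 0) {
    ct_stop(sprintf(
      "no cell types remain after tissue filter (keywords: %s); check keyword spelling against the database tissues",
      paste(keywords, collapse = ", ")), "ct_error_empty")
  }
  gene_set_collection(records = recs, species = collection$species,
                      source_name = collection$source)
}

#' Load a gene symbol to Entrez ID map
#'
#' Reads a two-column TSV (`symbol`, `entrez_id`) into a named lookup
#' vector.  The mapping must be functional: each symbol maps to exactly one
#' ID; duplicated symbols keep their first occurrence with a warning.
#'
#' @param path Path to the mapping TSV.
#' @return Named character vector (names = symbols, values = Entrez IDs)
#'   with attribute `provenance`.
#' @export
load_symbol_map <- function(path) {
  if (!file.exists(path)) {
    ct_stop(sprintf("symbol map file not found: %s", path), "ct_error_io")
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("symbol", "entrez_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    ct_stop(sprintf("symbol map is missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "ct_error_schema")
  }
  dup <- duplicated(raw$symbol)
  if (any(dup)) {
    ct_warn(sprintf("symbol map: %d duplicated symbol(s), keeping first occurrence",
                    sum(dup)))
    raw <- raw[!dup, , drop = FALSE]
  }
  map <- stats::setNames(raw$entrez_id, raw$symbol)
  attr(map, "provenance") <- path
  map
}

#' Convert gene symbols to Entrez IDs
#'
#' Looks up each symbol (case-sensitively) in a symbol map.  Mapped IDs are
#' returned in input order; symbols absent from the map are reported
#' separately and excluded, with a warning — never silently dropped.
#'
#' @param genes Character vector of gene symbols.
#' @param map Named character vector as returned by [load_symbol_map()],
#'   or any named vector symbol -> ID.
#' @return A list with components `ids` (mapped IDs, input order) and
#'   `unmapped` (symbols with no entry).
#' @examples
#' convert_symbols(c("CD19", "MS4A1"), c(CD19 = "930", MS4A1 = "931"))
#' @export
convert_symbols <- function(genes, map) {
  genes <- as.character(genes)
  if (length(genes) == 0) {
    return(list(ids = character(0), unmapped = character(0)))
  }
  hit <- genes %in% names(map)
  ids <- unname(map[genes[hit]])
  unmapped <- genes[!hit]
  if (length(unmapped) > 0) {
    ct_warn(sprintf("%d gene symbol(s) could not be mapped to Entrez IDs and were dropped: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  list(ids = ids, unmapped = unmapped)
}
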