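#' Read a drug half-life table
#'
#' Reads a delimited table of drugs and their terminal half-lives (hours).
#' Rows with missing or non-positive half-lives are skipped with a message;
#' duplicated drug identifiers are an error.
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#' @param id_col,halflife_col Names of the drug-identifier and half-life
#'   columns. Half-life values must already be in hours; no unit conversion
#'   is attempted.
#' @param name_col Optional name of a display-name column.
#' @return A tibble with columns `drug_id`, `half_life_hours` and, when
#'   available, `name`. The number of skipped rows is attached as attribute
#'   `"n_skipped"`.
#' @export
read_halflife_table <- function(path, id_col = "drug_id",
                                halflife_col = "half_life_hours",
                                name_col = NULL) {
  if (!file.exists(path)) abort(sprintf("half-life table not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  for (col in c(id_col, halflife_col)) {
    if (!col %in% names(raw)) {
      abort(sprintf("column `%s` not found in %s.", col, path))
    }
  }
  out <- tibble(
    drug_id = as.character(raw[[id_col]]),
    half_life_hours = suppressWarnings(as.numeric(raw[[halflife_col]]))
  )
  if (!is.null(name_col)) {
    if (!name_col %in% names(raw)) abort(sprintf("column `%s` not found in %s.", name_col, path))
    out$name <- as.character(raw[[name_col]])
  }
  bad <- is.na(out$half_life_hours) | out$half_life_hours <= 0
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    inform(sprintf("read_halflife_table: skipped %d row(s) with missing or non-positive half-life.",
                   n_skipped))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) abort(sprintf("no parsable half-life rows in %s.", path))
  dup <- duplicated(out$drug_id)
  if (any(dup)) {
    abort(sprintf("duplicated drug_id(s) in %s: %s", path,
                  paste(unique(out$drug_id[dup]), collapse = ", ")))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Normalize STITCH chemical identifiers
#'
#' STITCH encodes PubChem compounds as `CIDmNNNNNNNN` (the "merged"
#' stereo-unaware flavor) and `CIDsNNNNNNNN` (stereo-specific). The prefix
#' and leading zeros are stripped; with `merge_stereo = TRUE` (default) both
#' flavors of the same numeric CID collapse to one drug identifier, otherwise
#' the flavor letter is kept as a suffix (`"1234.m"`, `"1234.s"`).
#' Identifiers without a `CID[ms]` prefix pass through unchanged.
#'
#' @param x Character vector of chemical identifiers.
#' @param merge_stereo Merge the two stereo flavors of a CID?
#' @return Character vector of normalized drug identifiers.
#' @keywords internal
normalize_chemical_id <- function(x, merge_stereo = TRUE) {
  is_cid <- grepl("^CID[ms][0-9]+$", x)
  flavor <- substr(x, 4L, 4L)
  num <- sub("^0+", "", substr(x, 5L, nchar(x)))
  num[num == ""] <- "0"
  out <- x
  out[is_cid] <- if (merge_stereo) num[is_cid] else paste0(num[is_cid], ".", flavor[is_cid])
  out
}

#' Read a STITCH-dialect protein-chemical links file
#'
#' Parses a tab-separated `protein_chemical.links` file (columns `chemical`,
#' `protein`, `combined_score`; optionally gzipped, with or without the
#' standard header line). Only links whose protein identifier starts with
#' `organism_prefix` and whose score is at least `min_score` are retained;
#' the organism prefix is stripped from protein identifiers, which are
#' otherwise treated as opaque strings. Duplicate links collapse to one
#' (set semantics).
#'
#' @param path Path to the links file.
#' @param min_score Minimum `combined_score` to retain a link. The default 0
#'   keeps every interaction.
#' @param organism_prefix Protein-identifier prefix selecting the organism
#'   (default `"9606."`, human).
#' @param merge_stereo Merge CIDm/CIDs flavors of a chemical; see
#'   [normalize_chemical_id()].
#' @return An `interaction_map`: a tibble of distinct (`drug_id`, `protein`)
#'   pairs with attributes `universe` (character vector of all retained
#'   proteins) and `min_score`.
#' @export
read_stitch_links <- function(path, min_score = 0, organism_prefix = "9606.",
                              merge_stereo = TRUE) {
  if (!file.exists(path)) abort(sprintf("links file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) && grepl("^chemical\t", lines[[1]])) {
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn(sprintf("no data lines in %s; returning an empty interaction map.", path))
    return(interaction_map(tibble(drug_id = character(), protein = character()),
                           universe = character(), min_score = min_score))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    abort(sprintf("malformed links line %d in %s: expected 3 tab-separated fields, got %d.",
                  which(nf != 3L)[1L], path, nf[nf != 3L][1L]))
  }
  mat <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  score <- suppressWarnings(as.integer(mat[, 3L]))
  if (anyNA(score)) {
    abort(sprintf("malformed links line %d in %s: combined_score `%s` is not an integer.",
                  which(is.na(score))[1L], path, mat[which(is.na(score))[1L], 3L]))
  }
  keep <- startsWith(mat[, 2L], organism_prefix) & score >= min_score
  pairs <- tibble(
    drug_id = normalize_chemical_id(mat[keep, 1L], merge_stereo = merge_stereo),
    protein = substring(mat[keep, 2L], nchar(organism_prefix) + 1L)
  )
  pairs <- dplyr::distinct(pairs)
  if (nrow(pairs) == 0) {
    warn(sprintf("no links passed the filters (organism `%s`, min_score %d) in %s.",
                 organism_prefix, as.integer(min_score), path))
  }
  interaction_map(pairs, universe = sort(unique(pairs$protein)), min_score = min_score)
}

#' Construct an interaction map
#'
#' @param pairs Tibble of (`drug_id`, `protein`) pairs.
#' @param universe Character vector of protein identifiers; must contain
#'   every protein in `pairs`.
#' @param min_score Confidence cutoff applied at parse time (metadata).
#' @return The pairs tibble with class `interaction_map` and attributes
#'   `universe` and `min_score`.
#' @export
interaction_map <- function(pairs, universe = sort(unique(pairs$protein)),
                            min_score = 0) {
  pairs <- as_tibble(pairs)
  if (!all(c("drug_id", "protein") %in% names(pairs))) {
    abort("`pairs` must have columns `drug_id` and `protein`.")
  }
  stray <- setdiff(pairs$protein, universe)
  if (length(stray)) {
    abort(sprintf("protein(s) outside the declared universe: %s",
                  paste(head(stray, 5L), collapse = ", ")))
  }
  structure(pairs,
            universe = as.character(universe),
            min_score = min_score,
            class = c("interaction_map", class(tibble())))
}

#' Drug protein sets from an interaction map
#'
#' @param interactions An `interaction_map`.
#' @return Named list: `drug_id` -> character vector of proteins, ordered by
#'   drug identifier.
#' @export
drug_protein_sets <- function(interactions) {
  sets <- split(interactions$protein, interactions$drug_id)
  sets[order(names(sets))]
}

#' Read a GMT annotation collection
#'
#' Parses the standard gene-set exchange format: one term per line,
#' `term_id TAB description TAB member TAB member ...`. Lines with fewer
#' than three fields and duplicated term identifiers are errors.
#'
#' @param path Path to a GMT file.
#' @param namespace `"GO"` or `"KEGG"` (metadata tag on the collection).
#' @param universe_size Size N of the background protein universe. When
#'   `NULL`, N defaults to the size of the union of all member sets. N must
#'   be at least that union size.
#' @return An `annotation_collection`: a tibble with columns `term_id`,
#'   `name` and list-column `proteins`, with attributes `namespace` and
#'   `universe_size`.
#' @export
read_gmt <- function(path, namespace = c("GO", "KEGG"), universe_size = NULL) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("no records in GMT file %s.", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    abort(sprintf("GMT line %d in %s has %d field(s); at least 3 (term, description, >=1 member) required.",
                  which(nf < 3L)[1L], path, nf[nf < 3L][1L]))
  }
  terms <- tibble(
    term_id = vapply(parts, `[[`, character(1), 1L),
    name = vapply(parts, `[[`, character(1), 2L),
    proteins = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
  empty <- lengths(terms$proteins) == 0L
  if (any(empty)) {
    abort(sprintf("GMT line %d in %s has an empty member list.", which(empty)[1L], path))
  }
  annotation_collection(terms, namespace = namespace, universe_size = universe_size)
}

#' Construct an annotation collection
#'
#' @param terms Tibble with `term_id`, `name` and list-column `proteins`
#'   (non-empty character vectors).
#' @param namespace `"GO"` or `"KEGG"`.
#' @param universe_size Background universe size N, or `NULL` to use the
#'   union of all member sets.
#' @return An `annotation_collection` tibble.
#' @export
annotation_collection <- function(terms, namespace = c("GO", "KEGG"),
                                  universe_size = NULL) {
  namespace <- match.arg(namespace)
  terms <- as_tibble(terms)
  if (!all(c("term_id", "name", "proteins") %in% names(terms))) {
    abort("`terms` must have columns `term_id`, `name` and `proteins`.")
  }
  dup <- duplicated(terms$term_id)
  if (any(dup)) {
    abort(sprintf("duplicated term_id(s): %s",
                  paste(unique(terms$term_id[dup]), collapse = ", ")))
  }
  if (any(lengths(terms$proteins) == 0L)) abort("every term must annotate at least one protein.")
  union_size <- length(unique(unlist(terms$proteins, use.names = FALSE)))
  if (is.null(universe_size)) universe_size <- union_size
  universe_size <- as.integer(universe_size)
  if (universe_size < union_size) {
    abort(sprintf("universe_size (%d) is smaller than the union of member sets (%d).",
                  universe_size, union_size))
  }
  if (universe_size < 1L) abort("universe_size must be positive.")
  structure(terms,
            namespace = namespace,
            universe_size = universe_size,
            class = c("annotation_collection", class(tibble())))
}

# TSV writer preserving doubles bit-exactly: 17 significant digits suffice to
# round-trip any IEEE double through decimal text.
write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  readr::write_tsv(df, path, progress = FALSE)
}

#' Write / read an enrichment matrix as TSV
#'
#' Drugs as rows (first column `drug_id`), terms as columns, full float
#' precision, rows in the matrix's drug order.
#'
#' @param x An `enrichment_matrix` (see [encode_drugs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_matrix <- function(x, path) {
  stopifnot(inherits(x, "enrichment_matrix"))
  if (nrow(x$scores) == 0 || ncol(x$scores) == 0) abort("refusing to write an empty matrix.")
  df <- tibble(drug_id = rownames(x$scores))
  df <- dplyr::bind_cols(df, as_tibble(x$scores))
  write_tsv_full(df, path)
  invisible(path)
}

# Re-reading goes through base as.numeric (correctly rounded strtod) rather
# than the fast vroom double path, which can be off by one ulp.
read_tsv_full <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  num_re <- "^[+-]?([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?|Inf|NaN|NA)$"
  for (col in names(df)) {
    v <- df[[col]]
    if (all(grepl(num_re, v))) df[[col]] <- as.numeric(v)
  }
  df
}

#' @rdname write_enrichment_matrix
#' @param namespace Namespace tag to attach on re-read.
#' @export
read_enrichment_matrix <- function(path, namespace = c("GO", "KEGG")) {
  namespace <- match.arg(namespace)
  df <- read_tsv_full(path)
  df$drug_id <- as.character(df$drug_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$drug_id
  new_enrichment_matrix(m, namespace = namespace, dropped_drugs = character())
}

#' Write a ranked feature list as TSV
#'
#' Columns: `rank`, `term_id`, `name`, `mi` — the layout of a MaxRel table.
#'
#' @param ranked A ranked-list tibble (see [maxrel_rank()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path) {
  if (!is.data.frame(ranked) || nrow(ranked) == 0) abort("refusing to write an empty ranked list.")
  cols <- intersect(c("rank", "term_id", "name", "mi"), names(ranked))
  write_tsv_full(ranked[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- read_tsv_full(path)
  df$term_id <- as.character(df$term_id)
  if ("rank" %in% names(df)) df$rank <- as.integer(df$rank)
  df
}
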