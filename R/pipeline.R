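#' Pipeline configuration
#'
#' Bundles the file paths and parameters of a full analysis run. At least
#' one of `go_gmt` / `kegg_gmt` must be given; each present namespace is
#' encoded, ranked, thresholded and profiled independently.
#'
#' @param halflife Path to the drug half-life table (TSV/CSV, hours).
#' @param links Path to the STITCH-dialect protein-chemical links file.
#' @param go_gmt,kegg_gmt Paths to GMT annotation collections.
#' @param out_dir Output directory.
#' @param min_score Minimum STITCH combined score (default 0: keep all).
#' @param merge_stereo Merge CIDm/CIDs chemical flavors (default TRUE).
#' @param universe_size Background universe size N; `NULL` uses each
#'   collection's member union.
#' @param mi_threshold_go,mi_threshold_kegg MI selection thresholds
#'   (defaults 0.03 and 0.013, inclusive).
#' @param sigma Discretization width multiplier (default 1).
#' @param mi_base MI logarithm base (default 2).
#' @param top_k Optional truncation of the ranked lists before writing.
#' @param id_col,halflife_col Column names in the half-life table.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(halflife, links, go_gmt = NULL, kegg_gmt = NULL,
                            out_dir = "hlenrich_out",
                            min_score = 0, merge_stereo = TRUE,
                            universe_size = NULL,
                            mi_threshold_go = 0.03, mi_threshold_kegg = 0.013,
                            sigma = 1, mi_base = 2, top_k = NULL,
                            id_col = "drug_id", halflife_col = "half_life_hours",
                            seed = 1L) {
  if (is.null(go_gmt) && is.null(kegg_gmt)) {
    abort("at least one of `go_gmt` / `kegg_gmt` is required.")
  }
  if (mi_threshold_go < 0 || mi_threshold_kegg < 0) abort("MI thresholds must be >= 0.")
  structure(list(
    halflife = halflife, links = links, go_gmt = go_gmt, kegg_gmt = kegg_gmt,
    out_dir = out_dir, min_score = min_score, merge_stereo = merge_stereo,
    universe_size = universe_size,
    mi_threshold_go = mi_threshold_go, mi_threshold_kegg = mi_threshold_kegg,
    sigma = sigma, mi_base = mi_base, top_k = top_k,
    id_col = id_col, halflife_col = halflife_col,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML document
#'
#' Keys are the arguments of [pipeline_config()]; `overrides` (e.g. parsed
#' command-line flags) take precedence over file values.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of values overriding the file's.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
          parent = e)
  })
}

#' Run the full half-life enrichment analysis
#'
#' Parse -> categorize -> encode -> rank -> select -> level-profile, writing
#' per namespace an enrichment matrix, the full MaxRel ranked list, the
#' selected-term list and the level-value matrix, plus a JSON manifest
#' recording input checksums, parameters, the category census and the drug
#' attrition chain (parsed -> with interactions -> encoded). Identical
#' configuration and inputs yield identical outputs; partial outputs are
#' removed if any stage fails.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    drugs <- run_stage("parse_halflife", read_halflife_table(
      config$halflife, id_col = config$id_col, halflife_col = config$halflife_col))
    n_parsed <- nrow(drugs)
    n_skipped <- attr(drugs, "n_skipped") %||% 0L
    drugs <- run_stage("categorize", categorize_drugs(drugs))
    census <- category_census(drugs)

    interactions <- run_stage("parse_links", read_stitch_links(
      config$links, min_score = config$min_score, merge_stereo = config$merge_stereo))
    with_links <- intersect(drugs$drug_id, unique(interactions$drug_id))
    n_with_interactions <- length(with_links)
    drugs_linked <- drugs[drugs$drug_id %in% with_links, , drop = FALSE]
    pairs <- interactions[interactions$drug_id %in% with_links, , drop = FALSE]
    interactions <- interaction_map(pairs, universe = attr(interactions, "universe"),
                                    min_score = config$min_score)

    namespaces <- list()
    if (!is.null(config$go_gmt)) namespaces$GO <- list(gmt = config$go_gmt, thr = config$mi_threshold_go)
    if (!is.null(config$kegg_gmt)) namespaces$KEGG <- list(gmt = config$kegg_gmt, thr = config$mi_threshold_kegg)

    ns_manifest <- list()
    for (ns in names(namespaces)) {
      spec <- namespaces[[ns]]
      ann <- run_stage(paste0("parse_gmt_", ns), read_gmt(
        spec$gmt, namespace = ns, universe_size = config$universe_size))
      em <- run_stage(paste0("encode_", ns), encode_drugs(interactions, ann))
      encoded_ids <- rownames(em$scores)
      labels <- drugs_linked$category[match(encoded_ids, drugs_linked$drug_id)]
      term_names <- setNames(ann$name, ann$term_id)
      ranked <- run_stage(paste0("rank_", ns), maxrel_rank(
        em, labels, sigma = config$sigma, base = config$mi_base, names = term_names))
      if (!is.null(config$top_k)) ranked <- head(ranked, config$top_k)
      selected <- run_stage(paste0("select_", ns), select_features(ranked, spec$thr))
      if (nrow(selected) == 0) {
        abort(sprintf("no %s terms reach the MI threshold %g.", ns, spec$thr))
      }
      levels_mat <- run_stage(paste0("levels_", ns), level_values(
        em, labels, selected_terms = selected$term_id))

      prefix <- file.path(config$out_dir, tolower(ns))
      files <- c(
        matrix = paste0(prefix, "_enrichment_matrix.tsv"),
        ranked = paste0(prefix, "_maxrel_ranking.tsv"),
        selected = paste0(prefix, "_selected_terms.tsv"),
        levels = paste0(prefix, "_level_values.tsv")
      )
      write_enrichment_matrix(em, files[["matrix"]])
      write_ranked_list(ranked, files[["ranked"]])
      write_ranked_list(selected, files[["selected"]])
      write_level_matrix(levels_mat, files[["levels"]])
      written <- c(written, unname(files))

      ns_manifest[[ns]] <- list(
        gmt = spec$gmt,
        n_terms = nrow(ann),
        universe_size = attr(ann, "universe_size"),
        n_encoded = nrow(em$scores),
        n_dropped_empty = length(em$dropped_drugs),
        mi_threshold = spec$thr,
        n_selected = nrow(selected),
        files = as.list(files)
      )
    }

    inputs <- Filter(Negate(is.null),
                     list(halflife = config$halflife, links = config$links,
                          go_gmt = config$go_gmt, kegg_gmt = config$kegg_gmt))
    manifest <- list(
      inputs = lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
      parameters = config[c("min_score", "merge_stereo", "mi_threshold_go",
                            "mi_threshold_kegg", "sigma", "mi_base", "top_k",
                            "universe_size", "seed")],
      attrition = list(
        n_parsed = n_parsed,
        n_skipped_rows = n_skipped,
        n_with_interactions = n_with_interactions,
        n_encoded = lapply(ns_manifest, `[[`, "n_encoded")
      ),
      category_census = setNames(as.list(census$n), paste0("category_", census$category)),
      namespaces = ns_manifest
    )
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, manifest_path)
    inform(sprintf("run_pipeline: %d parsed -> %d with interactions; wrote %d files to %s.",
                   n_parsed, n_with_interactions, length(written), config$out_dir))
    invisible(manifest)
  }, error = on_fail_cleanup)
}
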