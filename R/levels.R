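#' Per-category mean enrichment scores ("level values")
#'
#' The level value of a term in a half-life category is the unweighted
#' arithmetic mean of that term's enrichment scores over the drugs of the
#' category. Computed for the selected terms against every requested
#' category.
#'
#' @param em An `enrichment_matrix` or a numeric matrix with drug rownames
#'   and term colnames.
#' @param labels Category labels (integers 1-5) aligned with the matrix rows.
#' @param selected_terms Character vector of term ids; every one must be a
#'   matrix column. Defaults to all terms.
#' @param categories Categories to report; defaults to those present in
#'   `labels`, in increasing order. Requesting a category with zero drugs is
#'   an error (an absent category has no mean, and 0 would be a meaningful
#'   score).
#' @return A `level_matrix` tibble: one row per term, columns `term_id` then
#'   `category_1` ... in increasing category order.
#' @export
level_values <- function(em, labels, selected_terms = NULL, categories = NULL) {
  scores <- if (inherits(em, "enrichment_matrix")) em$scores else as.matrix(em)
  if (length(labels) != nrow(scores)) {
    abort(sprintf("length(labels) is %d but the matrix has %d rows.",
                  length(labels), nrow(scores)))
  }
  if (is.null(selected_terms)) selected_terms <- colnames(scores)
  unknown <- setdiff(selected_terms, colnames(scores))
  if (length(unknown)) {
    abort(sprintf("unknown term_id(s): %s", paste(head(unknown, 5L), collapse = ", ")))
  }
  present <- sort(unique(labels))
  if (is.null(categories)) categories <- present
  missing_cat <- setdiff(categories, present)
  if (length(missing_cat)) {
    abort(sprintf("category(ies) with zero drugs: %s",
                  paste(missing_cat, collapse = ", ")))
  }
  sub <- scores[, selected_terms, drop = FALSE]
  means <- vapply(categories, function(cat) {
    colMeans(sub[labels == cat, , drop = FALSE])
  }, numeric(length(selected_terms)))
  means <- matrix(means, nrow = length(selected_terms),
                  dimnames = list(selected_terms, paste0("category_", categories)))
  out <- dplyr::bind_cols(tibble(term_id = selected_terms), as_tibble(means))
  class(out) <- c("level_matrix", class(out))
  attr(out, "categories") <- as.integer(categories)
  out
}

#' Export a level-value matrix as TSV
#'
#' Terms as rows, categories as columns in increasing category order (the
#' heat-map orientation), regardless of how the object was built.
#'
#' @param level A `level_matrix` from [level_values()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_level_matrix <- function(level, path) {
  if (!is.data.frame(level) || nrow(level) == 0) abort("refusing to write an empty level matrix.")
  cat_cols <- grep("^category_", names(level), value = TRUE)
  ord <- order(as.integer(sub("^category_", "", cat_cols)))
  write_tsv_full(level[, c("term_id", cat_cols[ord]), drop = FALSE], path)
  invisible(path)
}

#' @rdname write_level_matrix
#' @export
read_level_matrix <- function(path) {
  out <- read_tsv_full(path)
  out$term_id <- as.character(out$term_id)
  class(out) <- c("level_matrix", class(out))
  attr(out, "categories") <- as.integer(sub("^category_", "",
                                            grep("^category_", names(out), value = TRUE)))
  out
}

#' Tidy a level matrix into long format
#'
#' @param x A `level_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `term_id`, `category`, `level`.
#' @exportS3Method generics::tidy
tidy.level_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(x), dplyr::starts_with("category_"),
                              names_to = "category", values_to = "level")
  dplyr::mutate(long, category = as.integer(sub("^category_", "", .data$category)))
}

#' Heat map of level values
#'
#' Terms as rows, half-life categories as columns, fill = mean enrichment
#' score.
#'
#' @param object A `level_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.level_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$category),
                                     y = factor(.data$term_id, levels = rev(object$term_id)),
                                     fill = .data$level)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "level value") +
    ggplot2::labs(x = "half-life category", y = NULL,
                  title = "Mean enrichment score per half-life category")
}
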