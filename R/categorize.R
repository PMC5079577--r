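#' Half-life category bin edges (hours)
#'
#' The five categories partition the positive half-life axis: category 1 is
#' t < 1 h, category 2 is 1 <= t < 4 h, category 3 is 4 <= t < 12 h,
#' category 4 is 12 <= t < 24 h, and category 5 is t >= 24 h. Bins are
#' lower-closed / upper-open so that every positive half-life maps to exactly
#' one category.
#'
#' @keywords internal
HALFLIFE_BREAKS <- c(1, 4, 12, 24)

#' Assign a half-life category
#'
#' Maps biological half-lives (hours) to the five-category scheme used
#' throughout the package. Vectorized.
#'
#' @param half_life_hours Numeric vector of positive half-lives, in hours.
#' @return Integer vector of categories in `1:5`.
#' @examples
#' assign_category(c(0.25, 2, 8, 20, 48))
#' @export
assign_category <- function(half_life_hours) {
  if (!is.numeric(half_life_hours)) {
    abort("`half_life_hours` must be numeric.")
  }
  bad <- !is.finite(half_life_hours) | half_life_hours <= 0
  if (any(bad)) {
    abort(sprintf(
      "`half_life_hours` must be finite and positive; offending value(s) at position(s) %s.",
      paste(head(which(bad), 5L), collapse = ", ")
    ))
  }
  findInterval(half_life_hours, HALFLIFE_BREAKS) + 1L
}

#' Categorize a drug table
#'
#' Adds (or overwrites) a `category` column on a drug half-life tibble, as
#' read by [read_halflife_table()].
#'
#' @param drugs A data frame with at least `drug_id` and `half_life_hours`.
#' @return The input as a tibble with an integer `category` column.
#' @seealso [category_census()]
#' @export
categorize_drugs <- function(drugs) {
  drugs <- as_tibble(drugs)
  if (!all(c("drug_id", "half_life_hours") %in% names(drugs))) {
    abort("`drugs` must have columns `drug_id` and `half_life_hours`.")
  }
  dplyr::mutate(drugs, category = assign_category(.data$half_life_hours))
}

#' Category census
#'
#' Counts drugs per half-life category; all five categories always appear,
#' with zero counts where empty.
#'
#' @param drugs A data frame with a `category` column (see
#'   [categorize_drugs()]), or an integer vector of category labels.
#' @return A tibble with columns `category` (1-5) and `n`.
#' @export
category_census <- function(drugs) {
  labels <- if (is.data.frame(drugs)) {
    if (!"category" %in% names(drugs)) {
      abort("`drugs` has no `category` column; run `categorize_drugs()` first.")
    }
    drugs$category
  } else {
    drugs
  }
  if (length(labels) && !all(labels %in% 1:5)) {
    abort("category labels must be integers in 1..5.")
  }
  counts <- tabulate(labels, nbins = 5L)
  tibble(category = 1:5, n = counts)
}
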