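#' Discretize a score vector into three states
#'
#' The convention used by mutual-information feature ranking on continuous
#' features: values below `mean - sigma * s` are `"low"`, above
#' `mean + sigma * s` are `"high"`, and `"mid"` otherwise, where `s` is the
#' population standard deviation of the vector. A constant vector maps
#' entirely to `"mid"`.
#'
#' @param values Non-empty numeric vector.
#' @param sigma Width multiplier on the population standard deviation
#'   (default 1).
#' @return Factor with levels `low`, `mid`, `high`, same length as `values`.
#' @export
discretize_scores <- function(values, sigma = 1) {
  if (!is.numeric(values) || length(values) == 0) abort("`values` must be a non-empty numeric vector.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  mu <- mean(values)
  s <- sqrt(mean((values - mu)^2))
  states <- rep("mid", length(values))
  states[values < mu - sigma * s] <- "low"
  states[values > mu + sigma * s] <- "high"
  factor(states, levels = c("low", "mid", "high"))
}

#' Plug-in mutual information of a contingency table
#'
#' Computes the plug-in estimate
#' \deqn{I(x, y) = \sum_{x,y} p(x,y) \log \frac{p(x,y)}{p(x)\,p(y)}}
#' from a table of joint counts, with zero-probability cells contributing 0.
#' The result is non-negative and 0 exactly when rows and columns are
#' empirically independent.
#'
#' @param counts Non-negative integer matrix: rows = feature states,
#'   columns = class labels (or any two discrete variables).
#' @param base Logarithm base; 2 (bits, the default) or `exp(1)` (nats).
#' @return Mutual information, a non-negative scalar.
#' @examples
#' mutual_information(matrix(c(3, 0, 0, 3), 2)) # 1 bit
#' @export
mutual_information <- function(counts, base = 2) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) abort("`counts` must be non-negative and finite.")
  n <- sum(counts)
  if (n < 1) abort("`counts` must contain at least one observation.")
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  expected <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / expected[nz])) / log(base)
  max(mi, 0)
}

#' Rank terms by mutual information with category labels (Max-Relevance)
#'
#' For every term column of the enrichment matrix: discretize the scores
#' into three states ([discretize_scores()]), cross-tabulate against the
#' half-life category labels, and compute the plug-in mutual information.
#' Terms are returned sorted by descending MI, ties broken by ascending
#' `term_id`, which makes the ranking a deterministic function of its
#' inputs.
#'
#' @param em An `enrichment_matrix` from [encode_drugs()], or a numeric
#'   matrix with drug rownames and term colnames.
#' @param labels Category labels aligned with the matrix rows; at least two
#'   distinct labels must be present.
#' @param sigma Discretization width multiplier, passed to
#'   [discretize_scores()].
#' @param base MI logarithm base (default 2, bits).
#' @param names Optional named character vector (`term_id` -> display name)
#'   used to populate the `name` column.
#' @return A `maxrel_ranking` tibble with columns `rank`, `term_id`, `name`,
#'   `mi`, ordered by rank.
#' @export
maxrel_rank <- function(em, labels, sigma = 1, base = 2, names = NULL) {
  scores <- if (inherits(em, "enrichment_matrix")) em$scores else as.matrix(em)
  if (length(labels) != nrow(scores)) {
    abort(sprintf("length(labels) is %d but the matrix has %d rows.",
                  length(labels), nrow(scores)))
  }
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) abort("at least two distinct category labels are required.")
  term_ids <- colnames(scores)
  mi <- vapply(seq_along(term_ids), function(j) {
    states <- discretize_scores(scores[, j], sigma = sigma)
    mutual_information(table(states, labels), base = base)
  }, numeric(1))
  term_names <- if (is.null(names)) term_ids else unname(names[term_ids])
  out <- tibble(term_id = term_ids, name = term_names, mi = mi)
  out <- dplyr::arrange(out, dplyr::desc(.data$mi), .data$term_id)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  class(out) <- c("maxrel_ranking", class(out))
  attr(out, "sigma") <- sigma
  attr(out, "base") <- base
  out
}

#' Select features at an MI threshold
#'
#' Keeps the entries whose MI value is at least `threshold` (inclusive
#' comparison: published lists contain entries printed exactly at the
#' threshold), preserving rank order. `top_k` optionally truncates the list
#' first.
#'
#' @param ranked A ranked-list tibble with an `mi` column.
#' @param threshold Non-negative MI cutoff.
#' @param top_k Optional truncation applied before thresholding.
#' @return The filtered tibble.
#' @export
select_features <- function(ranked, threshold, top_k = NULL) {
  if (!is.data.frame(ranked) || !"mi" %in% names(ranked)) {
    abort("`ranked` must be a data frame with an `mi` column.")
  }
  if (!is.numeric(threshold) || threshold < 0) abort("`threshold` must be >= 0.")
  if (!is.null(top_k)) ranked <- head(ranked, top_k)
  dplyr::filter(ranked, .data$mi >= threshold)
}

#' @exportS3Method generics::glance
glance.maxrel_ranking <- function(x, ...) {
  tibble(n_terms = nrow(x), mi_max = max(x$mi), mi_min = min(x$mi),
         sigma = attr(x, "sigma"), base = attr(x, "base"))
}

#' Plot a MaxRel ranking as MI against rank
#'
#' @param object A `maxrel_ranking`.
#' @param threshold Optional MI threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.maxrel_ranking <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$mi)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank", y = "mutual information (bits)",
                  title = "Max-Relevance feature ranking")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
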