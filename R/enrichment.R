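# Scores are -log10 of an upper-tail hypergeometric probability; the smallest
# positive double is ~1e-308, so 300 caps the matrix while staying finite.
SCORE_CAP <- 300

#' Hypergeometric upper-tail enrichment score
#'
#' The enrichment score of an overlap of size `m` between a drug's protein
#' set (size `n`) and a term's annotation set (size `M`) over a background
#' universe of `N` proteins is
#' \deqn{-\log_{10} \sum_{k=m}^{\min(n,M)} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},}
#' the upper-tail probability \eqn{P(X \ge m)} of a hypergeometric variable.
#' The tail is evaluated in log space and the score is capped at 300 so the
#' result stays finite when the probability underflows. All arguments are
#' vectorized and recycled.
#'
#' @param N Background universe size (total proteins), `>= 1`.
#' @param M Term annotation-set size, `0 <= M <= N`.
#' @param n Drug protein-set size, `0 <= n <= N`.
#' @param m Overlap size, `0 <= m <= min(n, M)`.
#' @return Non-negative numeric vector of scores; 0 exactly when `m = 0`.
#' @examples
#' hypergeom_tail_score(N = 10, M = 5, n = 4, m = 4) # ~1.623
#' @export
hypergeom_tail_score <- function(N, M, n, m) {
  k <- vapply(list(N = N, M = M, n = n, m = m), length, integer(1))
  len <- max(k)
  args <- list(N = rep_len(N, len), M = rep_len(M, len),
               n = rep_len(n, len), m = rep_len(m, len))
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v) | v < 0 | v != floor(v))) {
      abort(sprintf("`%s` must be a non-negative integer.", nm))
    }
  }
  with(args, {
    if (any(N < 1)) abort("`N` must be at least 1.")
    if (any(M > N)) abort("`M` must not exceed `N`.")
    if (any(n > N)) abort("`n` must not exceed `N`.")
    if (any(m > pmin(n, M))) abort("`m` must not exceed min(`n`, `M`).")
    log_tail <- phyper(m - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE)
    score <- -log_tail / log(10)
    score[m == 0] <- 0
    pmin(pmax(score, 0), SCORE_CAP)
  })
}

new_enrichment_matrix <- function(scores, namespace, dropped_drugs = character()) {
  structure(
    list(scores = scores, namespace = namespace, dropped_drugs = dropped_drugs),
    class = "enrichment_matrix"
  )
}

#' Encode drugs as gene-set enrichment-score vectors
#'
#' Builds the drug x term matrix of hypergeometric enrichment scores: for
#' drug `d` with protein set `P(d)` and term `t` annotating set `P(t)`, the
#' cell is [hypergeom_tail_score()] with `n = |P(d)|`, `M = |P(t)|`,
#' `m = |P(d) intersect P(t)|` and `N` the collection's declared universe
#' size. Drug proteins absent from the annotated universe still count in
#' `n` but can never contribute to `m`. Drugs with an empty protein set are
#' dropped and reported in the result.
#'
#' @param interactions An [interaction_map()].
#' @param annotations An [annotation_collection()].
#' @return An `enrichment_matrix`: list with `scores` (dense numeric matrix,
#'   drugs x terms, dimnames set), `namespace`, and `dropped_drugs`.
#' @export
encode_drugs <- function(interactions, annotations) {
  stopifnot(inherits(annotations, "annotation_collection"))
  if (nrow(annotations) == 0) abort("empty annotation collection.")
  sets <- drug_protein_sets(interactions)
  n_prot <- lengths(sets)
  dropped <- names(sets)[n_prot == 0L]
  sets <- sets[n_prot > 0L]
  if (!length(sets)) abort("all drugs have empty protein sets; nothing to encode.")
  if (length(dropped)) {
    inform(sprintf("encode_drugs: dropped %d drug(s) with empty protein sets.", length(dropped)))
  }

  N <- attr(annotations, "universe_size")
  term_ids <- annotations$term_id
  term_sets <- annotations$proteins
  M <- lengths(term_sets)

  # overlap counts via a shared protein index; drugs x terms cross-tabulation
  prot_index <- sort(unique(unlist(term_sets, use.names = FALSE)))
  term_of <- rep.int(seq_along(term_ids), M)
  prot_of_term <- match(unlist(term_sets, use.names = FALSE), prot_index)

  drug_ids <- names(sets)
  n_draw <- lengths(sets)
  if (any(n_draw > N)) {
    abort("a drug's protein set exceeds the declared universe size N; increase universe_size.")
  }

  # incidence matrices: terms x proteins and drugs x proteins (dense logical;
  # problem sizes here are hundreds x thousands)
  term_inc <- matrix(0L, nrow = length(term_ids), ncol = length(prot_index))
  term_inc[cbind(term_of, prot_of_term)] <- 1L
  drug_prot <- lapply(sets, function(p) match(p, prot_index))
  drug_of <- rep.int(seq_along(sets), lengths(sets))
  hit <- unlist(drug_prot, use.names = FALSE)
  keep <- !is.na(hit)
  drug_inc <- matrix(0L, nrow = length(sets), ncol = length(prot_index))
  if (any(keep)) drug_inc[cbind(drug_of[keep], hit[keep])] <- 1L

  m_overlap <- drug_inc %*% t(term_inc)

  scores <- hypergeom_tail_score(
    N = N,
    M = rep(M, each = length(sets)),
    n = rep.int(n_draw, length(term_ids)),
    m = as.vector(m_overlap)
  )
  scores <- matrix(scores, nrow = length(sets), ncol = length(term_ids),
                   dimnames = list(drug_ids, term_ids))
  new_enrichment_matrix(scores, namespace = attr(annotations, "namespace"),
                        dropped_drugs = dropped)
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix [%s]> %d drugs x %d terms; %d drug(s) dropped (empty sets)\n",
              x$namespace, nrow(x$scores), ncol(x$scores), length(x$dropped_drugs)))
  invisible(x)
}

#' Tidy an enrichment matrix into long format
#'
#' @param x An `enrichment_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `drug_id`, `term_id`, `score`.
#' @exportS3Method generics::tidy
tidy.enrichment_matrix <- function(x, ...) {
  tibble(
    drug_id = rep(rownames(x$scores), times = ncol(x$scores)),
    term_id = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores)
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.enrichment_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble(drug_id = rownames(x$scores)), as_tibble(x$scores))
}

#' @export
dim.enrichment_matrix <- function(x) dim(x$scores)
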