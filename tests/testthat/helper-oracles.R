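# Independent oracles used across the suite.

# Hypergeometric upper tail P(X >= m) by direct enumeration of the pmf
# through binomial-coefficient ratios (no log-space machinery).
hyper_tail_oracle <- function(N, M, n, m) {
  ks <- m:min(n, M)
  sum(vapply(ks, function(k) choose(M, k) * choose(N - M, n - k), numeric(1))) /
    choose(N, n)
}

# Mutual information via the entropy decomposition I = H(X) + H(Y) - H(X,Y),
# an algebraically different route than the plug-in cell sum.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  entropy_bits(rowSums(p)) + entropy_bits(colSums(p)) - entropy_bits(as.vector(p))
}

# Tiny hand-built fixture shared by encoding/ranking tests: 3 drugs over a
# 10-protein universe and 2 terms.
tiny_fixture <- function() {
  pairs <- tibble::tibble(
    drug_id = c(rep("a", 4), rep("b", 3), rep("c", 2)),
    protein = c("P1", "P2", "P3", "P4", "P8", "P9", "P10", "P1", "P6")
  )
  interactions <- interaction_map(pairs, universe = paste0("P", 1:10))
  annotations <- annotation_collection(
    tibble::tibble(
      term_id = c("T1", "T2"),
      name = c("term one", "term two"),
      proteins = list(c("P1", "P2", "P3", "P4", "P5"), c("P6", "P7"))
    ),
    namespace = "GO", universe_size = 10
  )
  list(interactions = interactions, annotations = annotations)
}

# Extends a packaged reference ranked list with n synthetic below-threshold
# filler rows, mimicking the untruncated tail of a MaxRel list.
with_filler_tail <- function(ranked, n, below) {
  filler <- tibble::tibble(
    rank = max(ranked$rank) + seq_len(n),
    term_id = sprintf("FILL:%04d", seq_len(n)),
    name = "synthetic filler term",
    mi = seq(below * 0.9, 0, length.out = n)
  )
  dplyr::bind_rows(ranked, filler)
}
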