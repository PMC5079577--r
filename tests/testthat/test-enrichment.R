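test_that("tail scores match hand-derived values", {
  expect_equal(hypergeom_tail_score(N = 10, M = 5, n = 4, m = 0), 0)
  # P = C(5,4)/C(10,4) = 5/210
  expect_equal(hypergeom_tail_score(N = 10, M = 5, n = 4, m = 4),
               -log10(5 / 210), tolerance = 1e-12)
  # symmetric tail: P(X >= 3) = 0.5
  expect_equal(hypergeom_tail_score(N = 20, M = 10, n = 5, m = 3),
               -log10(0.5), tolerance = 1e-12)
})

test_that("tail scores agree with exact pmf enumeration across a parameter grid", {
  set.seed(11)
  for (i in 1:400) {
    N <- sample(1:60, 1)
    M <- sample(0:N, 1)
    n <- sample(0:N, 1)
    m <- sample(0:min(n, M), 1)
    p_impl <- 10^(-hypergeom_tail_score(N, M, n, m))
    p_oracle <- hyper_tail_oracle(N, M, n, m)
    expect_equal(p_impl, p_oracle, tolerance = 1e-9,
                 label = sprintf("P(N=%d,M=%d,n=%d,m=%d)", N, M, n, m))
  }
})

test_that("scores are monotone in the overlap and zero exactly at m = 0", {
  for (m in 0:9) {
    s <- hypergeom_tail_score(100, 20, 10, 0:min(10, 20))
    expect_true(all(diff(s) >= 0))
  }
  expect_identical(hypergeom_tail_score(50, 10, 5, 0), 0)
  expect_true(all(hypergeom_tail_score(50, 10, 5, 1:5) > 0))
})

test_that("underflowing tails are capped, not infinite", {
  s <- hypergeom_tail_score(N = 20000, M = 4000, n = 4000, m = 4000)
  expect_true(is.finite(s))
  expect_equal(s, 300)
})

test_that("precondition violations name the offending parameter", {
  expect_error(hypergeom_tail_score(0, 0, 0, 0), "`N`")
  expect_error(hypergeom_tail_score(10, 11, 5, 0), "`M`")
  expect_error(hypergeom_tail_score(10, 5, 11, 0), "`n`")
  expect_error(hypergeom_tail_score(10, 5, 4, 5), "`m`")
  expect_error(hypergeom_tail_score(10, 5, 4, -1), "`m`")
  expect_error(hypergeom_tail_score(10.5, 5, 4, 1), "`N`")
})

test_that("drug encoding fills cells from set overlaps and drops empty drugs", {
  fx <- tiny_fixture()
  em <- encode_drugs(fx$interactions, fx$annotations)
  expect_identical(dim(em), c(3L, 2L))
  # drug a: P(a) = {P1..P4} is a subset of T1 (M=5, N=10, n=4, m=4)
  expect_equal(em$scores["a", "T1"], -log10(5 / 210), tolerance = 1e-12)
  # drug b: {P8,P9,P10} disjoint from both terms -> row of zeros
  expect_identical(unname(em$scores["b", ]), c(0, 0))
  # drug c: {P1,P6} overlaps both terms once
  expect_equal(em$scores["c", "T1"], -log10(hyper_tail_oracle(10, 5, 2, 1)),
               tolerance = 1e-12)
  expect_equal(em$scores["c", "T2"], -log10(hyper_tail_oracle(10, 2, 2, 1)),
               tolerance = 1e-12)
})

test_that("drugs with empty protein sets are excluded and reported", {
  fx <- tiny_fixture()
  pairs <- dplyr::bind_rows(
    tibble::as_tibble(fx$interactions),
    tibble::tibble(drug_id = character(), protein = character())
  )
  # represent an empty-set drug explicitly through drug_protein_sets on a
  # filtered map: drop all links of drug "b"
  kept <- pairs[pairs$drug_id != "b", ]
  im <- interaction_map(kept, universe = attr(fx$interactions, "universe"))
  em <- encode_drugs(im, fx$annotations)
  expect_identical(rownames(em$scores), c("a", "c"))
})

test_that("drug proteins outside the annotation universe count in n but never in m", {
  pairs <- tibble::tibble(drug_id = rep("d", 4),
                          protein = c("P1", "X1", "X2", "X3"))
  im <- interaction_map(pairs, universe = c("P1", "P2", "X1", "X2", "X3"))
  ann <- annotation_collection(
    tibble::tibble(term_id = "T1", name = "t", proteins = list(c("P1", "P2"))),
    namespace = "GO", universe_size = 10
  )
  em <- encode_drugs(im, ann)
  expect_equal(em$scores["d", "T1"], -log10(hyper_tail_oracle(10, 2, 4, 1)),
               tolerance = 1e-12)
})

test_that("uniform protein relabeling leaves the score matrix unchanged", {
  fx <- tiny_fixture()
  em1 <- encode_drugs(fx$interactions, fx$annotations)
  relabel <- setNames(paste0("Q", 10:1), paste0("P", 1:10))
  pairs <- dplyr::mutate(tibble::as_tibble(fx$interactions),
                         protein = unname(relabel[protein]))
  im2 <- interaction_map(pairs, universe = unname(relabel))
  ann2 <- annotation_collection(
    dplyr::mutate(tibble::as_tibble(fx$annotations),
                  proteins = lapply(proteins, function(p) unname(relabel[p]))),
    namespace = "GO", universe_size = 10
  )
  em2 <- encode_drugs(im2, ann2)
  expect_equal(em2$scores, em1$scores)
})

test_that("tidy and as_tibble views expose the matrix consistently", {
  fx <- tiny_fixture()
  em <- encode_drugs(fx$interactions, fx$annotations)
  long <- generics::tidy(em)
  expect_equal(nrow(long), prod(dim(em)))
  expect_equal(long$score[long$drug_id == "a" & long$term_id == "T1"],
               em$scores["a", "T1"])
  wide <- tibble::as_tibble(em)
  expect_identical(wide$drug_id, rownames(em$scores))
})
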