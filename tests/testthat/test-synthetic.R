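test_that("generation is byte-identical under a fixed seed", {
  cfg <- syn_config(n_drugs = 60, n_proteins = 400, n_terms = 40, seed = 4L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$drugs, d2$drugs)
  expect_identical(tibble::as_tibble(d1$interactions), tibble::as_tibble(d2$interactions))
  expect_identical(d1$annotations$proteins, d2$annotations$proteins)
  expect_identical(d1$planted, d2$planted)
  d3 <- generate_dataset(syn_config(n_drugs = 60, n_proteins = 400, n_terms = 40, seed = 5L))
  expect_false(identical(d1$drugs$half_life_hours, d3$drugs$half_life_hours))
})

test_that("sampled half-lives round-trip through category assignment", {
  ds <- generate_dataset(syn_config(n_drugs = 200, seed = 2L))
  expect_identical(assign_category(ds$drugs$half_life_hours), ds$drugs$category)
  expect_identical(sum(category_census(ds$drugs)$n), 200L)
})

test_that("exact counts follow the declared category proportions", {
  ds <- generate_dataset(syn_config(n_drugs = 565, exact_counts = TRUE, seed = 1L))
  expect_identical(category_census(ds$drugs)$n, c(56L, 231L, 154L, 61L, 63L))
})

test_that("planted terms overlap their target category more than the rest", {
  ds <- generate_dataset(syn_config(seed = 1L))
  sets <- drug_protein_sets(ds$interactions)
  for (i in seq_len(nrow(ds$planted))) {
    tid <- ds$planted$term_id[i]
    target <- ds$planted$category[i]
    tset <- ds$annotations$proteins[[match(tid, ds$annotations$term_id)]]
    overlap <- vapply(sets, function(p) length(intersect(p, tset)), numeric(1))
    in_cat <- ds$drugs$category[match(names(sets), ds$drugs$drug_id)] == target
    expect_gt(mean(overlap[in_cat]), mean(overlap[!in_cat]))
  }
})

test_that("a null construction (rho = 0) does not elevate planted terms", {
  top_frac <- vapply(1:5, function(seed) {
    ds <- generate_dataset(syn_config(n_drugs = 150, n_proteins = 800, n_terms = 100,
                                      rho = 0, seed = seed))
    em <- encode_drugs(ds$interactions, ds$annotations)
    labels <- ds$drugs$category[match(rownames(em$scores), ds$drugs$drug_id)]
    ranked <- maxrel_rank(em, labels)
    mean(ds$planted$term_id %in% head(ranked$term_id, 15))
  }, numeric(1))
  # 10 planted among 100 terms: top-15 membership should look like chance,
  # not systematic recovery
  expect_lt(mean(top_frac), 0.5)
})

test_that("stronger planting does not weaken the weakest planted term", {
  min_mi <- vapply(c(0.2, 0.8), function(rho) {
    ds <- generate_dataset(syn_config(n_drugs = 150, n_proteins = 800, n_terms = 100,
                                      rho = rho, seed = 7L))
    em <- encode_drugs(ds$interactions, ds$annotations)
    labels <- ds$drugs$category[match(rownames(em$scores), ds$drugs$drug_id)]
    ranked <- maxrel_rank(em, labels)
    min(ranked$mi[ranked$term_id %in% ds$planted$term_id])
  }, numeric(1))
  expect_gte(min_mi[2], min_mi[1])
})

test_that("recovery reports are monotone in k and hit their closed forms", {
  ranked <- tibble::tibble(term_id = c("A", "B", "C", "D"), mi = c(4, 3, 2, 1))
  full <- recovery_report(ranked, c("A", "B"), k = c(1, 2, 4))
  expect_equal(full$recall, c(0.5, 1, 1))
  none <- recovery_report(ranked, c("X", "Y"), k = c(2, 4))
  expect_equal(none$recall, c(0, 0))
  set.seed(12)
  shuffled <- ranked[sample(4), ]
  rep <- recovery_report(shuffled, c("A", "D"), k = 1:4)
  expect_true(all(diff(rep$recall) >= 0))
  expect_error(recovery_report(ranked, character(0)), "at least one")
})

test_that("persisted datasets re-enter the pipeline unchanged", {
  ds <- generate_dataset(syn_config(n_drugs = 40, n_proteins = 300, n_terms = 30, seed = 3L))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  drugs <- read_halflife_table(paths$halflife)
  expect_equal(dplyr::arrange(drugs, as.integer(drug_id))$half_life_hours,
               ds$drugs$half_life_hours)
  im <- read_stitch_links(paths$links)
  sort_pairs <- function(x) {
    df <- as.data.frame(x)[, c("drug_id", "protein")]
    df <- df[order(df$drug_id, df$protein), ]
    rownames(df) <- NULL
    df
  }
  expect_identical(sort_pairs(im), sort_pairs(ds$interactions))
  ann <- read_gmt(paths$gmt, namespace = "GO", universe_size = 300)
  expect_identical(ann$term_id, ds$annotations$term_id)
  expect_identical(ann$proteins, ds$annotations$proteins)
})

test_that("infeasible configurations are rejected", {
  expect_error(syn_config(n_planted = 300), "n_planted")
  expect_error(syn_config(rho = 1.2), "rho")
  expect_error(syn_config(drug_set_size_range = c(1, 3), n_planted = 10), "infeasible")
  expect_error(syn_config(category_proportions = c(1, 1, 1, 1)), "5 non-negative")
})
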