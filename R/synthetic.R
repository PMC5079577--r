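# Half-life sampling windows per category, hours. Category bins are
# lower-closed/upper-open; sampling stays strictly inside each bin.
SYN_HALFLIFE_LOWER <- c(0.05, 1, 4, 12, 24)
SYN_HALFLIFE_UPPER <- c(1, 4, 12, 24, 120)

#' Synthetic-benchmark configuration
#'
#' Defaults emulate the study conditions the pipeline is built for: five
#' half-life categories in the published 56:231:154:61:63 proportions, a
#' 2000-protein universe, 200 annotation terms of 10-80 proteins, drug
#' protein sets of 5-40 proteins, and 10 planted terms whose protein sets
#' are overrepresented (fraction `rho` of each planted term's proteins
#' forced into its target category's drugs) so that ranking recovery can be
#' measured against known ground truth.
#'
#' @param n_drugs Number of drugs (default 300).
#' @param category_proportions Length-5 non-negative vector, normalized
#'   internally; default the published category distribution.
#' @param n_proteins Protein universe size (default 2000).
#' @param n_terms Number of annotation terms (default 200).
#' @param term_size_range Integer range of term set sizes (default 10-80).
#' @param drug_set_size_range Integer range of drug protein-set sizes
#'   (default 5-40).
#' @param n_planted Number of planted informative terms (default 10),
#'   assigned round-robin to categories 1-5.
#' @param rho Planting strength in `[0, 1]`: the fraction of a planted
#'   term's proteins forced into each target-category drug's set, capped by
#'   the drug's share of set capacity (default 0.8). `rho = 0` is the null
#'   construction.
#' @param exact_counts Use exact (largest-remainder) category counts instead
#'   of a multinomial draw.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A validated `syn_config` list.
#' @export
syn_config <- function(n_drugs = 300,
                       category_proportions = c(56, 231, 154, 61, 63),
                       n_proteins = 2000,
                       n_terms = 200,
                       term_size_range = c(10L, 80L),
                       drug_set_size_range = c(5L, 40L),
                       n_planted = 10,
                       rho = 0.8,
                       exact_counts = FALSE,
                       seed = 1L) {
  if (length(category_proportions) != 5 || any(category_proportions < 0) ||
      sum(category_proportions) <= 0) {
    abort("`category_proportions` must be 5 non-negative values with a positive sum.")
  }
  category_proportions <- category_proportions / sum(category_proportions)
  if (n_planted > n_terms) abort("`n_planted` must not exceed `n_terms`.")
  if (rho < 0 || rho > 1) abort("`rho` must be in [0, 1].")
  if (max(term_size_range) > n_proteins || max(drug_set_size_range) > n_proteins) {
    abort("set size ranges must fit inside the protein universe.")
  }
  n_per_cat <- ceiling(n_planted / 5)
  if (rho > 0 && min(drug_set_size_range) < n_per_cat) {
    abort("infeasible config: smallest drug set cannot hold one protein per applicable planted term.")
  }
  structure(list(
    n_drugs = as.integer(n_drugs),
    category_proportions = category_proportions,
    n_proteins = as.integer(n_proteins),
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    drug_set_size_range = as.integer(drug_set_size_range),
    n_planted = as.integer(n_planted),
    rho = rho,
    exact_counts = isTRUE(exact_counts),
    seed = as.integer(seed)
  ), class = "syn_config")
}

# uniform integer draws on [lo, hi]; safe when lo == hi (unlike sample(seq))
sample_int_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

largest_remainder_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a planted-signal synthetic dataset
#'
#' Produces drugs with half-lives sampled inside their assigned category's
#' bin, a flat annotation collection over a protein universe, and a
#' drug-protein interaction map in which each planted term's proteins are
#' overrepresented among drugs of its target category: each such drug's set
#' receives `ceiling(rho * |term|)` proteins sampled from the term, capped
#' at the drug's share of its set capacity when several planted terms target
#' the same category. All remaining proteins are drawn uniformly from the
#' universe; non-planted term sets are uniform draws.
#'
#' @param config A [syn_config()].
#' @return A `syn_dataset` list: `drugs` (tibble: drug_id, half_life_hours,
#'   category), `interactions` ([interaction_map()]), `annotations`
#'   ([annotation_collection()]), and `planted` (tibble: term_id, category
#'   — the ground-truth registry).
#' @export
generate_dataset <- function(config = syn_config()) {
  stopifnot(inherits(config, "syn_config"))
  withr::with_seed(config$seed, {
    counts <- if (config$exact_counts) {
      largest_remainder_counts(config$n_drugs, config$category_proportions)
    } else {
      as.integer(stats::rmultinom(1, config$n_drugs, config$category_proportions))
    }
    cats <- rep.int(1:5, counts)
    half_life <- runif(config$n_drugs,
                       SYN_HALFLIFE_LOWER[cats], SYN_HALFLIFE_UPPER[cats])
    drugs <- tibble(
      drug_id = as.character(seq_len(config$n_drugs)),
      half_life_hours = half_life,
      category = cats
    )

    proteins <- sprintf("P%05d", seq_len(config$n_proteins))
    term_ids <- sprintf("T%04d", seq_len(config$n_terms))
    term_sizes <- sample_int_range(config$term_size_range[1], config$term_size_range[2],
                                   config$n_terms)
    term_sets <- lapply(term_sizes, function(s) sort(sample(proteins, s)))
    names(term_sets) <- term_ids

    planted_idx <- round(seq(1, config$n_terms, length.out = config$n_planted))
    planted <- tibble(
      term_id = term_ids[planted_idx],
      category = rep_len(1:5, config$n_planted)
    )

    pairs <- vector("list", config$n_drugs)
    for (i in seq_len(config$n_drugs)) {
      s <- sample_int_range(config$drug_set_size_range[1], config$drug_set_size_range[2], 1L)
      forced <- character(0)
      applicable <- planted$term_id[planted$category == cats[i]]
      if (config$rho > 0 && length(applicable)) {
        cap_per <- s %/% length(applicable)
        if (cap_per < 1) {
          abort(sprintf("infeasible draw: drug set of size %d cannot host %d planted term(s).",
                        s, length(applicable)))
        }
        for (tid in sort(applicable)) {
          tset <- term_sets[[tid]]
          k <- min(ceiling(config$rho * length(tset)), cap_per)
          forced <- union(forced, sample(tset, k))
        }
        forced <- forced[seq_len(min(length(forced), s))]
      }
      filler <- sample(setdiff(proteins, forced), s - length(forced))
      pairs[[i]] <- sort(c(forced, filler))
    }

    interactions <- interaction_map(
      tibble(
        drug_id = rep(drugs$drug_id, lengths(pairs)),
        protein = unlist(pairs, use.names = FALSE)
      ),
      universe = proteins
    )
    annotations <- annotation_collection(
      tibble(term_id = term_ids,
             name = paste("synthetic term", term_ids),
             proteins = unname(term_sets)),
      namespace = "GO",
      universe_size = config$n_proteins
    )
    structure(list(drugs = drugs, interactions = interactions,
                   annotations = annotations, planted = planted,
                   config = config),
              class = "syn_dataset")
  })
}

#' @export
print.syn_dataset <- function(x, ...) {
  cat(sprintf("<syn_dataset> %d drugs, %d proteins, %d terms (%d planted), rho = %g, seed = %d\n",
              nrow(x$drugs), x$config$n_proteins, nrow(x$annotations),
              nrow(x$planted), x$config$rho, x$config$seed))
  invisible(x)
}

#' Persist a synthetic dataset as the three pipeline input files
#'
#' Writes a half-life TSV, a STITCH-dialect links TSV (chemical ids in the
#' `CIDm` flavor, constant confidence score), and a GMT annotation file, so
#' the full pipeline can be exercised from files.
#'
#' @param dataset A `syn_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named list of the three paths (`halflife`, `links`, `gmt`),
#'   invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "syn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    halflife = file.path(dir, "halflife.tsv"),
    links = file.path(dir, "links.tsv"),
    gmt = file.path(dir, "annotations.gmt")
  )
  readr::write_tsv(dataset$drugs[, c("drug_id", "half_life_hours")],
                   paths$halflife, progress = FALSE)
  links <- tibble(
    chemical = sprintf("CIDm%08d", as.integer(dataset$interactions$drug_id)),
    protein = paste0("9606.", dataset$interactions$protein),
    combined_score = 900L
  )
  readr::write_tsv(links, paths$links, progress = FALSE)
  gmt_lines <- vapply(seq_len(nrow(dataset$annotations)), function(i) {
    paste(c(dataset$annotations$term_id[i], dataset$annotations$name[i],
            dataset$annotations$proteins[[i]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, paths$gmt)
  invisible(paths)
}

#' Planted-term recovery report
#'
#' For each cutoff `k`, the fraction of planted terms found among the top
#' `k` ranks of a MaxRel list — the recovery instrument for the synthetic
#' benchmark.
#'
#' @param ranked A ranked-list tibble ([maxrel_rank()]).
#' @param registry The planted-term registry: a tibble with a `term_id`
#'   column (as in `syn_dataset$planted`) or a character vector of term ids.
#' @param k Integer vector of cutoffs.
#' @return A tibble with columns `k` and `recall`.
#' @export
recovery_report <- function(ranked, registry, k = c(5, 10, 15, 20, 50)) {
  ids <- if (is.data.frame(registry)) registry$term_id else as.character(registry)
  if (!length(ids)) abort("`registry` must name at least one planted term.")
  tibble(
    k = as.integer(k),
    recall = vapply(k, function(kk) {
      mean(ids %in% head(ranked$term_id, kk))
    }, numeric(1))
  )
}
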