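#' Configuration for the synthetic benchmark generator
#'
#' Describes a synthetic drug-indication benchmark with the statistical
#' structure the interaction method relies on: drugs sharing an
#' indication are connected more often than drugs that do not (label
#' homophily), and descriptor vectors of drugs in the same category point
#' in similar directions. Defaults emulate the cancer benchmark's shape:
#' 8 categories, a modest multi-label fraction, and STITCH-like integer
#' confidence scores on the 0--1000 scale.
#'
#' @param n_drugs Number of drugs.
#' @param n_categories Number of indication categories M (>= 2).
#' @param category_weights Probability vector of length M for the primary
#'   label (uniform by default; normalised to sum to 1).
#' @param multi_label_prob Probability that a drug receives a second,
#'   distinct label (default 18/68, the benchmark's multi-label drug
#'   fraction).
#' @param p_within Edge probability for drug pairs sharing at least one
#'   label.
#' @param p_between Edge probability for pairs sharing none. Homophily
#'   requires `p_within >= p_between`.
#' @param score_range Integer range confidence scores of label-sharing
#'   (within-category) edges are drawn from, uniformly (default 150--999,
#'   the usable part of the 0--1000 scale).
#' @param score_range_between Integer score range for edges between drugs
#'   sharing no label; defaults to `score_range`. Setting it lower than
#'   `score_range` puts the homophily signal into the score magnitudes
#'   (weighted homophily) rather than, or in addition to, the topology —
#'   the regime the score-permutation control is sensitive to.
#' @param descriptor_dim Descriptor vector dimension.
#' @param descriptor_effect Within-category mean shift of descriptors;
#'   0 gives pure noise, larger values raise within-category cosine
#'   similarity.
#' @param category_counts Optional integer vector of exact per-category
#'   label counts (exact-count mode); overrides `category_weights`.
#' @param n_multi Number of multi-label (>= 2 indications) drugs in
#'   exact-count mode; defaults to `min(n_drugs, sum(category_counts) -
#'   n_drugs)`, i.e. extra labels are spread over as many drugs as
#'   possible. Must satisfy `n_multi <= extra <= n_multi * (M - 1)` where
#'   `extra = sum(category_counts) - n_drugs`.
#' @param seed Integer seed; same seed, same bundle, byte-identical
#'   fixtures.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 60L,
                             n_categories = 8L,
                             category_weights = NULL,
                             multi_label_prob = 18 / 68,
                             p_within = 0.3,
                             p_between = 0.05,
                             score_range = c(150L, 999L),
                             score_range_between = NULL,
                             descriptor_dim = 32L,
                             descriptor_effect = 2,
                             category_counts = NULL,
                             n_multi = NULL,
                             seed = 1L) {
  if (n_categories < 2L) stop("need n_categories >= 2", call. = FALSE)
  if (n_drugs < 2L) stop("need n_drugs >= 2", call. = FALSE)
  category_weights <- category_weights %||% rep(1 / n_categories,
                                                n_categories)
  if (length(category_weights) != n_categories ||
      any(category_weights < 0) || sum(category_weights) <= 0)
    stop("category_weights must be a non-negative vector of length M",
         call. = FALSE)
  category_weights <- category_weights / sum(category_weights)
  for (p in c(multi_label_prob, p_within, p_between))
    if (p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(category_counts)) {
    if (length(category_counts) != n_categories)
      stop("category_counts must have length n_categories", call. = FALSE)
    extra <- sum(category_counts) - n_drugs
    if (extra < 0L)
      stop("exact-count mode needs sum(category_counts) >= n_drugs",
           call. = FALSE)
    if (max(category_counts) > n_drugs)
      stop("a category cannot have more drugs than n_drugs", call. = FALSE)
    n_multi <- n_multi %||% min(n_drugs, extra)
    if (n_multi > n_drugs || extra < n_multi ||
        extra > n_multi * (n_categories - 1L))
      stop("n_multi incompatible with category_counts: need n_multi <= ",
           "extra labels <= n_multi * (M - 1)", call. = FALSE)
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_categories = as.integer(n_categories),
                 category_weights = category_weights,
                 multi_label_prob = multi_label_prob,
                 p_within = p_within, p_between = p_between,
                 score_range = as.integer(score_range),
                 score_range_between =
                   as.integer(score_range_between %||% score_range),
                 descriptor_dim = as.integer(descriptor_dim),
                 descriptor_effect = descriptor_effect,
                 category_counts = category_counts,
                 n_multi = if (is.null(category_counts)) NULL
                           else as.integer(n_multi),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic benchmark bundle
#'
#' Draws a labelled drug set, a homophilous interaction network and a
#' descriptor matrix from a [synthetic_config()]. Labels are sampled from
#' the category weights with an optional second label per drug, or, in
#' exact-count mode, assigned without replacement so the per-category
#' column sums match `category_counts` exactly. Edges appear
#' independently with probability `p_within` for label-sharing pairs and
#' `p_between` otherwise; scores are uniform integers in `score_range`
#' for label-sharing pairs and `score_range_between` for the rest.
#' Each category has a random direction in descriptor space; a drug's
#' descriptor vector is the mean of its categories' directions scaled by
#' `descriptor_effect` plus standard normal noise.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `drugs` ([drug_set()]), `network`
#'   ([interaction_network()]), `descriptors` ([descriptor_matrix()]) and
#'   `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    cats <- label_catalog(paste0("C", seq_len(cfg$n_categories)))
    ids <- sprintf("drug%03d", seq_len(cfg$n_drugs))
    lab <- draw_labels(cfg)
    drugs <- drug_set(ids, lab, cats)
    net <- draw_network(cfg, ids, lab)
    desc <- draw_descriptors(cfg, ids, lab)
    list(drugs = drugs, network = net, descriptors = desc, config = cfg)
  })
}

draw_labels <- function(cfg) {
  n <- cfg$n_drugs; m <- cfg$n_categories
  lab <- matrix(0L, n, m)
  if (is.null(cfg$category_counts)) {
    primary <- sample.int(m, n, replace = TRUE,
                          prob = cfg$category_weights)
    lab[cbind(seq_len(n), primary)] <- 1L
    second <- stats::runif(n) < cfg$multi_label_prob
    for (i in which(second)) {
      w <- cfg$category_weights
      w[primary[i]] <- 0
      if (sum(w) == 0) next
      lab[i, sample.int(m, 1L, prob = w)] <- 1L
    }
  } else {
    # exact-count mode: deal shuffled category slots so column sums hit
    # category_counts exactly; n_multi drugs get >= 2 distinct labels.
    # Greedy deal with restarts (collisions are cheap at benchmark sizes).
    n_multi <- cfg$n_multi
    extra <- sum(cfg$category_counts) - n
    for (attempt in seq_len(1000L)) {
      cand <- exact_label_attempt(n, m, cfg$category_counts, n_multi,
                                  extra)
      if (!is.null(cand)) return(cand)
    }
    stop("could not satisfy exact category counts; counts too skewed",
         call. = FALSE)
  }
  lab
}

# one randomised attempt at an exact-marginal label matrix; NULL on a
# dead end (caller retries with a fresh shuffle)
exact_label_attempt <- function(n, m, counts, n_multi, extra) {
  slots <- sample(rep.int(seq_len(m), counts))
  lab <- matrix(0L, n, m)
  lab[cbind(seq_len(n), slots[seq_len(n)])] <- 1L
  if (extra == 0L) return(lab)
  rest <- slots[n + seq_len(extra)]
  multi <- sample.int(n, n_multi)
  # first give every multi-label drug one extra distinct label
  for (d in multi) {
    ok <- which(lab[d, rest] == 0L)
    if (length(ok) == 0L) return(NULL)
    pick <- ok[sample.int(length(ok), 1L)]
    lab[d, rest[pick]] <- 1L
    rest <- rest[-pick]
  }
  # then deal the remaining slots to any multi drug still lacking them
  for (s in rest) {
    ok <- multi[lab[multi, s] == 0L]
    if (length(ok) == 0L) return(NULL)
    d <- if (length(ok) == 1L) ok else sample(ok, 1L)
    lab[d, s] <- 1L
  }
  lab
}

draw_network <- function(cfg, ids, lab) {
  n <- length(ids)
  share <- tcrossprod(lab) > 0L
  iu <- which(upper.tri(share), arr.ind = TRUE)
  p <- ifelse(share[iu], cfg$p_within, cfg$p_between)
  on <- stats::runif(nrow(iu)) < p
  from <- ids[iu[on, 1L]]
  to <- ids[iu[on, 2L]]
  within <- share[iu][on]
  draw <- function(rng, k) if (k == 0L) integer() else
    sample(seq.int(rng[1L], rng[2L]), k, replace = TRUE)
  score <- integer(sum(on))
  score[within] <- draw(cfg$score_range, sum(within))
  score[!within] <- draw(cfg$score_range_between, sum(!within))
  interaction_network(from, to, score)
}

draw_descriptors <- function(cfg, ids, lab) {
  d <- cfg$descriptor_dim; m <- cfg$n_categories
  dirs <- matrix(stats::rnorm(m * d), m, d)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  centre <- (lab / pmax(rowSums(lab), 1L)) %*% dirs * cfg$descriptor_effect
  mat <- centre + matrix(stats::rnorm(length(ids) * d), length(ids), d)
  rownames(mat) <- ids
  colnames(mat) <- sprintf("x%03d", seq_len(d))
  descriptor_matrix(mat, quiet = TRUE)
}

#' Write a synthetic bundle as a file fixture
#'
#' Emits the three standard files into a directory: `network.tsv`
#' (detailed-links dialect), `labels.csv` (long form) and
#' `descriptors.csv`, each readable by the corresponding reader and
#' round-tripping exactly.
#'
#' @param bundle A bundle from [generate_synthetic()] (or any list with
#'   `drugs`, `network`, `descriptors`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             labels = file.path(dir, "labels.csv"),
             descriptors = file.path(dir, "descriptors.csv"))
  write_stitch_links(bundle$network, paths["network"])
  write_drug_labels(bundle$drugs, paths["labels"])
  write_descriptors(bundle$descriptors, paths["descriptors"])
  invisible(paths)
}

#' Marginals of the cancer-drug indication benchmark
#'
#' The published per-category drug counts of the KEGG/DrugBank-derived
#' cancer benchmark this package's method was developed on: 8 cancer
#' classes (tags C1..C8), a 59-drug training set with 77 drug-indication
#' pairs, a 9-drug validation set with 34 pairs, and a 44-drug
#' independent set with 58 pairs. Useful as realistic shape parameters
#' for [synthetic_config()] exact-count mode and for the worked
#' arithmetic around [choose_m()] and [uniform_guess_rate()].
#'
#' @return List with `catalog` (a [label_catalog()]), `counts` (8 x 3
#'   integer matrix of per-category drug counts by dataset), `n_drugs`
#'   and `n_pairs` (per-dataset totals).
#' @export
benchmark_marginals <- function() {
  counts <- cbind(training = c(8L, 8L, 24L, 13L, 4L, 9L, 5L, 6L),
                  validation = c(1L, 5L, 6L, 6L, 6L, 5L, 2L, 3L),
                  independent = c(1L, 6L, 21L, 11L, 2L, 9L, 1L, 7L))
  rownames(counts) <- paste0("C", 1:8)
  list(catalog = label_catalog(paste0("C", 1:8)),
       counts = counts,
       n_drugs = c(training = 59L, validation = 9L, independent = 44L),
       n_pairs = colSums(counts))
}
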