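#' Random label-transfer baseline
#'
#' The null control in which each drug, jackknife style, receives the
#' true indication set of one uniformly drawn OTHER drug from the set.
#' Produces unordered predicted sets, evaluated with
#' [precision_recall()].
#'
#' @param data A [drug_set()] with at least 2 drugs.
#' @param seed Optional integer seed for reproducibility.
#' @return Named list of predicted category sets, one per drug.
#' @export
random_guess <- function(data, seed = NULL) {
  stopifnot(inherits(data, "drug_set"))
  n <- length(data)
  if (n < 2L) stop("random_guess needs at least 2 drugs", call. = FALSE)
  sets <- label_sets(data)
  with_seed(seed, {
    donor <- vapply(seq_len(n), function(i)
      if (n == 2L) setdiff(seq_len(n), i) else
        sample(setdiff(seq_len(n), i), 1L), integer(1))
    stats::setNames(sets[donor], data$drug_ids)
  })
}

#' Uniform single-category guessing baseline
#'
#' Assigns one category uniformly at random to each drug. Its hit rate
#' (fraction of drugs whose guess lies in their true set) converges to
#' the [uniform_guess_rate()] of the dataset.
#'
#' @param data A [drug_set()].
#' @param seed Optional integer seed.
#' @return Named character vector: one guessed category per drug.
#' @export
random_label_guess <- function(data, seed = NULL) {
  stopifnot(inherits(data, "drug_set"))
  cats <- unclass(data$catalog)
  with_seed(seed,
    stats::setNames(sample(cats, length(data), replace = TRUE),
                    data$drug_ids))
}

#' Permute interaction confidence scores
#'
#' The score-randomisation control: the set of interactive pairs is kept
#' fixed and the multiset of confidence scores is reassigned to the pairs
#' by a uniform random permutation (optionally only within a random
#' subset of the edges). Destroying the score-to-pair assignment while
#' conserving both the topology and the score distribution isolates the
#' contribution of the confidence scores themselves.
#'
#' @param net A non-empty [interaction_network()].
#' @param seed Optional integer seed.
#' @param fraction Fraction of edges among which scores are shuffled
#'   (default 1 = all edges).
#' @return An `interaction_network` with the same pairs and the same
#'   score multiset.
#' @export
permute_confidences <- function(net, seed = NULL, fraction = 1) {
  stopifnot(inherits(net, "interaction_network"))
  ne <- edge_count(net)
  if (ne == 0L) stop("network has no edges", call. = FALSE)
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]", call. = FALSE)
  e <- net$edges
  with_seed(seed, {
    k <- max(2L, round(fraction * ne))
    k <- min(k, ne)
    idx <- if (k == ne) seq_len(ne) else sample(ne, k)
    e$score[idx] <- e$score[idx][sample.int(k)]
  })
  interaction_network(e$a, e$b, e$score, channel = net$channel)
}
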