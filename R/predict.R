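#' Score indication categories for a query drug by interaction evidence
#'
#' The core guilt-by-association scorer. For each category k, the score is
#' the sum over training drugs d of `Q(query, d) * y[d, k]`, where Q is
#' the interaction confidence score (0 for non-interactive pairs) and y
#' the binary indication matrix: every interactive training partner votes
#' for its own indications with weight equal to the interaction
#' confidence. A query with no interactive partner in the training set
#' scores 0 everywhere (no evidence). The query drug never contributes to
#' its own score: self-pairs are not representable in the network, which
#' makes leave-one-out evaluation of a training drug exact.
#'
#' @param query_id Drug identifier (may or may not occur in `train`).
#' @param train A [drug_set()] of labelled training drugs.
#' @param net An [interaction_network()].
#' @return Named numeric score vector over the catalogue (all entries
#'   `>= 0`).
#' @examples
#' cat8 <- label_catalog(paste0("C", 1:8))
#' tr <- drug_set(c("d1", "d2"), list("C3", c("C3", "C4")), cat8)
#' net <- interaction_network(c("q", "q"), c("d1", "d2"), c(300, 200))
#' score_categories("q", tr, net)  # C3 = 500, C4 = 200
#' @export
score_categories <- function(query_id, train, net) {
  stopifnot(inherits(train, "drug_set"),
            inherits(net, "interaction_network"))
  if (length(train) == 0L)
    stop("training set is empty", call. = FALSE)
  query_id <- as.character(query_id)
  e <- net$edges
  hit <- e$a == query_id | e$b == query_id
  partner <- ifelse(e$a[hit] == query_id, e$b[hit], e$a[hit])
  w <- e$score[hit]
  idx <- match(partner, train$drug_ids)
  keep <- !is.na(idx) & partner != query_id
  scores <- as.numeric(
    crossprod(train$labels[idx[keep], , drop = FALSE], w[keep]))
  stats::setNames(scores, unclass(train$catalog))
}

#' Rank categories by descending score
#'
#' Produces the full ordered candidate list: all catalogue categories
#' arranged by decreasing score, so the category at position j is the
#' j-th order prediction. Equal scores (including the zero tail of
#' categories with no evidence) are broken by ascending catalogue
#' position, and each run of equal scores is recorded as a tie group so
#' any alternative tie policy remains auditable.
#'
#' @param scores Numeric score vector aligned to the catalogue.
#' @param catalog A [label_catalog()].
#' @param query_id Optional identifier stored in the result.
#' @param truncate_zero Drop trailing zero-score categories instead of
#'   keeping the full-length ranking (off by default; evaluation assumes
#'   full-length rankings).
#' @return A `ranked_prediction`: list with `query_id`, `categories`
#'   (ordered tags), `scores` (non-increasing), `tie_group` (integer id
#'   per position; equal ids = tied scores).
#' @export
rank_categories <- function(scores, catalog, query_id = NA_character_,
                            truncate_zero = FALSE) {
  catalog <- as_catalog(catalog)
  if (length(scores) != length(catalog))
    stop("scores must align with the catalog", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  s <- as.numeric(scores)[ord]
  if (truncate_zero && any(s == 0)) {
    keep <- s != 0
    ord <- ord[keep]; s <- s[keep]
  }
  grp <- if (length(s) > 0L) cumsum(c(TRUE, diff(s) != 0)) else integer()
  structure(list(query_id = as.character(query_id),
                 categories = unclass(catalog)[ord],
                 scores = s,
                 tie_group = as.integer(grp)),
            class = "ranked_prediction")
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat("<ranked_prediction> ", x$query_id, ": ",
      paste0(x$categories, " (", signif(x$scores, 4), ")",
             collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ranked_prediction <- function(x, ...) {
  data.frame(query_id = x$query_id,
             rank = seq_along(x$categories),
             category = x$categories,
             score = x$scores,
             tie_group = x$tie_group)
}

#' Batch ranked prediction
#'
#' Scores and ranks every query drug against a labelled training set,
#' using either interaction-network evidence (sum of confidence scores,
#' [score_categories()]) or molecular-descriptor evidence (sum of cosine
#' similarities, [score_categories_descriptor()]) depending on the class
#' of `evidence`.
#'
#' @param query_ids Character vector of query drug ids.
#' @param train A [drug_set()].
#' @param evidence An [interaction_network()] or a [descriptor_matrix()].
#' @param truncate_zero Passed to [rank_categories()].
#' @return List of `ranked_prediction`, in input order, named by query.
#' @export
predict_indications <- function(query_ids, train, evidence,
                                truncate_zero = FALSE) {
  scorer <- evidence_scorer(evidence)
  out <- lapply(as.character(query_ids), function(q)
    rank_categories(scorer(q, train), train$catalog, query_id = q,
                    truncate_zero = truncate_zero))
  stats::setNames(out, as.character(query_ids))
}

evidence_scorer <- function(evidence) {
  if (inherits(evidence, "interaction_network"))
    function(q, train) score_categories(q, train, evidence)
  else if (inherits(evidence, "descriptor_matrix"))
    function(q, train) score_categories_descriptor(q, train, evidence)
  else stop("evidence must be an interaction_network or a ",
            "descriptor_matrix", call. = FALSE)
}

#' Predictions as a tidy table
#'
#' @param preds List of `ranked_prediction` (e.g. from
#'   [predict_indications()] or [jackknife()]).
#' @return A data.frame with columns query_id, rank, category, score,
#'   tie_group.
#' @export
predictions_table <- function(preds) {
  do.call(rbind, lapply(preds, as.data.frame))
}
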