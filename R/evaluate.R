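#' Jackknife (leave-one-out) ranked prediction
#'
#' Each drug in the set is singled out in turn and ranked by a model
#' built from the remaining drugs. For both scorers the left-out drug's
#' only possible contribution to its own score is the self-term, which is
#' excluded unconditionally, so the leave-one-out prediction is computed
#' by scoring each drug against the full set with itself removed from the
#' evidence sum.
#'
#' @param data A [drug_set()] with at least 2 drugs.
#' @param evidence An [interaction_network()] or [descriptor_matrix()].
#' @param truncate_zero Passed to [rank_categories()].
#' @return List of `ranked_prediction`, one per drug, named by drug id.
#' @export
jackknife <- function(data, evidence, truncate_zero = FALSE) {
  stopifnot(inherits(data, "drug_set"))
  if (length(data) < 2L)
    stop("jackknife needs at least 2 drugs", call. = FALSE)
  predict_indications(data$drug_ids, data, evidence,
                      truncate_zero = truncate_zero)
}

check_preds <- function(preds, truth) {
  stopifnot(inherits(truth, "drug_set"))
  if (!all(vapply(preds, inherits, logical(1), "ranked_prediction")))
    stop("preds must be a list of ranked_prediction", call. = FALSE)
  ids <- vapply(preds, `[[`, character(1), "query_id")
  if (!all(ids %in% truth$drug_ids))
    stop("prediction for drug(s) absent from the truth set: ",
         paste(setdiff(ids, truth$drug_ids), collapse = ", "),
         call. = FALSE)
  ids
}

#' j-th order prediction accuracy
#'
#' The fraction of drugs whose j-th ranked category belongs to their true
#' indication set. The first-order accuracy (j = 1) is the headline
#' statistic of a ranking classifier; a good ranker has high accuracy at
#' low orders and low accuracy at high orders.
#'
#' @param preds List of `ranked_prediction`.
#' @param truth A [drug_set()] with the true indication sets.
#' @param j Order index, `1 <= j <= M`.
#' @return Fraction in `[0, 1]`.
#' @export
order_accuracy <- function(preds, truth, j) {
  ids <- check_preds(preds, truth)
  m <- length(truth$catalog)
  if (!(j >= 1L && j <= m))
    stop("order index j must be in 1..", m, call. = FALSE)
  hit <- vapply(seq_along(preds), function(i) {
    p <- preds[[i]]
    if (j > length(p$categories)) return(FALSE)
    truth$labels[ids[i], p$categories[j]] == 1L
  }, logical(1))
  mean(hit)
}

#' Per-category order accuracy matrix
#'
#' Entry `[i, k]`: among the drugs whose true indication set contains
#' category k, the fraction whose i-th ranked category is exactly k. A
#' category treated by no drug in the set has an undefined (NA) column,
#' distinct from a genuine 0% over a non-empty denominator.
#'
#' @param preds List of `ranked_prediction`.
#' @param truth A [drug_set()].
#' @return M x M numeric matrix (rows = prediction order, columns =
#'   categories); attribute `"n_k"` holds the per-category denominators.
#' @export
per_category_order_accuracy <- function(preds, truth) {
  ids <- check_preds(preds, truth)
  cats <- unclass(truth$catalog)
  m <- length(cats)
  acc <- matrix(NA_real_, m, m, dimnames = list(NULL, cats))
  n_k <- colSums(truth$labels[ids, , drop = FALSE])
  for (k in seq_len(m)) {
    if (n_k[k] == 0L) next
    in_k <- which(truth$labels[ids, k] == 1L)
    for (i in seq_len(m)) {
      hits <- vapply(in_k, function(d) {
        p <- preds[[d]]
        i <= length(p$categories) && p$categories[i] == cats[k]
      }, logical(1))
      acc[i, k] <- sum(hits) / n_k[k]
    }
  }
  attr(acc, "n_k") <- as.integer(n_k)
  acc
}

#' Coverage ratio of the first m predictions
#'
#' The proportion of all true drug-indication pairs in the dataset that
#' are recovered within each drug's first m ranked predictions:
#' `sum_i |top-m(i) intersect true(i)| / sum_i n_i`. With full-length
#' rankings the ratio reaches 1 at m = M.
#'
#' @param preds List of `ranked_prediction`.
#' @param truth A [drug_set()].
#' @param m Number of leading predictions considered, `1 <= m <= M`.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_ratio <- function(preds, truth, m) {
  ids <- check_preds(preds, truth)
  M <- length(truth$catalog)
  if (!(m >= 1L && m <= M))
    stop("m must be in 1..", M, call. = FALSE)
  sets <- label_sets(truth)
  covered <- vapply(seq_along(preds), function(i) {
    top <- preds[[i]]$categories[seq_len(min(m, length(preds[[i]]$categories)))]
    length(intersect(top, sets[[ids[i]]]))
  }, numeric(1))
  sum(covered) / sum(n_labels(truth)[ids])
}

#' Default number of leading predictions to evaluate
#'
#' The smallest integer no less than the dataset's average number of
#' indications per drug: `ceiling(sum_i n_i / N)`. This is the
#' conventional choice of m for [coverage_ratio()].
#'
#' @param truth A [drug_set()] (non-empty).
#' @return Positive integer.
#' @examples
#' # 77 indication pairs over 59 drugs -> average 1.31 -> m = 2
#' @export
choose_m <- function(truth) {
  stopifnot(inherits(truth, "drug_set"))
  if (length(truth) == 0L) stop("empty drug set", call. = FALSE)
  as.integer(ceiling(sum(n_labels(truth)) / length(truth)))
}

#' Set-based precision and recall
#'
#' For per-drug predicted indication sets (no order information):
#' precision is the mean over drugs of `c_i / p_i` and recall the mean of
#' `c_i / n_i`, with `c_i` the number of correctly predicted categories,
#' `p_i` the predicted-set size and `n_i` the true-set size. Drugs with
#' an empty predicted set contribute 0 to precision (logged).
#'
#' @param pred_sets Named list of character vectors: predicted category
#'   sets per drug (names must be drug ids in `truth`).
#' @param truth A [drug_set()].
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(pred_sets, truth) {
  stopifnot(inherits(truth, "drug_set"))
  ids <- names(pred_sets)
  if (is.null(ids) || !all(ids %in% truth$drug_ids))
    stop("pred_sets must be named by drug ids present in truth",
         call. = FALSE)
  sets <- label_sets(truth)
  ci <- vapply(ids, function(d)
    length(intersect(pred_sets[[d]], sets[[d]])), numeric(1))
  pi_ <- lengths(pred_sets)
  ni <- n_labels(truth)[ids]
  if (any(pi_ == 0L))
    message(sum(pi_ == 0L), " drug(s) with empty predicted set ",
            "contribute 0 to precision")
  prec <- mean(ifelse(pi_ == 0L, 0, ci / pi_))
  rec <- mean(ci / ni)
  c(precision = prec, recall = rec)
}

#' Leading predictions as sets
#'
#' Utility converting ranked predictions into per-drug sets of their
#' first m categories, the form consumed by [precision_recall()]. With
#' m = 1 the singleton first-order sets make precision identical to the
#' first-order accuracy.
#'
#' @param preds List of `ranked_prediction`.
#' @param m Number of leading categories to keep.
#' @return Named list of character vectors.
#' @export
top_m_sets <- function(preds, m) {
  out <- lapply(preds, function(p)
    p$categories[seq_len(min(m, length(p$categories)))])
  stats::setNames(out, vapply(preds, `[[`, character(1), "query_id"))
}

#' Aggregate evaluation report
#'
#' Computes the full evaluation suite for a set of ranked predictions
#' against their true indication sets: per-order accuracies Q_1..Q_M,
#' the per-category order-accuracy matrix, the coverage ratio at m
#' (defaulting to [choose_m()]), and precision/recall of the first-order
#' singleton predictions.
#'
#' @param preds List of `ranked_prediction`.
#' @param truth A [drug_set()].
#' @param m Coverage cutoff; `NULL` uses [choose_m()].
#' @return An `evaluation_report` list with fields `order_accuracy`,
#'   `per_category`, `coverage` (`m_used`, `ratio`), `avg_labels`,
#'   `n_drugs`, `n_label_pairs`, `precision`, `recall`.
#' @export
evaluate <- function(preds, truth, m = NULL) {
  ids <- check_preds(preds, truth)
  M <- length(truth$catalog)
  sub <- if (setequal(ids, truth$drug_ids)) truth else
    drug_set(ids, truth$labels[ids, , drop = FALSE], truth$catalog)
  m_used <- as.integer(m %||% choose_m(sub))
  q <- vapply(seq_len(M), function(j) order_accuracy(preds, truth, j),
              numeric(1))
  pr <- precision_recall(top_m_sets(preds, 1L), truth)
  rep <- list(order_accuracy = stats::setNames(q, paste0("Q", seq_len(M))),
              per_category = per_category_order_accuracy(preds, truth),
              coverage = list(m_used = m_used,
                              ratio = coverage_ratio(preds, truth, m_used)),
              avg_labels = sum(n_labels(sub)) / length(sub),
              n_drugs = length(sub),
              n_label_pairs = as.integer(sum(n_labels(sub))),
              precision = unname(pr["precision"]),
              recall = unname(pr["recall"]))
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  cat("<evaluation_report> ", x$n_drugs, " drugs, ", x$n_label_pairs,
      " indication pairs (avg ", sprintf("%.2f", x$avg_labels),
      " per drug)\n", sep = "")
  cat("  order accuracies: ",
      paste0(names(x$order_accuracy), "=", pct(x$order_accuracy),
             collapse = " "), "\n", sep = "")
  cat("  coverage at m=", x$coverage$m_used, ": ", pct(x$coverage$ratio),
      "\n", sep = "")
  cat("  1st-order precision: ", pct(x$precision),
      "  recall: ", pct(x$recall), "\n", sep = "")
  invisible(x)
}

#' Expected success rate of uniform random single-category guessing
#'
#' If one category out of M is guessed uniformly at random for each drug,
#' the expected chance of hitting one of the drug's true indications is
#' the dataset's average label count divided by M. The benchmark papers'
#' convention rounds the average to 2 decimals before dividing
#' (`rounded = TRUE` reproduces those printed rates, e.g. an average of
#' 77/59 reported as 1.31 gives 16.38%); `rounded = FALSE` gives the
#' full-precision rate.
#'
#' @param truth A [drug_set()], or a number (the average label count).
#' @param n_categories M; defaults to the catalogue size when `truth` is
#'   a drug set.
#' @param rounded Round the average label count to 2 decimals first.
#' @return Expected hit fraction in `[0, 1]`.
#' @export
uniform_guess_rate <- function(truth, n_categories = NULL,
                               rounded = FALSE) {
  if (inherits(truth, "drug_set")) {
    avg <- sum(n_labels(truth)) / length(truth)
    n_categories <- n_categories %||% length(truth$catalog)
  } else {
    avg <- as.numeric(truth)
    if (is.null(n_categories))
      stop("n_categories required when truth is a number", call. = FALSE)
  }
  if (rounded) avg <- round(avg, 2L)
  avg / n_categories
}
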