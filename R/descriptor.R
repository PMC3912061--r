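#' Cosine similarity of two descriptor vectors
#'
#' `dot(v1, v2) / (||v1|| * ||v2||)`. If either vector has zero norm the
#' similarity is defined as 0 (neutral evidence) with a warning; the
#' value otherwise lies in `[-1, 1]` up to floating-point error.
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @return A single number in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 0, 1))  # 4 / (3 * sqrt(5))
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("descriptor vectors differ in dimension: ", length(v1), " vs ",
         length(v2), call. = FALSE)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    warning("zero-norm descriptor vector; similarity set to 0")
    return(0)
  }
  sum(v1 * v2) / (n1 * n2)
}

#' Score indication categories for a query drug by descriptor similarity
#'
#' The structure-based comparator: identical in form to
#' [score_categories()] but with the pairwise cosine similarity of
#' molecular-descriptor vectors in place of the interaction confidence
#' score. For each category k the score is the sum over training drugs d
#' of `cos(query, d) * y[d, k]`. Negative cosines are summed as-is
#' (negative evidence lowers a category); descriptors are used raw unless
#' `standardise = TRUE` z-scores each column first.
#'
#' @param query_id Drug identifier; must have a row in `desc`, as must
#'   every training drug.
#' @param train A [drug_set()].
#' @param desc A [descriptor_matrix()].
#' @param standardise Z-score descriptor columns before computing
#'   cosines (off by default).
#' @return Named numeric score vector over the catalogue (entries may be
#'   negative).
#' @export
score_categories_descriptor <- function(query_id, train, desc,
                                        standardise = FALSE) {
  stopifnot(inherits(train, "drug_set"))
  if (length(train) == 0L)
    stop("training set is empty", call. = FALSE)
  query_id <- as.character(query_id)
  need <- unique(c(query_id, train$drug_ids))
  missing <- setdiff(need, rownames(desc))
  if (length(missing) > 0L)
    stop("no descriptor row for drug(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mat <- unclass(desc)[need, , drop = FALSE]
  if (standardise) {
    sds <- apply(mat, 2L, stats::sd)
    sds[sds == 0] <- 1
    mat <- scale(mat, center = TRUE, scale = sds)
  }
  q <- mat[query_id, ]
  others <- setdiff(train$drug_ids, query_id)
  if (length(others) == 0L)
    return(stats::setNames(numeric(length(train$catalog)),
                           unclass(train$catalog)))
  tv <- mat[others, , drop = FALSE]
  qn <- sqrt(sum(q^2))
  tn <- sqrt(rowSums(tv^2))
  zero <- tn == 0 | qn == 0
  if (any(zero))
    warning(sum(zero), " zero-norm descriptor vector(s); similarity 0")
  sims <- numeric(length(others))
  ok <- !zero
  if (qn > 0)
    sims[ok] <- as.numeric(tv[ok, , drop = FALSE] %*% q) / (tn[ok] * qn)
  y <- train$labels[match(others, train$drug_ids), , drop = FALSE]
  stats::setNames(as.numeric(crossprod(y, sims)), unclass(train$catalog))
}
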