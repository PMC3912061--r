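#' Create an indication category catalogue
#'
#' A `label_catalog` is the fixed, ordered set of indication categories a
#' model predicts over (for the cancer-drug benchmark these are the eight
#' tags `C1`...`C8`, one per cancer class). The catalogue order is fixed at
#' construction and is used everywhere a deterministic order is needed:
#' tie-breaking within equal prediction scores, column order of label
#' matrices, and report layout.
#'
#' @param categories Character vector of unique, non-empty category
#'   identifiers, length at least 2.
#' @return A `label_catalog` object (a classed character vector).
#' @examples
#' label_catalog(paste0("C", 1:8))
#' @export
label_catalog <- function(categories) {
  categories <- as.character(categories)
  if (length(categories) < 2L)
    stop("a catalog needs at least 2 categories", call. = FALSE)
  if (anyNA(categories) || any(!nzchar(categories)))
    stop("category identifiers must be non-empty", call. = FALSE)
  if (anyDuplicated(categories))
    stop("category identifiers must be unique", call. = FALSE)
  structure(categories, class = "label_catalog")
}

#' @export
print.label_catalog <- function(x, ...) {
  cat("<label_catalog> ", length(x), " categories: ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.label_catalog` <- function(x, i) unclass(x)[i]

as_catalog <- function(x) {
  if (inherits(x, "label_catalog")) x else label_catalog(x)
}

#' Create a labelled drug set
#'
#' Holds the binary indication matrix for a set of drug compounds: row `i`
#' is the indicator vector of drug `i` over the catalogue categories (1 if
#' the drug treats that category). Every drug must carry at least one
#' indication; multi-label drugs (several indications) are the norm in the
#' cancer benchmark.
#'
#' @param drug_ids Character vector of unique drug identifiers.
#' @param labels Binary (0/1) matrix, one row per drug, one column per
#'   catalogue category. A character vector/list of category tags per drug
#'   is also accepted.
#' @param catalog A [label_catalog()] (or character vector coerced to one).
#' @return A `drug_set` object.
#' @examples
#' cat8 <- label_catalog(paste0("C", 1:8))
#' drug_set(c("d1", "d2"), list(c("C3", "C4"), "C3"), cat8)
#' @export
drug_set <- function(drug_ids, labels, catalog) {
  catalog <- as_catalog(catalog)
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(drug_ids))
    stop("drug ids must be unique", call. = FALSE)
  m <- length(catalog)
  if (is.list(labels) || (is.character(labels) && !is.matrix(labels))) {
    tags <- if (is.list(labels)) labels else as.list(labels)
    if (length(tags) != length(drug_ids))
      stop("one label set per drug required", call. = FALSE)
    lab <- matrix(0L, nrow = length(drug_ids), ncol = m)
    for (i in seq_along(tags)) {
      idx <- match(tags[[i]], catalog)
      if (anyNA(idx))
        stop("unknown category tag(s) for drug '", drug_ids[i], "': ",
             paste(setdiff(tags[[i]], catalog), collapse = ", "),
             "; catalog is: ", paste(unclass(catalog), collapse = ", "),
             call. = FALSE)
      lab[i, idx] <- 1L
    }
    labels <- lab
  }
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (nrow(labels) != length(drug_ids) || ncol(labels) != m)
    stop("label matrix must be n_drugs x n_categories", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(drug_ids) > 0L && any(rowSums(labels) == 0L))
    stop("every drug needs at least one indication; offending: ",
         paste(drug_ids[rowSums(labels) == 0L], collapse = ", "),
         call. = FALSE)
  dimnames(labels) <- list(drug_ids, unclass(catalog))
  structure(list(drug_ids = drug_ids, labels = labels, catalog = catalog),
            class = "drug_set")
}

#' @export
print.drug_set <- function(x, ...) {
  cat("<drug_set> ", length(x$drug_ids), " drugs, ",
      length(x$catalog), " categories, ",
      sum(x$labels), " drug-indication pairs\n", sep = "")
  invisible(x)
}

#' @export
length.drug_set <- function(x) length(x$drug_ids)

#' Number of indications per drug
#'
#' @param x A [drug_set()].
#' @return Named integer vector of per-drug label counts (n_i).
#' @export
n_labels <- function(x) {
  stopifnot(inherits(x, "drug_set"))
  stats::setNames(as.integer(rowSums(x$labels)), x$drug_ids)
}

#' True indication sets per drug
#'
#' @param x A [drug_set()].
#' @return Named list of character vectors of category tags.
#' @export
label_sets <- function(x) {
  stopifnot(inherits(x, "drug_set"))
  out <- apply(x$labels, 1L, function(r) unclass(x$catalog)[r == 1L],
               simplify = FALSE)
  stats::setNames(out, x$drug_ids)
}

#' Drop drugs from a drug set
#'
#' @param x A [drug_set()].
#' @param drop Character vector of drug ids to remove.
#' @return A `drug_set` without the named drugs.
#' @export
drop_drugs <- function(x, drop) {
  stopifnot(inherits(x, "drug_set"))
  keep <- !(x$drug_ids %in% drop)
  drug_set(x$drug_ids[keep], x$labels[keep, , drop = FALSE], x$catalog)
}
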