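#' Read a STITCH detailed-links interaction table
#'
#' Parses the tab-separated "detailed links" dialect: two compound
#' identifier columns followed by per-channel scores (`similarity`,
#' `experimental`, `database`, `textmining`, `combined_score`; header
#' matched case-insensitively). A pair is interactive if and only if its
#' score on the chosen channel is greater than zero; only such rows
#' become edges. Duplicate unordered pairs keep the maximum score (with a
#' warning when scores conflict). Identifiers are taken verbatim; an
#' optional mapping table can translate them (e.g. STITCH CID to KEGG
#' D-number) before filtering.
#'
#' @param path Path to the TSV file (first two columns are the compound
#'   ids).
#' @param channel Score channel to use; `"combined_score"` (the default)
#'   or any other header name, matched case-insensitively (`"combined"`
#'   matches `combined_score`).
#' @param id_filter Optional character vector: keep only rows whose two
#'   endpoints (after mapping) are both in this set.
#' @param id_map Optional two-column data.frame (`from`, `to`): compound
#'   identifiers equal to a `from` value are replaced by the matching
#'   `to` value; unmatched identifiers pass through unchanged.
#' @param quiet Suppress the row-count message.
#' @return An [interaction_network()]. The attribute `"row_counts"`
#'   records `rows` (data rows read), `positive` (rows with positive
#'   channel score, i.e. directed bookkeeping) and `pairs` (unordered
#'   pairs stored), so either edge-counting convention can be checked.
#' @export
read_stitch_links <- function(path, channel = "combined_score",
                              id_filter = NULL, id_map = NULL,
                              quiet = FALSE) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("expected >= 3 tab-separated columns (two ids + scores)",
         call. = FALSE)
  score_cols <- names(tab)[-(1:2)]
  norm <- tolower(score_cols)
  want <- tolower(channel)
  j <- match(want, norm)
  if (is.na(j)) j <- match(paste0(want, "_score"), norm)
  if (is.na(j))
    stop("score channel '", channel, "' not found; available columns: ",
         paste(score_cols, collapse = ", "), call. = FALSE)
  raw <- tab[[score_cols[j]]]
  score <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(score))
  if (length(bad) > 0L)
    stop("non-numeric '", score_cols[j], "' value at file line ",
         bad[1L] + 1L, ": '", raw[bad[1L]], "'", call. = FALSE)
  id1 <- tab[[1L]]; id2 <- tab[[2L]]
  if (!is.null(id_map)) {
    id_map <- as.data.frame(id_map)
    id1 <- map_ids(id1, id_map)
    id2 <- map_ids(id2, id_map)
  }
  if (!is.null(id_filter)) {
    keep <- id1 %in% id_filter & id2 %in% id_filter
    id1 <- id1[keep]; id2 <- id2[keep]; score <- score[keep]
  }
  net <- interaction_network(id1, id2, score, channel = score_cols[j])
  counts <- c(rows = nrow(tab), positive = sum(score > 0 & id1 != id2),
              pairs = edge_count(net))
  attr(net, "row_counts") <- counts
  if (!quiet)
    message("read ", counts["rows"], " rows; ", counts["positive"],
            " with positive ", score_cols[j], "; ", counts["pairs"],
            " unordered pairs stored")
  net
}

map_ids <- function(ids, id_map) {
  i <- match(ids, as.character(id_map[[1L]]))
  ifelse(is.na(i), ids, as.character(id_map[[2L]])[i])
}

#' Write an interaction network in the detailed-links dialect
#'
#' Emits a tab-separated file with the standard header (`chemical1`,
#' `chemical2`, four sub-channel columns, `combined_score`); the network's
#' scores go in the `combined_score` column and sub-channels are written
#' as 0. Reloading with [read_stitch_links()] round-trips the edge set
#' and scores exactly.
#'
#' @param net An [interaction_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stitch_links <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  e <- net$edges
  out <- data.frame(chemical1 = e$a, chemical2 = e$b,
                    similarity = 0L, experimental = 0L, database = 0L,
                    textmining = 0L, combined_score = e$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a drug-indication label table
#'
#' Accepts two layouts, distinguished by the header. Wide form: a
#' `drug_id` column plus one binary 0/1 column per catalogue category.
#' Long form: each row is a drug id followed by one or more category
#' tags (extra empty fields are ignored), with multi-label drugs spread
#' over several rows or several fields. Separator (tab or comma) is
#' sniffed from the header.
#'
#' @param path Path to the CSV/TSV file.
#' @param catalog A [label_catalog()]; unknown tags are an error.
#' @param quiet Suppress the row-count message.
#' @return A [drug_set()]; empty input yields an empty (0-drug) set.
#' @export
read_drug_labels <- function(path, catalog, quiet = FALSE) {
  catalog <- as_catalog(catalog)
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (nrow(tab) == 0L) {
    if (!quiet) message("empty label table: 0 drugs loaded")
    return(drug_set(character(), matrix(0L, 0L, length(catalog)), catalog))
  }
  wide <- ncol(tab) > 1L && all(names(tab)[-1L] %in% unclass(catalog))
  if (wide) {
    ids <- tab[[1L]]
    lab <- matrix(0L, nrow(tab), length(catalog))
    for (k in seq_along(catalog)) {
      col <- tab[[unclass(catalog)[k]]]
      if (is.null(col)) next
      v <- suppressWarnings(as.integer(col))
      if (anyNA(v) || !all(v %in% 0:1))
        stop("wide-form label column '", unclass(catalog)[k],
             "' must be binary 0/1", call. = FALSE)
      lab[, k] <- v
    }
    ds <- drug_set(ids, lab, catalog)
  } else {
    ids <- tab[[1L]]
    tags <- lapply(seq_len(nrow(tab)), function(i) {
      v <- as.character(unlist(tab[i, -1L], use.names = FALSE))
      v[!is.na(v) & nzchar(v)]
    })
    if (any(lengths(tags) == 0L))
      stop("row(s) without any category tag for drug(s): ",
           paste(unique(ids[lengths(tags) == 0L]), collapse = ", "),
           call. = FALSE)
    unknown <- setdiff(unique(unlist(tags)), unclass(catalog))
    if (length(unknown) > 0L)
      stop("unknown category tag(s): ", paste(unknown, collapse = ", "),
           "; catalog is: ", paste(unclass(catalog), collapse = ", "),
           call. = FALSE)
    uid <- unique(ids)
    sets <- lapply(uid, function(d) unique(unlist(tags[ids == d])))
    ds <- drug_set(uid, sets, catalog)
  }
  if (!quiet)
    message("read ", nrow(tab), " rows: ", length(ds), " drugs, ",
            sum(ds$labels), " drug-indication pairs")
  ds
}

#' Write a drug-indication label table
#'
#' @param drugs A [drug_set()].
#' @param path Output file path (written as CSV).
#' @param format `"long"` (one drug-category row, default) or `"wide"`
#'   (binary matrix with one column per category).
#' @return `path`, invisibly.
#' @export
write_drug_labels <- function(drugs, path, format = c("long", "wide")) {
  stopifnot(inherits(drugs, "drug_set"))
  format <- match.arg(format)
  if (format == "long") {
    sets <- label_sets(drugs)
    out <- data.frame(drug_id = rep(names(sets), lengths(sets)),
                      category = unlist(sets, use.names = FALSE))
  } else {
    out <- data.frame(drug_id = drugs$drug_ids,
                      as.data.frame(drugs$labels), check.names = FALSE)
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a molecular-descriptor matrix
#'
#' Reads a delimited numeric matrix (drugs in rows; first column is the
#' drug id) and drops every descriptor column containing at least one
#' missing value, the standard cleanup for descriptor suites computed by
#' quantum-chemistry pipelines where some descriptors fail for some
#' molecules (e.g. 454 raw descriptors reduced to 355 complete ones).
#'
#' @param path Path to the CSV/TSV file (separator sniffed from header).
#' @param quiet Suppress the dimension message.
#' @return A numeric matrix with drug ids as row names and class
#'   `descriptor_matrix`; attribute `"dropped"` lists removed columns.
#' @export
read_descriptors <- function(path, quiet = FALSE) {
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  descriptor_matrix(mat, quiet = quiet)
}

#' Construct a descriptor matrix, dropping incomplete columns
#'
#' @param mat Numeric matrix, drug ids as row names.
#' @param quiet Suppress the dimension message.
#' @return A `descriptor_matrix` (see [read_descriptors()]).
#' @export
descriptor_matrix <- function(mat, quiet = FALSE) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(rownames(mat)))
    stop("descriptor matrix needs drug ids as row names", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate drug ids in descriptor matrix", call. = FALSE)
  incomplete <- apply(mat, 2L, anyNA)
  dropped <- colnames(mat)[incomplete] %||% which(incomplete)
  mat <- mat[, !incomplete, drop = FALSE]
  if (ncol(mat) == 0L)
    stop("no usable descriptors: every column has missing values",
         call. = FALSE)
  if (!quiet)
    message("descriptor matrix: ", nrow(mat), " drugs x ", ncol(mat),
            " descriptors retained (", sum(incomplete), " dropped)")
  structure(mat, dropped = dropped, class = c("descriptor_matrix",
                                              class(mat)))
}

#' Write a descriptor matrix
#'
#' @param desc A [descriptor_matrix()].
#' @param path Output file path (CSV; first column `drug_id`).
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(desc, path) {
  out <- data.frame(drug_id = rownames(desc),
                    as.data.frame(unclass(desc)), check.names = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
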