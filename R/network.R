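#' Create a chemical-chemical interaction network
#'
#' A symmetric map from unordered compound pairs to a positive confidence
#' score (the STITCH `combined_score` convention: 0--1000, greater than
#' zero iff the pair is interactive). Absent pairs score exactly 0; zero
#' scores are never stored, self-pairs are rejected or dropped, and
#' duplicate unordered pairs keep the maximum score with a warning.
#'
#' @param from,to Character vectors of compound identifiers (endpoints).
#' @param score Numeric vector of confidence scores; entries `<= 0` are
#'   dropped (non-interactive by definition).
#' @param channel Optional name of the score channel these values came
#'   from, kept as metadata.
#' @param warn_dups Warn when conflicting duplicate pairs are collapsed.
#' @return An `interaction_network` object.
#' @examples
#' interaction_network(c("a", "b"), c("b", "c"), c(500, 700))
#' @export
interaction_network <- function(from, to, score, channel = "combined_score",
                                warn_dups = TRUE) {
  from <- as.character(from); to <- as.character(to)
  score <- as.numeric(score)
  if (length(from) != length(to) || length(from) != length(score))
    stop("from, to, score must have equal length", call. = FALSE)
  if (anyNA(score))
    stop("scores must be numeric and non-missing", call. = FALSE)
  self <- from == to
  if (any(self & score > 0))
    warning(sum(self & score > 0), " self-interaction(s) ignored")
  keep <- score > 0 & !self
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  s <- score[keep]
  key <- pair_key(a, b)
  if (anyDuplicated(key)) {
    mx <- tapply(s, key, max)
    conflict <- tapply(s, key, function(v) length(unique(v)) > 1L)
    if (warn_dups && any(conflict))
      warning(sum(conflict), " duplicate pair(s) with conflicting scores; ",
              "maximum kept")
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]
    s <- as.numeric(mx[pair_key(a, b)])
    key <- key[first]
  }
  ord <- order(a, b)
  edges <- data.frame(a = a[ord], b = b[ord], score = s[ord],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, channel = channel,
                 keys = pair_key(edges$a, edges$b)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", nrow(x$edges), " edges among ",
      length(network_drugs(x)), " compounds (channel: ", x$channel, ")\n",
      sep = "")
  invisible(x)
}

#' Confidence score lookup
#'
#' Vectorised lookup of the confidence score Q for unordered compound
#' pairs. Pairs not stored in the network (non-interactive compounds) and
#' self-pairs return exactly 0.
#'
#' @param net An [interaction_network()].
#' @param a,b Compound identifier vectors (recycled to common length).
#' @return Numeric vector of scores, 0 for absent pairs.
#' @export
interaction_score <- function(net, a, b) {
  stopifnot(inherits(net, "interaction_network"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  idx <- match(pair_key(a, b), net$keys)
  out <- ifelse(is.na(idx), 0, net$edges$score[idx])
  out[a == b] <- 0
  out
}

#' Compounds present in a network
#'
#' @param net An [interaction_network()].
#' @return Sorted character vector of compound ids with at least one edge.
#' @export
network_drugs <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  sort(unique(c(net$edges$a, net$edges$b)))
}

#' Number of stored edges (unordered interactive pairs)
#'
#' @param net An [interaction_network()].
#' @return Integer edge count.
#' @export
edge_count <- function(net) nrow(net$edges)

#' Induced subnetwork on a set of compounds
#'
#' @param net An [interaction_network()].
#' @param ids Compound ids to keep; edges with either endpoint outside
#'   `ids` are dropped.
#' @return An `interaction_network`.
#' @export
induced_subnetwork <- function(net, ids) {
  stopifnot(inherits(net, "interaction_network"))
  e <- net$edges
  keep <- e$a %in% ids & e$b %in% ids
  interaction_network(e$a[keep], e$b[keep], e$score[keep],
                      channel = net$channel)
}
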