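# Independent brute-force oracles: naive double loops over raw edge
# lists and label sets, kept free of the package's vectorised paths.

# score of every category for query q: sum over train drugs of Q(q, d) * y
oracle_scores_net <- function(q, train, edges) {
  cats <- as.character(train$catalog)
  out <- stats::setNames(numeric(length(cats)), cats)
  for (d in train$drug_ids) {
    if (d == q) next
    s <- 0
    for (r in seq_len(nrow(edges))) {
      if ((edges$a[r] == q && edges$b[r] == d) ||
          (edges$a[r] == d && edges$b[r] == q))
        s <- max(s, edges$score[r])
    }
    if (s > 0)
      for (k in cats)
        out[k] <- out[k] + s * (train$labels[d, k] == 1L)
  }
  out
}

oracle_scores_desc <- function(q, train, desc) {
  cats <- as.character(train$catalog)
  out <- stats::setNames(numeric(length(cats)), cats)
  qv <- unclass(desc)[q, ]
  for (d in train$drug_ids) {
    if (d == q) next
    dv <- unclass(desc)[d, ]
    den <- sqrt(sum(qv^2)) * sqrt(sum(dv^2))
    cs <- if (den == 0) 0 else sum(qv * dv) / den
    for (k in cats)
      out[k] <- out[k] + cs * (train$labels[d, k] == 1L)
  }
  out
}

# stable sort by (-score, catalog position)
oracle_rank <- function(scores, cats) {
  ord <- order(-as.numeric(scores), seq_along(scores))
  as.character(cats)[ord]
}

oracle_order_accuracy <- function(preds, truth, j) {
  hits <- 0
  for (p in preds) {
    true_set <- names(which(truth$labels[p$query_id, ] == 1L))
    if (p$categories[j] %in% true_set) hits <- hits + 1
  }
  hits / length(preds)
}

oracle_per_category <- function(preds, truth) {
  cats <- as.character(truth$catalog)
  m <- length(cats)
  acc <- matrix(NA_real_, m, m)
  for (k in seq_len(m)) {
    members <- Filter(function(p) truth$labels[p$query_id, cats[k]] == 1L,
                      preds)
    if (length(members) == 0L) next
    for (i in seq_len(m)) {
      hits <- sum(vapply(members, function(p) p$categories[i] == cats[k],
                         logical(1)))
      acc[i, k] <- hits / length(members)
    }
  }
  acc
}

oracle_coverage <- function(preds, truth, m) {
  num <- 0; den <- 0
  for (p in preds) {
    true_set <- names(which(truth$labels[p$query_id, ] == 1L))
    num <- num + length(intersect(p$categories[seq_len(m)], true_set))
    den <- den + length(true_set)
  }
  num / den
}

oracle_precision_recall <- function(pred_sets, truth) {
  ps <- 0; rs <- 0
  for (d in names(pred_sets)) {
    true_set <- names(which(truth$labels[d, ] == 1L))
    ci <- length(intersect(pred_sets[[d]], true_set))
    ps <- ps + if (length(pred_sets[[d]]) == 0L) 0 else
      ci / length(pred_sets[[d]])
    rs <- rs + ci / length(true_set)
  }
  c(precision = ps / length(pred_sets), recall = rs / length(pred_sets))
}

# a small random labelled instance: <= 12 drugs, M <= 8, random network
random_instance <- function(seed) {
  set.seed(seed)
  m <- sample(2:8, 1)
  n <- sample(3:12, 1)
  cats <- label_catalog(paste0("C", seq_len(m)))
  ids <- paste0("d", seq_len(n))
  lab <- matrix(0L, n, m)
  for (i in seq_len(n))
    lab[i, sample.int(m, sample(1:min(3, m), 1))] <- 1L
  drugs <- drug_set(ids, lab, cats)
  pairs <- t(combn(ids, 2))
  on <- runif(nrow(pairs)) < 0.5
  net <- interaction_network(pairs[on, 1], pairs[on, 2],
                             sample(1:999, sum(on), replace = TRUE))
  desc <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, paste0("x", 1:5)))
  list(drugs = drugs, net = net,
       desc = descriptor_matrix(desc, quiet = TRUE))
}
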