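cat4 <- label_catalog(paste0("C", 1:4))

# a fixed 4-drug instance with hand-checkable rankings
hand_instance <- function() {
  drugs <- drug_set(paste0("d", 1:4),
                    list("C1", c("C1", "C2"), "C3", c("C2", "C4")), cat4)
  net <- interaction_network(
    c("d1", "d1", "d2", "d3"),
    c("d2", "d3", "d4", "d4"),
    c(500, 100, 300, 50))
  list(drugs = drugs, net = net)
}

test_that("jackknife leaves each drug out of its own evidence", {
  # 2-drug set with one edge: each ranking driven solely by the other
  ds <- drug_set(c("a", "b"), list("C2", "C3"), cat4)
  net <- interaction_network("a", "b", 700)
  preds <- jackknife(ds, net)
  expect_equal(preds[["a"]]$categories[1], "C3")
  expect_equal(preds[["b"]]$categories[1], "C2")
  # a drug with no edges gets the all-tied catalog-order ranking
  ds3 <- drug_set(c("a", "b", "x"), list("C2", "C3", "C4"), cat4)
  preds3 <- jackknife(ds3, net)
  expect_equal(preds3[["x"]]$categories, paste0("C", 1:4))
  expect_equal(preds3[["x"]]$tie_group, rep(1L, 4))
  expect_error(jackknife(drug_set("a", list("C1"), cat4), net),
               "at least 2")
})

test_that("jackknife equals explicit leave-one-out retraining", {
  inst <- random_instance(42)
  preds <- jackknife(inst$drugs, inst$net)
  for (q in inst$drugs$drug_ids) {
    rest <- drop_drugs(inst$drugs, q)
    manual <- rank_categories(score_categories(q, rest, inst$net),
                              inst$drugs$catalog, query_id = q)
    expect_equal(preds[[q]], manual)
  }
})

test_that("order accuracy counts j-th-rank hits over all drugs", {
  h <- hand_instance()
  preds <- jackknife(h$drugs, h$net)
  # d1: evidence d2 (500, C1+C2) + d3 (100, C3) -> C1=500,C2=500,C3=100
  expect_equal(preds[["d1"]]$categories, c("C1", "C2", "C3", "C4"))
  # d2: d1 (500, C1) + d4 (300, C2+C4) -> C1=500,C2=300,C4=300
  expect_equal(preds[["d2"]]$categories, c("C1", "C2", "C4", "C3"))
  # d3: d1 (100, C1) + d4 (50, C2+C4) -> C1, then C2/C4 tied, C3 last
  expect_equal(preds[["d3"]]$categories, c("C1", "C2", "C4", "C3"))
  # d4: d2 (300, C1+C2) + d3 (50, C3) -> C1=300,C2=300,C3=50
  expect_equal(preds[["d4"]]$categories, c("C1", "C2", "C3", "C4"))
  # hits at order 1: d1 (C1 true), d2 (C1 true) -> 2/4
  expect_equal(order_accuracy(preds, h$drugs, 1), 0.5)
  # order 2: d1 no (C2 not in {C1}), d2 yes (C2), d3 no, d4 yes -> 2/4
  expect_equal(order_accuracy(preds, h$drugs, 2), 0.5)
  expect_equal(order_accuracy(preds, h$drugs, 3), 0)
  expect_equal(order_accuracy(preds, h$drugs, 4), 0.5)  # d3: C3, d4: C4
  expect_error(order_accuracy(preds, h$drugs, 5), "1..4")
  # oracle agreement
  for (j in 1:4)
    expect_equal(order_accuracy(preds, h$drugs, j),
                 oracle_order_accuracy(preds, h$drugs, j))
})

test_that("per-category accuracies use per-category denominators", {
  h <- hand_instance()
  preds <- jackknife(h$drugs, h$net)
  acc <- per_category_order_accuracy(preds, h$drugs)
  # C1 drugs: d1, d2 -- both rank C1 first
  expect_equal(unname(acc[1, "C1"]), 1)
  # C3 drugs: d3 only, ranks C3 fourth
  expect_equal(unname(acc[4, "C3"]), 1)
  expect_equal(unname(acc[1, "C3"]), 0)
  expect_equal(acc, oracle_per_category(preds, h$drugs),
               ignore_attr = TRUE)
  # full rankings place each category exactly once: columns sum to 1
  expect_equal(unname(colSums(acc)), rep(1, 4))
  # an untreated category is undefined (NA), not zero
  ds <- drug_set(c("a", "b"), list("C1", "C2"), cat4)
  preds2 <- jackknife(ds, interaction_network("a", "b", 10))
  acc2 <- per_category_order_accuracy(preds2, ds)
  expect_true(all(is.na(acc2[, "C4"])))
  expect_false(anyNA(acc2[, "C1"]))
})

test_that("coverage ratio counts true pairs within the first m ranks", {
  h <- hand_instance()
  preds <- jackknife(h$drugs, h$net)
  # m=1: covered = d1:1, d2:1, d3:0, d4:0 of 6 pairs
  expect_equal(coverage_ratio(preds, h$drugs, 1), 2 / 6)
  expect_equal(coverage_ratio(preds, h$drugs, 2), 4 / 6)
  for (m in 1:4)
    expect_equal(coverage_ratio(preds, h$drugs, m),
                 oracle_coverage(preds, h$drugs, m))
  # non-decreasing in m; full-length rankings cover everything at m = M
  cov <- vapply(1:4, function(m) coverage_ratio(preds, h$drugs, m),
                numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_equal(cov[4], 1)
  # single drug with n=2 and one true label in its first two ranks
  ds <- drug_set(c("a", "b"), list(c("C1", "C3"), "C2"), cat4)
  p <- predict_indications("a", ds, interaction_network("a", "b", 10))
  expect_equal(coverage_ratio(p, ds, 2), 0.5)  # ranks C2,C1; C1 true
  expect_error(coverage_ratio(preds, h$drugs, 9), "1..4")
})

test_that("the coverage cutoff m is the ceiling of the average label count", {
  h <- hand_instance()
  expect_equal(choose_m(h$drugs), 2L)  # 6/4 = 1.5 -> 2
  single <- drug_set(c("a", "b"), list("C1", "C2"), cat4)
  expect_equal(choose_m(single), 1L)
})

test_that("precision and recall average per-drug set overlaps", {
  h <- hand_instance()
  sets <- label_sets(h$drugs)
  pr <- precision_recall(sets, h$drugs)
  expect_equal(unname(pr), c(1, 1))
  # hand instance with n_i in {1, 2}
  pred <- list(d1 = c("C1", "C2"), d2 = "C3", d3 = "C3",
               d4 = c("C2", "C3"))
  pr2 <- precision_recall(pred, h$drugs)
  expect_equal(unname(pr2["precision"]), mean(c(1 / 2, 0, 1, 1 / 2)))
  expect_equal(unname(pr2["recall"]), mean(c(1, 0, 1, 1 / 2)))
  expect_equal(pr2, oracle_precision_recall(pred, h$drugs))
  # empty predicted set contributes zero precision
  expect_message(
    pr3 <- precision_recall(list(d1 = character(), d2 = "C1"), h$drugs),
    "empty predicted set")
  expect_equal(unname(pr3["precision"]), mean(c(0, 1)))
})

test_that("singleton first-order precision equals first-order accuracy", {
  for (seed in c(3, 14, 25)) {
    inst <- random_instance(seed)
    preds <- jackknife(inst$drugs, inst$net)
    pr <- precision_recall(top_m_sets(preds, 1), inst$drugs)
    expect_identical(unname(pr["precision"]),
                     order_accuracy(preds, inst$drugs, 1))
  }
})

test_that("the aggregate report is internally consistent", {
  inst <- random_instance(9)
  preds <- jackknife(inst$drugs, inst$net)
  rep <- evaluate(preds, inst$drugs)
  M <- length(inst$drugs$catalog)
  expect_length(rep$order_accuracy, M)
  expect_true(all(rep$order_accuracy >= 0 & rep$order_accuracy <= 1))
  expect_equal(rep$coverage$m_used, choose_m(inst$drugs))
  expect_equal(rep$coverage$ratio,
               coverage_ratio(preds, inst$drugs, rep$coverage$m_used))
  expect_equal(rep$n_label_pairs, sum(n_labels(inst$drugs)))
  expect_gte(rep$n_label_pairs, rep$n_drugs)
  expect_equal(rep$precision, rep$order_accuracy[["Q1"]])
  # with full-length rankings every true pair lands at exactly one order:
  # sum_j Q_j * N = sum_i n_i
  expect_equal(sum(rep$order_accuracy) * rep$n_drugs,
               sum(n_labels(inst$drugs)))
  expect_output(print(rep), "order accuracies")
})

test_that("uniform guess rate reflects average labels per category count", {
  ds <- hand_instance()$drugs  # avg 1.5 labels over 4 categories
  expect_equal(uniform_guess_rate(ds), 1.5 / 4)
  expect_equal(uniform_guess_rate(1.31, n_categories = 8), 0.16375)
  expect_error(uniform_guess_rate(1.31), "n_categories")
})
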