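toy_distance <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(2 * n), n, 2)
  as.matrix(stats::dist(pts))
}

test_that("stratified splits respect counts, fractions and seeds", {
  labels <- rep(c("a", "b", "c"), each = 10)
  plan <- stratified_splits(labels, train_fraction = 0.5, n_replicates = 4,
                            seed = 1)
  for (r in plan$replicates) {
    expect_length(r$train, 15L)
    expect_length(r$test, 15L)
    expect_equal(as.integer(table(labels[r$train])), rep(5L, 3))
    expect_length(intersect(r$train, r$test), 0L)
    expect_setequal(c(r$train, r$test), 1:30)
  }
  expect_identical(stratified_splits(labels, 0.5, n_replicates = 4, seed = 1),
                   plan)
  expect_error(stratified_splits(rep(c("a", "b"), c(8, 8)),
                                 train_counts = 10, n_replicates = 2),
               "test object")
  expect_error(stratified_splits(c("a", "a", "b"), 0.5), "at least 2")
})

test_that("k-NN prediction follows the majority/nearest-tie rules", {
  # distance 0 to one training object wins at k = 1
  D <- matrix(1, 4, 4); diag(D) <- 0; D[4, 1] <- D[1, 4] <- 0
  pred <- knn_predict(D, train = 1:3, train_labels = c("x", "y", "z"),
                      test = 4L, k = 1)
  expect_equal(as.character(pred), "x")

  # majority (A, A, B) -> A
  D2 <- matrix(10, 4, 4); diag(D2) <- 0
  D2[4, 1:3] <- D2[1:3, 4] <- c(1, 2, 3)
  pred2 <- knn_predict(D2, 1:3, c("A", "A", "B"), 4L, k = 3)
  expect_equal(as.character(pred2), "A")

  # 2-2 vote tie -> class of the single nearest neighbour
  D3 <- matrix(10, 5, 5); diag(D3) <- 0
  D3[5, 1:4] <- D3[1:4, 5] <- c(1, 4, 2, 3)
  pred3 <- knn_predict(D3, 1:4, c("B", "B", "A", "A"), 5L, k = 4)
  expect_equal(as.character(pred3), "B")

  expect_error(knn_predict(D3, 1:4, c("B", "B", "A", "A"), 4L, k = 2),
               "disjoint")
  expect_error(knn_predict(D3, 1:4, c("B", "B", "A", "A"), 5L, k = 9),
               "out of range")
})

test_that("k-NN matches the brute-force oracle on toy matrices", {
  set.seed(42)
  for (seed in 1:3) {
    n <- 50
    D <- toy_distance(n, seed)
    labels <- sample(c("p", "q", "r"), n, replace = TRUE)
    train <- sort(sample(n, 30))
    test <- setdiff(1:n, train)
    for (k in c(1:12)) {
      mine <- as.character(knn_predict(D, train, labels, test, k))
      orac <- oracle_knn(D, train, labels, test, k)
      expect_identical(mine, unname(orac))
    }
  }
})

test_that("weighted F1 reproduces hand-computed values", {
  expect_equal(weighted_f1(c("A", "A", "B", "B"), c("A", "B", "B", "B")),
               11 / 15)
  expect_equal(weighted_f1(c("A", "A", "B", "B"), c("A", "A", "B", "B")), 1)
  expect_equal(weighted_f1(c("A", "A", "B", "B"), c("A", "A", "A", "A")),
               1 / 3)
  # invariant to consistent renaming
  set.seed(9)
  truth <- sample(c("a", "b", "c"), 30, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 30, replace = TRUE)
  map <- c(a = "z", b = "x", c = "y")
  expect_equal(weighted_f1(truth, pred),
               weighted_f1(unname(map[truth]), unname(map[pred])))
  expect_error(weighted_f1(character(0), character(0)), "empty")
  expect_error(weighted_f1(c("a"), c("a", "b")), "length")
})

test_that("evaluation reports mean F1, CI and bookkeeping-consistent confusion", {
  # perfectly separated blocks
  n <- 24
  labels <- rep(c("u", "v", "w"), each = 8)
  D <- matrix(5, n, n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    D[idx, idx] <- 0.1
  }
  diag(D) <- 0
  plan <- stratified_splits(labels, 0.5, n_replicates = 5, seed = 2)
  ev <- knn_evaluate(D, labels, plan, k = 3)
  expect_equal(ev$f1_mean, 1)
  expect_equal(diff(ev$f1_ci95), 0)
  # confusion row sums = test counts summed over replicates
  expect_equal(unname(rowSums(ev$confusion)), rep(4L * 5L, 3))

  # shuffled labels give chance-level accuracy on 4 balanced classes
  set.seed(7)
  n2 <- 80
  lab2 <- rep(c("a", "b", "c", "d"), each = 20)
  D2 <- toy_distance(n2, seed = 7)
  lab_shuffled <- sample(lab2)
  plan2 <- stratified_splits(lab_shuffled, 0.5, n_replicates = 20, seed = 7)
  ev2 <- knn_evaluate(D2, lab_shuffled, plan2, k = 5)
  expect_gt(ev2$f1_mean, 0.15)
  expect_lt(ev2$f1_mean, 0.35)
})

test_that("k tuning maximizes mean F1 and breaks ties downward", {
  set.seed(3)
  ds <- make_dataset(make_families(3, seed = 3),
                     nuisance_spec(vertex_noise_sd = 0.02,
                                   reparam_strength = 0,
                                   start_shift = FALSE),
                     n_per_class = 8, n_points = 40, seed = 3)
  al <- procrustes_align(lapply(ds$outlines, resample_arclength,
                                n_points = 40))
  D <- eigenshape_distances(fit_eigenshapes(al), variance_fraction = 0.99)
  plan <- stratified_splits(ds$labels, 0.5, n_replicates = 5, seed = 3)
  tuned <- tune_k(D, ds$labels, plan, 3:12)
  expect_true(all(tuned$scores[as.character(tuned$best_k)] >= tuned$scores))
  expect_identical(tune_k(D, ds$labels, plan, 7)$best_k, 7L)
  expect_error(tune_k(D, ds$labels, plan, integer(0)), "non-empty")
})

test_that("unlabeled partitions are scored by optimal group matching", {
  # relabel-invariance: any renaming of a perfect partition scores 1
  truth <- rep(c("A", "B", "C"), each = 4)
  groups <- rep(c(3, 1, 2), each = 4)
  expect_equal(partition_f1(truth, groups), 1)

  # hand-computed two-group case: best matching gives 11/15
  expect_equal(partition_f1(c("A", "A", "B", "B"), c(1, 1, 1, 2)), 11 / 15)

  expect_error(partition_f1(c("A", "A", "B", "B"), c(1, 2, 3, 3)),
               "more groups")

  # random partitions stay near chance level
  set.seed(11)
  truth4 <- rep(c("A", "B", "C", "D"), each = 10)
  scores <- vapply(1:100, function(i)
    partition_f1(truth4, sample(rep(1:4, each = 10))), numeric(1))
  expect_lt(mean(scores), 0.6)
  expect_gt(mean(scores), 0.2)
})

test_that("method comparisons use a paired t-test over shared replicates", {
  set.seed(6)
  n <- 60
  labels <- rep(c("a", "b", "c"), each = 20)
  pts <- matrix(stats::rnorm(2 * n), n, 2)
  pts[labels == "b", 1] <- pts[labels == "b", 1] + 3
  pts[labels == "c", 2] <- pts[labels == "c", 2] + 3
  D_good <- as.matrix(stats::dist(pts))
  D_bad <- toy_distance(n, seed = 99)              # label-free distances
  plan <- stratified_splits(labels, 0.5, n_replicates = 10, seed = 6)
  ev_good <- knn_evaluate(D_good, labels, plan, 3)
  ev_bad <- knn_evaluate(D_bad, labels, plan, 3)
  cmp <- compare_methods(ev_good, ev_bad)
  expect_gt(cmp$mean_difference, 0)
  expect_lt(cmp$p_value, 0.05)
  plan2 <- stratified_splits(labels, 0.5, n_replicates = 5, seed = 7)
  expect_error(compare_methods(ev_good,
                               knn_evaluate(D_bad, labels, plan2, 3)),
               "same split plan")
})
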