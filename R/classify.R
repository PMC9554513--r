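#' Stratified train/test split plans
#'
#' Repeated stratified holdout: each replicate samples a fixed number of
#' training objects per class without replacement (the rest are the test
#' set). With `train_fraction` the per-class counts are allocated by
#' largest-remainder rounding of class proportions.
#'
#' @param labels class labels (factor or character), one per object.
#' @param train_fraction overall training fraction (used unless
#'   `train_counts` is given).
#' @param train_counts per-class training counts: a single number applied
#'   to every class, or a named vector by class.
#' @param n_replicates number of replicates.
#' @param seed integer seed; identical seeds give identical plans.
#' @return a `split_plan`: list with `replicates` (list of
#'   `list(train, test)` index vectors), `n_replicates`, `seed`,
#'   `stratified = TRUE`.
#' @examples
#' plan <- stratified_splits(rep(c("a", "b"), each = 10), 0.5,
#'                           n_replicates = 4, seed = 1)
#' lengths(plan$replicates[[1]])
#' @export
stratified_splits <- function(labels, train_fraction = 0.67,
                              train_counts = NULL, n_replicates = 100L,
                              seed = 1L) {
  labels <- factor(labels)
  n <- length(labels)
  sizes <- table(labels)
  if (any(sizes < 2L)) stop("every class needs at least 2 members")
  cls <- levels(labels)
  if (is.null(train_counts)) {
    stopifnot(train_fraction > 0, train_fraction < 1)
    total <- round(train_fraction * n)
    raw <- as.numeric(sizes) * total / n
    cnt <- floor(raw)
    rem <- total - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    train_counts <- stats::setNames(as.integer(cnt), cls)
  } else if (length(train_counts) == 1L) {
    train_counts <- stats::setNames(rep(as.integer(train_counts),
                                        length(cls)), cls)
  } else {
    if (is.null(names(train_counts)) || !all(cls %in% names(train_counts)))
      stop("`train_counts` must be named by class")
    train_counts <- stats::setNames(as.integer(train_counts[cls]), cls)
  }
  if (any(train_counts < 1L))
    stop("each class needs at least 1 training object")
  if (any(train_counts >= as.numeric(sizes)))
    stop("training count must leave at least one test object per class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  reps <- lapply(seq_len(n_replicates), function(r) {
    train <- integer(0)
    for (cl in cls) {
      idx <- which(labels == cl)
      train <- c(train, sample(idx, train_counts[[cl]]))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
  structure(list(replicates = reps, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), stratified = TRUE,
                 train_counts = train_counts, labels = labels),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  r1 <- x$replicates[[1L]]
  cat(sprintf("<split_plan> %d replicates, %d train / %d test, seed %d\n",
              x$n_replicates, length(r1$train), length(r1$test), x$seed))
  invisible(x)
}

#' k-nearest-neighbour prediction from a distance matrix
#'
#' For each test object the k nearest training objects vote; the modal
#' label wins. A vote tie is resolved in favour of the tied class with the
#' single nearest neighbour; distance ties at the k-th neighbour are broken
#' by object order (stable, deterministic).
#'
#' @param D a [shape_dist] or square distance matrix.
#' @param train,test disjoint index vectors into the matrix.
#' @param train_labels labels of the training objects (recycled from
#'   `labels[train]` if a full `labels` vector is passed).
#' @param k neighbourhood size (1 <= k <= length(train)).
#' @return factor of predicted labels, one per test object.
#' @export
knn_predict <- function(D, train, train_labels, test, k) {
  V <- if (inherits(D, "shape_dist")) D$values else as.matrix(D)
  if (length(train_labels) == nrow(V)) train_labels <- train_labels[train]
  stopifnot(length(train_labels) == length(train))
  if (length(intersect(train, test)) > 0L)
    stop("train and test sets must be disjoint")
  if (k < 1L || k > length(train)) stop("`k` out of range")
  train_labels <- factor(train_labels)
  pred <- character(length(test))
  for (ti in seq_along(test)) {
    d <- V[test[ti], train]
    ord <- order(d)                 # stable: ties by training object order
    nb <- ord[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      # tie: the tied class owning the single nearest neighbour wins
      for (cand in nb) {
        lab <- as.character(train_labels[cand])
        if (lab %in% top) { top <- lab; break }
      }
    }
    pred[ti] <- top[1L]
  }
  factor(pred, levels = levels(train_labels))
}

#' Support-weighted F1 score
#'
#' Per class c: precision P = TP/(TP+FP), recall R = TP/(TP+FN),
#' F1 = 2PR/(P+R) (zero when P+R = 0); the score is the support-weighted
#' average over the classes present in the truth.
#'
#' @param truth true labels.
#' @param pred predicted labels (same length).
#' @return scalar in [0, 1].
#' @examples
#' weighted_f1(c("A", "A", "B", "B"), c("A", "B", "B", "B"))  # 11/15
#' @export
weighted_f1 <- function(truth, pred) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  truth <- as.character(truth)
  pred <- as.character(pred)
  n <- length(truth)
  out <- 0
  for (cl in unique(truth)) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out <- out + (tp + fn) / n * f1
  }
  out
}

#' Evaluate a k-NN classifier over a split plan
#'
#' Runs [knn_predict] on every replicate, reporting the per-replicate
#' weighted F1 scores, their mean with a normal-approximation 95%
#' confidence interval (mean +/- 1.96 sd/sqrt(R)) and the confusion matrix
#' pooled over all test predictions (rows = truth, columns = predicted).
#'
#' @param D a [shape_dist] or square distance matrix.
#' @param labels class labels for all objects.
#' @param plan a `split_plan`.
#' @param k neighbourhood size.
#' @return a `knn_eval`: list with `f1_mean`, `f1_ci95`, `per_replicate_f1`,
#'   `confusion`, `k`.
#' @export
knn_evaluate <- function(D, labels, plan, k) {
  V <- if (inherits(D, "shape_dist")) D$values else as.matrix(D)
  labels <- factor(labels)
  if (length(labels) != nrow(V)) stop("labels and distance matrix disagree")
  stopifnot(inherits(plan, "split_plan"))
  f1s <- numeric(plan$n_replicates)
  conf <- matrix(0L, nlevels(labels), nlevels(labels),
                 dimnames = list(truth = levels(labels),
                                 predicted = levels(labels)))
  for (r in seq_len(plan$n_replicates)) {
    sp <- plan$replicates[[r]]
    pred <- knn_predict(V, sp$train, labels, sp$test, k)
    truth <- labels[sp$test]
    f1s[r] <- weighted_f1(truth, pred)
    conf <- conf + unclass(table(truth, pred))
  }
  m <- mean(f1s)
  half <- if (plan$n_replicates > 1L)
    1.96 * stats::sd(f1s) / sqrt(plan$n_replicates) else 0
  structure(list(f1_mean = m, f1_ci95 = c(m - half, m + half),
                 per_replicate_f1 = f1s, confusion = conf, k = k),
            class = "knn_eval")
}

#' @export
print.knn_eval <- function(x, ...) {
  cat(sprintf("<knn_eval> k = %d, mean weighted F1 = %.3f (95%% CI %.3f-%.3f, %d replicates)\n",
              x$k, x$f1_mean, x$f1_ci95[1L], x$f1_ci95[2L],
              length(x$per_replicate_f1)))
  invisible(x)
}

#' @export
summary.knn_eval <- function(object, ...) {
  print(object)
  cat("\nPooled confusion matrix (rows = truth):\n")
  print(object$confusion)
  invisible(object)
}

#' Tune the k-NN neighbourhood size
#'
#' @param D distance matrix, `labels`, `plan` as in [knn_evaluate].
#' @param labels class labels.
#' @param plan a `split_plan`.
#' @param k_grid candidate k values (default 3:12).
#' @return list with `best_k` (smallest k maximizing the mean F1) and
#'   `scores` (named mean-F1 vector over the grid).
#' @export
tune_k <- function(D, labels, plan, k_grid = 3:12) {
  if (length(k_grid) == 0L) stop("`k_grid` must be non-empty")
  n_train <- min(vapply(plan$replicates, function(r) length(r$train),
                        integer(1)))
  k_grid <- sort(k_grid[k_grid <= n_train])
  if (length(k_grid) == 0L)
    stop("no k in the grid fits the training-set size")
  scores <- vapply(k_grid, function(k)
    knn_evaluate(D, labels, plan, k)$f1_mean, numeric(1))
  names(scores) <- k_grid
  best <- k_grid[which.max(scores)]  # which.max takes the first maximum;
                                     # grid sorted ascending => smallest k
  list(best_k = as.integer(best), scores = scores)
}

#' Score an unlabeled partition against ground truth
#'
#' Expert-style classifications assign objects to anonymous groups. Each
#' group is matched one-to-one to a distinct ground-truth class by the
#' assignment that maximizes the weighted F1 (Hungarian algorithm on the
#' per-pair F1 contributions), and that maximal weighted F1 is returned.
#'
#' @param truth true class labels.
#' @param groups group memberships (any labels), same length; at most as
#'   many distinct groups as classes.
#' @return scalar weighted F1 in [0, 1].
#' @examples
#' partition_f1(c("A", "A", "B", "B"), c(1, 1, 1, 2))  # 11/15
#' @export
partition_f1 <- function(truth, groups) {
  if (length(truth) != length(groups)) stop("inputs differ in length")
  truth <- factor(truth)
  groups <- factor(groups)
  n <- length(truth)
  K <- nlevels(truth)
  G <- nlevels(groups)
  if (G > K) stop("more groups than ground-truth classes")
  # W[g, c]: weighted-F1 contribution if group g is read as class c
  W <- matrix(0, G, K)
  for (g in seq_len(G)) for (cl in seq_len(K)) {
    tp <- sum(groups == levels(groups)[g] & truth == levels(truth)[cl])
    gsz <- sum(groups == levels(groups)[g])
    csz <- sum(truth == levels(truth)[cl])
    if (tp > 0) W[g, cl] <- (csz / n) * 2 * tp / (gsz + csz)
  }
  sol <- clue::solve_LSAP(W, maximum = TRUE)
  sum(W[cbind(seq_len(G), as.integer(sol))])
}

#' Paired comparison of two shape-method evaluations
#'
#' Paired two-tailed t-test over per-replicate weighted F1 scores from two
#' [knn_evaluate] runs that used the same split plan, asking whether one
#' distance method outperforms the other beyond split-to-split noise.
#'
#' @param eval1,eval2 `knn_eval` objects evaluated on the same `split_plan`.
#' @return list with `mean_difference` (eval1 minus eval2), `p_value`,
#'   `t_statistic`.
#' @export
compare_methods <- function(eval1, eval2) {
  stopifnot(inherits(eval1, "knn_eval"), inherits(eval2, "knn_eval"))
  a <- eval1$per_replicate_f1
  b <- eval2$per_replicate_f1
  if (length(a) != length(b))
    stop("evaluations must share the same split plan")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(mean_difference = mean(a - b),
       p_value = tt$p.value,
       t_statistic = unname(tt$statistic))
}
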