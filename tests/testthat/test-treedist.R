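test_that("class-average distances reduce the object matrix correctly", {
  D <- matrix(0, 3, 3)
  D[1, 3] <- D[3, 1] <- 2
  D[2, 3] <- D[3, 2] <- 4
  D[1, 2] <- D[2, 1] <- 1
  labels <- c("a", "a", "b")
  cm <- class_mean_distances(D, labels)
  expect_equal(cm$values["a", "b"], 3)     # mean of 2 and 4
  expect_equal(cm$values["a", "a"], 1)     # the single within pair
  expect_equal(cm$values["b", "b"], 0)     # singleton class

  # permutation invariance
  perm <- c(3, 1, 2)
  cm2 <- class_mean_distances(D[perm, perm], labels[perm])
  expect_equal(cm2$values, cm$values)

  # block-constant matrices are reproduced exactly
  lab <- rep(c("x", "y"), each = 3)
  B <- matrix(7, 6, 6)
  B[1:3, 1:3] <- 2; B[4:6, 4:6] <- 3
  diag(B) <- 0
  cb <- class_mean_distances(B, lab)
  expect_equal(cb$values["x", "y"], 7)
  expect_error(class_mean_distances(D, c("a", "a")), "cover")
})

test_that("metric correlation is affine-invariant Pearson r off the diagonal", {
  set.seed(4)
  V <- matrix(stats::runif(16, 1, 5), 4, 4)
  V <- (V + t(V)) / 2
  ids <- letters[1:4]
  m1 <- structure(list(values = V, class_ids = ids, method = "m1"),
                  class = "class_dist")
  V2 <- 2 * V + 1
  m2 <- structure(list(values = V2, class_ids = ids, method = "m2"),
                  class = "class_dist")
  expect_equal(metric_correlation(m1, m2), 1)
  m3 <- m2; m3$values <- -V
  expect_equal(metric_correlation(m1, m3), -1)

  # shuffled entries decorrelate on average
  set.seed(8)
  K <- 6
  W <- matrix(stats::runif(K * K), K, K); W <- (W + t(W)) / 2; diag(W) <- 0
  base <- structure(list(values = W, class_ids = letters[1:K], method = "m"),
                    class = "class_dist")
  ut <- which(upper.tri(W))
  rs <- vapply(1:200, function(i) {
    Wp <- W
    Wp[ut] <- sample(W[ut])
    Wp[lower.tri(Wp)] <- t(Wp)[lower.tri(Wp)]
    metric_correlation(base, structure(list(values = Wp,
                                            class_ids = letters[1:K],
                                            method = "p"),
                                       class = "class_dist"))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)

  small <- structure(list(values = W[1:2, 1:2], class_ids = letters[1:2],
                          method = "m"), class = "class_dist")
  expect_error(metric_correlation(small, small), "at least 3")
})

test_that("neighbour joining recovers additive trees exactly", {
  # 4-taxon tree ((A:1,B:2):5,(C:3,D:4)) -> additive distance matrix
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3                # 1 + 2
  D["A", "C"] <- 9                # 1 + 5 + 3
  D["A", "D"] <- 10               # 1 + 5 + 4
  D["B", "C"] <- 10               # 2 + 5 + 3
  D["B", "D"] <- 11               # 2 + 5 + 4
  D["C", "D"] <- 7                # 3 + 4
  D <- D + t(D)
  tr <- neighbour_joining(D)
  expect_s3_class(tr, "phylo")
  # topology: AB vs CD split; path lengths reproduce the inputs exactly
  paths <- ape::cophenetic.phylo(tr)
  expect_equal(paths[rownames(D), colnames(D)], D, tolerance = 1e-10)
  expect_true(ape::is.monophyletic(ape::root(tr, "A"), c("C", "D")))

  # small perturbations leave the topology unchanged
  set.seed(12)
  for (i in 1:5) {
    noise <- matrix(stats::runif(16, -0.005, 0.005), 4, 4)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    tr2 <- neighbour_joining(D * (1 + noise))
    expect_equal(unname(ape::dist.topo(ape::unroot(tr),
                                       ape::unroot(tr2))[1]), 0)
  }
  expect_error(neighbour_joining(matrix(c(0, NA, NA, 0), 2, 2)), "finite")
})

test_that("negative NJ branch estimates are clamped without losing length", {
  # a non-additive matrix known to produce a negative NJ branch
  D <- matrix(c(0, 2, 2, 0.1,
                2, 0, 0.1, 2,
                2, 0.1, 0, 2,
                0.1, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(stats::as.dist(D))
  tr <- neighbour_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-10)
})

test_that("rooting preserves leaf-to-leaf path lengths", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 9; D["A", "D"] <- 10
  D["B", "C"] <- 10; D["B", "D"] <- 11; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbour_joining(D)
  for (taxon in LETTERS[1:4]) {
    rooted <- root_at(tr, taxon)
    p1 <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
    p2 <- ape::cophenetic.phylo(rooted)[LETTERS[1:4], LETTERS[1:4]]
    expect_lt(max(abs(p1 - p2)), 1e-10)
    expect_equal(ape::dist.topo(ape::unroot(rooted), ape::unroot(tr))[1], 0)
  }
  expect_error(root_at(tr, "Z"), "unknown")
})

test_that("monophyly verdicts agree with the bipartition oracle", {
  cater <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  res <- monophyly_check(cater, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_true(all(res))
  mixed <- ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1);")
  res2 <- monophyly_check(mixed, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_false(any(res2))

  set.seed(21)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    fam <- sample(c("f1", "f2", "f3"), 8, replace = TRUE)
    names(fam) <- tr$tip.label
    mine <- monophyly_check(tr, fam)
    for (f in unique(fam)) {
      tips <- names(fam)[fam == f]
      if (length(tips) <= 1) next
      expect_identical(unname(mine[f]), oracle_monophyletic(tr, tips))
    }
  }
  expect_error(monophyly_check(cater, c(A1 = "A")), "group assignment")
})

test_that("trees write to parseable Newick", {
  tr <- ape::read.tree(text = "((A:1,B:2):5,(C:3,D:4):0);")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tr$tip.label)
})
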