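#' Class-average distance matrix
#'
#' Mean pairwise distance between (and within) classes: entry (a, b) with
#' a != b is the mean of all cross-pairs, entry (a, a) the mean within-class
#' pairwise distance (0 for singletons). The diagonal is reported but
#' excluded from correlations and tree building.
#'
#' @param D a [shape_dist] or square distance matrix.
#' @param labels class labels, one per object.
#' @return a `class_dist`: list with `values` (K x K), `class_ids`,
#'   `method`.
#' @export
class_mean_distances <- function(D, labels) {
  V <- if (inherits(D, "shape_dist")) D$values else as.matrix(D)
  labels <- factor(labels)
  if (length(labels) != nrow(V))
    stop("labels must cover all objects in the distance matrix")
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 classes")
  M <- matrix(0, K, K, dimnames = list(levels(labels), levels(labels)))
  for (a in seq_len(K)) for (b in a:K) {
    ia <- which(labels == levels(labels)[a])
    ib <- which(labels == levels(labels)[b])
    if (a == b) {
      M[a, a] <- if (length(ia) > 1L)
        mean(V[ia, ia][upper.tri(diag(length(ia)))]) else 0
    } else {
      M[a, b] <- M[b, a] <- mean(V[ia, ib])
    }
  }
  structure(list(values = M, class_ids = levels(labels),
                 method = if (inherits(D, "shape_dist")) D$method else "unknown"),
            class = "class_dist")
}

#' @export
print.class_dist <- function(x, ...) {
  cat(sprintf("<class_dist> %d classes, method %s\n",
              length(x$class_ids), x$method))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.matrix.class_dist <- function(x, ...) x$values

#' Pearson correlation between two class-distance matrices
#'
#' Correlates the K(K-1)/2 off-diagonal upper-triangular entries; high r
#' means the two metrics place the classes similarly in shape space.
#'
#' @param M1,M2 `class_dist` objects over the same classes in the same
#'   order.
#' @return Pearson r.
#' @export
metric_correlation <- function(M1, M2) {
  stopifnot(inherits(M1, "class_dist"), inherits(M2, "class_dist"))
  if (!identical(M1$class_ids, M2$class_ids))
    stop("class sets differ or are ordered differently")
  K <- length(M1$class_ids)
  if (K < 3L) stop("correlation needs at least 3 classes")
  ut <- upper.tri(M1$values)
  stats::cor(M1$values[ut], M2$values[ut])
}

#' Neighbour-joining tree from class-average distances
#'
#' Standard neighbour joining (via ape) on the off-diagonal class-average
#' distances. Negative branch-length estimates are clamped to zero with the
#' deficit transferred to the sibling edge, preserving path lengths through
#' the parent node.
#'
#' @param M a `class_dist`, [shape_dist] or square distance matrix with at
#'   least 3 classes.
#' @return an ape `phylo` tree with the classes as tips.
#' @export
neighbour_joining <- function(M) {
  V <- if (inherits(M, "class_dist")) M$values
       else if (inherits(M, "shape_dist")) M$values
       else as.matrix(M)
  if (!all(is.finite(V))) stop("distance matrix has non-finite entries")
  if (nrow(V) < 3L) stop("neighbour joining needs at least 3 classes")
  V0 <- V
  diag(V0) <- 0
  tr <- ape::nj(stats::as.dist(V0))
  .clamp_negative_edges(tr)
}

# zero out negative branch lengths, moving the deficit to the sibling edge
.clamp_negative_edges <- function(tr) {
  el <- tr$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent & seq_along(el) != e)
    if (length(sibs) > 0L) el[sibs[1L]] <- el[sibs[1L]] + el[e]
    el[e] <- 0
  }
  el[el < 0] <- 0
  tr$edge.length <- el
  tr
}

#' Re-root a tree at a named tip
#'
#' @param tree an ape `phylo`.
#' @param taxon tip label to use as outgroup root.
#' @return rooted `phylo`; leaf-to-leaf path lengths are unchanged.
#' @export
root_at <- function(tree, taxon) {
  stopifnot(inherits(tree, "phylo"))
  if (!taxon %in% tree$tip.label) stop("unknown taxon: ", taxon)
  ape::root(tree, outgroup = taxon, resolve.root = TRUE)
}

#' Monophyly of predefined groups on a tree
#'
#' A group is monophyletic when some edge of the tree separates exactly its
#' tips from all others (the bipartition sense, so the verdict does not
#' depend on where the tree is rooted).
#'
#' @param tree an ape `phylo` (rooted or unrooted).
#' @param groups named character vector mapping tip label -> group (family).
#' @return named logical vector, one entry per group.
#' @export
monophyly_check <- function(tree, groups) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(groups)))
    stop("every tip needs a group assignment")
  n_tip <- length(tree$tip.label)
  parts <- lapply(ape::prop.part(tree), sort)
  fams <- unique(unname(groups[tree$tip.label]))
  out <- vapply(fams, function(f) {
    target <- sort(unname(which(groups[tree$tip.label] == f)))
    if (length(target) <= 1L) return(TRUE)
    comp <- sort(setdiff(seq_len(n_tip), target))
    any(vapply(parts, function(p)
      identical(p, target) || identical(p, comp), logical(1)))
  }, logical(1))
  names(out) <- fams
  out
}

#' Write a tree in Newick format
#' @param tree an ape `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
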