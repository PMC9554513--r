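#' Eigenshape analysis of Procrustes-aligned outlines
#'
#' Linear (geometric-morphometric) shape space: the aligned semi-landmark
#' coordinates of each outline are flattened to a 2N-vector and reduced by
#' principal components analysis of their covariance (via singular value
#' decomposition of the centred data matrix). Shape distances are Euclidean
#' distances between score vectors truncated at a variance-explained cutoff.
#'
#' @param aligned an `aligned_set` from [procrustes_align] with >= 3 members.
#' @return an `eigenshapes` model: list with `mean_vector` (2N),
#'   `components` (2N x r orthonormal columns), `eigenvalues` (descending),
#'   `scores` (n x r), `ids`, `n_points`, `closed`.
#' @examples
#' ds <- make_dataset(make_families(3, seed = 1), n_per_class = 5, seed = 2)
#' al <- procrustes_align(lapply(ds$outlines, resample_arclength, n_points = 60))
#' es <- fit_eigenshapes(al)
#' summary(es)
#' @export
fit_eigenshapes <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_set"))
  n <- length(aligned$outlines)
  if (n < 3L) stop("eigenshape analysis needs at least 3 shapes")
  X <- t(vapply(aligned$outlines, function(o) as.vector(o$points),
                numeric(2L * nrow(aligned$outlines[[1L]]$points))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(mean_vector = pc$center,
                 components = pc$rotation,
                 eigenvalues = pc$sdev^2,
                 scores = pc$x,
                 ids = vapply(aligned$outlines,
                              function(o) if (is.null(o$id)) "" else o$id,
                              character(1)),
                 n_points = nrow(aligned$outlines[[1L]]$points),
                 closed = aligned$outlines[[1L]]$closed),
            class = "eigenshapes")
}

#' @export
print.eigenshapes <- function(x, ...) {
  cat(sprintf("<eigenshapes> %d shapes, %d semi-landmarks, %d components\n",
              nrow(x$scores), x$n_points, ncol(x$scores)))
  invisible(x)
}

#' @export
summary.eigenshapes <- function(object, ...) {
  ev <- object$eigenvalues
  cum <- cumsum(ev) / sum(ev)
  cat(sprintf("Eigenshape model: %d shapes, %d semi-landmarks\n",
              nrow(object$scores), object$n_points))
  k <- min(10L, length(ev))
  print(data.frame(component = seq_len(k), eigenvalue = signif(ev[seq_len(k)], 4),
                   cum_variance = round(cum[seq_len(k)], 4)), row.names = FALSE)
  invisible(object)
}

#' Smallest dimension explaining a variance fraction
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @param variance_fraction target fraction of total variance in (0, 1].
#' @return smallest d with cumulative variance ratio >= `variance_fraction`.
#' @examples
#' select_dims(c(9, 1), 0.75)  # 1
#' select_dims(c(9, 1), 0.95)  # 2
#' @export
select_dims <- function(eigenvalues, variance_fraction) {
  stopifnot(is.numeric(eigenvalues), length(eigenvalues) >= 1L,
            variance_fraction > 0, variance_fraction <= 1)
  if (all(eigenvalues <= 0)) stop("all eigenvalues are zero")
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  as.integer(which(cum >= variance_fraction - 1e-12)[1L])
}

#' Euclidean shape distances in truncated eigenshape space
#'
#' @param model an `eigenshapes` model.
#' @param d number of leading components to use, or `variance_fraction` to
#'   choose d via [select_dims].
#' @param variance_fraction optional variance-explained cutoff (used when
#'   `d` is missing).
#' @return a [shape_dist] distance matrix.
#' @export
eigenshape_distances <- function(model, d = NULL, variance_fraction = NULL) {
  stopifnot(inherits(model, "eigenshapes"))
  if (is.null(d)) {
    if (is.null(variance_fraction))
      stop("supply `d` or `variance_fraction`")
    d <- select_dims(model$eigenvalues, variance_fraction)
  }
  if (d < 1L || d > ncol(model$scores))
    stop("`d` exceeds the number of available components")
  D <- as.matrix(stats::dist(model$scores[, seq_len(d), drop = FALSE]))
  shape_dist(D, ids = model$ids, method = sprintf("eigenshapes_d%d", d))
}

#' Linear (vertex-wise arithmetic) mean shape
#'
#' @param aligned an `aligned_set`.
#' @param members optional indices or ids of the members to average.
#' @return an [outline]; carries attribute `degenerate = TRUE` when the
#'   mean collapses (centroid size below 1e-10).
#' @export
linear_mean <- function(aligned, members = NULL) {
  stopifnot(inherits(aligned, "aligned_set"))
  os <- aligned$outlines
  if (!is.null(members)) {
    if (is.character(members)) {
      ids <- vapply(os, function(o) if (is.null(o$id)) "" else o$id, character(1))
      members <- match(members, ids)
      if (anyNA(members)) stop("unknown member id")
    }
    os <- os[members]
  }
  if (length(os) == 0L) stop("empty member set")
  m <- Reduce(`+`, lapply(os, function(o) o$points)) / length(os)
  degenerate <- sqrt(sum(sweep(m, 2L, colMeans(m))^2)) < 1e-10
  if (degenerate) {
    out <- structure(list(points = m, closed = os[[1L]]$closed,
                          id = NULL, label = NULL), class = "outline")
  } else {
    out <- outline(m, closed = os[[1L]]$closed)
  }
  attr(out, "degenerate") <- degenerate
  out
}
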