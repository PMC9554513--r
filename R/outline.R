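#' Planar outline curves
#'
#' An `outline` is an ordered sequence of planar points, either closed
#' (a polygon; the first vertex is not repeated at the end) or open
#' (endpoints are meaningful, e.g. homologous landmarks). It is the
#' universal shape record passed between all stages of the package.
#'
#' @param points numeric matrix with two columns (x, y) and at least 3 rows.
#' @param closed logical; is the curve a closed polygon?
#' @param id optional object identifier.
#' @param label optional class label.
#' @return an object of class `outline`: a list with elements `points`,
#'   `closed`, `id`, `label`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 101)[-101]
#' circ <- outline(cbind(cos(th), sin(th)))
#' print(circ)
#' @export
outline <- function(points, closed = TRUE, id = NULL, label = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  if (nrow(points) < 3L) stop("an outline needs at least 3 points")
  if (!all(is.finite(points))) stop("outline coordinates must be finite")
  if (isTRUE(closed) &&
      sqrt(sum((points[1L, ] - points[nrow(points), ])^2)) < 1e-12) {
    points <- points[-nrow(points), , drop = FALSE]  # drop duplicated closure
  }
  d <- sqrt(rowSums((points - rbind(points[-1L, , drop = FALSE],
                                    points[1L, , drop = FALSE]))^2))
  if (!closed) d <- d[-length(d)]
  if (any(d < 1e-300)) stop("consecutive outline points must be distinct")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, closed = isTRUE(closed),
                 id = id, label = label),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s, %d points%s%s\n",
              if (x$closed) "closed" else "open", nrow(x$points),
              if (!is.null(x$id)) paste0(", id=", x$id) else "",
              if (!is.null(x$label)) paste0(", label=", x$label) else ""))
  invisible(x)
}

#' @export
plot.outline <- function(x, ..., asp = 1, type = "l") {
  pts <- x$points
  if (x$closed) pts <- rbind(pts, pts[1L, ])
  plot(pts, asp = asp, type = type, xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' @export
lines.outline <- function(x, ...) {
  pts <- x$points
  if (x$closed) pts <- rbind(pts, pts[1L, ])
  lines(pts, ...)
  invisible(x)
}

#' @export
as.matrix.outline <- function(x, ...) x$points

is_outline <- function(x) inherits(x, "outline")

#' Outline centroid and centroid size
#'
#' Centroid size is the root sum of squared distances of the vertices from
#' their centroid, the standard size measure of geometric morphometrics.
#'
#' @param x an [outline] or a two-column coordinate matrix.
#' @return `outline_centroid`: length-2 numeric. `centroid_size`: scalar.
#' @export
outline_centroid <- function(x) {
  pts <- if (is_outline(x)) x$points else as.matrix(x)
  colMeans(pts)
}

#' @rdname outline_centroid
#' @export
centroid_size <- function(x) {
  pts <- if (is_outline(x)) x$points else as.matrix(x)
  ctr <- colMeans(pts)
  sqrt(sum(sweep(pts, 2L, ctr)^2))
}

#' Signed polygon area of a closed outline
#'
#' Shoelace formula; positive for counter-clockwise orientation.
#'
#' @param x a closed [outline].
#' @return scalar signed area.
#' @export
outline_area <- function(x) {
  stopifnot(is_outline(x), x$closed)
  p <- x$points
  q <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  sum(p[, 1L] * q[, 2L] - q[, 1L] * p[, 2L]) / 2
}

#' Perimeter (total chord length) of an outline
#' @param x an [outline].
#' @return scalar length.
#' @export
outline_perimeter <- function(x) {
  p <- x$points
  seg <- diff(rbind(p, if (x$closed) p[1L, , drop = FALSE]))
  sum(sqrt(rowSums(seg^2)))
}

#' Canonical storage form of an outline
#'
#' Closed outlines are stored counter-clockwise, starting at the vertex of
#' maximum y (ties broken by minimum x), which keeps file round-trips and
#' seed searches reproducible. Open outlines are returned unchanged.
#'
#' @param x an [outline].
#' @return an [outline] in canonical form.
#' @export
canonicalize_outline <- function(x) {
  stopifnot(is_outline(x))
  p <- x$points
  if (x$closed) {
    if (outline_area(x) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    i <- which(p[, 2L] == max(p[, 2L]))
    if (length(i) > 1L) i <- i[which.min(p[i, 1L])]
    if (i > 1L) p <- p[c(i:nrow(p), 1L:(i - 1L)), , drop = FALSE]
  }
  outline(p, closed = x$closed, id = x$id, label = x$label)
}

#' Read and write outline CSV files
#'
#' One outline per file: ordered `x`, `y` columns. A closed outline is
#' stored without repeating its first vertex.
#'
#' @param x an [outline].
#' @param path file path.
#' @param closed logical, closure flag to attach on read.
#' @param id,label optional metadata to attach on read.
#' @return `read_outline_csv` returns an [outline]; `write_outline_csv`
#'   returns `path` invisibly.
#' @export
write_outline_csv <- function(x, path) {
  stopifnot(is_outline(x))
  utils::write.csv(as.data.frame(x$points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path, closed = TRUE, id = NULL, label = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("outline CSV needs x,y columns")
  outline(cbind(df$x, df$y), closed = closed, id = id, label = label)
}

#' Number of unordered pairs among n objects
#'
#' The length of the upper triangle of an n-by-n distance matrix,
#' n(n-1)/2 — e.g. 716 objects give 255970 pairwise distances.
#'
#' @param n integer >= 2.
#' @return integer pair count.
#' @examples
#' pair_count(716)
#' @export
pair_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2")
  as.integer(round(n * (n - 1) / 2))
}
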