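#' Binarize a greyscale image
#'
#' @param image numeric matrix with values in [0, 1] (rows are image rows).
#' @param threshold scalar in (0, 1), or `"otsu"` to select it automatically
#'   by Otsu's method.
#' @param polarity `"light"` if the object is brighter than the background
#'   (foreground = pixels above threshold), `"dark"` for the reverse.
#' @return integer 0/1 matrix of the same dimensions.
#' @export
binarize <- function(image, threshold = "otsu", polarity = c("light", "dark")) {
  polarity <- match.arg(polarity)
  image <- as.matrix(image)
  if (length(image) == 0L) stop("empty image")
  if (identical(threshold, "otsu")) {
    threshold <- EBImage::otsu(image, range = c(0, 1))
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  fg <- if (polarity == "light") image > threshold else image < threshold
  if (all(fg) || !any(fg))
    stop("thresholding produced an empty foreground or background")
  mode(fg) <- "integer"
  fg
}

#' Extract the dominant closed contour from a binary mask
#'
#' Marching squares (via isoband) at level 0.5; when several closed
#' contours exist, the one enclosing the greatest polygon area is returned,
#' oriented counter-clockwise. Pixel (row r, col c) maps to
#' (x = c, y = nrow - r) so the outline lives in y-up coordinates.
#'
#' @param mask 0/1 integer matrix (e.g. from [binarize] or
#'   [rasterize_outline]).
#' @return a closed [outline] in pixel units.
#' @export
extract_contour <- function(mask) {
  mask <- as.matrix(mask)
  if (!any(mask > 0)) stop("mask has no foreground component")
  nr <- nrow(mask)
  iso <- isoband::isolines(x = seq_len(ncol(mask)), y = seq_len(nr),
                           z = mask * 1.0, levels = 0.5)[[1L]]
  if (length(iso$x) == 0L) stop("no contour found at level 0.5")
  best <- NULL
  best_area <- -Inf
  for (k in unique(iso$id)) {
    sel <- iso$id == k
    px <- iso$x[sel]
    py <- nr - iso$y[sel]
    n <- length(px)
    if (n < 4L) next
    closed_ring <- sqrt((px[1L] - px[n])^2 + (py[1L] - py[n])^2) < 1e-9
    if (!closed_ring) next
    px <- px[-n]; py <- py[-n]
    area <- abs(sum(px * c(py[-1L], py[1L]) - c(px[-1L], px[1L]) * py) / 2)
    if (area > best_area) {
      best_area <- area
      best <- cbind(px, py)
    }
  }
  if (is.null(best)) stop("no closed contour found")
  canonicalize_outline(outline(best, closed = TRUE))
}

#' Resample an outline to equally spaced points along a fitted spline
#'
#' Fits a parametric spline through the vertices (periodic boundary
#' conditions for closed outlines, natural conditions for open ones) and
#' samples it at `n_points` positions of equal arc length along the spline.
#' Open curves keep their original endpoints exactly.
#'
#' @param x an [outline] with at least 4 points.
#' @param n_points number of output points (>= 3).
#' @param spline_degree 1 (piecewise linear) or 3 (cubic, default).
#' @return resampled [outline] (same closure flag and metadata).
#' @examples
#' th <- sort(runif(40, 0, 2 * pi))
#' o <- outline(cbind(cos(th), sin(th)))
#' r <- resample_arclength(o, 100)
#' @export
resample_arclength <- function(x, n_points = 100L, spline_degree = 3L) {
  stopifnot(is_outline(x))
  if (nrow(x$points) < 4L) stop("outline needs at least 4 points to resample")
  if (n_points < 3L) stop("`n_points` must be >= 3")
  if (!spline_degree %in% c(1L, 3L))
    stop("`spline_degree` must be 1 (linear) or 3 (cubic)")
  p <- x$points
  if (x$closed) p <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(p)^2))
  if (sum(seg) < 1e-12) stop("degenerate (zero-length) outline")
  s <- c(0, cumsum(seg))

  # dense sampling of the fitted spline, then arc-length inversion
  dense_n <- max(4000L, 25L * n_points)
  sd_ <- seq(0, s[length(s)], length.out = dense_n)
  if (spline_degree == 1L) {
    fx <- stats::approxfun(s, p[, 1L])
    fy <- stats::approxfun(s, p[, 2L])
  } else {
    method <- if (x$closed) "periodic" else "natural"
    fx <- stats::splinefun(s, p[, 1L], method = method)
    fy <- stats::splinefun(s, p[, 2L], method = method)
  }
  dx <- fx(sd_); dy <- fy(sd_)
  arc <- c(0, cumsum(sqrt(diff(dx)^2 + diff(dy)^2)))
  total <- arc[length(arc)]
  targets <- if (x$closed) {
    seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  } else {
    seq(0, total, length.out = n_points)
  }
  s_eq <- stats::approx(arc, sd_, xout = targets, ties = "ordered")$y
  out <- cbind(fx(s_eq), fy(s_eq))
  if (!x$closed) {  # pin the original endpoints exactly
    out[1L, ] <- x$points[1L, ]
    out[n_points, ] <- x$points[nrow(x$points), ]
  }
  outline(out, closed = x$closed, id = x$id, label = x$label)
}

#' Enforce mirror symmetry about the vertical centroid axis
#'
#' Splits a closed outline at its topmost and bottommost vertices, keeps the
#' side of shorter arc length, reflects it about the vertical axis through
#' the centroid and joins the two copies into a closed, mirror-symmetric
#' outline (the treatment used to strip asymmetric appendages such as the
#' spouts of pouring vessels).
#'
#' @param x a closed [outline].
#' @return closed, mirror-symmetric [outline].
#' @export
symmetrize_vertical <- function(x) {
  stopifnot(is_outline(x), x$closed)
  p <- x$points
  n <- nrow(p)
  i_top <- which.max(p[, 2L])
  i_bot <- which.min(p[, 2L])
  if (i_top == i_bot) stop("top and bottom split points coincide")
  xc <- mean(p[, 1L])
  idx_side <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1L:to)
  }
  side1 <- idx_side(i_top, i_bot)   # top -> bottom following stored order
  side2 <- idx_side(i_bot, i_top)   # bottom -> top (the complement)
  arc_len <- function(idx) sum(sqrt(rowSums(diff(p[idx, , drop = FALSE])^2)))
  if (arc_len(side1) <= arc_len(side2)) {
    keep <- p[side1, , drop = FALSE]          # runs top -> bottom
  } else {
    keep <- p[rev(side2), , drop = FALSE]     # reorient to top -> bottom
  }
  refl <- cbind(2 * xc - keep[, 1L], keep[, 2L])
  m <- nrow(keep)
  # keep (top->bottom) + reflected side traversed bottom->top, dropping the
  # duplicate extremal vertices where the two copies meet
  full <- rbind(keep, refl[rev(seq_len(m)), , drop = FALSE])
  dup <- sqrt(rowSums((full - rbind(full[-1L, ], full[1L, ]))^2)) < 1e-12
  full <- full[!dup, , drop = FALSE]
  canonicalize_outline(outline(full, closed = TRUE, id = x$id, label = x$label))
}

#' Generalized Procrustes alignment of outlines
#'
#' Removes translation (centroid to origin), scale (unit centroid size) and
#' rotation (iterative orthogonal fits to the running mean shape, until the
#' mean changes by less than `tol` or `max_iter` passes). Points must be in
#' corresponding order across outlines. Reflections are excluded unless
#' `allow_reflection = TRUE`.
#'
#' @param outlines list of [outline]s sharing the same number of points and
#'   closure flag.
#' @param allow_reflection allow improper (reflecting) rotations?
#' @param tol convergence tolerance on the mean-shape update.
#' @param max_iter maximum alignment passes.
#' @return an `aligned_set`: list with `outlines` (aligned copies),
#'   `mean_shape` ([outline]), `scale_removed`, `rotation_removed`.
#' @export
procrustes_align <- function(outlines, allow_reflection = FALSE,
                             tol = 1e-8, max_iter = 100L) {
  stopifnot(is.list(outlines), length(outlines) >= 1L)
  ns <- vapply(outlines, function(o) nrow(o$points), integer(1))
  if (length(unique(ns)) != 1L) stop("all outlines must share the same N")
  cls <- vapply(outlines, function(o) o$closed, logical(1))
  if (length(unique(cls)) != 1L) stop("all outlines must share the closed flag")
  X <- lapply(outlines, function(o) {
    p <- sweep(o$points, 2L, colMeans(o$points))
    p / sqrt(sum(p^2))
  })
  rot_to <- function(a, ref) {
    # orthogonal Procrustes: a -> ref
    m <- crossprod(ref, a)           # 2x2
    sv <- svd(m)
    R <- sv$u %*% t(sv$v)
    if (!allow_reflection && det(R) < 0) {
      u <- sv$u; u[, 2L] <- -u[, 2L]
      R <- u %*% t(sv$v)
    }
    a %*% t(R)
  }
  mean_shape <- X[[1L]]
  for (it in seq_len(max_iter)) {
    X <- lapply(X, rot_to, ref = mean_shape)
    new_mean <- Reduce(`+`, X) / length(X)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  X <- lapply(X, rot_to, ref = mean_shape)
  aligned <- Map(function(o, p) outline(p, closed = o$closed, id = o$id,
                                        label = o$label),
                 outlines, X)
  structure(list(outlines = aligned,
                 mean_shape = outline(mean_shape,
                                      closed = outlines[[1L]]$closed),
                 scale_removed = TRUE, rotation_removed = TRUE,
                 allow_reflection = allow_reflection),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d outlines, %d points each\n",
              length(x$outlines), nrow(x$mean_shape$points)))
  invisible(x)
}

#' Cut a closed outline into an open curve between two landmarks
#'
#' Returns the open curve running from `start_index` to `end_index` in the
#' stored (counter-clockwise) vertex order, so homologous landmarks become
#' fixed endpoints for constrained open-curve matching.
#'
#' @param x a closed [outline].
#' @param start_index,end_index distinct vertex indices in 1..N.
#' @return an open [outline].
#' @export
cut_at_landmarks <- function(x, start_index, end_index) {
  stopifnot(is_outline(x), x$closed)
  n <- nrow(x$points)
  if (start_index < 1L || start_index > n || end_index < 1L || end_index > n)
    stop("landmark index out of range")
  if (start_index == end_index) stop("landmark indices must differ")
  idx <- if (start_index <= end_index) start_index:end_index
         else c(start_index:n, 1L:end_index)
  outline(x$points[idx, , drop = FALSE], closed = FALSE,
          id = x$id, label = x$label)
}

#' Read a greyscale image file (PNG or TIFF)
#'
#' @param path image path; multi-channel images are averaged to greyscale.
#' @return numeric matrix in [0, 1].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package required")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package required")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3L]),
                                               drop = FALSE], c(1L, 2L), mean)
  img
}
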