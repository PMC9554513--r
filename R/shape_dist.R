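#' Pairwise shape distance matrices
#'
#' Thin container for a symmetric pairwise distance matrix with object
#' identifiers and a tag naming the method that produced it. Matrices are
#' symmetrized on construction (average of the two triangles) and checked
#' for non-negative entries and a zero diagonal.
#'
#' @param values square numeric matrix.
#' @param ids object identifiers (defaults to rownames or seq).
#' @param method method tag string.
#' @return a `shape_dist` object.
#' @export
shape_dist <- function(values, ids = NULL, method = "unknown") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("distance matrix must be square")
  if (!all(is.finite(values))) stop("distance matrix must be finite")
  if (max(abs(values - t(values))) > 1e-6)
    stop("distance matrix is not symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (min(values) < -1e-9) stop("distances must be non-negative")
  values[values < 0] <- 0
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("`ids` length must match matrix size")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, method = method),
            class = "shape_dist")
}

#' @export
print.shape_dist <- function(x, ...) {
  cat(sprintf("<shape_dist> %d objects, method %s, range [%.4g, %.4g]\n",
              length(x$ids), x$method, min(x$values),
              max(x$values)))
  invisible(x)
}

#' @export
as.matrix.shape_dist <- function(x, ...) x$values

#' @export
as.dist.shape_dist <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$values, diag = diag, upper = upper)

#' Read and write shape distance matrices as CSV
#'
#' Square CSV with object ids as header row and first column.
#'
#' @param x a [shape_dist].
#' @param path file path.
#' @param method method tag attached on read.
#' @return `read_distances` returns a [shape_dist]; `write_distances`
#'   returns `path` invisibly.
#' @export
write_distances <- function(x, path) {
  stopifnot(inherits(x, "shape_dist"))
  df <- data.frame(object_id = x$ids, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path, method = "file") {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  shape_dist(vals, ids = ids, method = method)
}

# number of objects
n_objects <- function(D) length(D$ids)

# generic as.dist needs stats; declare S3 method for stats::as.dist
#' @importFrom stats as.dist
NULL
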