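#' Square-root velocity transform of an outline
#'
#' Represents a curve c(t) by q(t) = c'(t) / sqrt(||c'(t)||). Translation is
#' discarded by construction; scale is removed by normalizing q to unit L2
#' norm, after which shapes are points on the unit sphere in q-space and
#' geodesic distances are great-circle arcs (the arccos of the L2 inner
#' product). The outline's vertices are treated as samples on a uniform
#' parameter grid and interpolated to `grid_size` points; derivatives use
#' central finite differences (circular for closed curves).
#'
#' @param x an [outline] with >= 4 distinct points.
#' @param grid_size number of grid points M (default: the outline's N).
#' @return an `srvf_curve`: list with `q` (M x 2), `closed`, `normalized`,
#'   `scale` (L2 norm removed), `id`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 121)[-121]
#' q <- srvf_transform(outline(cbind(cos(th), sin(th))), grid_size = 100)
#' @export
srvf_transform <- function(x, grid_size = NULL) {
  stopifnot(is_outline(x))
  p <- x$points
  n <- nrow(p)
  if (n < 4L) stop("outline needs at least 4 points")
  M <- if (is.null(grid_size)) n else as.integer(grid_size)
  if (M < 3L) stop("`grid_size` must be >= 3")
  if (M != n) p <- .interp_param(p, M, x$closed)
  # analytic derivative of the interpolating cubic spline (periodic knots
  # for closed curves); much less curvature-dependent error than finite
  # differences, which matters when comparing differently parametrized
  # copies of one curve
  if (x$closed) {
    tt <- (0:M) / M
    fx <- stats::splinefun(tt, c(p[, 1L], p[1L, 1L]), method = "periodic")
    fy <- stats::splinefun(tt, c(p[, 2L], p[1L, 2L]), method = "periodic")
    tg <- (seq_len(M) - 1L) / M
  } else {
    tg <- (seq_len(M) - 1L) / (M - 1L)
    fx <- stats::splinefun(tg, p[, 1L], method = "natural")
    fy <- stats::splinefun(tg, p[, 2L], method = "natural")
  }
  der <- cbind(fx(tg, deriv = 1L), fy(tg, deriv = 1L))
  spd <- sqrt(rowSums(der^2))
  if (max(spd) < 1e-12) stop("curve has zero derivative everywhere")
  q <- der / sqrt(pmax(spd, 1e-300))
  q[spd < 1e-12, ] <- 0
  nrm <- sqrt(.q_norm2(q, x$closed))
  structure(list(q = q / nrm, closed = x$closed, normalized = TRUE,
                 scale = nrm, id = x$id),
            class = "srvf_curve")
}

# interpolate the vertex polygon at M uniform parameter positions
# (cubic spline: linear resampling would add curvature kinks that bias
# the matching between differently gridded copies)
.interp_param <- function(p, M, closed) {
  n <- nrow(p)
  if (closed) {
    t_in <- (seq_len(n + 1L) - 1L) / n
    pp <- rbind(p, p[1L, ])
    t_out <- (seq_len(M) - 1L) / M
    method <- "periodic"
  } else {
    t_in <- (seq_len(n) - 1L) / (n - 1L)
    pp <- p
    t_out <- (seq_len(M) - 1L) / (M - 1L)
    method <- "natural"
  }
  cbind(stats::splinefun(t_in, pp[, 1L], method = method)(t_out),
        stats::splinefun(t_in, pp[, 2L], method = method)(t_out))
}

# squared L2 norm of a sampled q: rectangle rule on the period for closed
# curves, trapezoid on [0,1] for open
.q_norm2 <- function(q, closed) {
  M <- nrow(q)
  s <- rowSums(q^2)
  if (closed) sum(s) / M
  else (sum(s) - s[1L] / 2 - s[M] / 2) / (M - 1L)
}

.q_inner <- function(q1, q2, closed) {
  M <- nrow(q1)
  s <- rowSums(q1 * q2)
  if (closed) sum(s) / M
  else (sum(s) - s[1L] / 2 - s[M] / 2) / (M - 1L)
}

#' @export
print.srvf_curve <- function(x, ...) {
  cat(sprintf("<srvf_curve> %s, %d grid points%s\n",
              if (x$closed) "closed" else "open", nrow(x$q),
              if (isTRUE(x$normalized)) ", unit norm" else ""))
  invisible(x)
}

is_srvf <- function(x) inherits(x, "srvf_curve")

# default DP neighbourhood: coprime slope moves with components <= 3,
# giving local warp slopes in {1/3 .. 3}
.dp_neighbors <- function(slope_max = 3L) {
  nb <- NULL
  for (a in 1:slope_max) for (b in 1:slope_max)
    if (.gcd(a, b) == 1L) nb <- rbind(nb, c(a, b))
  storage.mode(nb) <- "integer"
  nb
}
.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Reconstruct an outline from its SRVF
#'
#' Inverts the square-root velocity transform by cumulative integration,
#' c(t) = integral of q(s) ||q(s)|| ds; the result is centred on its
#' centroid at unit scale (unit curve length for a unit-norm q). For closed
#' SRVFs any small closure defect of the integrated curve is removed by
#' subtracting the linear drift.
#'
#' @param q an `srvf_curve`.
#' @return an [outline].
#' @export
inverse_srvf <- function(q) {
  stopifnot(is_srvf(q))
  M <- nrow(q$q)
  dt <- if (q$closed) 1 / M else 1 / (M - 1L)
  v <- q$q * sqrt(rowSums(q$q^2))
  if (q$closed) {
    p <- rbind(c(0, 0), apply(v * dt, 2L, cumsum))      # M+1 points
    drift <- p[M + 1L, ] - p[1L, ]
    p <- p - outer(seq(0, 1, length.out = M + 1L), drift)
    p <- p[-(M + 1L), , drop = FALSE]
  } else {
    vm <- (v[-M, , drop = FALSE] + v[-1L, , drop = FALSE]) / 2
    p <- rbind(c(0, 0), apply(vm * dt, 2L, cumsum))     # M points, trapezoid
  }
  p <- sweep(p, 2L, colMeans(p))
  outline(p, closed = q$closed, id = q$id)
}

#' Elastic alignment of open SRVF curves
#'
#' Finds the monotone reparametrization gamma of `q2` maximizing the L2
#' inner product <q1, (q2 o gamma) sqrt(gamma')> by dynamic programming on
#' a monotone lattice. With `fix_endpoints = TRUE` (the landmark-constrained
#' mode) gamma is pinned to gamma(0) = 0, gamma(1) = 1, so the curve
#' endpoints act as homologous landmarks. Rotation is not optimized by
#' default: with fixed, ordered endpoints the orientation is informative and
#' removing it would discard that information.
#'
#' @param q1,q2 open `srvf_curve`s on the same grid.
#' @param fix_endpoints pin gamma at both ends?
#' @param allow_rotation also optimize a planar rotation (alternating with
#'   the reparametrization, `rot_iters` rounds)?
#' @param rot_iters alternation rounds when rotation is enabled.
#' @param slope_max largest local warp slope in the DP lattice.
#' @return an `elastic_match`: list with `gamma`, `rotation`, `seed_shift`
#'   (always 0 for open curves), `ip`, `distance` = arccos of the clamped
#'   inner product.
#' @export
align_open <- function(q1, q2, fix_endpoints = TRUE, allow_rotation = FALSE,
                       rot_iters = 2L, slope_max = 3L, refine = 3L) {
  stopifnot(is_srvf(q1), is_srvf(q2))
  if (q1$closed || q2$closed) stop("align_open needs open curves")
  if (nrow(q1$q) != nrow(q2$q)) stop("grid size mismatch")
  nb <- .dp_neighbors(slope_max)
  M <- nrow(q1$q)
  w <- rep(1 / (M - 1L), M); w[c(1L, M)] <- 0.5 / (M - 1L)
  R <- diag(2)
  gamma <- seq(0, 1, length.out = M)
  iters <- if (allow_rotation) rot_iters else 1L
  ip <- NA_real_
  for (it in seq_len(iters)) {
    if (allow_rotation) {
      qw <- cpp_warp_q(q2$q, gamma)
      R <- cpp_opt_rotation(q1$q, qw, w)
    }
    m <- cpp_dp_match(q1$q, q2$q %*% t(R), nb, pin_ends = fix_endpoints)
    gamma <- m$gamma
    ip <- m$ip
  }
  if (refine > 0L && fix_endpoints) {
    q2r <- q2$q %*% t(R)
    rr <- cpp_refine_gamma(q1$q, q2r, gamma, as.integer(refine))
    gamma <- rr$gamma
    ip <- rr$ip
    for (radius in c(0.5, 0.2, 0.08)) {
      mm <- cpp_micro_open(q1$q, q2r, gamma, radius, 11L)
      if (mm$ip > ip) { gamma <- mm$gamma; ip <- mm$ip }
    }
  }
  structure(list(gamma = gamma, rotation = R, seed_shift = 0L,
                 ip = ip, distance = acos(max(-1, min(1, ip)))),
            class = "elastic_match")
}

#' Elastic alignment of closed SRVF curves
#'
#' Jointly optimizes the cyclic seed (start) point of `q2` (every
#' `seed_stride`-th vertex is a candidate), a planar rotation (orthogonal
#' Procrustes, alternated with the matching for `rot_iters` rounds) and a
#' monotone reparametrization (dynamic programming), maximizing the L2
#' inner product. `top` > 0 restricts the full optimization to the `top`
#' most promising seeds under a cheap rotation-only score, which is how the
#' pairwise distance driver keeps large matrices affordable; `top = 0`
#' optimizes every candidate seed exhaustively.
#'
#' @param q1,q2 closed `srvf_curve`s on the same grid.
#' @param seed_stride spacing of candidate start vertices (1 = all).
#' @param rot_iters rotation/matching alternation rounds.
#' @param rotation optimize rotation at all?
#' @param top number of preselected seeds (0 = no preselection).
#' @param slope_max largest local warp slope in the DP lattice.
#' @return an `elastic_match` with `gamma` (on the extended M+1 grid),
#'   `rotation`, `seed_shift`, `ip` and `distance`.
#' @export
align_closed <- function(q1, q2, seed_stride = 1L, rot_iters = 2L,
                         rotation = TRUE, top = 0L, slope_max = 3L,
                         refine = 6L) {
  stopifnot(is_srvf(q1), is_srvf(q2))
  if (!q1$closed || !q2$closed) stop("align_closed needs closed curves")
  if (nrow(q1$q) != nrow(q2$q)) stop("grid size mismatch")
  nb <- .dp_neighbors(slope_max)
  res <- cpp_align_closed(q1$q, q2$q, as.integer(seed_stride),
                          as.integer(rot_iters), isTRUE(rotation), nb,
                          as.integer(top), as.integer(refine))
  structure(list(gamma = res$gamma, rotation = res$rotation,
                 seed_shift = res$seed, delta = res$delta,
                 positions = res$positions, ip = res$ip,
                 distance = acos(max(-1, min(1, res$ip)))),
            class = "elastic_match")
}

#' @export
print.elastic_match <- function(x, ...) {
  cat(sprintf("<elastic_match> distance %.4f (inner product %.6f), seed %d\n",
              x$distance, x$ip, x$seed_shift))
  invisible(x)
}

# apply an elastic_match to a closed srvf curve: cyclic resampling at the
# matched positions (seed + sub-vertex shift + warp), rotation, then
# renormalization to the unit sphere. Used where only the q-level
# representative is needed; warping in q-space does not preserve closure
# exactly, so shape-critical consumers use the outline-level variant below.
.apply_match_closed <- function(q2, match) {
  M <- nrow(q2$q)
  qw <- cpp_warp_closed(q2$q, match$positions, match$rotation)
  qw <- qw[-(M + 1L), , drop = FALSE]
  qw / sqrt(.q_norm2(qw, TRUE))
}

.apply_match_open <- function(q2, match) {
  qw <- cpp_warp_q(q2$q %*% t(match$rotation), match$gamma)
  qw / sqrt(.q_norm2(qw, FALSE))
}

# shape-exact application of a match: resample the original curve's spline
# at the warped positions and re-transform, so the aligned representative
# has exactly the source shape (reparametrized and rotated), with closure
# preserved by construction
.warp_outline_closed <- function(o2, match, grid_size) {
  M <- length(match$positions) - 1L
  tpos <- (match$positions[-(M + 1L)] %% M) / M   # in [0, 1)
  p <- o2$points
  n <- nrow(p)
  t_in <- (0:n) / n
  fx <- stats::splinefun(t_in, c(p[, 1L], p[1L, 1L]), method = "periodic")
  fy <- stats::splinefun(t_in, c(p[, 2L], p[1L, 2L]), method = "periodic")
  pw <- cbind(fx(tpos), fy(tpos)) %*% t(match$rotation)
  srvf_transform(outline(pw, closed = TRUE, id = o2$id), grid_size = M)
}

.warp_outline_open <- function(o2, match, grid_size) {
  M <- length(match$gamma)
  p <- o2$points
  n <- nrow(p)
  t_in <- (seq_len(n) - 1L) / (n - 1L)
  fx <- stats::splinefun(t_in, p[, 1L], method = "natural")
  fy <- stats::splinefun(t_in, p[, 2L], method = "natural")
  tpos <- pmin(pmax(match$gamma, 0), 1)
  pw <- cbind(fx(tpos), fy(tpos)) %*% t(match$rotation)
  srvf_transform(outline(pw, closed = FALSE, id = o2$id), grid_size = M)
}

#' Elastic (SRVF geodesic) distance between two outlines
#'
#' The great-circle distance d = arccos(<q1, q2*>) on the SRVF shape
#' sphere, where q2* is q2 optimally aligned over rotation, start point
#' (closed mode) and reparametrization. By construction the distance is
#' invariant to translation, scale, rotation, cyclic start shifts and
#' smooth reparametrization of either curve (closed mode), and lies in
#' [0, pi].
#'
#' @param o1,o2 [outline]s (both closed for `mode = "closed"`, any for
#'   `"open"` — open mode cuts nothing, it simply treats the stored curve
#'   as open with fixed endpoints).
#' @param mode `"closed"` or `"open"`.
#' @param grid_size SRVF grid M (open curves are first re-sampled to
#'   `grid_size` equally spaced points along a fitted spline).
#' @param symmetrize average d(o1, o2) and d(o2, o1)? (The DP asymmetry is
#'   below 1e-3 on typical curves; off by default.)
#' @param ... further arguments to [align_closed] or [align_open].
#' @return scalar distance in [0, pi].
#' @examples
#' a <- family_template(make_families(2, seed = 1)[[1]], 80)
#' elastic_distance(a, a)
#' @export
elastic_distance <- function(o1, o2, mode = c("closed", "open"),
                             grid_size = 100L, symmetrize = FALSE, ...) {
  mode <- match.arg(mode)
  d1 <- .elastic_distance_1(o1, o2, mode, grid_size, ...)
  if (!symmetrize) return(d1)
  d2 <- .elastic_distance_1(o2, o1, mode, grid_size, ...)
  (d1 + d2) / 2
}

.elastic_distance_1 <- function(o1, o2, mode, grid_size, ...) {
  if (mode == "closed") {
    if (!o1$closed || !o2$closed) stop("closed mode needs closed outlines")
    q1 <- srvf_transform(o1, grid_size)
    q2 <- srvf_transform(o2, grid_size)
    align_closed(q1, q2, ...)$distance
  } else {
    oo1 <- .as_open(o1, grid_size)
    oo2 <- .as_open(o2, grid_size)
    align_open(srvf_transform(oo1), srvf_transform(oo2), ...)$distance
  }
}

.as_open <- function(o, grid_size) {
  if (o$closed) {
    p <- o$points
    o <- outline(rbind(p, p[1L, ]), closed = FALSE, id = o$id, label = o$label)
  }
  resample_arclength(o, n_points = grid_size)
}

# project a closed-curve SRVF onto the closure constraint
# integral of q ||q|| dt = 0, by a few Newton steps on the two residual
# components, then renormalize to the unit sphere
.project_closed_q <- function(q, max_iter = 10L, tol = 1e-10) {
  M <- nrow(q)
  dt <- 1 / M
  for (it in seq_len(max_iter)) {
    nq <- sqrt(rowSums(q^2))
    r <- colSums(q * nq) * dt
    if (sum(r^2) < tol^2) break
    # constraint gradients v_b(t)_a = delta_ab ||q|| + q_a q_b / ||q||
    safe <- pmax(nq, 1e-12)
    v1 <- cbind(nq + q[, 1L]^2 / safe, q[, 1L] * q[, 2L] / safe)
    v2 <- cbind(q[, 1L] * q[, 2L] / safe, nq + q[, 2L]^2 / safe)
    A <- matrix(c(sum(v1 * v1), sum(v1 * v2),
                  sum(v1 * v2), sum(v2 * v2)), 2L, 2L) * dt
    beta <- tryCatch(solve(A, -r), error = function(e) c(0, 0))
    q <- q + beta[1L] * v1 + beta[2L] * v2
    q <- q / sqrt(.q_norm2(q, TRUE))
  }
  q / sqrt(.q_norm2(q, TRUE))
}

# resample an outline's spline at given parameter positions (in the
# outline's own uniform vertex parameter); shape-preserving
.resample_at <- function(o, tpos) {
  p <- o$points
  n <- nrow(p)
  if (o$closed) {
    t_in <- (0:n) / n
    fx <- stats::splinefun(t_in, c(p[, 1L], p[1L, 1L]), method = "periodic")
    fy <- stats::splinefun(t_in, c(p[, 2L], p[1L, 2L]), method = "periodic")
    tpos <- tpos[-length(tpos)]
  } else {
    t_in <- (seq_len(n) - 1L) / (n - 1L)
    fx <- stats::splinefun(t_in, p[, 1L], method = "natural")
    fy <- stats::splinefun(t_in, p[, 2L], method = "natural")
  }
  outline(cbind(fx(tpos), fy(tpos)), closed = o$closed, id = o$id)
}

#' Pairwise elastic distance matrix
#'
#' @param outlines list of [outline]s (or a `shape_dataset`).
#' @param mode `"closed"` or `"open"`.
#' @param grid_size SRVF grid M.
#' @param seed_stride,top,rot_iters closed-mode alignment controls
#'   (see [align_closed]).
#' @param symmetrize average the two directions?
#' @param progress print a progress line every 500 pairs?
#' @return a [shape_dist].
#' @export
elastic_distances <- function(outlines, mode = c("closed", "open"),
                              grid_size = 60L, seed_stride = 1L, top = 8L,
                              rot_iters = 2L, refine = 3L, symmetrize = FALSE,
                              progress = FALSE) {
  mode <- match.arg(mode)
  if (inherits(outlines, "shape_dataset")) outlines <- outlines$outlines
  n <- length(outlines)
  ids <- vapply(seq_len(n), function(i) {
    id <- outlines[[i]]$id
    if (is.null(id)) as.character(i) else id
  }, character(1))
  qs <- if (mode == "closed") {
    lapply(outlines, srvf_transform, grid_size = grid_size)
  } else {
    lapply(outlines, function(o) srvf_transform(.as_open(o, grid_size)))
  }
  D <- matrix(0, n, n)
  done <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- if (mode == "closed") {
      align_closed(qs[[i]], qs[[j]], seed_stride = seed_stride,
                   rot_iters = rot_iters, top = top,
                   refine = refine)$distance
    } else {
      align_open(qs[[i]], qs[[j]])$distance
    }
    if (symmetrize) {
      d2 <- if (mode == "closed") {
        align_closed(qs[[j]], qs[[i]], seed_stride = seed_stride,
                     rot_iters = rot_iters, top = top,
                     refine = refine)$distance
      } else {
        align_open(qs[[j]], qs[[i]])$distance
      }
      d <- (d + d2) / 2
    }
    D[i, j] <- D[j, i] <- d
    done <- done + 1L
    if (progress && done %% 500L == 0L)
      message(sprintf("  %d / %d pairs", done, n * (n - 1L) / 2L))
  }
  shape_dist(D, ids = ids, method = paste0("srvf_", mode))
}

#' Geodesic path (shape transformation series) between two outlines
#'
#' After elastic alignment, intermediate shapes are read off the great
#' circle q(tau) = [sin((1 - tau) theta) q1 + sin(tau theta) q2*] / sin
#' theta at tau = j/kappa and back-transformed to outlines; closed-curve
#' intermediates are projected back to closed curves (drift removal) before
#' integration. The path energy is the sum of elastic distances between
#' consecutive steps; for a geodesic it approaches the endpoint distance.
#'
#' @param o1,o2 [outline]s.
#' @param kappa number of steps (path has kappa + 1 shapes), >= 2.
#' @param mode `"closed"` or `"open"`.
#' @param grid_size SRVF grid M.
#' @param energy compute the path energy (kappa extra distance
#'   evaluations)?
#' @param ... alignment controls passed on.
#' @return a `geodesic_path`: list with `steps` (kappa + 1 [outline]s),
#'   `kappa`, `distance`, `energy`, `mode`.
#' @export
geodesic_path <- function(o1, o2, kappa = 5L, mode = c("closed", "open"),
                          grid_size = 100L, energy = TRUE, ...) {
  mode <- match.arg(mode)
  if (kappa < 2L) stop("`kappa` must be >= 2")
  if (mode == "closed") {
    q1 <- srvf_transform(o1, grid_size)
    q2 <- srvf_transform(o2, grid_size)
    match <- align_closed(q1, q2, ...)
    q2a <- .warp_outline_closed(o2, match, grid_size)$q
  } else {
    oo2 <- .as_open(o2, grid_size)
    q1 <- srvf_transform(.as_open(o1, grid_size))
    q2 <- srvf_transform(oo2)
    match <- align_open(q1, q2, ...)
    q2a <- .warp_outline_open(oo2, match, grid_size)$q
  }
  closed <- mode == "closed"
  ip <- .q_inner(q1$q, q2a, closed)
  theta <- acos(max(-1, min(1, ip)))
  taus <- seq(0, 1, length.out = kappa + 1L)
  # normalized warp from the first curve's parameter to the second's, used
  # to spread the reparametrization evenly along the path: each step's
  # vertex distribution interpolates between the endpoint parametrizations
  # (the shape is untouched), so no step carries the full warp relative to
  # either endpoint
  gwarp <- if (closed) {
    (match$positions - match$positions[1L]) /
      (length(match$positions) - 1L)
  } else match$gamma
  tgrid <- seq(0, 1, length.out = length(gwarp))
  steps <- lapply(taus, function(tau) {
    qt <- if (theta < 1e-9) q1$q else {
      (sin((1 - tau) * theta) * q1$q + sin(tau * theta) * q2a) / sin(theta)
    }
    qt <- qt / sqrt(.q_norm2(qt, closed))
    if (closed) qt <- .project_closed_q(qt)
    sq <- structure(list(q = qt, closed = closed, normalized = TRUE,
                         scale = 1, id = NULL), class = "srvf_curve")
    step <- inverse_srvf(sq)
    if (theta < 1e-9 || tau == 0) return(step)
    # phi_tau = (1 - tau) id + tau * warp; resample at phi_tau^{-1}
    phi <- (1 - tau) * tgrid + tau * gwarp
    tk <- stats::approx(phi, tgrid, xout = tgrid, rule = 2,
                        ties = "ordered")$y
    .resample_at(step, tk)
  })
  en <- if (energy) {
    sum(vapply(seq_len(kappa), function(j)
      elastic_distance(steps[[j]], steps[[j + 1L]], mode = mode,
                       grid_size = grid_size, ...), numeric(1)))
  } else NA_real_
  structure(list(steps = steps, kappa = as.integer(kappa),
                 distance = theta, energy = en, mode = mode,
                 match = match),
            class = "geodesic_path")
}

#' @export
print.geodesic_path <- function(x, ...) {
  cat(sprintf("<geodesic_path> %s, %d steps, distance %.4f, energy %s\n",
              x$mode, x$kappa + 1L, x$distance,
              if (is.na(x$energy)) "not computed" else sprintf("%.4f", x$energy)))
  invisible(x)
}

#' @export
plot.geodesic_path <- function(x, ncol = length(x$steps), ...) {
  op <- graphics::par(mfrow = c(ceiling(length(x$steps) / ncol), ncol),
                      mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (j in seq_along(x$steps))
    plot(x$steps[[j]], axes = FALSE, main = sprintf("step %d", j - 1L), ...)
  invisible(x)
}

#' Energy of a shape transformation series
#'
#' Sum of elastic distances between consecutive outlines — the deformation
#' cost of the series; a geodesic minimizes it.
#'
#' @param steps list of [outline]s (>= 2).
#' @param mode,grid_size,... passed to [elastic_distance].
#' @return scalar energy.
#' @export
path_energy <- function(steps, mode = c("closed", "open"),
                        grid_size = 100L, ...) {
  mode <- match.arg(mode)
  if (!is.list(steps) || length(steps) < 2L) stop("need at least 2 steps")
  sum(vapply(seq_len(length(steps) - 1L), function(j)
    elastic_distance(steps[[j]], steps[[j + 1L]], mode = mode,
                     grid_size = grid_size, ...), numeric(1)))
}

#' Karcher (Frechet) mean shape on the SRVF sphere
#'
#' The intrinsic average: each curve is elastically aligned to the current
#' estimate, the log-map (shooting) vectors are averaged, and the estimate
#' moves along the exponential map by `step` times the mean vector until
#' the update norm falls below `tol`. Initialized at the normalized
#' extrinsic (coordinate-wise) average.
#'
#' @param outlines list of [outline]s (or a `shape_dataset`).
#' @param mode `"closed"` or `"open"`.
#' @param grid_size SRVF grid M.
#' @param tol convergence tolerance on the mean update norm.
#' @param max_iter maximum iterations.
#' @param step gradient step size in (0, 1].
#' @param ... alignment controls passed on.
#' @return a `karcher_mean`: list with `mean_q` (`srvf_curve`),
#'   `mean_outline` ([outline]), `iterations`, `final_gradient_norm`.
#' @export
karcher_mean <- function(outlines, mode = c("closed", "open"),
                         grid_size = 60L, tol = 1e-4, max_iter = 50L,
                         step = 0.5, ...) {
  mode <- match.arg(mode)
  if (inherits(outlines, "shape_dataset")) outlines <- outlines$outlines
  if (!is.list(outlines) || length(outlines) == 0L)
    stop("need at least one outline")
  closed <- mode == "closed"
  os <- if (closed) outlines
        else lapply(outlines, .as_open, grid_size = grid_size)
  qs <- if (closed) lapply(os, srvf_transform, grid_size = grid_size)
        else lapply(os, srvf_transform)
  align_to <- function(ref_q, i) {
    if (closed) {
      .warp_outline_closed(os[[i]], align_closed(ref_q, qs[[i]], ...),
                           grid_size)$q
    } else {
      .warp_outline_open(os[[i]], align_open(ref_q, qs[[i]]), grid_size)$q
    }
  }
  # initialization: extrinsic average of the curves aligned to the first
  # one (averaging unaligned SRVFs would start from a meaningless point)
  aligned0 <- lapply(seq_along(qs), function(i) align_to(qs[[1L]], i))
  mu <- Reduce(`+`, aligned0) / length(aligned0)
  mu <- mu / sqrt(.q_norm2(mu, closed))
  grad_norm <- Inf
  it <- 0L
  mu_curve <- function(m) structure(list(q = m, closed = closed,
                                         normalized = TRUE, scale = 1,
                                         id = NULL), class = "srvf_curve")
  while (it < max_iter) {
    it <- it + 1L
    vbar <- matrix(0, nrow(mu), 2L)
    for (qi in qs) {
      qa <- if (closed) {
        .apply_match_closed(qi, align_closed(mu_curve(mu), qi, ...))
      } else {
        .apply_match_open(qi, align_open(mu_curve(mu), qi, ...))
      }
      ipi <- max(-1, min(1, .q_inner(mu, qa, closed)))
      th <- acos(ipi)
      if (th > 1e-10)
        vbar <- vbar + (th / sin(th)) * (qa - ipi * mu)
    }
    vbar <- vbar / length(qs)
    grad_norm <- sqrt(.q_norm2(vbar, closed))
    if (grad_norm * step < tol) break
    mu <- cos(step * grad_norm) * mu +
      sin(step * grad_norm) * vbar / grad_norm
    mu <- mu / sqrt(.q_norm2(mu, closed))
  }
  mq <- mu_curve(mu)
  structure(list(mean_q = mq, mean_outline = inverse_srvf(mq),
                 iterations = it, final_gradient_norm = grad_norm,
                 n = length(qs), mode = mode),
            class = "karcher_mean")
}

#' @export
print.karcher_mean <- function(x, ...) {
  cat(sprintf(
    "<karcher_mean> of %d shapes (%s), %d iterations, gradient norm %.2e\n",
    x$n, x$mode, x$iterations, x$final_gradient_norm))
  invisible(x)
}

#' @export
plot.karcher_mean <- function(x, ...) plot(x$mean_outline, ...)

#' Mirror-symmetric geodesic transformation
#'
#' For outlines that are mirror-symmetric about their vertical centroid
#' axes the plain geodesic need not be symmetric, so the outlines are split
#' in half, the right halves transformed into each other as open curves
#' with pinned endpoints, and each intermediate half reflected and
#' re-attached into a closed symmetric outline.
#'
#' @param o1,o2 closed, mirror-symmetric [outline]s (asymmetry above 1% of
#'   centroid size is an error).
#' @param kappa number of transformation steps.
#' @param grid_size open-curve grid for the half outlines.
#' @return a `geodesic_path` of closed, symmetric outlines.
#' @export
symmetric_transform <- function(o1, o2, kappa = 5L, grid_size = 100L) {
  for (o in list(o1, o2)) {
    if (!o$closed) stop("symmetric_transform needs closed outlines")
    if (.asymmetry(o) > 0.01)
      stop("outline is not mirror-symmetric about its vertical axis")
  }
  h1 <- .right_half(o1)
  h2 <- .right_half(o2)
  hp <- geodesic_path(h1, h2, kappa = kappa, mode = "open",
                      grid_size = grid_size, energy = FALSE)
  steps <- lapply(hp$steps, .mirror_close)
  en <- sum(vapply(seq_len(kappa), function(j)
    elastic_distance(steps[[j]], steps[[j + 1L]], mode = "closed",
                     grid_size = grid_size), numeric(1)))
  structure(list(steps = steps, kappa = as.integer(kappa),
                 distance = hp$distance, energy = en, mode = "closed",
                 match = hp$match),
            class = "geodesic_path")
}

# max distance from each vertex to the reflected vertex set, relative to
# centroid size
.asymmetry <- function(o) {
  p <- sweep(o$points, 2L, colMeans(o$points))
  r <- cbind(-p[, 1L], p[, 2L])
  cs <- sqrt(sum(p^2))
  dmax <- max(vapply(seq_len(nrow(p)), function(i)
    min(sqrt((r[, 1L] - p[i, 1L])^2 + (r[, 2L] - p[i, 2L])^2)), numeric(1)))
  dmax / (cs / sqrt(nrow(p)))
}

# open curve: the half of the outline with x >= centroid x, from top
# vertex to bottom vertex
.right_half <- function(o) {
  p <- o$points
  n <- nrow(p)
  i_top <- which.max(p[, 2L]); i_bot <- which.min(p[, 2L])
  xc <- mean(p[, 1L])
  idx_side <- function(from, to) if (from <= to) from:to else c(from:n, 1L:to)
  s1 <- idx_side(i_top, i_bot)
  s2 <- rev(idx_side(i_bot, i_top))
  side <- if (mean(p[s1, 1L]) >= xc) s1 else s2
  outline(p[side, , drop = FALSE], closed = FALSE, id = o$id, label = o$label)
}

# reflect an open half (top->bottom) about the vertical axis through the
# endpoints' mean x, and close
.mirror_close <- function(half) {
  p <- half$points
  xc <- mean(p[c(1L, nrow(p)), 1L])
  refl <- cbind(2 * xc - p[, 1L], p[, 2L])
  full <- rbind(p, refl[rev(seq_len(nrow(p))), , drop = FALSE])
  dup <- sqrt(rowSums((full - rbind(full[-1L, ], full[1L, ]))^2)) < 1e-9
  full <- full[!dup, , drop = FALSE]
  canonicalize_outline(outline(full, closed = TRUE))
}
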