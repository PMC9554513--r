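# shared fixtures and independent oracles for the test suite

circle_outline <- function(n = 100, r = 1, phase = 0, closed = TRUE) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  outline(cbind(r * cos(th), r * sin(th)), closed = closed)
}

ellipse_outline <- function(n = 100, a = 2, b = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  outline(cbind(a * cos(th), b * sin(th)))
}

rigid_copy <- function(o, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  outline(sweep(scale * (o$points %*% t(R)), 2L, shift, "+"),
          closed = o$closed)
}

# ---- independent re-implementations used as oracles ---------------------

# Catmull-Rom interpolation matching the matcher's convention (clamped);
# vectorized over positions, returns a length(pos) x 2 matrix
oracle_interp <- function(q, pos) {
  n <- nrow(q)
  out <- matrix(0, length(pos), 2L)
  hi <- pos >= n - 1
  lo_m <- pos < 0
  mid <- !hi & !lo_m
  if (any(hi)) out[hi, ] <- matrix(q[n, ], sum(hi), 2L, byrow = TRUE)
  if (any(lo_m)) out[lo_m, ] <- matrix(q[1L, ], sum(lo_m), 2L, byrow = TRUE)
  if (any(mid)) {
    p <- pos[mid]
    lo <- floor(p)
    w <- p - lo
    for (col in 1:2) {
      p1 <- q[lo + 1, col]
      p2 <- q[lo + 2, col]
      p0 <- ifelse(lo > 0, q[pmax(lo, 1), col], 2 * p1 - p2)
      p3 <- ifelse(lo < n - 2, q[pmin(lo + 3, n), col], 2 * p2 - p1)
      out[mid, col] <- p1 + 0.5 * w * ((p2 - p0) +
        w * ((2 * p0 - 5 * p1 + 4 * p2 - p3) +
             w * (3 * (p1 - p2) + p3 - p0)))
    }
  }
  out
}

oracle_opt_rotation <- function(q1, q2, w) {
  C <- sum(w * (q1[, 1] * q2[, 1] + q1[, 2] * q2[, 2]))
  S <- sum(w * (q1[, 2] * q2[, 1] - q1[, 1] * q2[, 2]))
  th <- atan2(S, C)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

oracle_warp <- function(q, gamma) {
  M <- nrow(q)
  gdot <- c(gamma[2] - gamma[1],
            (gamma[3:M] - gamma[1:(M - 2)]) / 2,
            gamma[M] - gamma[M - 1]) * (M - 1)
  gdot <- pmax(gdot, 0)
  oracle_interp(q, gamma * (M - 1)) * sqrt(gdot)
}

# plain-R dynamic program over the monotone lattice with path recovery,
# mirroring the matching objective step for step (pinned endpoints)
oracle_dp_path <- function(q1, q2, nbrs) {
  M <- nrow(q1)
  dt <- 1 / (M - 1)
  val <- matrix(-Inf, M, M)
  predk <- matrix(NA_integer_, M, M)
  val[1, 1] <- 0
  # precompute edge integrands per neighbour move
  for (i in 2:M) for (j in 2:M) {
    best <- -Inf; bk <- NA_integer_
    for (k in seq_len(nrow(nbrs))) {
      di <- nbrs[k, 1]; dj <- nbrs[k, 2]
      pi_ <- i - di; pj <- j - dj
      if (pi_ < 1 || pj < 1) next
      pv <- val[pi_, pj]
      if (!is.finite(pv)) next
      ss <- 0:di
      qq <- oracle_interp(q2, (pj - 1) + dj * ss / di)
      fv <- q1[pi_ + ss, 1] * qq[, 1] + q1[pi_ + ss, 2] * qq[, 2]
      wts <- ifelse(ss == 0 | ss == di, 0.5, 1)
      cand <- pv + sum(wts * fv) * sqrt(dj / di) * dt
      if (cand > best) { best <- cand; bk <- k }
    }
    val[i, j] <- best
    predk[i, j] <- bk
  }
  g <- rep(NA_real_, M)
  g[M] <- 1
  i <- M; j <- M
  while (i > 1) {
    k <- predk[i, j]
    di <- nbrs[k, 1]; dj <- nbrs[k, 2]
    for (s in 0:(di - 1))
      g[i - di + s] <- (j - 1 - dj + dj * s / di) / (M - 1)
    i <- i - di; j <- j - dj
  }
  g[1] <- 0
  list(ip = val[M, M], gamma = g)
}

# exhaustive closed-curve alignment: every seed, rotation/DP rounds, no
# refinement — the reference for align_closed(seed_stride = 1, refine = 0)
oracle_align_closed <- function(q1, q2, nbrs, rot_iters = 2) {
  M <- nrow(q1)
  q1e <- rbind(q1, q1[1, ])
  w <- rep(1 / M, M + 1); w[c(1, M + 1)] <- 0.5 / M
  best <- list(ip = -2, seed = NA)
  for (s in 0:(M - 1)) {
    idx <- ((seq_len(M + 1) - 1 + s) %% M) + 1
    q2e <- q2[idx, , drop = FALSE]
    gamma <- (seq_len(M + 1) - 1) / M
    R <- diag(2)
    ip <- -2
    for (it in seq_len(rot_iters)) {
      qw <- oracle_warp(q2e, gamma)
      R <- oracle_opt_rotation(q1e, qw, w)
      dpr <- oracle_dp_path(q1e, q2e %*% t(R), nbrs)
      gamma <- dpr$gamma
      ip <- dpr$ip
    }
    if (ip > best$ip) best <- list(ip = ip, seed = s)
  }
  best
}

# the DP slope lattice used by the matcher: coprime moves up to smax
oracle_neighbors <- function(smax = 3) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  nb <- NULL
  for (a in 1:smax) for (b in 1:smax) if (g(a, b) == 1) nb <- rbind(nb, c(a, b))
  storage.mode(nb) <- "integer"
  nb
}

# brute-force k-NN on a distance matrix: full sort per test object
oracle_knn <- function(D, train, labels, test, k) {
  labels <- factor(labels)
  sapply(test, function(ti) {
    d <- D[ti, train]
    nb <- train[order(d)][seq_len(k)]
    votes <- table(as.character(labels[nb]))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      for (cand in nb) {
        l <- as.character(labels[cand])
        if (l %in% top) { top <- l; break }
      }
    }
    top[1]
  })
}

# all bipartitions of a tree, for the monophyly oracle
oracle_monophyletic <- function(tree, tips) {
  n_tip <- length(tree$tip.label)
  target <- sort(match(tips, tree$tip.label))
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    below <- if (node <= n_tip) node else {
      # collect tips below internal node
      desc <- node
      repeat {
        kids <- tree$edge[tree$edge[, 1] %in% desc, 2]
        new <- union(desc, kids)
        if (length(new) == length(desc)) break
        desc <- new
      }
      desc[desc <= n_tip]
    }
    below <- sort(below)
    other <- sort(setdiff(seq_len(n_tip), below))
    if (identical(below, target) || identical(other, target)) return(TRUE)
  }
  FALSE
}
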