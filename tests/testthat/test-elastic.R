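.q_norm2_test <- function(q) {
  s <- rowSums(q$q^2)
  if (q$closed) sum(s) / nrow(q$q)
  else (sum(s) - s[1] / 2 - s[length(s)] / 2) / (nrow(q$q) - 1)
}
.q_inner_test <- function(a, b) sum(rowSums(a * b)) / nrow(a)

test_that("the SRVF transform has the defining invariances", {
  circ <- circle_outline(100)
  q <- srvf_transform(circ)
  expect_equal(.q_norm2_test(q), 1, tolerance = 1e-9)

  # unit-speed curve: q proportional to the tangent before normalization
  # (a circle has constant speed, so q rows all have equal norm)
  expect_lt(diff(range(sqrt(rowSums(q$q^2)))), 1e-6)

  # translation leaves q untouched
  q_t <- srvf_transform(rigid_copy(circ, shift = c(4, -7)))
  expect_lt(max(abs(q_t$q - q$q)), 1e-10)

  # scaling leaves the normalized q untouched
  q_s <- srvf_transform(rigid_copy(circ, scale = 5))
  expect_lt(max(abs(q_s$q - q$q)), 1e-6)

  expect_error(srvf_transform(outline(cbind(1:3, 1:3), closed = FALSE)),
               "at least 4")
})

test_that("the inverse transform reconstructs curves up to similarity", {
  fam <- make_families(2, seed = 4)[[1]]
  o <- family_template(fam, 200)
  rec <- inverse_srvf(srvf_transform(o, 200))
  # same shape up to translation and scale: compare normalized forms
  a <- sweep(o$points, 2, colMeans(o$points)); a <- a / sqrt(sum(a^2))
  b <- sweep(rec$points, 2, colMeans(rec$points)); b <- b / sqrt(sum(b^2))
  expect_lt(sqrt(mean((a - b)^2)), 1e-3)

  # constant q integrates to a straight segment
  qc <- structure(list(q = cbind(rep(1, 50), rep(0, 50)), closed = FALSE,
                       normalized = FALSE, scale = 1, id = NULL),
                  class = "srvf_curve")
  seg <- inverse_srvf(qc)
  expect_lt(max(abs(seg$points[, 2])), 1e-12)
  expect_true(all(diff(seg$points[, 1]) > 0))

  # the SRVF of a circle integrates back to a circle
  qcirc <- srvf_transform(circle_outline(200), 200)
  back <- inverse_srvf(qcirc)
  radii <- sqrt(rowSums(back$points^2))
  expect_lt(diff(range(radii)) / mean(radii), 1e-3)
})

test_that("open-curve alignment recovers known warps and honours endpoints", {
  # a wiggly open curve
  tt <- seq(0, 1, length.out = 100)
  o1 <- outline(cbind(tt, 0.3 * sin(2 * pi * tt) + 0.1 * sin(5 * tt)),
                closed = FALSE)
  q1 <- srvf_transform(o1)
  m_self <- align_open(q1, q1)
  expect_lt(max(abs(m_self$gamma - tt)), 1e-9)
  expect_equal(m_self$ip, 1, tolerance = 1e-9)

  # known smooth warp of the same curve
  warp <- tt + 0.08 * sin(pi * tt)^2
  o2 <- outline(cbind(warp, 0.3 * sin(2 * pi * warp) + 0.1 * sin(5 * warp)),
                closed = FALSE)
  m <- align_open(q1, srvf_transform(o2))
  expect_gte(m$ip, 0.999)
  # recovered gamma close to the true inverse warp
  true_gamma <- stats::approx(warp, tt, xout = tt, rule = 2)$y
  expect_lt(max(abs(m$gamma - true_gamma)), 2 / 100)

  # endpoint-pinned match scores below the free-endpoint match when the
  # landmarks disagree: a sub-segment matched against the full curve can
  # be located exactly when the endpoints are free, but must stretch to
  # the full curve's ends when pinned (same optimization depth, and the
  # pinned feasible set is a subset of the free one)
  tt_sub <- seq(0.3, 0.7, length.out = 100)
  o_sub <- outline(cbind(tt_sub, 0.3 * sin(2 * pi * tt_sub) +
                           0.1 * sin(5 * tt_sub)), closed = FALSE)
  q_sub <- srvf_transform(o_sub)
  ip_fix <- align_open(q_sub, q1, fix_endpoints = TRUE, refine = 0)$ip
  ip_free <- align_open(q_sub, q1, fix_endpoints = FALSE, refine = 0)$ip
  expect_lt(ip_fix, ip_free)
})

test_that("closed-curve alignment undoes start shifts and rotations", {
  fam <- make_families(2, seed = 10)[[1]]
  o1 <- family_template(fam, 80)
  p <- o1$points
  shifted <- p[c(18:80, 1:17), ]                      # shift by 17 vertices
  ang <- 65 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  o2 <- outline(shifted %*% t(R))
  q1 <- srvf_transform(o1); q2 <- srvf_transform(o2)
  m <- align_closed(q1, q2)
  expect_lt(m$distance, 1e-2)
  expect_lt(align_closed(q1, q1)$distance, 1e-6)
})

test_that("elastic distances are metrics on the synthetic suite", {
  set.seed(30)
  fams <- make_families(4, seed = 30)
  os <- lapply(1:6, function(i)
    sample_outline(fams[[(i - 1) %% 4 + 1]],
                   nuisance_spec(vertex_noise_sd = 0.03), 80))
  # range, self-distance, symmetry
  for (i in 1:3) {
    d_self <- elastic_distance(os[[i]], os[[i]], grid_size = 60, refine = 2)
    expect_lt(d_self, 1e-6)
  }
  pairs <- utils::combn(6, 2)
  for (c_i in seq_len(ncol(pairs))) {
    a <- pairs[1, c_i]; b <- pairs[2, c_i]
    dab <- elastic_distance(os[[a]], os[[b]], grid_size = 60)
    dba <- elastic_distance(os[[b]], os[[a]], grid_size = 60)
    expect_gte(dab, 0); expect_lte(dab, pi)
    # raw directions agree within the optimizer envelope; the symmetrized
    # distance is exactly direction-free
    expect_lt(abs(dab - dba), 0.05)
    ds <- elastic_distance(os[[a]], os[[b]], grid_size = 60,
                           symmetrize = TRUE)
    expect_equal(ds, (dab + dba) / 2, tolerance = 1e-10)
  }
  # antipodal SRVFs sit at the far pole
  q <- srvf_transform(circle_outline(60))
  ipd <- .q_inner_test(q$q, -q$q)
  expect_equal(acos(max(-1, min(1, ipd))), pi)
})

test_that("triangle inequality holds within DP discretization slack", {
  set.seed(31)
  fams <- make_families(5, seed = 31)
  viol <- 0
  for (rep in 1:20) {
    os <- lapply(sample(5, 3, replace = TRUE), function(fi)
      sample_outline(fams[[fi]], nuisance_spec(vertex_noise_sd = 0.03), 70))
    dab <- elastic_distance(os[[1]], os[[2]], grid_size = 50, refine = 2)
    dbc <- elastic_distance(os[[2]], os[[3]], grid_size = 50, refine = 2)
    dac <- elastic_distance(os[[1]], os[[3]], grid_size = 50, refine = 2)
    if (dac > (dab + dbc) * 1.05) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("geodesic paths are energy-minimizing transformation series", {
  fams <- make_families(2, seed = 14, separation = 0.3)
  a <- family_template(fams[[1]], 100)
  b <- family_template(fams[[2]], 100)

  # identical endpoints: constant path with zero energy
  same <- geodesic_path(a, a, kappa = 3, mode = "closed", grid_size = 60,
                        refine = 2)
  expect_equal(same$distance, 0, tolerance = 1e-6)
  expect_equal(same$energy, 0, tolerance = 1e-6)

  # open-mode path energy stays within 5% of the endpoint distance
  # (consecutive-step distances are re-optimized, so the sum can fall
  # slightly below as well as above the single endpoint measurement)
  ao <- cut_at_landmarks(a, 1, 100)
  bo <- cut_at_landmarks(b, 1, 100)
  gp <- geodesic_path(ao, bo, kappa = 5, mode = "open", grid_size = 100)
  expect_gte(gp$energy, 0.95 * gp$distance)
  expect_lte(gp$energy, 1.05 * gp$distance)

  # kappa = 2 midpoint is equidistant from both endpoints within 5%
  gp2 <- geodesic_path(a, b, kappa = 2, mode = "closed", grid_size = 60)
  mid <- gp2$steps[[2]]
  d1 <- elastic_distance(a, mid, grid_size = 60)
  d2 <- elastic_distance(mid, b, grid_size = 60)
  expect_lt(abs(d1 - d2) / max(d1, d2), 0.05)

  # permuting interior steps cannot lower the energy
  en_perm <- path_energy(gp$steps[c(1, 4, 3, 2, 5, 6)], mode = "open",
                         grid_size = 100)
  expect_gte(en_perm, gp$energy - 1e-6)

  expect_error(geodesic_path(a, b, kappa = 1), ">= 2")
  expect_error(path_energy(list(a)), "2 steps")
})

test_that("Karcher means are intrinsic averages", {
  fams <- make_families(2, seed = 15, separation = 0.3)
  a <- family_template(fams[[1]], 80)

  # mean of copies is the shape itself, found in one step
  km <- karcher_mean(list(a, a, a), mode = "closed", grid_size = 60)
  expect_lte(km$iterations, 2L)
  expect_lt(km$final_gradient_norm, 1e-4)
  expect_lt(elastic_distance(km$mean_outline, a, grid_size = 60), 1e-2)

  # mean of two shapes sits between them (equidistant up to the
  # measurement envelope at this working resolution)
  b <- family_template(fams[[2]], 80)
  km2 <- karcher_mean(list(a, b), mode = "closed", grid_size = 60)
  d1 <- elastic_distance(km2$mean_outline, a, grid_size = 60)
  d2 <- elastic_distance(km2$mean_outline, b, grid_size = 60)
  expect_lt(abs(d1 - d2) / max(d1, d2), 0.15)
  dab <- elastic_distance(a, b, grid_size = 60)
  expect_lt(max(d1, d2), dab)

  # for a mild pair the mean coincides with the geodesic midpoint, and the
  # mean of two axis-aligned ellipses lies between them in aspect ratio
  e1 <- ellipse_outline(100, a = 1.5, b = 1)
  e2 <- ellipse_outline(100, a = 2.5, b = 1)
  km3 <- karcher_mean(list(e1, e2), mode = "closed", grid_size = 60)
  gp <- geodesic_path(e1, e2, kappa = 2, mode = "closed", grid_size = 60,
                      energy = FALSE)
  expect_lt(elastic_distance(km3$mean_outline, gp$steps[[2]],
                             grid_size = 60), 1e-2)
  pts <- km3$mean_outline$points
  aspect <- diff(range(pts[, 1])) / diff(range(pts[, 2]))
  expect_gte(aspect, 1.5)
  expect_lte(aspect, 2.5)

  expect_error(karcher_mean(list()), "at least one")
})

test_that("symmetric transforms stay mirror-symmetric at every step", {
  c1 <- circle_outline(120, r = 1)
  c2 <- circle_outline(120, r = 1)
  # two symmetric but different shapes: circle and tall ellipse
  e2 <- outline(cbind(cos(2 * pi * (0:119) / 120),
                      1.8 * sin(2 * pi * (0:119) / 120)))
  st <- symmetric_transform(c1, e2, kappa = 4, grid_size = 80)
  expect_length(st$steps, 5L)
  for (s in st$steps) {
    p <- s$points
    xc <- mean(p[, 1])
    refl <- cbind(2 * xc - p[, 1], p[, 2])
    dmax <- max(vapply(seq_len(nrow(p)), function(i)
      min(sqrt((refl[, 1] - p[i, 1])^2 + (refl[, 2] - p[i, 2])^2)),
      numeric(1)))
    expect_lt(dmax / centroid_size(s) * sqrt(nrow(p)), 0.02)
  }
  # asymmetric input is rejected
  tri <- outline(cbind(c(0, 3, 0.2), c(0, 0.3, 2)))
  expect_error(symmetric_transform(tri, c1), "mirror-symmetric")
})
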