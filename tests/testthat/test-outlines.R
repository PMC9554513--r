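test_that("binarize thresholds greyscale images and flags degenerate ones", {
  expect_error(binarize(matrix(0, 10, 10), threshold = 0.5),
               "empty foreground")
  disc <- rasterize_outline(circle_outline(100), image_size = 60)
  expect_identical(binarize(disc, threshold = 0.5), disc)  # idempotent
  # two-level image: otsu separates exactly the disc pixels
  img <- 0.2 + 0.6 * disc
  expect_identical(binarize(img, threshold = "otsu"), disc)
})

test_that("contour extraction recovers analytic area and perimeter", {
  mask <- matrix(0L, 200, 200)
  for (r in 1:200) for (cc in 1:200)
    if ((r - 100.5)^2 + (cc - 100.5)^2 <= 50^2) mask[r, cc] <- 1L
  cont <- extract_contour(mask)
  expect_true(cont$closed)
  expect_equal(outline_area(cont) / (pi * 50^2), 1, tolerance = 0.01)

  sq <- matrix(0L, 120, 120)
  sq[31:90, 31:90] <- 1L               # square of side 60
  cs <- extract_contour(sq)
  expect_gte(outline_perimeter(cs) / (4 * 60), 0.98)
  expect_lte(outline_perimeter(cs) / (4 * 60), 1.03)

  # largest component wins over a speck
  speck <- mask
  speck[5:7, 5:7] <- 1L
  c2 <- extract_contour(speck)
  expect_equal(outline_area(c2), outline_area(cont), tolerance = 1e-9)
  expect_error(extract_contour(matrix(0L, 5, 5)), "no foreground")
})

test_that("arc-length resampling gives equally spaced points on a spline", {
  set.seed(1)
  th <- sort(stats::runif(360, 0, 2 * pi))
  irregular <- outline(cbind(cos(th), sin(th)))
  rs <- resample_arclength(irregular, n_points = 100)
  ang <- atan2(rs$points[, 2], rs$points[, 1])
  dang <- diff(ang) %% (2 * pi)
  dang[dang > pi] <- dang[dang > pi] - 2 * pi
  expect_true(all(abs(abs(dang) * 180 / pi - 3.6) < 0.05))

  seg <- outline(cbind(c(0, 0.1, 0.45, 0.8, 1), rep(0, 5)), closed = FALSE)
  rs2 <- resample_arclength(seg, n_points = 5)
  expect_equal(rs2$points[, 1], c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-6)
  expect_equal(rs2$points[1, ], c(x = 0, y = 0))     # endpoints pinned
  expect_equal(rs2$points[5, ], c(x = 1, y = 0))

  # resampling an already equally spaced outline is near-identity
  circ <- circle_outline(100)
  again <- resample_arclength(circ, n_points = 100)
  expect_lt(max(abs(again$points - circ$points)), 1e-4)

  # chord lengths have coefficient of variation below 1%
  fam <- make_families(2, seed = 2)[[1]]
  rs3 <- resample_arclength(family_template(fam, 150), n_points = 120)
  chords <- sqrt(rowSums(diff(rbind(rs3$points, rs3$points[1, ]))^2))
  expect_lt(stats::sd(chords) / mean(chords), 0.01)
})

test_that("vertical symmetrization keeps the shorter side and mirrors it", {
  circ <- circle_outline(120)
  sym <- symmetrize_vertical(circ)
  # symmetric input is a fixed point (up to resampling tolerance)
  expect_equal(outline_area(sym), outline_area(circ), tolerance = 1e-3)

  # add a bump on the left (longer) side only; it must disappear
  th <- 2 * pi * (0:119) / 120
  r <- 1 + 0.3 * exp(-((th - pi)^2) / 0.05)   # bump at angle pi (left)
  bumped <- outline(cbind(r * cos(th), r * sin(th)))
  fixed <- symmetrize_vertical(bumped)
  # the kept right semicircle is reflected about the vertical axis through
  # the input centroid (pulled left by the bump), so the exact area is
  # pi + 4 |xc|: two half-discs plus the strip between the two flat edges
  xc <- mean(bumped$points[, 1])
  expect_equal(outline_area(fixed), pi + 4 * abs(xc), tolerance = 0.01)
  # and the bump itself is gone: no vertex further than ~1 from the axis
  ctr_x <- mean(fixed$points[, 1])
  expect_lt(max(sqrt((fixed$points[, 1] - ctr_x)^2 + fixed$points[, 2]^2)),
            1.05)

  # output is invariant under reflection about its own vertical axis
  p <- fixed$points
  xc <- mean(p[, 1])
  refl <- cbind(2 * xc - p[, 1], p[, 2])
  d <- vapply(seq_len(nrow(p)), function(i)
    min(sqrt((refl[, 1] - p[i, 1])^2 + (refl[, 2] - p[i, 2])^2)), numeric(1))
  expect_lt(max(d), 1e-6)
})

test_that("generalized Procrustes removes similarity transforms exactly", {
  base <- ellipse_outline(60)
  moved <- rigid_copy(base, angle = 40 * pi / 180, scale = 3, shift = c(5, -2))
  al <- procrustes_align(list(base, moved))
  expect_lt(max(abs(al$outlines[[1]]$points - al$outlines[[2]]$points)), 1e-8)

  # aligning an aligned set changes nothing
  al2 <- procrustes_align(al$outlines)
  for (i in 1:2)
    expect_lt(max(abs(al2$outlines[[i]]$points - al$outlines[[i]]$points)),
              1e-8)

  # mirror image: residual positive without reflection, zero with it
  asym <- outline(cbind(c(0, 2, 3, 1, -1), c(0, 0, 2, 3, 1)))
  mir <- outline(cbind(-asym$points[, 1], asym$points[, 2]))
  a_no <- procrustes_align(list(asym, mir), allow_reflection = FALSE)
  a_yes <- procrustes_align(list(asym, mir), allow_reflection = TRUE)
  rms <- function(a) sqrt(mean((a$outlines[[1]]$points -
                                a$outlines[[2]]$points)^2))
  expect_gt(rms(a_no), 1e-3)
  expect_lt(rms(a_yes), 1e-8)

  expect_error(procrustes_align(list(base, circle_outline(50))), "same N")
})

test_that("landmark cuts produce open curves between the landmarks", {
  circ <- circle_outline(100)                  # starts at angle 0
  cut <- cut_at_landmarks(circ, 1, 51)         # angle 0 to pi, ccw
  expect_false(cut$closed)
  expect_equal(nrow(cut$points), 51L)
  expect_equal(unname(cut$points[1, ]), c(1, 0), tolerance = 1e-9)
  expect_equal(unname(cut$points[51, ]), c(-1, 0), tolerance = 1e-9)
  # wrap-around cut covers the complement
  cut2 <- cut_at_landmarks(circ, 51, 1)
  expect_equal(nrow(cut2$points), 51L)
  expect_error(cut_at_landmarks(circ, 5, 5), "differ")
  expect_error(cut_at_landmarks(circ, 0, 5), "out of range")

  # rejoining both cuts recovers a cyclic shift of the input
  rejoined <- rbind(cut$points, cut2$points[-c(1, 51), ])
  expect_equal(canonicalize_outline(outline(rejoined))$points,
               canonicalize_outline(circ)$points, tolerance = 1e-9)
})

test_that("open and closed elastic distances differ on landmark-cut shapes", {
  fams <- make_families(2, seed = 8, separation = 0.4)
  a <- family_template(fams[[1]], 80)
  b <- family_template(fams[[2]], 80)
  d_closed <- elastic_distance(a, b, mode = "closed", grid_size = 60,
                               refine = 2)
  ao <- cut_at_landmarks(a, 1, 80)
  bo <- cut_at_landmarks(b, 1, 80)
  d_open <- elastic_distance(ao, bo, mode = "open", grid_size = 60)
  expect_gt(abs(d_open - d_closed), 1e-4)
})
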