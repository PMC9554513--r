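#' Synthetic outline families
#'
#' A shape family is a star-shaped template defined by a truncated Fourier
#' radius function r(theta) = 1 + sum_j a_j cos(j theta) + b_j sin(j theta).
#' Star-shaped templates guarantee simple (non-self-intersecting) closed
#' curves and admit analytic area and arc-length checks. `make_families`
#' draws `n_classes` such templates whose amplitude vectors are scaled by
#' `separation`, so larger separation means more distinct class means.
#'
#' @param n_classes number of families (>= 2).
#' @param n_harmonics number of Fourier harmonics per template.
#' @param separation positive scale of between-family amplitude differences;
#'   amplitudes are `separation * z_j / j` with fixed standard normal draws
#'   `z_j`, so a fixed seed gives templates that deform continuously (and
#'   monotonically) with `separation`.
#' @param seed integer seed; identical seeds give identical families.
#' @return list of `shape_family` objects (fields `family_id`,
#'   `amplitudes` — a 2 x n_harmonics matrix of cosine/sine coefficients —
#'   and `n_harmonics`).
#' @examples
#' fams <- make_families(3, separation = 0.3, seed = 1)
#' plot(family_template(fams[[1]], 100))
#' @export
make_families <- function(n_classes, n_harmonics = 6L, separation = 0.3,
                          seed = 1L) {
  if (!is.numeric(n_classes) || n_classes < 2)
    stop("`n_classes` must be >= 2")
  if (!is.numeric(separation) || separation <= 0)
    stop("`separation` must be positive")
  n_classes <- as.integer(n_classes)
  n_harmonics <- as.integer(n_harmonics)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_classes), function(i) {
    z <- matrix(stats::rnorm(2L * n_harmonics), nrow = 2L)
    amp <- separation * sweep(z, 2L, seq_len(n_harmonics), "/")
    # keep the template radius safely positive (star-shaped, simple curve)
    th <- seq(0, 2 * pi, length.out = 721L)
    r <- .fourier_radius(th, amp)
    if (min(r) < 0.25) amp <- amp * (0.75 / (1 - min(r)))
    structure(list(family_id = paste0("F", i), amplitudes = amp,
                   n_harmonics = n_harmonics),
              class = "shape_family")
  })
}

#' Nested synthetic families (classes grouped into higher-level families)
#'
#' Builds a two-level hierarchy: `n_families` well-separated base templates,
#' each spawning `n_subclasses` classes by smaller amplitude perturbations.
#' Emulates taxonomic structure (e.g. genera within families) for testing
#' whether distance-based trees recover the grouping.
#'
#' @param n_families number of top-level families (>= 2).
#' @param n_subclasses classes per family (>= 2).
#' @param separation between-family amplitude scale (see [make_families]).
#' @param sub_separation within-family, between-class amplitude scale
#'   (should be well below `separation`).
#' @param n_harmonics Fourier harmonics per template.
#' @param seed integer seed.
#' @return flat list of `shape_family` objects; each carries a `parent`
#'   field naming its family.
#' @export
make_nested_families <- function(n_families = 3L, n_subclasses = 2L,
                                 separation = 0.45, sub_separation = 0.12,
                                 n_harmonics = 6L, seed = 1L) {
  stopifnot(n_families >= 2L, n_subclasses >= 2L, sub_separation > 0)
  base <- make_families(n_families, n_harmonics = n_harmonics,
                        separation = separation, seed = seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 1L)
  out <- list()
  for (i in seq_len(n_families)) {
    for (j in seq_len(n_subclasses)) {
      z <- matrix(stats::rnorm(2L * n_harmonics), nrow = 2L)
      amp <- base[[i]]$amplitudes +
        sub_separation * sweep(z, 2L, seq_len(n_harmonics), "/")
      th <- seq(0, 2 * pi, length.out = 721L)
      r <- .fourier_radius(th, amp)
      if (min(r) < 0.25) amp <- amp * (0.75 / (1 - min(r)))
      fam <- structure(list(family_id = sprintf("F%d%s", i, letters[j]),
                            amplitudes = amp, n_harmonics = n_harmonics,
                            parent = sprintf("F%d", i)),
                       class = "shape_family")
      out[[length(out) + 1L]] <- fam
    }
  }
  out
}

#' @export
print.shape_family <- function(x, ...) {
  cat(sprintf("<shape_family> %s, %d harmonics\n", x$family_id, x$n_harmonics))
  invisible(x)
}

.fourier_radius <- function(theta, amp) {
  r <- rep(1, length(theta))
  for (j in seq_len(ncol(amp)))
    r <- r + amp[1L, j] * cos(j * theta) + amp[2L, j] * sin(j * theta)
  r
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Template outline of a shape family
#'
#' @param family a `shape_family`.
#' @param n_points vertices (equally spaced in angle).
#' @return closed [outline].
#' @export
family_template <- function(family, n_points = 100L) {
  stopifnot(inherits(family, "shape_family"))
  th <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  r <- .fourier_radius(th, family$amplitudes)
  outline(cbind(r * cos(th), r * sin(th)), closed = TRUE,
          id = family$family_id, label = family$family_id)
}

#' Nuisance transformation specification
#'
#' Describes the variation a shape method must be invariant to: rigid
#' motions, scaling, cyclic start-point shifts and smooth monotone
#' reparametrization, plus a smooth radial perturbation field standing in
#' for individual within-class shape variation. Defaults are the package's
#' reference study conditions.
#'
#' @param rotation_range max absolute rotation in radians (uniform draw).
#' @param scale_range length-2 positive interval for uniform scale draws.
#' @param translation_range max absolute translation per axis.
#' @param start_shift logical; randomly rotate the vertex ordering
#'   (cyclic start point)?
#' @param reparam_strength amplitude of the smooth monotone parameter warp,
#'   as the maximum deviation of the warp derivative from 1 (must be < 1 so
#'   the warp stays strictly monotone; capped at 0.9).
#' @param vertex_noise_sd standard deviation of the smooth radial
#'   perturbation field, as a fraction of the unit template radius.
#' @return a `nuisance_spec` object.
#' @export
nuisance_spec <- function(rotation_range = pi, scale_range = c(0.75, 1.35),
                          translation_range = 1, start_shift = TRUE,
                          reparam_strength = 0.15, vertex_noise_sd = 0.03) {
  stopifnot(rotation_range >= 0, length(scale_range) == 2L,
            all(scale_range > 1e-8), translation_range >= 0,
            reparam_strength >= 0, vertex_noise_sd >= 0)
  structure(list(rotation_range = rotation_range,
                 scale_range = sort(as.numeric(scale_range)),
                 translation_range = translation_range,
                 start_shift = isTRUE(start_shift),
                 reparam_strength = min(reparam_strength, 0.9),
                 vertex_noise_sd = vertex_noise_sd),
            class = "nuisance_spec")
}

#' No-op nuisance (identity transform, no noise)
#' @return a `nuisance_spec` with all ranges zero.
#' @export
nuisance_none <- function() {
  nuisance_spec(rotation_range = 0, scale_range = c(1, 1),
                translation_range = 0, start_shift = FALSE,
                reparam_strength = 0, vertex_noise_sd = 0)
}

#' Sample one outline from a family
#'
#' Applies, in order: smooth radial vertex noise, a smooth monotone
#' reparametrization of the angular parameter, a cyclic start-point shift,
#' rotation, scaling and translation. Uses the current RNG stream.
#'
#' @param family a `shape_family`.
#' @param nuisance a [nuisance_spec].
#' @param n_points vertices in the sampled outline (>= 20).
#' @param id,label optional metadata for the outline.
#' @return closed [outline].
#' @export
sample_outline <- function(family, nuisance = nuisance_spec(),
                           n_points = 100L, id = NULL, label = NULL) {
  stopifnot(inherits(family, "shape_family"), inherits(nuisance, "nuisance_spec"))
  if (n_points < 20L) stop("`n_points` must be >= 20")
  n_points <- as.integer(n_points)
  th <- 2 * pi * (seq_len(n_points) - 1L) / n_points

  # smooth monotone warp of the angular parameter
  if (nuisance$reparam_strength > 0) {
    J <- 3L
    u <- stats::runif(J, 0.5, 1)
    ph <- stats::runif(J, 0, 2 * pi)
    e <- nuisance$reparam_strength * u / (seq_len(J) * sum(u))
    # sum_j j*e_j = reparam_strength < 1 ensures a strictly monotone warp
    warp <- th
    for (j in seq_len(J)) warp <- warp + e[j] * sin(j * th + ph[j])
    dwarp <- rep(1, length(th))
    for (j in seq_len(J)) dwarp <- dwarp + j * e[j] * cos(j * th + ph[j])
    if (any(dwarp <= 0)) stop("internal error: non-monotone warp")
    th_eval <- warp
  } else th_eval <- th

  r <- .fourier_radius(th_eval, family$amplitudes)

  # smooth radial perturbation field with SD = vertex_noise_sd
  if (nuisance$vertex_noise_sd > 0) {
    Jn <- 6L
    cf <- stats::rnorm(2L * Jn, sd = nuisance$vertex_noise_sd / sqrt(Jn))
    g <- rep(0, n_points)
    for (j in seq_len(Jn))
      g <- g + cf[2L * j - 1L] * cos(j * th_eval) + cf[2L * j] * sin(j * th_eval)
    r <- r * (1 + g)
  }
  pts <- cbind(r * cos(th_eval), r * sin(th_eval))

  if (nuisance$start_shift) {
    s <- sample.int(n_points, 1L) - 1L
    if (s > 0L) pts <- pts[c((s + 1L):n_points, 1L:s), , drop = FALSE]
  }
  if (nuisance$rotation_range > 0) {
    a <- stats::runif(1L, -nuisance$rotation_range, nuisance$rotation_range)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
    pts <- pts %*% t(R)
  }
  if (diff(nuisance$scale_range) > 0 || any(nuisance$scale_range != 1)) {
    sc <- stats::runif(1L, nuisance$scale_range[1L], nuisance$scale_range[2L])
    pts <- pts * sc
  }
  if (nuisance$translation_range > 0) {
    tr <- stats::runif(2L, -nuisance$translation_range, nuisance$translation_range)
    pts <- sweep(pts, 2L, tr, "+")
  }
  outline(pts, closed = TRUE, id = id, label = label)
}

#' Generate a balanced labelled synthetic dataset
#'
#' Each object is drawn from its family with an independent, counter-derived
#' seed, so datasets are reproducible object-by-object from the single
#' dataset seed.
#'
#' @param families list of `shape_family` (from [make_families]).
#' @param nuisance a [nuisance_spec].
#' @param n_per_class objects per family (>= 2).
#' @param n_points vertices per outline.
#' @param seed integer dataset seed.
#' @return a `shape_dataset`: list with `outlines` (list of [outline]),
#'   `labels` (factor), `ids` (character), `seed`, `families`, `nuisance`.
#' @examples
#' ds <- make_dataset(make_families(3, seed = 1), n_per_class = 4, seed = 2)
#' table(ds$labels)
#' @export
make_dataset <- function(families, nuisance = nuisance_spec(),
                         n_per_class = 10L, n_points = 100L, seed = 1L) {
  if (!is.list(families) || length(families) == 0L)
    stop("`families` must be a non-empty list of shape families")
  if (n_per_class < 2L) stop("`n_per_class` must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  outlines <- list()
  labels <- character(0)
  ids <- character(0)
  counter <- 0L
  for (f in families) {
    for (i in seq_len(n_per_class)) {
      counter <- counter + 1L
      set.seed((as.integer(seed) + 104729L * counter) %% 2147483647L)
      oid <- sprintf("%s_%02d", f$family_id, i)
      outlines[[counter]] <- sample_outline(f, nuisance, n_points,
                                            id = oid, label = f$family_id)
      labels <- c(labels, f$family_id)
      ids <- c(ids, oid)
    }
  }
  structure(list(outlines = outlines, labels = factor(labels), ids = ids,
                 seed = as.integer(seed), families = families,
                 nuisance = nuisance),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf("<shape_dataset> %d outlines, %d classes, seed %d\n",
              length(x$outlines), nlevels(x$labels), x$seed))
  invisible(x)
}

#' Rasterize a closed outline to a binary mask
#'
#' Scanline even-odd polygon fill, no anti-aliasing; the outline is scaled
#' to fit the image with the given margin. Pixel (row r, col c) covers the
#' point (x = c, y = rows - r) so shapes stay in conventional y-up axes.
#'
#' @param x a closed, simple [outline].
#' @param image_size image side in pixels.
#' @param margin fraction of the image side kept empty on each border.
#' @return integer matrix (`image_size` x `image_size`) of 0/1 values.
#' @export
rasterize_outline <- function(x, image_size = 400L, margin = 0.05) {
  stopifnot(is_outline(x), x$closed)
  if (.self_intersects(x$points)) stop("outline is self-intersecting")
  image_size <- as.integer(image_size)
  p <- x$points
  rng <- apply(p, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ])
  usable <- image_size * (1 - 2 * margin)
  sc <- usable / span
  ctr <- colMeans(rng)
  px <- (p[, 1L] - ctr[1L]) * sc + (image_size + 1) / 2
  py <- (p[, 2L] - ctr[2L]) * sc + (image_size + 1) / 2
  mask <- matrix(0L, image_size, image_size)
  n <- length(px)
  xs <- px; ys <- py
  xe <- c(px[-1L], px[1L]); ye <- c(py[-1L], py[1L])
  for (r in seq_len(image_size)) {
    yc <- image_size - r + 1L  # pixel centre in y-up coordinates (y = rows - row + 1)
    # even-odd rule: edges crossing the scanline y = yc
    hit <- (ys <= yc & ye > yc) | (ye <= yc & ys > yc)
    if (!any(hit)) next
    xc <- xs[hit] + (yc - ys[hit]) / (ye[hit] - ys[hit]) * (xe[hit] - xs[hit])
    xc <- sort(xc)
    for (i in seq(1L, length(xc) - 1L, by = 2L)) {
      c0 <- max(1L, ceiling(xc[i])); c1 <- min(image_size, floor(xc[i + 1L]))
      if (c1 >= c0) mask[r, c0:c1] <- 1L
    }
  }
  # margin contract: border rows/columns stay background
  mask[1L, ] <- 0L; mask[image_size, ] <- 0L
  mask[, 1L] <- 0L; mask[, image_size] <- 0L
  mask
}

# O(n^2) segment-pair crossing test (non-adjacent edges only)
.self_intersects <- function(p) {
  n <- nrow(p)
  a <- p; b <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip edges adjacent to edge i
    d1 <- cross(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], a[js, 1L], a[js, 2L])
    d2 <- cross(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], b[js, 1L], b[js, 2L])
    d3 <- cross(a[js, 1L], a[js, 2L], b[js, 1L], b[js, 2L], a[i, 1L], a[i, 2L])
    d4 <- cross(a[js, 1L], a[js, 2L], b[js, 1L], b[js, 2L], b[i, 1L], b[i, 2L])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Write a synthetic dataset to disk
#'
#' One outline CSV per object plus a `manifest.csv` (object_id, class, file)
#' and, optionally, PNG binary masks.
#'
#' @param dataset a `shape_dataset`.
#' @param dir output directory (created if missing).
#' @param masks logical; also write rasterized PNG masks (needs the png
#'   package)?
#' @param image_size mask size in pixels when `masks = TRUE`.
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir, masks = FALSE, image_size = 400L) {
  stopifnot(inherits(dataset, "shape_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$outlines))
  for (i in seq_along(dataset$outlines)) {
    files[i] <- paste0(dataset$ids[i], ".csv")
    write_outline_csv(dataset$outlines[[i]], file.path(dir, files[i]))
    if (masks) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("the png package is required for masks = TRUE")
      m <- rasterize_outline(dataset$outlines[[i]], image_size = image_size)
      png::writePNG(m * 1.0, file.path(dir, paste0(dataset$ids[i], ".png")))
    }
  }
  manifest <- data.frame(object_id = dataset$ids,
                         class = as.character(dataset$labels),
                         file = files, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset]
#' @param dir directory containing `manifest.csv` and outline CSVs.
#' @return a `shape_dataset` (without generator metadata).
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  outlines <- lapply(seq_len(nrow(manifest)), function(i)
    read_outline_csv(file.path(dir, manifest$file[i]), closed = TRUE,
                     id = manifest$object_id[i], label = manifest$class[i]))
  structure(list(outlines = outlines, labels = factor(manifest$class),
                 ids = manifest$object_id, seed = NA_integer_,
                 families = NULL, nuisance = NULL),
            class = "shape_dataset")
}
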