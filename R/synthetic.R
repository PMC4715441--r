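## Synthetic data with analytic ground truth. Skeleton generators emit point
## clouds on convex polytopes whose volumes are known in closed form (never
## computed by the hull code under test); calibration generators draw masses
## from M = 10^(a + b*x + eps) with Gaussian log10-scale noise, optionally
## with Brownian-motion-correlated residuals on a phylogeny. Every generator
## is a pure function of its arguments and seed.

## Base polytopes, centred conveniently, with closed-form volumes.
base_polytope <- function(shape, size) {
  switch(shape,
    cuboid = {
      stopifnot(length(size) == 3L, all(size > 0))
      v <- as.matrix(expand.grid(x = c(0, size[1]), y = c(0, size[2]), z = c(0, size[3])))
      list(vertices = v, volume = prod(size))
    },
    tetrahedron = {
      stopifnot(length(size) == 1L, size > 0)
      ## regular tetrahedron with edge length `size`
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
        (size / (2 * sqrt(2)))
      list(vertices = v, volume = size^3 / (6 * sqrt(2)))
    },
    ellipsoid = {
      ## inscribed octahedral approximation of an ellipsoid with semi-axes
      ## `size`; the ground truth is the octahedron's own volume 4/3*abc,
      ## exactly, not the ellipsoid's
      stopifnot(length(size) == 3L, all(size > 0))
      v <- rbind(c(size[1], 0, 0), c(-size[1], 0, 0),
                 c(0, size[2], 0), c(0, -size[2], 0),
                 c(0, 0, size[3]), c(0, 0, -size[3]))
      list(vertices = v, volume = 4 / 3 * prod(size))
    },
    chm_error("invalid_spec", sprintf("unknown shape '%s'", shape)))
}

## Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q %*% diag(c(1, 1, det(Q)))
}

#' Generate a synthetic skeleton with analytic segment volumes
#'
#' Each segment is a point cloud on a convex polytope of closed-form volume:
#' all polytope vertices are included (so the hull is exactly recoverable)
#' plus strictly interior points drawn as positive-weight convex
#' combinations of the vertices. Segments are posed by a random rotation and
#' translation, which leaves volumes unchanged. Ground-truth volumes come
#' from the generator's closed forms, never from the hull code.
#'
#' @param segments list of segment specs, each a list with `label`,
#'   `shape` (`"cuboid"`, `"tetrahedron"` or `"ellipsoid"`), `size`
#'   (mm; length 3 for cuboid/ellipsoid semi-axes, length 1 for the
#'   tetrahedron edge), and optionally `n_interior` (default 50).
#' @param feet_labels segment names flagged as feet.
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @param specimen specimen identifier.
#' @return list with `skeleton` (a [skeleton_segments()]) and `truth`
#'   (a [hull_volume_table()] of analytic volumes).
#' @export
make_synthetic_skeleton <- function(segments, feet_labels = character(),
                                    seed = 1L, specimen = "synthetic") {
  if (length(segments) == 0L) chm_error("invalid_spec", "no segments in spec")
  labels <- vapply(segments, function(s) s$label %||% "", character(1))
  if (any(!nzchar(labels)) || anyDuplicated(labels)) {
    chm_error("invalid_spec", "every segment needs a unique non-empty label")
  }
  withr::with_seed(seed, {
    built <- lapply(segments, function(s) {
      bp <- tryCatch(base_polytope(s$shape %||% "cuboid", s$size),
                     error = function(e) chm_error("invalid_spec", conditionMessage(e)))
      n_int <- s$n_interior %||% 50L
      R <- random_rotation()
      shift <- stats::runif(3, -100, 100)
      interior <- if (n_int > 0) {
        w <- matrix(stats::rexp(n_int * nrow(bp$vertices)), n_int)
        (w / rowSums(w)) %*% bp$vertices
      } else {
        matrix(numeric(), 0L, 3L)
      }
      pts <- sweep(rbind(bp$vertices, interior) %*% t(R), 2, shift, "+")
      list(ps = point_set(s$label, pts), volume = bp$volume)
    })
  })
  truth <- vapply(built, `[[`, numeric(1), "volume")
  names(truth) <- labels
  list(
    skeleton = skeleton_segments(lapply(built, `[[`, "ps"),
                                 feet_labels = feet_labels, specimen = specimen),
    truth = hull_volume_table(truth, feet_labels = feet_labels, specimen = specimen))
}

#' Generate a calibration dataset from a known power law
#'
#' Draws log10 volumes uniformly on `x_range` and masses as
#' `10^(a + b*x + eps)` with `eps ~ Normal(0, sigma^2)` on the log10 scale.
#' With `sigma = 0` the fit recovers `(a, b)` exactly and r2 = 1.
#'
#' @param n number of specimens, >= 3.
#' @param a true intercept (log10 g).
#' @param b true slope.
#' @param sigma residual SD on the log10 scale, >= 0.
#' @param x_range range of log10 volume (log10 mm^3); default `c(4.6, 6.2)`,
#'   the extant pigeon span.
#' @param seed integer seed.
#' @param preparation preparation label given to every synthetic specimen.
#' @return a [calibration_dataset()] with attributes `true_a`, `true_b`,
#'   `true_sigma`.
#' @export
make_calibration_dataset <- function(n, a, b, sigma, x_range = c(4.6, 6.2),
                                     seed = 1L, preparation = "eviscerated") {
  if (n < 3L || sigma < 0 || diff(range(x_range)) <= 0) {
    chm_error("invalid_spec", "need n >= 3, sigma >= 0 and a non-degenerate x range")
  }
  withr::with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    eps <- stats::rnorm(n, 0, sigma)
  })
  vol <- 10^x
  df <- data.frame(
    species = sprintf("sim_sp_%03d", seq_len(n)),
    common_name = sprintf("simulated specimen %d", seq_len(n)),
    mass_g = 10^(a + b * x + eps),
    preparation = preparation,
    ch_vol_mm3 = vol,
    ch_vol_minus_feet_mm3 = vol,
    stringsAsFactors = FALSE)
  out <- calibration_dataset(df, subset_tag = "combined", predictor_variant = "minus_feet")
  attr(out, "true_a") <- a; attr(out, "true_b") <- b; attr(out, "true_sigma") <- sigma
  out
}

#' Generate a calibration dataset with Brownian-correlated residuals
#'
#' As [make_calibration_dataset()], but residuals are drawn multivariate
#' normal with covariance `sigma2 * C(tree)`, the Brownian-motion
#' expectation on the supplied phylogeny; species names are the tree's tip
#' labels. This is the regime PGLS assumes.
#'
#' @param tree an [ape::phylo] tree with >= 3 tips.
#' @param a,b true coefficients.
#' @param sigma2 Brownian rate (residual variance per unit branch length).
#' @param seed integer seed.
#' @param x_range range of log10 volume; default `c(4.6, 6.2)`.
#' @return a [calibration_dataset()] with truth attributes as above.
#' @export
make_brownian_dataset <- function(tree, a, b, sigma2, seed = 1L,
                                  x_range = c(4.6, 6.2)) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L || sigma2 < 0) {
    chm_error("invalid_spec", "need >= 3 tips and sigma2 >= 0")
  }
  C <- brownian_covariance(tree)
  withr::with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    z <- stats::rnorm(n)
  })
  eps <- if (sigma2 > 0) drop(t(chol(sigma2 * C)) %*% z) else rep(0, n)
  vol <- 10^x
  df <- data.frame(
    species = tree$tip.label,
    common_name = tree$tip.label,
    mass_g = 10^(a + b * x + eps),
    preparation = "eviscerated",
    ch_vol_mm3 = vol,
    ch_vol_minus_feet_mm3 = vol,
    stringsAsFactors = FALSE)
  out <- calibration_dataset(df, subset_tag = "combined", predictor_variant = "minus_feet")
  attr(out, "true_a") <- a; attr(out, "true_b") <- b; attr(out, "true_sigma2") <- sigma2
  out
}
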