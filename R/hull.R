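## 3D convex hull geometry.
##
## The hull is built by incremental insertion: start from a non-degenerate
## tetrahedron of extreme points, then for each remaining point find the
## facets it can "see" (positive signed distance), delete them, and stitch
## the point to the horizon edge loop. Facets are kept triangular and
## oriented outward throughout, so the enclosed volume is the sum of signed
## tetrahedra against any origin (the divergence theorem on a closed,
## consistently oriented surface).
##
## Tolerances are scale-free: planarity/containment tests use
## tau_planar = 1e-8 * bounding-box diagonal, relative volume comparisons
## tau_vol = 1e-9.

#' Relative tolerances used by the geometry module
#'
#' `tau_planar(points)` is the absolute planarity/containment tolerance for a
#' point cloud, defined as 1e-8 times its bounding-box diagonal; `tau_vol()`
#' is the relative tolerance for volume comparisons (1e-9).
#'
#' @param points numeric matrix of 3D coordinates (mm).
#' @return a single numeric tolerance.
#' @export
tau_planar <- function(points) {
  d <- sqrt(sum((apply(points, 2, max) - apply(points, 2, min))^2))
  1e-8 * max(d, 1)
}

#' @rdname tau_planar
#' @export
tau_vol <- function() 1e-9

## Coerce/validate a point cloud: n x 3 numeric matrix, all finite.
as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 3L) {
    points <- matrix(points, nrow = 1L)
  }
  if (!is.matrix(points) || ncol(points) != 3L || !is.numeric(points)) {
    chm_error("degenerate_geometry", "points must be an n x 3 numeric matrix")
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    chm_error("degenerate_geometry", "all coordinates must be finite")
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  points
}

#' Construct a labelled point set for one functional unit
#'
#' A point set is the geometric input for one anatomical segment (skull,
#' trunk, a neck sub-unit, a limb element, a foot...), expressed as 3D
#' coordinates in millimetres.
#'
#' @param label non-empty segment name.
#' @param points n x 3 numeric matrix of coordinates (mm), all finite, n >= 1.
#' @return an object of class `point_set` with fields `label` and `points`.
#' @export
point_set <- function(label, points) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    chm_error("degenerate_geometry", "segment label must be a non-empty string")
  }
  points <- as_points(points)
  if (nrow(points) < 1L) {
    chm_error("degenerate_geometry", sprintf("segment '%s' has no points", label))
  }
  structure(list(label = label, points = points), class = "point_set")
}

## Exact duplicate removal; degenerate simplices in facet construction come
## from repeated coordinates, not near-duplicates.
dedupe_points <- function(points) {
  points[!duplicated(points), , drop = FALSE]
}

## Cross products of rows of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Unnormalised outward-facing plane data for each triangular facet.
facet_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  n <- row_cross(v2 - v1, v3 - v1)
  list(normal = n, base = v1)
}

## Pick a robust initial tetrahedron: the farthest pair among the six axis
## extremes, the point farthest from their line, then farthest from the plane.
initial_simplex <- function(pts, tol) {
  ext <- unique(c(apply(pts, 2, which.min), apply(pts, 2, which.max)))
  d2 <- as.matrix(stats::dist(pts[ext, , drop = FALSE]))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  i1 <- ext[ij[1]]; i2 <- ext[ij[2]]
  if (d2[ij[1], ij[2]] < tol) {
    chm_error("degenerate_geometry", "point set collapses to a single point")
  }
  dvec <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- row_cross(rel, matrix(dvec, nrow(pts), 3, byrow = TRUE))
  line_d <- sqrt(rowSums(cr^2)) / sqrt(sum(dvec^2))
  i3 <- which.max(line_d)
  if (line_d[i3] < tol) {
    chm_error("degenerate_geometry", "points are collinear (affine rank < 2)")
  }
  nrm <- row_cross(matrix(pts[i2, ] - pts[i1, ], 1), matrix(pts[i3, ] - pts[i1, ], 1))[1, ]
  nrm <- nrm / sqrt(sum(nrm^2))
  plane_d <- abs(rel %*% nrm)
  i4 <- which.max(plane_d)
  if (plane_d[i4] < tol) {
    chm_error("degenerate_geometry", "points are coplanar (affine rank < 3)")
  }
  c(i1, i2, i3, i4)
}

## Orient a triangular facet (i, j, k) so that its normal points away from
## the interior witness point `inside`.
orient_facet <- function(face, pts, inside) {
  v1 <- pts[face[1], ]; v2 <- pts[face[2], ]; v3 <- pts[face[3], ]
  n <- row_cross(matrix(v2 - v1, 1), matrix(v3 - v1, 1))[1, ]
  if (sum(n * (inside - v1)) > 0) face[c(1, 3, 2)] else face
}

#' Minimum convex hull of a 3D point set
#'
#' Computes the smallest convex polytope containing the input points, the
#' geometric primitive of convex-hull volumetric mass estimation. Input may
#' be a bare n x 3 matrix or a [point_set()]. Duplicate points are removed;
#' faces or normals of an ingested mesh are irrelevant because the hull
#' depends only on the vertex set.
#'
#' @param points n x 3 numeric matrix of coordinates (mm), or a `point_set`.
#' @return an object of class `convex_polytope` with fields `vertices`
#'   (m x 3 matrix, each row an input point), `faces` (f x 3 integer matrix
#'   of vertex indices, outward oriented), and `label`.
#' @examples
#' cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' h <- convex_hull(cube)
#' polytope_volume(h) # 1
#' @export
convex_hull <- function(points) {
  label <- NULL
  if (inherits(points, "point_set")) {
    label <- points$label
    points <- points$points
  }
  pts <- dedupe_points(as_points(points))
  if (nrow(pts) < 4L) {
    chm_error("degenerate_geometry", sprintf(
      "need at least 4 distinct points to form a 3D hull (got %d)", nrow(pts)))
  }
  tol <- tau_planar(pts)
  eps_vis <- 1e-2 * tol # strict-visibility threshold, well inside tau_planar

  simplex <- initial_simplex(pts, tol)
  inside <- colMeans(pts[simplex, , drop = FALSE])
  faces <- t(apply(rbind(simplex[c(1, 2, 3)], simplex[c(1, 2, 4)],
                         simplex[c(1, 3, 4)], simplex[c(2, 3, 4)]),
                   1, orient_facet, pts = pts, inside = inside))

  remaining <- setdiff(seq_len(nrow(pts)), simplex)
  ## far points first: fewer facet churn steps and better conditioning
  if (length(remaining) > 1L) {
    d0 <- rowSums(sweep(pts[remaining, , drop = FALSE], 2, inside)^2)
    remaining <- remaining[order(d0, decreasing = TRUE)]
  }

  for (p in remaining) {
    fn <- facet_normals(pts, faces)
    sdist <- drop(fn$normal %*% pts[p, ] - rowSums(fn$normal * fn$base)) /
      sqrt(rowSums(fn$normal^2))
    vis <- sdist > eps_vis
    if (!any(vis)) next # inside (or on) the current hull within tolerance
    visf <- faces[vis, , drop = FALSE]
    edges <- rbind(visf[, 1:2, drop = FALSE], visf[, 2:3, drop = FALSE],
                   visf[, c(3, 1), drop = FALSE])
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rev_keys %in% keys), , drop = FALSE]
    ## keeping the horizon edge's direction from the deleted facet makes the
    ## new facet (a, b, p) outward oriented
    faces <- rbind(faces[!vis, , drop = FALSE],
                   cbind(horizon, rep.int(p, nrow(horizon))))
  }

  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  poly <- structure(
    list(vertices = pts[used, , drop = FALSE],
         faces = matrix(remap[faces], ncol = 3L),
         label = label),
    class = "convex_polytope")
  validate_polytope(poly)
  poly
}

## Undirected edge table of a facet set, as a 2-column matrix.
polytope_edges <- function(faces) {
  e <- rbind(faces[, 1:2, drop = FALSE], faces[, 2:3, drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

is_closed_surface <- function(faces) {
  e <- rbind(faces[, 1:2, drop = FALSE], faces[, 2:3, drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  keys <- paste(e[, 1], e[, 2])
  rev_keys <- paste(e[, 2], e[, 1])
  !anyDuplicated(keys) && all(rev_keys %in% keys)
}

#' Validate the structural invariants of a convex polytope
#'
#' Checks that the facet set is a closed oriented surface (every directed
#' edge paired with its reverse), that the Euler relation V - E + F = 2
#' holds, that all facet normals point away from the centroid, and that
#' every vertex lies on or inside every facet plane within `tau_planar`.
#'
#' @param poly a `convex_polytope`.
#' @return the polytope, invisibly; signals an error on violation.
#' @export
validate_polytope <- function(poly) {
  faces <- poly$faces
  V <- poly$vertices
  if (!is_closed_surface(faces)) {
    chm_error("open_surface", "facet set is not a closed oriented surface")
  }
  nE <- nrow(polytope_edges(faces))
  if (nrow(V) - nE + nrow(faces) != 2L) {
    chm_error("open_surface", "facet set violates the Euler relation V - E + F = 2")
  }
  fn <- facet_normals(V, faces)
  ctr <- colMeans(V)
  outward <- rowSums(fn$normal * sweep(fn$base, 2, ctr)) > 0
  if (!all(outward)) {
    chm_error("open_surface", "some facet normals point towards the centroid")
  }
  if (max_signed_distance(poly, V) > tau_planar(V)) {
    chm_error("open_surface", "a vertex lies outside a facet plane beyond tolerance")
  }
  invisible(poly)
}

#' Largest signed distance from points to the facet planes of a polytope
#'
#' For each query point, its signed distance to every facet plane is computed
#' (positive = outside); the maximum over facets and points is returned.
#' Values at or below `tau_planar` mean the points are contained in the hull.
#'
#' @param poly a `convex_polytope`.
#' @param points n x 3 numeric matrix of query points.
#' @return single numeric, the maximum signed point-plane distance (mm).
#' @export
max_signed_distance <- function(poly, points) {
  points <- as_points(points)
  fn <- facet_normals(poly$vertices, poly$faces)
  len <- sqrt(rowSums(fn$normal^2))
  ## distance of point q to facet plane: n . (q - base) / |n|
  d <- (fn$normal %*% t(points) - rowSums(fn$normal * fn$base)) / len
  max(d)
}

#' Volume enclosed by a convex polytope
#'
#' Sums signed tetrahedron volumes spanned by each oriented facet and an
#' arbitrary origin (the vertex centroid, for conditioning). The result is
#' origin-independent on a closed surface and positive for outward-oriented
#' facets.
#'
#' @param poly a `convex_polytope`.
#' @return volume in cubic millimetres.
#' @export
polytope_volume <- function(poly) {
  if (!is_closed_surface(poly$faces)) {
    chm_error("open_surface", "cannot compute the volume of an open surface")
  }
  origin <- colMeans(poly$vertices)
  a <- sweep(poly$vertices[poly$faces[, 1], , drop = FALSE], 2, origin)
  b <- sweep(poly$vertices[poly$faces[, 2], , drop = FALSE], 2, origin)
  c_ <- sweep(poly$vertices[poly$faces[, 3], , drop = FALSE], 2, origin)
  sum(rowSums(row_cross(a, b) * c_)) / 6
}

#' Reflect a segment's points across a plane
#'
#' Used to restore bilateral symmetry of incomplete material, e.g. mirroring
#' one side of a ribcage to stand in for missing ribs on the other. The
#' reflection is an involution and preserves hull volume.
#'
#' @param points n x 3 matrix or `point_set`.
#' @param plane_point a point on the mirror plane (length-3 numeric).
#' @param plane_normal plane normal (length-3 numeric, any non-zero length).
#' @return object of the same class as the input, reflected.
#' @export
mirror_segment <- function(points, plane_point, plane_normal) {
  nn <- sqrt(sum(plane_normal^2))
  if (!is.numeric(plane_normal) || length(plane_normal) != 3L ||
      !is.finite(nn) || nn == 0) {
    chm_error("invalid_plane", "plane normal must be a non-zero 3-vector")
  }
  nhat <- plane_normal / nn
  reflect <- function(m) {
    rel <- sweep(m, 2, plane_point)
    m - 2 * (rel %*% nhat) %*% t(nhat)
  }
  if (inherits(points, "point_set")) {
    out <- points
    out$points <- as_points(reflect(points$points))
    return(out)
  }
  as_points(reflect(as_points(points)))
}

#' @export
print.convex_polytope <- function(x, ...) {
  cat(sprintf("convex_polytope%s: %d vertices, %d facets, volume %.6g mm^3\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              nrow(x$vertices), nrow(x$faces), polytope_volume(x)))
  invisible(x)
}
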