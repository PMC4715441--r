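# Independent oracles. Each recomputes a quantity by a route disjoint from
# the implementation it checks: Monte-Carlo containment for hull volumes,
# direct normal-equations solves for regression coefficients, and
# root-to-MRCA path enumeration for Brownian covariances.

# Monte-Carlo volume of a convex polytope: fraction of bounding-box samples
# with non-positive signed distance to every facet plane, times box volume.
mc_hull_volume <- function(poly, n_samples = 1e5, seed = 1) {
  lo <- apply(poly$vertices, 2, min)
  hi <- apply(poly$vertices, 2, max)
  withr::with_seed(seed, {
    q <- cbind(runif(n_samples, lo[1], hi[1]),
               runif(n_samples, lo[2], hi[2]),
               runif(n_samples, lo[3], hi[3]))
  })
  v1 <- poly$vertices[poly$faces[, 1], , drop = FALSE]
  v2 <- poly$vertices[poly$faces[, 2], , drop = FALSE]
  v3 <- poly$vertices[poly$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  d <- nrm %*% t(q) - rowSums(nrm * v1)  # facets x samples
  inside_frac <- mean(apply(d <= 0, 2, all))
  inside_frac * prod(hi - lo)
}

# OLS coefficients by an explicit normal-equations solve.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# GLS coefficients by an explicit weighted normal-equations solve.
gls_normal_equations <- function(x, y, C) {
  X <- cbind(1, x)
  Ci <- solve(C)
  unname(drop(solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)))
}

# Brownian covariance by brute force: entry (i, j) is the summed branch
# length shared by the root-to-tip paths of tips i and j.
brownian_cov_bruteforce <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  elen_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen_of[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    out <- integer()
    node <- tip
    while (node != root) {
      out <- c(out, node)  # identify each edge by its child node
      node <- parent_of[node]
    }
    out
  }
  paths <- lapply(seq_len(ntip), path_edges)
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      C[i, j] <- sum(elen_of[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}

# Gaussian log-likelihood of a simple linear regression at the ML variance.
loglik_ols <- function(x, y, a, b) {
  n <- length(y)
  sse <- sum((y - a - b * x)^2)
  s2 <- sse / n
  -0.5 * (n * log(2 * pi * s2) + n)
}

# Random points on/inside the unit ball.
random_ball_points <- function(n, seed) {
  withr::with_seed(seed, {
    p <- matrix(rnorm(3 * n), ncol = 3)
    p / sqrt(rowSums(p^2)) * runif(n)^(1 / 3)
  })
}

random_rotation_matrix <- function(seed) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  })
  Q %*% diag(c(1, 1, det(Q)))
}

pigeons <- function() load_pigeon_fixture()
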