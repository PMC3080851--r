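# Airspace volumes via the divergence theorem and the bulk modulus via a
# small pressure perturbation.

# Signed fan volume of every face with respect to the origin, in the stored
# cycle orientation: sum over fan triangles (center, v_i, v_{i+1}) of
# det[c, a, b] / 6.
.face_fan_volumes <- function(network) {
  pos <- network$nodes$pos
  tri <- network$tri
  Pc <- pos[tri$c, , drop = FALSE]
  Pa <- pos[tri$a, , drop = FALSE]
  Pb <- pos[tri$b, , drop = FALSE]
  det6 <- Pc[, 1] * (Pa[, 2] * Pb[, 3] - Pa[, 3] * Pb[, 2]) -
          Pc[, 2] * (Pa[, 1] * Pb[, 3] - Pa[, 3] * Pb[, 1]) +
          Pc[, 3] * (Pa[, 1] * Pb[, 2] - Pa[, 2] * Pb[, 1])
  as.numeric(rowsum(det6 / 6, tri$face, reorder = TRUE))
}

# Flat (cell, face, sign) arrays from the per-cell lists.
.cf_arrays <- function(network) {
  list(cell = rep.int(seq_along(network$cells$faces),
                      lengths(network$cells$faces)),
       face = unlist(network$cells$faces, use.names = FALSE),
       sign = unlist(network$cells$sign, use.names = FALSE))
}

#' Per-cell volumes by the divergence theorem
#'
#' Each cell's volume is the sum of signed tetrahedron volumes over its
#' outward fan-triangulated faces (apex at the origin), which is exact also
#' for non-convex deformed cells. With `exclude_removed = TRUE` the removed
#' faces are skipped, giving each cell's *partial* surface integral; summing
#' partial volumes over the cells of one airspace cluster gives the cluster
#' volume, because the two contributions of every interior intact face
#' cancel.
#'
#' @param network a `spring_network`.
#' @param exclude_removed skip removed faces (see Details).
#' @return Numeric vector of length `n_cells`.
#' @export
cell_volumes <- function(network, exclude_removed = FALSE) {
  fv <- .face_fan_volumes(network)
  cf <- .cf_arrays(network)
  w <- cf$sign * fv[cf$face]
  if (exclude_removed) w[network$faces$removed[cf$face]] <- 0
  as.numeric(rowsum(w, cf$cell, reorder = TRUE))
}

#' Total enclosed volume of the block
#'
#' Divergence-theorem volume enclosed by the exterior (boundary) faces, which
#' stay intact throughout a destruction run.
#'
#' @param network a `spring_network`.
#' @return Scalar volume.
#' @export
total_volume <- function(network) {
  fv <- .face_fan_volumes(network)
  sum(fv[network$faces$is_boundary])
}

#' Volume of a closed triangulated surface
#'
#' Divergence-theorem volume of a consistently outward-oriented closed
#' triangle surface: the sum of signed volumes of tetrahedra formed by each
#' triangle and the origin. Exact for non-convex polyhedra and invariant
#' under translation. The surface must be closed: the area vectors of an open
#' or inconsistently oriented surface do not sum to zero and an error is
#' raised.
#'
#' @param triangles either a list of 3x3 matrices (one row per vertex) or an
#'   `n x 9` numeric matrix with rows `(x1,y1,z1,x2,y2,z2,x3,y3,z3)`.
#' @param tol closure tolerance on `|sum of area vectors| / max area`.
#' @return Scalar volume (positive for outward orientation).
#' @examples
#' cube <- rbind(
#'   # -z
#'   c(0,0,0, 0,1,0, 1,1,0), c(0,0,0, 1,1,0, 1,0,0),
#'   # +z
#'   c(0,0,1, 1,0,1, 1,1,1), c(0,0,1, 1,1,1, 0,1,1),
#'   # -y
#'   c(0,0,0, 1,0,0, 1,0,1), c(0,0,0, 1,0,1, 0,0,1),
#'   # +y
#'   c(0,1,0, 0,1,1, 1,1,1), c(0,1,0, 1,1,1, 1,1,0),
#'   # -x
#'   c(0,0,0, 0,0,1, 0,1,1), c(0,0,0, 0,1,1, 0,1,0),
#'   # +x
#'   c(1,0,0, 1,1,0, 1,1,1), c(1,0,0, 1,1,1, 1,0,1))
#' polyhedron_volume(cube)  # 1
#' @export
polyhedron_volume <- function(triangles, tol = 1e-9) {
  if (is.list(triangles))
    triangles <- t(vapply(triangles, function(m) as.numeric(t(m)), numeric(9)))
  stopifnot(is.matrix(triangles), ncol(triangles) == 9)
  a <- triangles[, 1:3, drop = FALSE]
  b <- triangles[, 4:6, drop = FALSE]
  cc <- triangles[, 7:9, drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  S <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  area <- sqrt(rowSums(S^2))
  closure <- sqrt(sum(colSums(S)^2))
  if (closure > tol * max(area, 1e-300))
    stop("surface is open or inconsistently oriented (area vectors do not sum to zero)")
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(det6) / 6
}

# Minimal union-find over cell indices.
.union_find <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Airspace clusters of a damaged network
#'
#' Cells merged by removed internal walls form a single airspace; the
#' clusters partition the cells and their volumes are computed from the
#' remaining (intact) faces by the divergence theorem. For an intact network
#' every cell is its own singleton cluster.
#'
#' @param network a `spring_network`.
#' @return An object of class `airspace_clusters`: list with `membership`
#'   (cluster id per cell), `volumes` (per cluster), `sizes` (cells per
#'   cluster) and `n` (number of clusters).
#' @export
airspace_clusters <- function(network) {
  stopifnot(inherits(network, "spring_network"))
  rem <- which(network$faces$removed & !network$faces$is_boundary)
  if (any(network$faces$removed & network$faces$is_boundary))
    stop("internal error: boundary face flagged removed")
  pairs <- network$faces$cells[rem, , drop = FALSE]
  n_cells <- length(network$cells$faces)
  membership <- .union_find(n_cells, pairs)
  pv <- cell_volumes(network, exclude_removed = TRUE)
  volumes <- as.numeric(rowsum(pv, membership, reorder = TRUE))
  structure(list(membership = membership, volumes = volumes,
                 sizes = tabulate(membership), n = length(volumes)),
            class = "airspace_clusters")
}

#' @export
print.airspace_clusters <- function(x, ...) {
  cat(sprintf("%d airspace clusters (largest spans %d cells); total volume %.6g\n",
              x$n, max(x$sizes), sum(x$volumes)))
  invisible(x)
}

#' First four moments of the airspace-volume distribution
#'
#' Mean and central moments of orders 2-4 of the cluster volumes normalized
#' by the initial single-cell volume `v0`, so all four are dimensionless and
#' comparable across lattice types. With `standardized = TRUE` the third and
#' fourth moments are additionally divided by `m2^(k/2)` (skewness/kurtosis
#' form).
#'
#' @param clusters an [airspace_clusters()] object, or a numeric vector of
#'   volumes.
#' @param v0 normalizing volume (defaults to 1 for a plain vector).
#' @param standardized return standardized moments 3 and 4.
#' @return Named numeric vector `c(mu, m2, m3, m4)`.
#' @export
volume_moments <- function(clusters, v0 = 1, standardized = FALSE) {
  v <- if (inherits(clusters, "airspace_clusters")) clusters$volumes
       else as.numeric(clusters)
  if (length(v) < 1L) stop("at least one cluster is required")
  x <- v / v0
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  if (standardized && m2 > 0) {
    m3 <- m3 / m2^1.5
    m4 <- m4 / m2^2
  }
  c(mu = mu, m2 = m2, m3 = m3, m4 = m4)
}

#' Measure the bulk modulus by a small pressure perturbation
#'
#' Starting from an equilibrated fixed-boundary state, the boundary
#' constraint is replaced by dead loads: each boundary node receives a
#' constant external force opposite (and equal in magnitude) to the resultant
#' spring force acting on it, after which all nodes are free and the state is
#' still an equilibrium. A small distending pressure increment `delta_P` is
#' then superposed on the exterior surface as facet forces, the network is
#' re-equilibrated (with the follower-force outer loop), and
#' `K = delta_P / (dV / V0)` is computed from the enclosed volumes before and
#' after. The probe is side-effect-free: the input network is not modified.
#'
#' @param network an equilibrated `spring_network`.
#' @param delta_P pressure increment; default 1% of the intact recoil
#'   pressure scale `k * eps0 / cell_size`.
#' @param control an [equilibrium_control()].
#' @param params constitutive parameters (default: the network's own).
#' @param warm_start optional `n_nodes x 3` matrix of starting positions for
#'   the perturbed state (e.g. the `probe_pos` of the previous measurement in
#'   a destruction run); purely an accelerator, the converged measurement
#'   does not depend on it.
#' @return A `modulus_measurement` list: `K`, `delta_P`, `V0`, `V1`,
#'   `converged`, and the perturbed-state positions `probe_pos`.
#' @export
bulk_modulus <- function(network, delta_P = NULL,
                         control = equilibrium_control(),
                         params = network$params, warm_start = NULL) {
  stopifnot(inherits(network, "spring_network"))
  if (is.null(delta_P)) {
    eps0 <- network$meta$prestrain - 1
    delta_P <- 0.01 * params$k * max(eps0, 0.01) / network$meta$cell_size
  }
  stopifnot(is.numeric(delta_P), length(delta_P) == 1L, delta_P > 0)

  probe <- network
  n <- nrow(probe$nodes$pos)
  Fs <- net_spring_forces(probe, params)
  base <- matrix(0, n, 3)
  bd <- probe$nodes$is_boundary
  base[bd, ] <- -Fs[bd, , drop = FALSE]
  V0 <- total_volume(probe)

  if (!is.null(warm_start)) {
    stopifnot(is.matrix(warm_start), nrow(warm_start) == n, ncol(warm_start) == 3)
    bc0 <- boundary_pressure(delta_P, base_forces = base)
    mv <- .node_masks(probe, bc0)$movable
    probe$nodes$pos[mv, ] <- warm_start[mv, , drop = FALSE]
  }
  probe <- equilibrate(probe, boundary_pressure(delta_P, base_forces = base),
                       control = control, params = params)
  V1 <- total_volume(probe)
  dV <- V1 - V0
  K <- if (dV > 0) delta_P / (dV / V0) else NA_real_
  structure(list(K = K, delta_P = delta_P, V0 = V0, V1 = V1,
                 converged = isTRUE(probe$equilibrium$converged) && dV > 0,
                 probe_pos = probe$nodes$pos),
            class = "modulus_measurement")
}

#' @export
print.modulus_measurement <- function(x, ...) {
  cat(sprintf("Bulk modulus K = %.6g (delta_P = %.3g, dV/V0 = %.3g, %s)\n",
              x$K, x$delta_P, (x$V1 - x$V0) / x$V0,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Closed-form bulk modulus of the intact lattice
#'
#' Under a uniform expansion `x = c + lambda (X - c)` of the intact periodic
#' lattice every spring carries strain `lambda - 1`, so the energy per unit
#' as-built volume is `u(lambda) = rho_m * F(lambda - 1)` with `rho_m` the
#' interior spring density `sum(k * L0^m) / V_cell` (each spring weighted by
#' the number of cells sharing it) and `F` the antiderivative of the force
#' law. The pressure-probe protocol (boundary reactions frozen as dead
#' loads, then a small pressure increment) measures
#' `K = u''(lambda0) / (9 lambda0) = rho_m * f'(eps0) / (9 lambda0)`.
#'
#' For the linear cubic lattice with the extension-based energy this reduces
#' to `K = k / (lambda0 * cell_size)`. The value is the bulk (interior)
#' modulus: the measured finite-lattice K approaches it from below as the
#' softer boundary layer becomes negligible (within 1% by 6 cells per side).
#' The density is read off an interior cell, so the lattice must be at least
#' 3 cells per side.
#'
#' @param network an intact `spring_network`.
#' @param params constitutive parameters (default: the network's own).
#' @return Scalar analytic bulk modulus.
#' @export
analytic_bulk_modulus <- function(network, params = network$params) {
  stopifnot(inherits(network, "spring_network"))
  if (any(network$springs$broken))
    stop("closed form applies to the intact network only")
  lam <- network$meta$prestrain
  eps0 <- lam - 1
  if (eps0 <= 0) stop("network must be pre-strained")
  m <- .law_form_exp(params)
  fp <- params$A + if (params$B != 0)
    params$B * params$p * eps0^(params$p - 1) else 0

  # interior cell: centroid closest to the box center
  pos <- network$nodes$pos
  ctr <- colMeans(network$meta$box)
  cent <- t(vapply(network$cells$faces, function(fs) {
    colMeans(pos[network$faces$center[fs], , drop = FALSE])
  }, numeric(3)))
  ci <- which.min(rowSums(sweep(cent, 2, ctr)^2))
  fs <- network$cells$faces[[ci]]
  if (any(network$faces$is_boundary[fs]))
    stop("no interior cell: need at least 3 cells per side")

  s <- network$springs
  S <- 0
  for (f in fs) {
    ncell <- sum(!is.na(network$faces$cells[f, ]))
    S <- S + sum(s$k[network$faces$springs[[f]]] *
                   s$L0[network$faces$springs[[f]]]^m) / ncell
  }
  for (e in unique(unlist(network$faces$edges[fs], use.names = FALSE))) {
    adj <- unique(as.integer(network$faces$cells[network$edges$faces[[e]], ]))
    adj <- adj[!is.na(adj)]
    sp <- network$edges$spring[e]
    S <- S + s$k[sp] * s$L0[sp]^m / length(adj)
  }
  v_cell <- cell_volumes(network)[ci] / lam^3 # as-built cell volume
  (S / v_cell) * fp / (9 * lam)
}
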