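# Lattice construction: space-filling blocks of cubes or tetrakaidecahedra
# (truncated octahedra), with face-center-to-vertex springs on every wall and
# one shared edge spring per distinct geometric edge.

#' @export
print.spring_network <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Alveolar spring network (%s lattice, %s cells of size %g)\n",
              m$lattice, paste(m$dims, collapse = "x"), m$cell_size))
  cat(sprintf("  %d cells, %d faces (%d removed), %d springs (%d broken)\n",
              length(x$cells$faces), length(x$faces$center),
              sum(x$faces$removed), length(x$springs$from),
              sum(x$springs$broken)))
  cat(sprintf("  %d nodes (%d boundary), prestrain expansion %.4g\n",
              nrow(x$nodes$pos), sum(x$nodes$is_boundary), m$prestrain))
  invisible(x)
}

# Assemble a spring network from merged vertex positions and, per cell, a
# list of faces given as outward-oriented cycles of vertex ids. Shared faces
# (identical vertex sets) are identified across cells; each face gets a
# center node and center-to-vertex springs; each distinct geometric edge gets
# one edge spring. Faces adjacent to a single cell form the fixed exterior.
.assemble_network <- function(vpos, cell_faces, lattice, dims, cell_size,
                              params) {
  n_cells <- length(cell_faces)
  inst_cell <- rep.int(seq_len(n_cells), lengths(cell_faces))
  inst_cycles <- unlist(cell_faces, recursive = FALSE, use.names = FALSE)
  keys <- vapply(inst_cycles, function(v) paste(sort(v), collapse = "_"), "")
  fid <- match(keys, unique(keys))
  n_faces <- max(fid)
  first <- !duplicated(fid)
  face_vertices <- inst_cycles[first]

  face_cells <- matrix(NA_integer_, n_faces, 2)
  owner_slot <- integer(length(fid)) # 1 if this instance defined the cycle
  for (i in seq_along(fid)) {
    f <- fid[i]
    if (is.na(face_cells[f, 1])) {
      face_cells[f, 1] <- inst_cell[i]
      owner_slot[i] <- 1L
    } else if (is.na(face_cells[f, 2])) {
      face_cells[f, 2] <- inst_cell[i]
      owner_slot[i] <- 2L
    } else {
      stop("internal error: face shared by more than two cells")
    }
  }

  n_v <- nrow(vpos)
  center_pos <- t(vapply(face_vertices,
                         function(v) colMeans(vpos[v, , drop = FALSE]),
                         numeric(3)))
  pos <- rbind(vpos, center_pos)
  center_node <- n_v + seq_len(n_faces)

  # face springs: center to each vertex of its cycle
  fs_face <- rep.int(seq_len(n_faces), lengths(face_vertices))
  fs_from <- center_node[fs_face]
  fs_to <- unlist(face_vertices, use.names = FALSE)
  face_spring_ids <- split(seq_along(fs_face), fs_face)

  # distinct geometric edges from consecutive cycle pairs
  e_a <- fs_to
  e_b <- unlist(lapply(face_vertices, function(v) c(v[-1], v[1])),
                use.names = FALSE)
  lo <- pmin(e_a, e_b); hi <- pmax(e_a, e_b)
  ekey <- paste(lo, hi, sep = "_")
  eid <- match(ekey, unique(ekey))
  n_edges <- max(eid)
  efirst <- !duplicated(eid)
  edge_verts <- cbind(lo[efirst], hi[efirst])
  edge_faces <- split(fs_face, eid) # faces sharing each edge (with dups removed)
  edge_faces <- lapply(edge_faces, unique)
  face_edges <- split(eid, fs_face)

  n_fs <- length(fs_from)
  from <- c(fs_from, edge_verts[, 1])
  to <- c(fs_to, edge_verts[, 2])
  L0 <- sqrt(rowSums((pos[from, , drop = FALSE] - pos[to, , drop = FALSE])^2))
  kind <- rep(c("face", "edge"), c(n_fs, n_edges))
  edge_spring <- n_fs + seq_len(n_edges)

  is_boundary_face <- is.na(face_cells[, 2])
  node_boundary <- logical(nrow(pos))
  node_boundary[unlist(face_vertices[is_boundary_face], use.names = FALSE)] <- TRUE
  node_boundary[center_node[is_boundary_face]] <- TRUE

  # per-cell face lists with orientation sign (+1: stored cycle is outward)
  cf_cell <- inst_cell
  cf_face <- fid
  cf_sign <- ifelse(owner_slot == 1L, 1, -1)
  ord <- order(cf_cell)
  cf_cell <- cf_cell[ord]; cf_face <- cf_face[ord]; cf_sign <- cf_sign[ord]
  cells_faces <- split(cf_face, cf_cell)
  cells_sign <- split(cf_sign, cf_cell)

  # fan triangulation (center, v_i, v_{i+1}) in stored-cycle orientation
  tri_face <- fs_face
  tri_a <- e_a
  tri_b <- e_b

  box <- rbind(apply(vpos, 2, min), apply(vpos, 2, max))

  net <- structure(list(
    nodes = list(pos = pos,
                 role = rep(c("vertex", "face_center"), c(n_v, n_faces)),
                 is_boundary = node_boundary),
    springs = list(from = from, to = to, L0 = L0, kind = kind,
                   k = rep(1, length(from)), broken = logical(length(from))),
    faces = list(vertices = face_vertices, center = center_node,
                 springs = face_spring_ids, edges = face_edges,
                 cells = face_cells, removed = logical(n_faces),
                 is_boundary = is_boundary_face),
    cells = list(faces = cells_faces, sign = cells_sign,
                 lattice_index = NULL),
    edges = list(verts = edge_verts, spring = edge_spring,
                 faces = edge_faces, live_faces = lengths(edge_faces)),
    tri = list(face = tri_face, c = center_node[tri_face], a = tri_a, b = tri_b),
    meta = list(lattice = lattice, dims = dims, cell_size = cell_size,
                prestrain = 1, v0 = cell_size^3, box = box,
                needs_equilibration = FALSE),
    params = params
  ), class = "spring_network")

  vol <- cell_volumes(net)
  if (any(vol <= 0))
    stop("internal error: non-positive cell volume after assembly")
  net
}

#' Build a cubic-lattice alveolar network
#'
#' Tiles a cuboidal block with `n[1] x n[2] x n[3]` cubic cells (a scalar `n`
#' gives a cube of `n^3` cells). Each square face carries four springs from
#' its center to its vertices; each distinct lattice edge carries one shared
#' edge spring. All rest lengths equal the as-built lengths. Outer faces, and
#' all their vertices and face centers, are flagged as the fixed boundary.
#'
#' An `n`-per-side cube has `n^3` cells, `3 n^2 (n+1)` faces and
#' `12 n^2 (n+1) + 3 n (n+1)^2` springs; `n = 8` gives the standard
#' 512-cell, 1728-face, 8856-spring block.
#'
#' @param n cells per side: a positive integer, or a length-3 integer vector
#'   of per-axis cell counts.
#' @param cell_size edge length of one cell (model length units).
#' @param params default [constitutive()] parameters attached to the network.
#' @return A `spring_network` object.
#' @examples
#' net <- cubic_network(2)
#' net
#' @export
cubic_network <- function(n, cell_size = 1, params = constitutive()) {
  if (length(n) == 1L) n <- rep(n, 3L)
  n <- as.integer(n)
  if (length(n) != 3L || any(is.na(n)) || any(n < 1L))
    stop("'n' must be a positive integer or length-3 integer vector")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a positive scalar")
  nx <- n[1]; ny <- n[2]; nz <- n[3]

  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  vpos <- as.matrix(g) * cell_size
  dimnames(vpos) <- NULL
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)

  cell_faces <- vector("list", nx * ny * nz)
  idx <- matrix(0L, nx * ny * nz, 3)
  ci <- 0L
  for (k in 0:(nz - 1L)) for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    c000 <- vid(i, j, k);     c100 <- vid(i + 1L, j, k)
    c010 <- vid(i, j + 1L, k); c110 <- vid(i + 1L, j + 1L, k)
    c001 <- vid(i, j, k + 1L); c101 <- vid(i + 1L, j, k + 1L)
    c011 <- vid(i, j + 1L, k + 1L); c111 <- vid(i + 1L, j + 1L, k + 1L)
    ci <- ci + 1L
    idx[ci, ] <- c(i, j, k)
    cell_faces[[ci]] <- list(
      c(c000, c001, c011, c010), # -x
      c(c100, c110, c111, c101), # +x
      c(c000, c100, c101, c001), # -y
      c(c010, c011, c111, c110), # +y
      c(c000, c010, c110, c100), # -z
      c(c001, c101, c111, c011)  # +z
    )
  }
  net <- .assemble_network(vpos, cell_faces, "cubic", n, cell_size, params)
  net$cells$lattice_index <- idx
  net
}

# ---- truncated octahedron (14-hedron) lattice ------------------------------

# Template 14-hedron centered at the origin in integer units: 24 vertices,
# the permutations of (0, +/-1, +/-2); 6 square and 8 regular hexagonal
# faces; spans [-2, 2]^3. Faces are returned as outward-oriented coordinate
# cycles (rows of a matrix).
.tkd_template <- function() {
  verts <- unique(do.call(rbind, lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                                             c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
    function(pm) {
      g <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1))
      do.call(rbind, lapply(seq_len(nrow(g)), function(r) {
        v <- c(0, g$s1[r] * 1, g$s2[r] * 2)
        v[order(pm)]
      }))
    })))
  faces <- list()
  for (ax in 1:3) for (s in c(-1, 1)) {
    sel <- verts[verts[, ax] == 2 * s, , drop = FALSE]
    faces[[length(faces) + 1L]] <- .orient_cycle(sel, s * replace(numeric(3), ax, 1))
  }
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    nrm <- c(s1, s2, s3)
    sel <- verts[as.numeric(verts %*% nrm) == 3, , drop = FALSE]
    faces[[length(faces) + 1L]] <- .orient_cycle(sel, nrm / sqrt(3))
  }
  faces
}

# Order coplanar points into a convex cycle with outward normal `nrm`.
.orient_cycle <- function(pts, nrm) {
  ctr <- colMeans(pts)
  u <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  rel <- sweep(pts, 2, ctr)
  ang <- atan2(as.numeric(rel %*% v), as.numeric(rel %*% u))
  pts[order(ang), , drop = FALSE]
}

.poly_normal <- function(P) { # Newell normal (area-weighted)
  Q <- rbind(P[-1, , drop = FALSE], P[1, , drop = FALSE])
  c(sum((P[, 2] - Q[, 2]) * (P[, 3] + Q[, 3])),
    sum((P[, 3] - Q[, 3]) * (P[, 1] + Q[, 1])),
    sum((P[, 1] - Q[, 1]) * (P[, 2] + Q[, 2]))) / 2
}

# Clip a convex cell (list of outward coordinate cycles) to the half-space
# nrm . x >= d, adding the planar cap face (outward normal -nrm).
.clip_cell <- function(polys, nrm, d, tol = 1e-9) {
  out <- list()
  for (P in polys) {
    dist <- as.numeric(P %*% nrm) - d
    if (all(dist >= -tol)) { out[[length(out) + 1L]] <- P; next }
    if (all(dist <= tol)) next
    m <- nrow(P)
    Q <- matrix(numeric(0), 0, 3)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      if (dist[i] >= -tol) Q <- rbind(Q, P[i, ])
      if ((dist[i] > tol && dist[j] < -tol) ||
          (dist[i] < -tol && dist[j] > tol)) {
        t <- dist[i] / (dist[i] - dist[j])
        Q <- rbind(Q, P[i, ] + t * (P[j, ] - P[i, ]))
      }
    }
    if (nrow(Q) >= 3) {
      dup <- c(rowSums((Q - rbind(Q[-1, , drop = FALSE],
                                  Q[1, , drop = FALSE]))^2) < tol^2)
      Q <- Q[!dup, , drop = FALSE]
      if (nrow(Q) >= 3 && sqrt(sum(.poly_normal(Q)^2)) > tol)
        out[[length(out) + 1L]] <- Q
    }
  }
  # cap: all retained points on the plane, ordered into a convex cycle
  cap <- do.call(rbind, lapply(out, function(P) {
    P[abs(as.numeric(P %*% nrm) - d) <= tol, , drop = FALSE]
  }))
  if (!is.null(cap) && nrow(cap) >= 3) {
    cap <- cap[!duplicated(round(cap, 6L)), , drop = FALSE]
    if (nrow(cap) >= 3) {
      capc <- .orient_cycle(cap, -nrm)
      if (sqrt(sum(.poly_normal(capc)^2)) > tol)
        out[[length(out) + 1L]] <- capc
    }
  }
  out
}

#' Build a tetrakaidecahedral (14-hedron) alveolar network
#'
#' Tiles a cuboidal block with truncated octahedra arranged on a body-centered
#' lattice: `n^3` whole cells plus `(n+1)^3` corner-sublattice cells that are
#' geometrically clipped by the box planes, so the block is exactly
#' space-filling with a flat exterior. Interior cells are regular 14-hedra
#' with 6 square and 8 regular hexagonal faces. Every face carries springs
#' from its center to each vertex; every distinct edge carries one shared
#' edge spring. All nodes on the box surface belong to single-cell faces and
#' are flagged as the fixed boundary.
#'
#' `cell_size` is the cube root of one whole cell's volume, so volumes
#' normalized by `cell_size^3` are comparable with the cubic lattice.
#'
#' @inheritParams cubic_network
#' @return A `spring_network` object.
#' @export
tkd_network <- function(n, cell_size = 1, params = constitutive()) {
  n <- as.integer(n[1])
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a positive scalar")
  tmpl <- .tkd_template()
  L <- 4 * n # box edge in template units; whole-cell volume is 32

  cells <- list()
  add_cell <- function(ctr, clip_planes) {
    polys <- lapply(tmpl, function(P) sweep(P, 2, ctr, `+`))
    for (cp in clip_planes) polys <- .clip_cell(polys, cp$nrm, cp$d)
    cells[[length(cells) + 1L]] <<- polys
  }
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) for (k in 0:(n - 1))
    add_cell(c(4 * i + 2, 4 * j + 2, 4 * k + 2), list())
  for (i in 0:n) for (j in 0:n) for (k in 0:n) {
    ctr <- c(4 * i, 4 * j, 4 * k)
    planes <- list()
    for (ax in 1:3) {
      if (ctr[ax] == 0)
        planes[[length(planes) + 1L]] <-
          list(nrm = replace(numeric(3), ax, 1), d = 0)
      if (ctr[ax] == L)
        planes[[length(planes) + 1L]] <-
          list(nrm = replace(numeric(3), ax, -1), d = -L)
    }
    add_cell(ctr, planes)
  }

  # merge vertices across cells by rounded-coordinate key
  allpts <- do.call(rbind, lapply(cells, function(ps) do.call(rbind, ps)))
  key <- apply(round(allpts * 1e6), 1, paste, collapse = "_")
  uid <- match(key, unique(key))
  vpos <- allpts[!duplicated(uid), , drop = FALSE]
  scale <- cell_size / 32^(1 / 3)
  off <- 0L
  cell_faces <- lapply(cells, function(ps) {
    lapply(ps, function(P) {
      ids <- uid[off + seq_len(nrow(P))]
      off <<- off + nrow(P)
      ids
    })
  })
  .assemble_network(vpos * scale, cell_faces, "tkd", rep(n, 3), cell_size,
                    params)
}

#' Apply a uniform pre-strain expansion
#'
#' Scales every node position about the box center by `factor`, leaving rest
#' lengths unchanged, so every spring of an intact network is stretched to
#' engineering strain `factor - 1`. Boundary nodes stay flagged immovable
#' (fixed-boundary pre-strain); the network is marked as requiring
#' re-equilibration. Tension-only springs make an unstrained network
#' unstable, hence `factor > 1` is required.
#'
#' @param network a `spring_network`.
#' @param factor expansion factor (> 1); the default 1.2 corresponds to 20%
#'   linear strain. A "1.5 times higher" pre-strain variant is strain 0.3,
#'   i.e. `factor = 1.3`.
#' @return The expanded `spring_network`.
#' @export
apply_prestrain <- function(network, factor = 1.2) {
  stopifnot(inherits(network, "spring_network"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1)
    stop("'factor' must be > 1: compression-free springs make a slack network unstable")
  ctr <- colMeans(network$meta$box)
  network$nodes$pos <- sweep(sweep(network$nodes$pos, 2, ctr), 2, ctr,
                             function(x, c) x * factor + c)
  network$meta$box <- sweep(sweep(network$meta$box, 2, ctr), 2, ctr,
                            function(x, c) x * factor + c)
  network$meta$prestrain <- network$meta$prestrain * factor
  network$meta$needs_equilibration <- TRUE
  network
}
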