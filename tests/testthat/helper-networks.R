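# Small shared builders. Heavier ensemble fixtures are cached lazily in
# .fixture_env by the functions below so several test files can share one
# computation.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

tiny_net <- function(prestrain = 1.2, n = 2, lattice = "cubic", ...) {
  net <- if (lattice == "cubic") cubic_network(n, ...) else tkd_network(n, ...)
  if (!is.null(prestrain)) net <- apply_prestrain(net, prestrain)
  net
}

# a damaged, equilibrated 2^3 block used by several mechanics tests
damaged_tiny <- function(seed = 7, n_remove = 3) {
  cached(sprintf("damaged_tiny_%d_%d", seed, n_remove), {
    net <- equilibrate(tiny_net())
    set.seed(seed)
    internal <- which(!net$faces$removed & !net$faces$is_boundary)
    net <- remove_faces(net, sample(internal, n_remove))
    equilibrate(net)
  })
}

# voxel-counting volume oracle for axis-aligned unions of boxes
voxel_volume <- function(inside, lower, upper, h = 0.02) {
  gx <- seq(lower[1] + h / 2, upper[1] - h / 2, by = h)
  gy <- seq(lower[2] + h / 2, upper[2] - h / 2, by = h)
  gz <- seq(lower[3] + h / 2, upper[3] - h / 2, by = h)
  g <- expand.grid(x = gx, y = gy, z = gz)
  sum(inside(g$x, g$y, g$z)) * h^3
}

# triangulate an axis-aligned box into 12 outward triangles (n x 9 matrix)
box_triangles <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- function(i, j, k) c(ifelse(i, hi[1], lo[1]),
                           ifelse(j, hi[2], lo[2]),
                           ifelse(k, hi[3], lo[3]))
  quad <- function(a, b, cc, d) rbind(c(a, b, cc), c(a, cc, d))
  rbind(
    quad(v(0,0,0), v(0,1,0), v(1,1,0), v(1,0,0)),   # -z
    quad(v(0,0,1), v(1,0,1), v(1,1,1), v(0,1,1)),   # +z
    quad(v(0,0,0), v(1,0,0), v(1,0,1), v(0,0,1)),   # -y
    quad(v(0,1,0), v(0,1,1), v(1,1,1), v(1,1,0)),   # +y
    quad(v(0,0,0), v(0,0,1), v(0,1,1), v(0,1,0)),   # -x
    quad(v(1,0,0), v(1,1,0), v(1,1,1), v(1,0,1)))   # +x
}
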