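test_that("cubic lattice counts match the closed forms for n = 1..4 and 8", {
  for (n in c(1:4, 8)) {
    net <- cubic_network(n)
    expect_identical(length(net$cells$faces), as.integer(n^3))
    expect_identical(length(net$faces$center), as.integer(3 * n^2 * (n + 1)))
    n_edges <- as.integer(3 * n * (n + 1)^2)
    expect_identical(length(net$springs$from),
                     as.integer(4 * 3 * n^2 * (n + 1)) + n_edges)
    expect_identical(sum(net$springs$kind == "edge"), n_edges)
  }
})

test_that("the standard 512-cell block has 1728 faces and 8856 springs", {
  net <- cubic_network(8)
  expect_identical(length(net$cells$faces), 512L)
  expect_identical(length(net$faces$center), 1728L)
  expect_identical(length(net$springs$from), 8856L)
})

test_that("face-cell adjacency: internal faces 2 cells, boundary faces 1", {
  for (net in list(cubic_network(2), tkd_network(1))) {
    n_adj <- rowSums(!is.na(net$faces$cells))
    expect_true(all(n_adj[net$faces$is_boundary] == 1L))
    expect_true(all(n_adj[!net$faces$is_boundary] == 2L))
    # boundary nodes lie on the bounding box surface
    pos <- net$nodes$pos[net$nodes$is_boundary, , drop = FALSE]
    box <- net$meta$box
    on_surface <- rep(FALSE, nrow(pos))
    for (d in 1:3)
      on_surface <- on_surface | abs(pos[, d] - box[1, d]) < 1e-9 |
        abs(pos[, d] - box[2, d]) < 1e-9
    expect_true(all(on_surface))
  }
})

test_that("every geometric edge carries exactly one shared edge spring", {
  net <- cubic_network(2)
  # each edge id maps to one spring; edge endpoints distinct
  expect_identical(length(unique(net$edges$spring)), nrow(net$edges$verts))
  expect_true(all(net$edges$verts[, 1] != net$edges$verts[, 2]))
  # every edge borders at least two faces in a 3D tiling
  expect_true(all(lengths(net$edges$faces) >= 2L))
})

test_that("both lattices are space-filling: cell volumes sum to the box volume", {
  for (net in list(cubic_network(2), cubic_network(3), tkd_network(1),
                   tkd_network(2))) {
    vb <- prod(net$meta$box[2, ] - net$meta$box[1, ])
    expect_equal(sum(cell_volumes(net)), vb, tolerance = 1e-9)
    expect_equal(total_volume(net), vb, tolerance = 1e-9)
    expect_true(all(cell_volumes(net) > 0))
  }
})

test_that("interior 14-hedron has 6 squares, 8 hexagons, 24 vertices, 36 edges", {
  net <- tkd_network(2) # 8 whole cells + 27 corner cells; whole cells interior-capable
  interior <- which(vapply(net$cells$faces, function(fs)
    !any(net$faces$is_boundary[fs]), TRUE))
  expect_true(length(interior) >= 1L)
  for (ci in interior) {
    fs <- net$cells$faces[[ci]]
    nv <- lengths(net$faces$vertices[fs])
    expect_identical(length(fs), 14L)
    expect_identical(sum(nv == 4L), 6L)
    expect_identical(sum(nv == 6L), 8L)
    verts <- unique(unlist(net$faces$vertices[fs]))
    edges <- unique(unlist(net$faces$edges[fs]))
    expect_identical(length(verts), 24L)
    expect_identical(length(edges), 36L)
    # Euler: V - E + F = 2
    expect_identical(length(verts) - length(edges) + length(fs), 2L)
  }
})

test_that("every face carries one spring per vertex; interior walls are squares or hexagons", {
  net <- tkd_network(2)
  nv <- lengths(net$faces$vertices)
  ns <- unname(lengths(net$faces$springs))
  expect_identical(ns, nv)
  # faces of fully interior cells are the regular 6 squares + 8 hexagons;
  # cells clipped by the box also expose triangles (cut squares) etc.
  interior <- which(vapply(net$cells$faces, function(fs)
    !any(net$faces$is_boundary[fs]), TRUE))
  fs <- unique(unlist(net$cells$faces[interior]))
  expect_setequal(unique(nv[fs]), c(4L, 6L))
})

test_that("building twice yields identical topology and geometry", {
  a <- cubic_network(3)
  b <- cubic_network(3)
  expect_identical(a$springs, b$springs)
  expect_identical(a$faces$vertices, b$faces$vertices)
  expect_identical(a$nodes$pos, b$nodes$pos)
  ta <- tkd_network(2)
  tb <- tkd_network(2)
  expect_identical(ta$springs, tb$springs)
  expect_identical(ta$nodes$pos, tb$nodes$pos)
})

test_that("pre-strain scales positions, leaves rest lengths, flags state", {
  net <- cubic_network(2)
  ps <- apply_prestrain(net, 1.2)
  s <- ps$springs
  len <- sqrt(rowSums((ps$nodes$pos[s$from, ] - ps$nodes$pos[s$to, ])^2))
  expect_equal(len / s$L0 - 1, rep(0.2, length(len)), tolerance = 1e-12)
  expect_identical(s$L0, net$springs$L0)
  expect_true(ps$meta$needs_equilibration)
  expect_equal(ps$meta$prestrain, 1.2)
  # strain composes multiplicatively: 1.2 then 1.25 gives factor 1.5
  ps2 <- apply_prestrain(ps, 1.25)
  expect_equal(ps2$meta$prestrain, 1.5)
})

test_that("invalid arguments are rejected", {
  expect_error(cubic_network(0), "positive")
  expect_error(cubic_network(2, cell_size = -1), "positive")
  expect_error(tkd_network(0), "positive")
  expect_error(apply_prestrain(cubic_network(1), 1.0), "slack")
  expect_error(apply_prestrain(cubic_network(1), 0.8), "slack")
})

test_that("a non-cubic block (4 x 4 x 8 = 128 cells) is supported", {
  net <- cubic_network(c(4, 4, 8))
  expect_identical(length(net$cells$faces), 128L)
  nf <- (4 + 1) * 4 * 8 + 4 * (4 + 1) * 8 + 4 * 4 * (8 + 1)
  expect_identical(length(net$faces$center), as.integer(nf))
  expect_equal(total_volume(net), 128)
})
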