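test_that("divergence-theorem volume of the unit cube is exact", {
  tri <- box_triangles()
  expect_identical(polyhedron_volume(tri), 1)
  # translation invariance of the closed-surface signed sum
  shifted <- tri + rep(c(17, -3, 5), 3)[col(tri)]
  expect_equal(polyhedron_volume(shifted), 1, tolerance = 1e-12)
})

test_that("volumes agree with a voxel oracle on convex and non-convex shapes", {
  # convex box
  b <- box_triangles(c(0, 0, 0), c(2, 1, 1))
  expect_equal(polyhedron_volume(b), 2, tolerance = 1e-12)
  vox <- voxel_volume(function(x, y, z) x <= 2 & y <= 1 & z <= 1,
                      c(0, 0, 0), c(2, 1, 1))
  expect_equal(polyhedron_volume(b), vox, tolerance = 1e-3)

  # non-convex L-shaped prism: two unit cubes glued along a face, with the
  # shared internal wall removed (triangles cancel pairwise when included,
  # so build the outer surface explicitly)
  c1 <- box_triangles(c(0, 0, 0), c(1, 1, 1))
  c2 <- box_triangles(c(1, 0, 0), c(2, 1, 1))
  L <- rbind(c1, c2) # internal +x/-x wall triangles cancel in the signed sum
  expect_equal(polyhedron_volume(L), 2, tolerance = 1e-12)
  voxL <- voxel_volume(function(x, y, z) (x <= 2), c(0, 0, 0), c(2, 1, 1))
  expect_equal(polyhedron_volume(L), voxL, tolerance = 1e-3)
})

test_that("an open or inconsistently oriented surface is rejected", {
  tri <- box_triangles()
  expect_error(polyhedron_volume(tri[-1, ]), "open|oriented")
  bad <- tri
  bad[1, ] <- bad[1, c(4:6, 1:3, 7:9)] # flip one triangle
  expect_error(polyhedron_volume(bad), "open|oriented")
})

test_that("intact network forms singleton clusters of equal volume", {
  net <- equilibrate(apply_prestrain(cubic_network(3), 1.2))
  cl <- airspace_clusters(net)
  expect_identical(cl$n, 27L)
  expect_identical(cl$sizes, rep(1L, 27L))
  expect_equal(max(cl$volumes) - min(cl$volumes), 0, tolerance = 1e-9)
  expect_equal(sum(cl$volumes), total_volume(net), tolerance = 1e-9)
})

test_that("removing one internal face merges exactly two cells, volumes add", {
  net <- equilibrate(apply_prestrain(cubic_network(2), 1.2))
  cl0 <- airspace_clusters(net)
  f <- which(!net$faces$is_boundary)[1]
  pair <- net$faces$cells[f, ]
  dmg <- equilibrate(remove_faces(net, f))
  cl <- airspace_clusters(dmg)
  expect_identical(cl$n, 7L)
  merged <- cl$membership[pair[1]]
  expect_identical(cl$membership[pair[2]], merged)
  # conservation: cluster volumes still partition the box
  expect_equal(sum(cl$volumes), total_volume(net), tolerance = 1e-9)
  expect_equal(sum(cl$volumes), sum(cl0$volumes), tolerance = 1e-9)
  # cluster count + cumulative merges = initial cell count
  expect_identical(cl$n + 1L, 8L)
})

test_that("volume moments match direct formulas", {
  expect_equal(volume_moments(c(1, 2, 3)),
               c(mu = 2, m2 = 2 / 3, m3 = 0, m4 = 2 / 3))
  expect_equal(volume_moments(rep(2.5, 10)),
               c(mu = 2.5, m2 = 0, m3 = 0, m4 = 0))
  # normalization by v0
  expect_equal(volume_moments(c(2, 4, 6), v0 = 2),
               c(mu = 2, m2 = 2 / 3, m3 = 0, m4 = 2 / 3))
  # standardized variant: skewness/kurtosis form
  x <- c(1, 1, 2, 5)
  mo <- volume_moments(x, standardized = TRUE)
  d <- x - mean(x)
  expect_equal(mo[["m3"]], mean(d^3) / mean(d^2)^1.5)
  expect_equal(mo[["m4"]], mean(d^4) / mean(d^2)^2)
  expect_error(volume_moments(numeric(0)), "at least one")
})

test_that("merging clusters with conserved total volume raises the mean", {
  net <- equilibrate(apply_prestrain(cubic_network(2), 1.2))
  mu0 <- volume_moments(airspace_clusters(net))[["mu"]]
  dmg <- equilibrate(remove_faces(net, which(!net$faces$is_boundary)[1]))
  mu1 <- volume_moments(airspace_clusters(dmg))[["mu"]]
  expect_gt(mu1, mu0)
})

test_that("measured bulk modulus of the intact lattice matches the closed form", {
  net <- cached("eq6", equilibrate(apply_prestrain(cubic_network(6), 1.2)))
  km <- cached("km6", bulk_modulus(net))
  expect_true(km$converged)
  ka <- analytic_bulk_modulus(net)
  expect_equal(ka, 1 / 1.2, tolerance = 1e-12) # k/(lambda * a) for this lattice
  expect_lt(abs(km$K - ka) / ka, 0.01)
})

test_that("the pressure probe is in the linear-response regime and repeatable", {
  net <- cached("eq6", equilibrate(apply_prestrain(cubic_network(6), 1.2)))
  km <- cached("km6", bulk_modulus(net))
  km_half <- bulk_modulus(net, delta_P = km$delta_P / 2)
  expect_lt(abs(km_half$K - km$K) / km$K, 0.005)
  km_rep <- bulk_modulus(net)
  expect_lt(abs(km_rep$K - km$K) / km$K, 0.001)
})

test_that("the probe is side-effect-free and damage lowers K", {
  net <- damaged_tiny()
  pos0 <- net$nodes$pos
  km <- bulk_modulus(net)
  expect_identical(net$nodes$pos, pos0)
  intact <- equilibrate(tiny_net())
  k_intact <- bulk_modulus(intact)
  expect_lt(km$K, k_intact$K)
})
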