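test_that("all internal walls of the uniform pre-strained lattice carry equal load", {
  net <- equilibrate(apply_prestrain(cubic_network(3), 1.2))
  loads <- face_load(net)
  expect_equal(max(loads) - min(loads), 0, tolerance = 1e-8)
  # 4 springs, tension k*(L - L0) = L0 * 0.2 each at 20% strain
  expect_equal(unname(loads[1]), 4 * (1 / sqrt(2)) * 0.2, tolerance = 1e-6)
})

test_that("stress concentrates on the walls of the cavity opened by a removal", {
  net <- equilibrate(apply_prestrain(cubic_network(4), 1.2))
  internal <- which(!net$faces$removed & !net$faces$is_boundary)
  # remove an internal face near the centre
  ctr <- colMeans(net$meta$box)
  fpos <- net$nodes$pos[net$faces$center[internal], ]
  f <- internal[which.min(rowSums(sweep(fpos, 2, ctr)^2))]
  dmg <- equilibrate(remove_faces(net, f))
  loads <- face_load(dmg)
  ids <- as.integer(names(loads))
  baseline <- 4 * (1 / sqrt(2)) * 0.2 # uniform-lattice wall load
  # the most loaded walls enclose the newly merged two-cell airspace: the
  # remaining walls of its two member cells inflate and take up the load
  cavity_walls <- setdiff(unique(as.integer(unlist(
    dmg$cells$faces[dmg$faces$cells[f, ]]))), f)
  top4 <- ids[order(-loads)][1:4]
  expect_true(all(top4 %in% cavity_walls))
  expect_gt(min(loads[as.character(intersect(cavity_walls, ids))]), baseline)
  # walls sharing an edge with the removed face are also elevated
  nbr <- setdiff(intersect(unique(unlist(
    dmg$edges$faces[unlist(dmg$faces$edges[f])])), ids), f)
  expect_gt(min(loads[as.character(nbr)]), baseline)
})

test_that("a wall with only slack springs carries zero load", {
  net <- equilibrate(tiny_net())
  # compress the whole block below rest length: everything slack
  slack <- net
  ctr <- colMeans(slack$meta$box)
  slack$nodes$pos <- sweep(sweep(slack$nodes$pos, 2, ctr), 2, ctr,
                           function(x, c) x * 0.5 + c)
  expect_true(all(face_load(slack) == 0))
})

test_that("mixed policy degenerates to random at r = 0 and to force at r = 1", {
  net <- equilibrate(tiny_net())
  for (step in c(0L, 1L)) {
    set.seed(31)
    a <- select_faces(net, destruction_policy("random", 2, seed = 1), step)
    set.seed(31)
    b <- select_faces(net, destruction_policy("mixed", 2, force_fraction = 0,
                                              seed = 1), step)
    expect_identical(a, b)
    set.seed(31)
    fo <- select_faces(net, destruction_policy("force", 2, seed = 1), step)
    set.seed(31)
    mx <- select_faces(net, destruction_policy("mixed", 2, force_fraction = 1,
                                               seed = 1), step)
    expect_identical(fo, mx)
  }
})

test_that("the first step of a force-based run is spatially random", {
  net <- equilibrate(tiny_net())
  set.seed(11)
  a <- select_faces(net, destruction_policy("force", 2), step_index = 0L)
  set.seed(11)
  b <- select_faces(net, destruction_policy("random", 2), step_index = 0L)
  expect_identical(a, b)
})

test_that("force policy selects among the elevated-load crack neighbours", {
  net <- equilibrate(apply_prestrain(cubic_network(4), 1.2))
  internal <- which(!net$faces$is_boundary)
  ctr <- colMeans(net$meta$box)
  fpos <- net$nodes$pos[net$faces$center[internal], ]
  f <- internal[which.min(rowSums(sweep(fpos, 2, ctr)^2))]
  dmg <- equilibrate(remove_faces(net, f))
  set.seed(2)
  sel <- select_faces(dmg, destruction_policy("force", 4), step_index = 1L)
  loads <- face_load(dmg)
  expect_true(all(loads[as.character(sel)] >= sort(loads, decreasing = TRUE)[4] - 1e-12))
})

test_that("face removal breaks its springs and prunes orphaned edge springs", {
  net <- equilibrate(tiny_net())
  f <- which(!net$faces$is_boundary)[1]
  dmg <- remove_faces(net, f)
  expect_true(dmg$faces$removed[f])
  expect_true(all(dmg$springs$broken[dmg$faces$springs[[f]]]))
  # 4 face springs broken, no edge springs (each edge borders intact faces)
  expect_identical(sum(dmg$springs$broken), 4L)
  # removing every face around one interior edge breaks its edge spring
  # (2^3 block: interior edges touch 4 internal faces)
  ie <- which(vapply(seq_len(nrow(net$edges$verts)), function(e) {
    fs <- net$edges$faces[[e]]
    all(!net$faces$is_boundary[fs]) && length(fs) == 4L
  }, TRUE))[1]
  around <- net$edges$faces[[ie]]
  dmg2 <- remove_faces(net, around)
  expect_true(dmg2$springs$broken[net$edges$spring[ie]])
  # and the edge spring count is exactly face springs + that one edge spring
  expect_identical(sum(dmg2$springs$broken), 4L * length(around) + 1L)
})

test_that("boundary walls and double removals are rejected; empty removal is identity", {
  net <- equilibrate(tiny_net())
  bf <- which(net$faces$is_boundary)[1]
  expect_error(remove_faces(net, bf), "boundary")
  f <- which(!net$faces$is_boundary)[1]
  dmg <- remove_faces(net, f)
  expect_error(remove_faces(dmg, f), "already removed")
  expect_identical(remove_faces(net, integer(0)), net)
})

test_that("an exhausted network raises the dedicated condition", {
  net <- equilibrate(tiny_net())
  internal <- which(!net$faces$is_boundary)
  dmg <- remove_faces(net, internal[-1])
  expect_error(select_faces(dmg, destruction_policy("random", 4)),
               class = "alveonet_exhausted")
})

test_that("destruction runs are reproducible and conserve total volume", {
  net <- equilibrate(tiny_net())
  pol <- destruction_policy("force", faces_per_step = 2L, seed = 123,
                            n_steps = 5L)
  a <- run_destruction(net, pol)
  b <- run_destruction(net, pol)
  expect_identical(a$steps, b$steps)
  expect_true(all(a$steps$eq_converged))
  v <- a$steps$total_volume
  expect_lt(max(abs(v / v[1] - 1)), 1e-6)
  # removed-face bookkeeping: no face removed twice
  expect_identical(as.integer(max(a$steps$faces_removed)),
                   sum(a$network$faces$removed))
  # global RNG untouched
  set.seed(77); x <- runif(1)
  set.seed(77); invisible(run_destruction(net, pol)); y <- runif(1)
  expect_identical(x, y)
})
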