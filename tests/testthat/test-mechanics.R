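test_that("spring force is tension-only and follows the law", {
  lin <- constitutive("linear", k = 2)
  expect_identical(spring_force(0, lin), 0)
  expect_identical(spring_force(-0.3, lin), 0)
  expect_equal(spring_force(0.2, lin), 0.4)
  pow <- constitutive("power", A = 1, B = 2, p = 3)
  expect_equal(spring_force(0.5, pow), 0.5 + 2 * 0.125)
  expect_identical(spring_force(-1, pow), 0)
  # strictly increasing in tension
  eps <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(spring_force(eps, pow)) > 0))
})

test_that("spring energy is the integral of the force (finite differences)", {
  h <- 1e-6
  for (params in list(constitutive("linear", k = 1.5),
                      constitutive("power", A = 1, p = 3),
                      constitutive("linear", form = "strain"),
                      constitutive("power", A = 2, p = 2.5, form = "strain"))) {
    L0 <- 0.7
    for (L in c(0.8, 0.9, 1.1)) {
      dEdL <- (spring_energy(L + h, L0, params) -
                 spring_energy(L - h, L0, params)) / (2 * h)
      eps <- (L - L0) / L0
      m <- if (params$form == "extension") 2 else 1
      tension <- L0^(m - 1) * spring_force(eps, params)
      expect_equal(dEdL, tension, tolerance = 1e-6)
    }
    expect_identical(spring_energy(L0, L0, params), 0)
    expect_identical(spring_energy(0.5 * L0, L0, params), 0)
  }
  expect_error(spring_energy(-1, 1), "positive")
  expect_error(spring_energy(1, 0), "positive")
})

test_that("total energy of the uniformly pre-strained lattice is the closed form", {
  net <- apply_prestrain(cubic_network(3), 1.2)
  s <- net$springs
  expect_equal(total_energy(net),
               sum(0.5 * s$k * s$L0^2 * 0.2^2), tolerance = 1e-12)
  # unstrained intact network has zero energy
  expect_identical(total_energy(cubic_network(2)), 0)
  # breaking springs at frozen positions cannot increase spring energy
  dmg <- net
  dmg$springs$broken[1:20] <- TRUE
  expect_lt(total_energy(dmg), total_energy(net))
})

test_that("interior nodes of the intact pre-strained cubic lattice do not move", {
  net <- apply_prestrain(cubic_network(3), 1.2)
  eq <- equilibrate(net)
  expect_true(eq$equilibrium$converged)
  expect_lt(max(abs(eq$nodes$pos - net$nodes$pos)), 1e-8)
})

test_that("the energy sequence of the minimizer is non-increasing", {
  net <- damaged_tiny()
  # perturb interior nodes and re-minimize with tracing
  set.seed(1)
  free <- !net$nodes$is_boundary
  net$nodes$pos[free, ] <- net$nodes$pos[free, ] +
    matrix(rnorm(sum(free) * 3, sd = 0.02), ncol = 3)
  eq <- equilibrate(net, control = equilibrium_control(trace_energy = TRUE))
  tr <- eq$equilibrium$energy_trace
  expect_gt(length(tr), 2L)
  expect_true(all(diff(tr) <= 1e-12))
  expect_true(eq$equilibrium$converged)
})

test_that("equilibrium satisfies both force criteria on free nodes", {
  net <- damaged_tiny()
  F <- alveonet:::net_spring_forces(net)
  free <- !net$nodes$is_boundary
  live <- tabulate(c(net$springs$from[!net$springs$broken],
                     net$springs$to[!net$springs$broken]),
                   nbins = nrow(net$nodes$pos)) > 0
  fn <- sqrt(rowSums(F[free & live, , drop = FALSE]^2))
  expect_lt(max(fn), 1e-6)
  expect_lt(mean(fn), 1e-7)
})

test_that("energies are invariant under rigid translation", {
  net <- damaged_tiny()
  shifted <- net
  shifted$nodes$pos <- sweep(net$nodes$pos, 2, c(17, -3, 5), `+`)
  expect_equal(total_energy(shifted), total_energy(net), tolerance = 1e-10)
})

test_that("re-equilibration returns to the same energy after random perturbations", {
  net <- damaged_tiny()
  E0 <- total_energy(net)
  set.seed(42)
  free <- !net$nodes$is_boundary
  for (i in 1:20) {
    pert <- net
    pert$nodes$pos[free, ] <- pert$nodes$pos[free, ] +
      matrix(rnorm(sum(free) * 3, sd = 0.03), ncol = 3)
    pe <- equilibrate(pert)
    expect_equal(total_energy(pe), E0, tolerance = 1e-6)
  }
})

test_that("no spring ever reports negative tension", {
  net <- damaged_tiny()
  la <- alveonet:::.law_args(net$params)
  s <- net$springs
  st <- alveonet:::spring_state_cpp(net$nodes$pos, s$from - 1L, s$to - 1L,
                                    s$L0, s$k, s$broken,
                                    la$A, la$B, la$p, la$form)
  expect_true(all(st$tension >= 0))
  expect_true(all(st$tension[s$broken] == 0))
})

test_that("simulated annealing reaches the gradient-descent minimum on damaged blocks", {
  net <- damaged_tiny()
  E_gd <- total_energy(net)
  # restart annealing from the un-equilibrated scaled configuration
  start <- apply_prestrain(cubic_network(2), 1.2)
  start$faces$removed <- net$faces$removed
  start$springs$broken <- net$springs$broken
  ann <- anneal(start, schedule = anneal_schedule(), seed = 99)
  E_sa <- total_energy(ann)
  expect_gte(E_sa, E_gd - 1e-4 * abs(E_gd))
  expect_lt(abs(E_sa - E_gd) / abs(E_gd), 1e-4)
})

test_that("annealing is deterministic given a seed", {
  net <- apply_prestrain(cubic_network(1), 1.2)
  a <- anneal(net, schedule = anneal_schedule(n_temps = 3L, sweeps = 5L,
                                              quench_sweeps = 10L), seed = 5)
  b <- anneal(net, schedule = anneal_schedule(n_temps = 3L, sweeps = 5L,
                                              quench_sweeps = 10L), seed = 5)
  expect_identical(a$nodes$pos, b$nodes$pos)
})
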