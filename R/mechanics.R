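# Boundary conditions, total energy, and quasi-static equilibration.

#' Boundary conditions
#'
#' Three ways of loading the pre-strained block. `boundary_fixed()` pins every
#' boundary node (uniform-expansion pre-strain with fixed exterior).
#' `boundary_force()` applies constant (dead) external forces to nodes and
#' frees all of them. `boundary_pressure()` applies a distending pressure `P`
#' to the exterior surface: each boundary face is fan-triangulated and a facet
#' with outward area vector `S` contributes a force `P * S` split equally over
#' its three nodes; because these follower forces depend on the geometry,
#' [equilibrate()] recomputes them in an outer loop until the free energy
#' stabilizes. Optional `base_forces` (e.g. frozen boundary reactions) are
#' added as dead loads.
#'
#' @param forces an `n_nodes x 3` matrix of external nodal forces.
#' @param P distending pressure (positive expands the network).
#' @param base_forces optional `n_nodes x 3` dead-load matrix.
#' @return A `boundary_condition` object.
#' @export
boundary_fixed <- function() {
  structure(list(mode = "fixed"), class = "boundary_condition")
}

#' @rdname boundary_fixed
#' @export
boundary_force <- function(forces) {
  stopifnot(is.matrix(forces), ncol(forces) == 3, all(is.finite(forces)))
  structure(list(mode = "force", forces = forces), class = "boundary_condition")
}

#' @rdname boundary_fixed
#' @export
boundary_pressure <- function(P, base_forces = NULL) {
  stopifnot(is.numeric(P), length(P) == 1L, is.finite(P))
  if (!is.null(base_forces))
    stopifnot(is.matrix(base_forces), ncol(base_forces) == 3)
  structure(list(mode = "pressure", P = P, base_forces = base_forces),
            class = "boundary_condition")
}

#' Equilibration control parameters
#'
#' Convergence requires both force criteria to hold: the maximum and the mean
#' resultant-force magnitude over the constrained free nodes must fall below
#' their thresholds (the former is the stricter condition for local
#' deformations, the latter for uniform ones). `NULL` tolerances default to
#' `1e-6 * k * cell_size` (max) and `1e-7 * k * cell_size` (mean) at
#' equilibration time.
#'
#' @param max_force_tol,mean_force_tol force thresholds (model force units).
#' @param max_iterations inner minimizer iteration cap.
#' @param energy_change_tol relative free-energy change ending the
#'   pressure-mode outer loop.
#' @param max_outer pressure-mode outer iteration cap.
#' @param step0 initial line-search step, in units of `cell_size`.
#' @param armijo_c Armijo sufficient-decrease constant.
#' @param trace_energy record the per-iteration energy sequence.
#' @return An `equilibrium_control` list.
#' @export
equilibrium_control <- function(max_force_tol = NULL, mean_force_tol = NULL,
                                max_iterations = 100000L,
                                energy_change_tol = 1e-10, max_outer = 60L,
                                step0 = 0.1, armijo_c = 1e-4,
                                trace_energy = FALSE) {
  stopifnot(is.null(max_force_tol) || max_force_tol > 0,
            is.null(mean_force_tol) || mean_force_tol > 0,
            energy_change_tol > 0, max_iterations >= 1, step0 > 0)
  structure(list(max_force_tol = max_force_tol,
                 mean_force_tol = mean_force_tol,
                 max_iterations = as.integer(max_iterations),
                 energy_change_tol = energy_change_tol,
                 max_outer = as.integer(max_outer),
                 step0 = step0, armijo_c = armijo_c,
                 trace_energy = isTRUE(trace_energy)),
            class = "equilibrium_control")
}

.law_args <- function(params) {
  list(A = params$A, B = params$B, p = params$p,
       form = .law_form_exp(params))
}

.zero_ext <- function() matrix(numeric(0), 0, 3)

# Net nodal forces from the springs alone (n_nodes x 3).
net_spring_forces <- function(network, params = network$params) {
  la <- .law_args(params)
  s <- network$springs
  net_forces_cpp(network$nodes$pos, s$from - 1L, s$to - 1L, s$L0, s$k,
                 s$broken, la$A, la$B, la$p, la$form, .zero_ext())
}

# Pressure facet forces on the exterior surface: outward fan triangles of the
# boundary faces; each triangle's force P * S is split over its three nodes.
.pressure_forces <- function(network, P) {
  tri <- network$tri
  keep <- network$faces$is_boundary[tri$face]
  pos <- network$nodes$pos
  ic <- tri$c[keep]; ia <- tri$a[keep]; ib <- tri$b[keep]
  e1 <- pos[ia, , drop = FALSE] - pos[ic, , drop = FALSE]
  e2 <- pos[ib, , drop = FALSE] - pos[ic, , drop = FALSE]
  S <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  Ftri <- P * S / 3
  F <- matrix(0, nrow(pos), 3)
  idx <- c(ic, ia, ib)
  contrib <- rbind(Ftri, Ftri, Ftri)
  agg <- rowsum(contrib, idx)
  F[as.integer(rownames(agg)), ] <- agg
  F
}

#' Total (free) energy of the network
#'
#' Sum of the stored energies of all unbroken springs, minus the work of
#' external forces (force mode) or of the applied pressure over the enclosed
#' volume (pressure mode). Broken springs and compressed springs contribute
#' exactly zero.
#'
#' @param network a `spring_network`.
#' @param bc a [boundary_fixed()], [boundary_force()] or
#'   [boundary_pressure()] condition.
#' @param params constitutive parameters (default: the network's own).
#' @return Scalar energy (model units).
#' @export
total_energy <- function(network, bc = boundary_fixed(),
                         params = network$params) {
  stopifnot(inherits(network, "spring_network"),
            inherits(bc, "boundary_condition"))
  la <- .law_args(params)
  s <- network$springs
  E <- net_energy_cpp(network$nodes$pos, s$from - 1L, s$to - 1L, s$L0, s$k,
                      s$broken, la$A, la$B, la$p, la$form, .zero_ext())
  if (bc$mode == "force") {
    E <- E - sum(bc$forces * network$nodes$pos)
  } else if (bc$mode == "pressure") {
    if (!is.null(bc$base_forces))
      E <- E - sum(bc$base_forces * network$nodes$pos)
    E <- E - bc$P * total_volume(network)
  }
  E
}

# Movable / active node masks for a boundary condition. Isolated free nodes
# (every incident spring broken) are frozen and excluded from the criteria.
.node_masks <- function(network, bc) {
  n <- nrow(network$nodes$pos)
  movable <- if (bc$mode == "fixed") !network$nodes$is_boundary else rep(TRUE, n)
  s <- network$springs
  live <- !s$broken
  deg <- tabulate(c(s$from[live], s$to[live]), nbins = n)
  movable <- movable & deg > 0L
  list(movable = movable, active = movable)
}

.resolve_tols <- function(control, params, cell_size) {
  sc <- params$k * cell_size
  list(max = if (is.null(control$max_force_tol)) 1e-6 * sc else control$max_force_tol,
       mean = if (is.null(control$mean_force_tol)) 1e-7 * sc else control$mean_force_tol)
}

.minimize <- function(network, ext, movable, active, tols, control, params) {
  la <- .law_args(params)
  s <- network$springs
  minimize_net_cpp(network$nodes$pos, s$from - 1L, s$to - 1L, s$L0, s$k,
                   s$broken, la$A, la$B, la$p, la$form, ext,
                   movable, active, tols$max, tols$mean,
                   control$max_iterations,
                   control$step0 * network$meta$cell_size,
                   control$armijo_c, control$trace_energy)
}

#' Equilibrate the network by energy minimization
#'
#' Gradient descent on the free node positions (Barzilai-Borwein trial step
#' with Armijo backtracking, so the energy sequence is non-increasing) until
#' both the maximum and the mean resultant-force magnitude fall below their
#' thresholds. Under a pressure boundary the follower facet forces are
#' recomputed in an outer loop after each inner minimization, until the free
#' energy change between successive minimizations falls below
#' `energy_change_tol` (relative).
#'
#' Non-convergence within `max_iterations` is not an error: the returned
#' network carries the residual force norms in its `equilibrium` field so the
#' caller can decide.
#'
#' @inheritParams total_energy
#' @param control an [equilibrium_control()] list.
#' @return The network with updated node positions and an `equilibrium` field
#'   (`converged`, `iterations`, `max_force`, `mean_force`, `energy`, and the
#'   energy trace when requested).
#' @export
equilibrate <- function(network, bc = boundary_fixed(),
                        control = equilibrium_control(),
                        params = network$params) {
  stopifnot(inherits(network, "spring_network"),
            inherits(bc, "boundary_condition"),
            inherits(control, "equilibrium_control"))
  tols <- .resolve_tols(control, params, network$meta$cell_size)
  masks <- .node_masks(network, bc)
  n <- nrow(network$nodes$pos)

  if (bc$mode %in% c("fixed", "force")) {
    ext <- if (bc$mode == "force") bc$forces else .zero_ext()
    res <- .minimize(network, ext, masks$movable, masks$active, tols,
                     control, params)
    network$nodes$pos <- res$pos
    network$equilibrium <- list(
      mode = bc$mode, converged = res$converged,
      iterations = res$iterations, max_force = res$max_force,
      mean_force = res$mean_force, energy = res$energy,
      energy_trace = if (control$trace_energy) res$energy_trace)
  } else {
    base <- if (is.null(bc$base_forces)) matrix(0, n, 3) else bc$base_forces
    F_prev <- NA_real_
    outer <- 0L
    res <- NULL
    repeat {
      outer <- outer + 1L
      ext <- base + .pressure_forces(network, bc$P)
      res <- .minimize(network, ext, masks$movable, masks$active, tols,
                       control, params)
      network$nodes$pos <- res$pos
      F_now <- total_energy(network, bc, params)
      done <- !is.na(F_prev) &&
        abs(F_now - F_prev) <= control$energy_change_tol * max(abs(F_now), 1)
      F_prev <- F_now
      if (done || outer >= control$max_outer) break
    }
    network$equilibrium <- list(
      mode = "pressure", converged = res$converged && outer < control$max_outer,
      iterations = res$iterations, outer_iterations = outer,
      max_force = res$max_force, mean_force = res$mean_force,
      energy = F_prev,
      energy_trace = if (control$trace_energy) res$energy_trace)
  }
  network$meta$needs_equilibration <- FALSE
  network
}

#' Anneal schedule for the Metropolis cross-check
#'
#' @param T0 starting temperature (energy units).
#' @param alpha geometric cooling factor in (0, 1).
#' @param n_temps number of temperature stages.
#' @param sweeps Metropolis sweeps (one proposal per free node) per stage.
#' @param sigma proposal standard deviation, units of `cell_size`.
#' @param quench_sweeps zero-temperature polishing sweeps with shrinking
#'   proposal size appended after the schedule.
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(T0 = 1e-2, alpha = 0.7, n_temps = 25L,
                            sweeps = 40L, sigma = 0.05,
                            quench_sweeps = 200L) {
  stopifnot(T0 > 0, alpha > 0, alpha < 1, n_temps >= 1, sweeps >= 1, sigma > 0)
  structure(list(T0 = T0, alpha = alpha, n_temps = as.integer(n_temps),
                 sweeps = as.integer(sweeps), sigma = sigma,
                 quench_sweeps = as.integer(quench_sweeps)),
            class = "anneal_schedule")
}

#' Simulated-annealing energy minimization (cross-check oracle)
#'
#' Per-node Metropolis moves with the acceptance rule `exp(-dE/T)` under a
#' geometric cooling schedule, followed by zero-temperature polishing sweeps
#' (accept only downhill, with shrinking proposal size). Intended as an
#' independent check that gradient descent reaches the global minimum on
#' small systems; far too slow for production runs. Fully reproducible from
#' `seed`.
#'
#' @inheritParams equilibrate
#' @param schedule an [anneal_schedule()].
#' @param seed integer RNG seed.
#' @return The network with updated positions and an `equilibrium` field.
#' @export
anneal <- function(network, bc = boundary_fixed(),
                   schedule = anneal_schedule(), seed = 1L,
                   params = network$params) {
  stopifnot(inherits(network, "spring_network"),
            inherits(schedule, "anneal_schedule"))
  if (bc$mode == "pressure")
    stop("anneal() supports fixed and force boundary conditions only")
  masks <- .node_masks(network, bc)
  free <- which(masks$movable)
  n <- nrow(network$nodes$pos)
  ext <- if (bc$mode == "force") bc$forces else matrix(0, n, 3)
  la <- .law_args(params)
  s <- network$springs

  # incident unbroken springs per node, for local energy differences
  live <- which(!s$broken)
  inc <- split(rep(live, 2L), c(s$from[live], s$to[live]))
  inc_of <- function(i) inc[[as.character(i)]]

  local_E <- function(pos, i, sp) {
    if (length(sp) == 0L) return(-sum(ext[i, ] * pos[i, ]))
    d <- pos[s$from[sp], , drop = FALSE] - pos[s$to[sp], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    sum(spring_energy(pmax(len, 1e-12), s$L0[sp], params)) -
      sum(ext[i, ] * pos[i, ])
  }

  pos <- network$nodes$pos
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)

  sweep_once <- function(Temp, sigma) {
    for (i in free) {
      sp <- inc_of(i)
      e0 <- local_E(pos, i, sp)
      old <- pos[i, ]
      pos[i, ] <<- old + rnorm(3, sd = sigma * network$meta$cell_size)
      dE <- local_E(pos, i, sp) - e0
      if (dE > 0 && (Temp <= 0 || runif(1) >= exp(-dE / Temp)))
        pos[i, ] <<- old
    }
  }

  Temp <- schedule$T0
  for (t in seq_len(schedule$n_temps)) {
    for (sw in seq_len(schedule$sweeps)) sweep_once(Temp, schedule$sigma)
    Temp <- Temp * schedule$alpha
  }
  sig <- schedule$sigma
  for (sw in seq_len(schedule$quench_sweeps)) {
    sweep_once(0, sig)
    sig <- max(sig * 0.97, 1e-7)
  }

  network$nodes$pos <- pos
  bc_eval <- if (bc$mode == "force") bc else boundary_fixed()
  network$equilibrium <- list(mode = paste0("anneal-", bc$mode),
                              converged = NA,
                              energy = total_energy(network, bc_eval, params))
  network
}
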