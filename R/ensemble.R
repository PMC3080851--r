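# The reference simulation ensemble: base random/force pairs on the 6^3
# cubic lattice plus the held-out generalization scenarios (higher
# pre-strain, 14-hedral lattice, mixed pattern, 128-cell block, nonlinear
# springs).

#' Run the reference destruction ensemble
#'
#' Simulates the study conditions behind the structure-function estimator:
#' `n_base` spatially random and `n_base` force-based destruction runs on a
#' 6-per-side cubic lattice (pre-strain 1.2, 4 faces per step, run until
#' K/K0 reaches 0.3), and optionally the held-out generalization scenarios:
#' force-based and random runs at 1.5x higher pre-strain (strain 0.3) on a
#' 5^3 block, a mixed run with force fraction 0.1 (5^3), a force-based run
#' on a 14-hedral lattice (3 whole cells per side, 91 cells), a force-based
#' run on a 128-cell (4 x 4 x 8) block, and a force-based run with
#' nonlinear (stiffening power-law) springs (5^3).
#'
#' Every run's RNG seed is derived deterministically from `seed`, so the
#' whole ensemble is reproducible from one integer.
#'
#' @param seed integer master seed.
#' @param n_base number of random and of force-based base runs (default 3).
#' @param base_n cells per side of the base cubic lattice (default 6).
#' @param heldout include the held-out scenarios (default TRUE).
#' @param control an [equilibrium_control()].
#' @param verbose print one line per completed run.
#' @return Named list of `destruction_trajectory` objects. Base runs are
#'   named `random_1 ... random_<n>` and `force_1 ... force_<n>`; held-out
#'   runs `force_hi_prestrain`, `random_hi_prestrain`, `mixed_r0.1`,
#'   `force_tkd`, `force_128`, `force_nonlinear`.
#' @export
destruction_ensemble <- function(seed = 1L, n_base = 3L, base_n = 6L,
                                 heldout = TRUE,
                                 control = equilibrium_control(),
                                 verbose = FALSE) {
  seed <- as.integer(seed)
  run_seed <- function(i) (seed * 1000L + i) %% 2147483629L
  out <- list()
  tick <- function(nm, tr) {
    if (verbose)
      cat(sprintf("%-20s %3d steps, K/K0 -> %.3f\n", nm,
                  nrow(tr$steps) - 1L, tr$steps$K_over_K0[nrow(tr$steps)]))
    tr
  }

  base <- equilibrate(apply_prestrain(cubic_network(base_n), 1.2), control = control)
  for (i in seq_len(n_base)) {
    nm <- paste0("random_", i)
    out[[nm]] <- tick(nm, run_destruction(
      base, destruction_policy("random", seed = run_seed(i)), control = control))
  }
  for (i in seq_len(n_base)) {
    nm <- paste0("force_", i)
    out[[nm]] <- tick(nm, run_destruction(
      base, destruction_policy("force", seed = run_seed(100L + i)), control = control))
  }
  if (!heldout) return(out)

  hi <- equilibrate(apply_prestrain(cubic_network(5), 1.3), control = control)
  out$force_hi_prestrain <- tick("force_hi_prestrain", run_destruction(
    hi, destruction_policy("force", seed = run_seed(201L)), control = control))
  out$random_hi_prestrain <- tick("random_hi_prestrain", run_destruction(
    hi, destruction_policy("random", seed = run_seed(202L)), control = control))

  med <- equilibrate(apply_prestrain(cubic_network(5), 1.2), control = control)
  out$`mixed_r0.1` <- tick("mixed_r0.1", run_destruction(
    med, destruction_policy("mixed", force_fraction = 0.1,
                            seed = run_seed(203L)), control = control))

  tkd <- equilibrate(apply_prestrain(tkd_network(3), 1.2), control = control)
  out$force_tkd <- tick("force_tkd", run_destruction(
    tkd, destruction_policy("force", seed = run_seed(204L)), control = control))

  blk <- equilibrate(apply_prestrain(cubic_network(c(4, 4, 8)), 1.2),
                     control = control)
  out$force_128 <- tick("force_128", run_destruction(
    blk, destruction_policy("force", seed = run_seed(205L)), control = control))

  nl <- cubic_network(5, params = constitutive("power"))
  nl <- equilibrate(apply_prestrain(nl, 1.2), control = control)
  out$force_nonlinear <- tick("force_nonlinear", run_destruction(
    nl, destruction_policy("force", seed = run_seed(206L)), control = control))

  out
}

# names of the base runs in an ensemble list (replicates are numbered 1-9;
# the 128-cell held-out run is "force_128" and must not match)
.base_runs <- function(trajectories) {
  grep("^(random|force)_[1-9]$", names(trajectories), value = TRUE)
}

# names of the spatially correlated (force-based and mixed) held-out runs
.correlated_heldout <- function(trajectories) {
  intersect(c("force_hi_prestrain", "mixed_r0.1", "force_tkd", "force_128",
              "force_nonlinear"),
            names(trajectories))
}
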