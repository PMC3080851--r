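# Wall-removal policies and the destroy -> equilibrate -> measure loop.

#' Destruction policy
#'
#' At every step a fixed number of internal walls is removed: uniformly at
#' random (`"random"`), the highest-load walls (`"force"`), or a mixture in
#' which a fraction `force_fraction` of the walls per step is removed by
#' force and the rest at random (`"mixed"`). The initial seed of the
#' destruction process is spatially random for every pattern: the first step
#' of a force-based or mixed run is drawn uniformly. Boundary walls are never
#' eligible, so the exterior surface stays watertight.
#'
#' @param pattern `"random"`, `"force"` or `"mixed"`.
#' @param faces_per_step number of walls removed per step (default 4).
#' @param force_fraction fraction in `[0, 1]` of per-step removals that are
#'   force-ranked (mixed pattern; 1 reduces to `"force"`, 0 to `"random"`).
#' @param seed integer RNG seed; a run is fully reproducible from it.
#' @param n_steps optional cap on the number of destruction steps.
#' @param k_stop stop once `K/K0` falls to this value (default 0.3).
#' @param load_aggregate how a wall's load is aggregated from its face-spring
#'   tensions (see [face_load()]).
#' @return A `destruction_policy` object.
#' @export
destruction_policy <- function(pattern = c("random", "force", "mixed"),
                               faces_per_step = 4L, force_fraction = NULL,
                               seed = 1L, n_steps = Inf, k_stop = 0.3,
                               load_aggregate = c("sum", "mean", "max")) {
  pattern <- match.arg(pattern)
  load_aggregate <- match.arg(load_aggregate)
  faces_per_step <- as.integer(faces_per_step)
  if (is.na(faces_per_step) || faces_per_step < 1L)
    stop("'faces_per_step' must be a positive integer")
  if (pattern == "mixed") {
    if (is.null(force_fraction) || !is.numeric(force_fraction) ||
        force_fraction < 0 || force_fraction > 1)
      stop("mixed pattern requires 'force_fraction' in [0, 1]")
  } else {
    force_fraction <- if (pattern == "force") 1 else 0
  }
  stopifnot(k_stop > 0, k_stop < 1, n_steps >= 1)
  structure(list(pattern = pattern, faces_per_step = faces_per_step,
                 force_fraction = force_fraction, seed = as.integer(seed),
                 n_steps = n_steps, k_stop = k_stop,
                 load_aggregate = load_aggregate),
            class = "destruction_policy")
}

#' @export
print.destruction_policy <- function(x, ...) {
  cat(sprintf(
    "Destruction policy: %s (%d faces/step, force fraction %.2f, seed %d)\n",
    x$pattern, x$faces_per_step, x$force_fraction, x$seed))
  cat(sprintf("  stop at K/K0 <= %g or after %s steps\n", x$k_stop,
              format(x$n_steps)))
  invisible(x)
}

#' Force carried by a wall
#'
#' The load of a face is aggregated from the tensions of its unbroken
#' center-to-vertex springs (sum by default; the paper leaves the aggregate
#' open, so mean and max are offered as alternatives). A face whose springs
#' are all slack carries zero load. Querying a removed face is an error.
#'
#' @param network a `spring_network`.
#' @param face_ids faces to evaluate (default: all internal intact faces).
#' @param params constitutive parameters (default: the network's own).
#' @param aggregate `"sum"`, `"mean"` or `"max"`.
#' @return Numeric vector of loads named by face id.
#' @export
face_load <- function(network, face_ids = NULL, params = network$params,
                      aggregate = c("sum", "mean", "max")) {
  stopifnot(inherits(network, "spring_network"))
  aggregate <- match.arg(aggregate)
  if (is.null(face_ids))
    face_ids <- which(!network$faces$removed & !network$faces$is_boundary)
  face_ids <- as.integer(face_ids)
  if (any(network$faces$removed[face_ids]))
    stop("cannot evaluate the load of a removed face")
  la <- .law_args(params)
  s <- network$springs
  st <- spring_state_cpp(network$nodes$pos, s$from - 1L, s$to - 1L, s$L0,
                         s$k, s$broken, la$A, la$B, la$p, la$form)
  tension <- st$tension
  agg <- switch(aggregate, sum = sum, mean = mean, max = max)
  loads <- vapply(network$faces$springs[face_ids], function(sp) {
    live <- sp[!s$broken[sp]]
    if (length(live) == 0L) 0 else agg(tension[live])
  }, numeric(1))
  names(loads) <- face_ids
  loads
}

#' Select the walls to remove at one step
#'
#' Implements the per-step selection of [destruction_policy()] using the
#' current R random number generator (seed the RNG, or use
#' [run_destruction()], for reproducibility). At `step_index = 0` the
#' selection is uniformly random for every pattern (the spatially random
#' initial seed); afterwards the force-ranked part takes the
#' `round(force_fraction * faces_per_step)` eligible walls of highest load
#' (ties broken at random) and the remainder is drawn uniformly from the
#' other eligible walls.
#'
#' @param network a `spring_network`.
#' @param policy a [destruction_policy()].
#' @param step_index 0-based step counter.
#' @param params constitutive parameters (default: the network's own).
#' @return Integer vector of face ids.
#' @export
select_faces <- function(network, policy, step_index = 0L,
                         params = network$params) {
  stopifnot(inherits(network, "spring_network"),
            inherits(policy, "destruction_policy"))
  eligible <- which(!network$faces$removed & !network$faces$is_boundary)
  nf <- policy$faces_per_step
  if (length(eligible) < nf)
    stop(structure(class = c("alveonet_exhausted", "error", "condition"),
                   list(message = sprintf(
                     "only %d eligible internal faces remain (need %d)",
                     length(eligible), nf), call = sys.call())))
  n_force <- if (step_index == 0L) 0L else as.integer(round(policy$force_fraction * nf))
  chosen <- integer(0)
  if (n_force > 0L) {
    loads <- face_load(network, eligible, params = params,
                       aggregate = policy$load_aggregate)
    ord <- order(-loads, runif(length(loads)))
    chosen <- eligible[ord[seq_len(n_force)]]
  }
  n_rand <- nf - n_force
  if (n_rand > 0L) {
    pool <- setdiff(eligible, chosen)
    chosen <- c(chosen, pool[sample.int(length(pool), n_rand)])
  }
  chosen
}

#' Remove walls and prune dangling edge springs
#'
#' Breaks the face springs spanning each removed wall and flags the wall
#' removed. When all the walls adjoining a geometric edge have been
#' eliminated, the corresponding edge spring is also broken. Boundary walls
#' cannot be removed (the exterior must stay closed); removing an
#' already-removed wall is an error. Removing zero faces is the identity.
#'
#' @param network a `spring_network`.
#' @param face_ids integer vector of internal face ids.
#' @return The modified `spring_network`, flagged for re-equilibration.
#' @export
remove_faces <- function(network, face_ids) {
  stopifnot(inherits(network, "spring_network"))
  face_ids <- as.integer(face_ids)
  if (length(face_ids) == 0L) return(network)
  if (anyDuplicated(face_ids)) stop("duplicate face ids")
  if (any(network$faces$is_boundary[face_ids]))
    stop("boundary faces cannot be removed: the exterior surface must stay closed")
  if (any(network$faces$removed[face_ids]))
    stop("face already removed")
  network$faces$removed[face_ids] <- TRUE
  network$springs$broken[unlist(network$faces$springs[face_ids],
                                use.names = FALSE)] <- TRUE
  eids <- unlist(network$faces$edges[face_ids], use.names = FALSE)
  cnt <- table(eids)
  idx <- as.integer(names(cnt))
  network$edges$live_faces[idx] <- network$edges$live_faces[idx] -
    as.integer(cnt)
  dead <- idx[network$edges$live_faces[idx] == 0L]
  if (length(dead))
    network$springs$broken[network$edges$spring[dead]] <- TRUE
  network$meta$needs_equilibration <- TRUE
  network
}

# evaluate one trajectory record
.measure_step <- function(network, step, faces_removed, delta_P, control,
                          params, K0 = NA_real_, warm_start = NULL) {
  cl <- airspace_clusters(network)
  mo <- volume_moments(cl, v0 = network$meta$v0)
  km <- bulk_modulus(network, delta_P = delta_P, control = control,
                     params = params, warm_start = warm_start)
  eq <- network$equilibrium
  rec <- data.frame(step = step, faces_removed = faces_removed,
             n_clusters = cl$n,
             mu = mo[["mu"]], m2 = mo[["m2"]], m3 = mo[["m3"]],
             m4 = mo[["m4"]], K = km$K,
             K_over_K0 = if (is.na(K0)) 1 else km$K / K0,
             total_volume = sum(cl$volumes),
             eq_converged = isTRUE(eq$converged),
             K_converged = km$converged,
             eq_iterations = if (is.null(eq)) NA_integer_ else eq$iterations,
             max_force = if (is.null(eq)) NA_real_ else eq$max_force,
             energy = if (is.null(eq)) NA_real_ else eq$energy)
  list(record = rec, probe_pos = km$probe_pos)
}

#' Run a full destruction trajectory
#'
#' The simulation loop: select walls per the policy, remove them, find the
#' new equilibrium under the fixed boundary, and measure the airspace-volume
#' moments and the bulk modulus, repeating until `K/K0` reaches the policy's
#' stopping value, the step cap is hit, or the eligible walls are exhausted.
#' Step 0 records the intact pre-strained network (so `K_over_K0` starts at
#' 1). The run is fully reproducible from the policy seed; the global RNG
#' state is left untouched.
#'
#' @param network a pre-strained `spring_network` (it is equilibrated first
#'   if needed).
#' @param policy a [destruction_policy()].
#' @param delta_P pressure increment for [bulk_modulus()] (default as there).
#' @param control an [equilibrium_control()].
#' @param params constitutive parameters (default: the network's own).
#' @param verbose print a one-line summary per step.
#' @return A `destruction_trajectory`: list with `steps` (one data frame row
#'   per step), `policy`, `K0`, `meta`, and the final `network`.
#' @export
run_destruction <- function(network, policy, delta_P = NULL,
                            control = equilibrium_control(),
                            params = network$params, verbose = FALSE) {
  stopifnot(inherits(network, "spring_network"),
            inherits(policy, "destruction_policy"))
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(policy$seed)

  network <- equilibrate(network, boundary_fixed(), control, params)
  ms <- .measure_step(network, 0L, 0L, delta_P, control, params)
  rec0 <- ms$record
  K0 <- rec0$K
  rec0$K_over_K0 <- 1
  records <- list(rec0)
  probe_pos <- ms$probe_pos
  if (verbose)
    cat(sprintf("step %3d: K0 = %.5g, %d clusters\n", 0L, K0, rec0$n_clusters))

  step <- 0L
  repeat {
    eligible <- sum(!network$faces$removed & !network$faces$is_boundary)
    if (eligible < policy$faces_per_step) break
    if (step >= policy$n_steps) break
    ids <- select_faces(network, policy, step_index = step, params = params)
    network <- remove_faces(network, ids)
    network <- equilibrate(network, boundary_fixed(), control, params)
    step <- step + 1L
    ms <- .measure_step(network, step, step * policy$faces_per_step,
                        delta_P, control, params, K0 = K0,
                        warm_start = probe_pos)
    rec <- ms$record
    probe_pos <- ms$probe_pos
    records[[length(records) + 1L]] <- rec
    if (verbose)
      cat(sprintf("step %3d: %4d faces removed, K/K0 = %.4f, %d clusters\n",
                  step, rec$faces_removed, rec$K_over_K0, rec$n_clusters))
    if (is.finite(rec$K_over_K0) && rec$K_over_K0 <= policy$k_stop) break
  }

  structure(list(steps = do.call(rbind, records), policy = policy, K0 = K0,
                 meta = c(network$meta[c("lattice", "dims", "cell_size",
                                         "prestrain", "v0")],
                          list(law = params$law, delta_P = delta_P)),
                 network = network),
            class = "destruction_trajectory")
}

#' @export
print.destruction_trajectory <- function(x, ...) {
  st <- x$steps
  cat(sprintf(
    "Destruction trajectory: %s pattern on %s %s lattice (seed %d)\n",
    x$policy$pattern, paste(x$meta$dims, collapse = "x"), x$meta$lattice,
    x$policy$seed))
  cat(sprintf(
    "  %d steps, %d faces removed, K/K0: 1 -> %.3f, clusters: %d -> %d\n",
    nrow(st) - 1L, max(st$faces_removed), st$K_over_K0[nrow(st)],
    st$n_clusters[1], st$n_clusters[nrow(st)]))
  if (!all(st$eq_converged & st$K_converged))
    cat(sprintf("  WARNING: %d step(s) with unconverged measurements\n",
                sum(!(st$eq_converged & st$K_converged))))
  invisible(x)
}

#' @export
as.data.frame.destruction_trajectory <- function(x, ...) x$steps

#' @export
plot.destruction_trajectory <- function(x, ...) {
  st <- x$steps
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(st$faces_removed, st$mu, type = "b", xlab = "faces removed",
       ylab = "mean airspace volume (cells)", main = "mean", ...)
  plot(st$faces_removed, st$m2, type = "b", xlab = "faces removed",
       ylab = "variance of airspace volumes", main = "variance", ...)
  plot(st$faces_removed, st$K_over_K0, type = "b", xlab = "faces removed",
       ylab = "K / K0", ylim = c(0, 1), main = "bulk modulus", ...)
  invisible(x)
}
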