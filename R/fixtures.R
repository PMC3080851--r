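# Deterministic small fixtures for tests and examples.

#' Deterministic test fixtures
#'
#' Builds small pre-strained, equilibrated cubic networks (2^3 for `"tiny"`,
#' plus 4^3 for `"small"`) and a short force-based destruction trajectory on
#' the 2^3 block. Entirely deterministic for a given `seed`; no external
#' input of any kind.
#'
#' @param size `"tiny"` (2^3 only) or `"small"` (adds the 4^3 block).
#' @param seed integer seed for the bundled trajectory.
#' @param dir optional directory; when given, the networks (JSON) and the
#'   trajectory (CSV + manifest) are written there.
#' @return A list with `tiny` (and `small`) networks and `trajectory`.
#' @export
make_fixtures <- function(size = c("tiny", "small"), seed = 42L, dir = NULL) {
  size <- match.arg(size)
  out <- list()
  out$tiny <- equilibrate(apply_prestrain(cubic_network(2), 1.2))
  if (size == "small")
    out$small <- equilibrate(apply_prestrain(cubic_network(4), 1.2))
  pol <- destruction_policy("force", faces_per_step = 2L, seed = seed,
                            n_steps = 4L)
  out$trajectory <- run_destruction(out$tiny, pol)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_network_json(out$tiny, file.path(dir, "tiny_2x2x2.json"))
    if (!is.null(out$small))
      write_network_json(out$small, file.path(dir, "small_4x4x4.json"))
    write_trajectory(out$trajectory, file.path(dir, "tiny_force_trajectory.csv"))
  }
  out
}
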