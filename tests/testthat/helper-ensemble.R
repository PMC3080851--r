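# Reference ensemble shared by the acceptance tests: 5 random + 5 force base
# runs on the 6^3 cubic lattice plus the held-out generalization scenarios.
# Built once per test session (about two minutes) and cached.

acceptance_ensemble <- function() {
  cached("acceptance_ensemble", {
    ens <- destruction_ensemble(seed = 1, n_base = 5, heldout = TRUE)
    lapply(ens, function(tr) { tr$network <- NULL; tr })
  })
}

# removed-face count at which a run's K/K0 first reaches `k` (interpolated)
faces_to_reach <- function(tr, k) {
  d <- tr$steps
  i <- which(d$K_over_K0 <= k)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  f0 <- d$faces_removed[i - 1]; f1 <- d$faces_removed[i]
  k0 <- d$K_over_K0[i - 1]; k1 <- d$K_over_K0[i]
  f0 + (f1 - f0) * (k0 - k) / (k0 - k1)
}

moments_at_faces <- function(tr, f) {
  d <- tr$steps
  i <- which.min(abs(d$faces_removed - f))
  c(mu = d$mu[i], m2 = d$m2[i])
}
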