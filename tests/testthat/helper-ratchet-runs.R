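# Full-scale ratchet runs are expensive, and two different properties
# (equilibrium spacing and the end-biased deviation spectrum) are read off
# the same trajectories, so runs are cached per (radius, seed).
.ratchet_cache <- new.env(parent = emptyenv())

ratchet_reference_run <- function(repair_radius, seed) {
  key <- sprintf("R%d_s%d", repair_radius, seed)
  if (!exists(key, envir = .ratchet_cache)) {
    p <- hipscan::ratchet_params(
      length = 200000L, gc = 0.5, circular = TRUE, mu = 1e-4, p_meth = 1,
      repair_radius = as.integer(repair_radius), generations = 40000L,
      seed = as.integer(seed), init_site_per_nt = 1e-4)
    assign(key, hipscan::ratchet_run(p, record_every = 100L),
           envir = .ratchet_cache)
  }
  get(key, envir = .ratchet_cache)
}
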