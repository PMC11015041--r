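# Session cache for expensive coupled simulations so that several test
# files can share one 50 h run instead of recomputing it.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# receptor-recycling sweep on the tumor-1 surrogate (4 x 50 h runs)
krec_sweep_tumor1 <- function() {
  cached("krec_t1", run_sweep("k_rec", c(1e-4, 1e-3, 1e-2, 1e-1)))
}

# the two extreme recycling rates on the tumor-2 surrogate
krec_pair_tumor2 <- function() {
  cached("krec_t2", run_sweep("k_rec", c(1e-4, 1e-1), scenario = "tumor2"))
}

labeled_fraction_sweep <- function() {
  cached("frac_t1", run_sweep("labeled_fraction", c(0.01, 0.10)))
}

amount_sweep_tumor1 <- function() {
  cached("amount_t1", run_sweep("amount_total", seq(100, 1000, by = 100)))
}

bolus_infusion_pair <- function() {
  cached("cmp_t1", compare_bolus_infusion())
}

# default bolus run at halved time step, for the temporal-convergence check
halved_dt_run <- function() {
  cached("dt_half", run_scenario(dt_min = 0.05))
}

receptor_density_sweep <- function() {
  cached("dr_t1", run_sweep("receptor_density", c(10, 50, 100, 200, 500)))
}
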