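# Shared fixtures for the test suite. All inputs are generated in code.

default_params <- function() zipcode_defaults()$params
default_conditions <- function() zipcode_defaults()$conditions

# Random non-negative species state at nanomolar scale.
random_state <- function() {
  v <- stats::runif(6, 0, 1e-8)
  species_state(R = v[1], P = v[2], C3 = v[3], C4 = v[4], CC = v[5], D = v[6])
}

# Random rate set log-uniform within a factor `spread` of the defaults,
# with the closure rates constructed to keep the thermodynamic cycle
# consistent (kC4/kC3 = kon4/kon3).
random_consistent_params <- function(spread = 10) {
  base <- c(kon3 = 3.0e4, koff3 = 0.046, kon4 = 1.4e5, koff4 = 0.13,
            kC3 = 2)
  f <- exp(stats::runif(5, -log(spread), log(spread)))
  r <- base * f
  kinetic_parameters(r[["kon3"]], r[["koff3"]], r[["kon4"]], r[["koff4"]],
                     kC3 = r[["kC3"]],
                     kC4 = r[["kC3"]] * r[["kon4"]] / r[["kon3"]])
}

max_rel_diff <- function(a, b, floor = 1e-18) {
  a <- unclass(a)[c("R", "P", "C3", "C4", "CC", "D")]
  b <- unclass(b)[c("R", "P", "C3", "C4", "CC", "D")]
  max(abs(a - b) / pmax(abs(b), floor))
}

# Settings sized for a randomised draw: step from the stability bound,
# stop on a relative-derivative criterion loose enough to be fast but far
# below the 0.1% comparison level.
grid_settings <- function(params, conditions) {
  integrator_settings(dt = suggest_dt(params, conditions, safety = 0.25),
                      t_end = 20000, equilibrium_tol = 1e-7,
                      store_every = 100L)
}
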