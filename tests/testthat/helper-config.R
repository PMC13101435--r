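# Shared fixtures: the worked-example operating point (basal half-life
# 480 min, accelerated half-life 30 min at 200 mg/dL, beta = 1.5) and the
# enzyme constants used in the examples.

target_spec <- function() halflife_spec(480, 30, 200, units = "mgdl")

opt_params <- function(beta = 1.5) params_from_halflives(target_spec(), beta)

anchored_enzyme <- function(kin = opt_params(), k_cons = 0.02) {
  enz <- enzyme_params(k_cons = k_cons)
  enz$alpha_H <- calibrate_alpha_H(enz, kin, target_spec())
  enz
}

# random valid kinetic parameter sets for property-style loops
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    t_base <- runif(1, 100, 2000)
    t_ref <- runif(1, 5, t_base * 0.5)
    params_from_halflives(
      halflife_spec(t_base, t_ref, runif(1, 50, 400), units = "mgdl"),
      beta = runif(1, 0.5, 3))
  })
}
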