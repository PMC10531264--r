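# Shared fixtures: a small, constant-input world for engine tests and the
# default synthetic world for scenario/economics tests. Built once per run.

constant_world <- local({
  cfg <- synthetic_config(pop_growth = 0, mean_age_drift = 0,
                          inflation = 0, gdp_real_growth = 0)
  list(config = cfg, demography = make_demography(cfg),
       incidence = make_incidence(cfg), macro = make_macro(cfg))
})

default_world <- local({
  cfg <- synthetic_config()
  list(config = cfg, demography = make_demography(cfg),
       incidence = make_incidence(cfg), macro = make_macro(cfg))
})

random_valid_params <- function() {
  # draw every probability uniformly inside its declared bounds
  default_parameters(
    delta = runif(4), alphaU = runif(3),
    gamma = matrix(runif(12), 4, 3), alphaD = matrix(runif(12), 4, 3),
    lambda = matrix(runif(8), 4, 2),
    cost = matrix(runif(12, 1e5, 1e7), 4, 3), cost_diag = runif(1, 1e5, 1e6),
    epsilon = runif(1, 0.1, 1))
}

random_state <- function(n_ages = 7, scale = 100) {
  st <- disease_state(n_ages)
  st$N[] <- runif(length(st$N), 0, scale)
  st$D[] <- runif(length(st$D), 0, scale)
  st
}
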