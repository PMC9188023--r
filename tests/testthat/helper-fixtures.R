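# Shared fixtures, computed once per test run (the expensive ones are the
# embryo-shooting pipelines).

fixture_species <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reference_fixture()
    cache
  }
})

fixture_traits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_trait_table(reference_fixture())
    cache
  }
})

# The default synthetic family (seeded), shared by the scaling-recovery
# acceptance checks.
default_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- generate_parameter_table(synthetic_config(seed = 1L))
      cache <<- list(params = params, traits = build_trait_table(params))
    }
    cache
  }
})

# A reptile-like base parameter set for single-species numerical tests.
base_params <- function(...) {
  args <- list(...)
  defaults <- list(species_id = "base", p_Am = 200, v = 0.06, kappa = 0.8,
                   p_M = 18, k_J = 0.002, E_G = 7800, E_Hb = 2e3,
                   E_Hp = 4e5, h_a = 1e-9, s_G = 1e-4, kappa_R = 0.95,
                   T_A = 8000, f = 1)
  defaults[names(args)] <- args
  do.call(deb_params, defaults)
}
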