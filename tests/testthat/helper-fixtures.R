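# Shared fixtures. Expensive objects (singular strategies, analysis states)
# are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# symmetric two-sex parameter set (moderate size matching)
sym_params <- function() sexual_niche_params()
# sex-asymmetric set producing disruptive selection on male growth
asym_params <- function() {
  sexual_niche_params(c = 0.5, alpha = 0.1, mu_e_f = 0.1, mu_e_m = 0.05,
                      beta_f = 0.1, beta_m = 0.01, kappa = 2, K = 1e4)
}

sym_model <- function() cached("sym_model", sexual_niche_model(sym_params()))
asym_model <- function() cached("asym_model", sexual_niche_model(asym_params()))

sym_vstar <- function() cached("sym_vstar",
  find_singular_strategy(sym_model(), c(0.5, 0.45))$v_flat)
asym_vstar <- function() cached("asym_vstar",
  find_singular_strategy(asym_model(), c(0.65, 0.55))$v_flat)
sym_vl <- function() cached("sym_vl",
  find_singular_strategy(sym_model(), c(0.4, 0.4),
                         constraints = list(c(1L, 2L)))$v_flat[1L])
asym_vl <- function() cached("asym_vl",
  find_singular_strategy(asym_model(), c(0.3, 0.3),
                         constraints = list(c(1L, 2L)))$v_flat[1L])

sym_state <- function() cached("sym_state",
  ontosel:::analysis_state(sym_model(), sym_vstar()))
asym_state <- function() cached("asym_state",
  ontosel:::analysis_state(asym_model(), asym_vstar()))

# a demographically consistent single-class haploid model: constant fecundity
# tuned to mortality so that lifetime reproduction is one
haploid_model <- function(fec = 0.3, mort = 0.3) {
  life_history_model(
    n_classes = 1L, n_traits = 1L, n_states = 1L,
    fecundity = function(i, j, z, x, env) rep(fec, nrow(x)),
    mortality = function(j, z, x, env) rep(mort, nrow(x)),
    growth = function(j, z, x, env) z[1L] - x[, 1L],
    initial_states = list(0),
    genetics = genetic_system("haploid_single_class"),
    class_proportions = matrix(1, 1L, 1L)
  )
}
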