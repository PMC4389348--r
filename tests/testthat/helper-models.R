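# shared fixture helpers; all models are built in code, no data files

RT310 <- 1.9872e-3 * 310

# one two-configuration site bound by species `sp`
ts_site <- function(name, sp = "L") {
  list(site = site_spec(name, c("empty", sp)),
       ligand = ligand_spec(sp, data.frame(site = name, configuration = sp)))
}

# single-site chain with binding rate k_bind and unbinding rate k_unbind:
# bound Boltzmann weight w = k_bind / k_unbind at D = k_bind
two_state_rm <- function(k_bind = 3, k_unbind = 1) {
  fx <- make_fixture("single_site", bound_weight = k_bind / k_unbind)
  rate_matrix(equilibrium(fx$model, fx$cond), D = k_bind)
}

# 3-site model with nearest-neighbour cooperativity plus one steric exclusion
# (10 microstates); site b has three configurations so projections are
# non-binary
coupled_triple <- function(conc = 1) {
  a <- site_spec("a", c("empty", "X"))
  b <- site_spec("b", c("empty", "X", "Y"))
  c_ <- site_spec("c", c("empty", "X"))
  lx <- ligand_spec("X", data.frame(site = c("a", "b", "c"), configuration = "X"))
  ly <- ligand_spec("Y", data.frame(site = "b", configuration = "Y"))
  model <- binding_model(
    list(a, b, c_), list(lx, ly),
    exclusions = list(exclusion_rule("b", "Y", "c", "X")),
    energy_terms = list(
      energy_term(data.frame(site = "a", configuration = "X"), -0.5),
      energy_term(data.frame(site = "b", configuration = "X"), -0.3),
      energy_term(data.frame(site = "b", configuration = "Y"), -0.8),
      energy_term(data.frame(site = "c", configuration = "X"), -0.4),
      energy_term(data.frame(site = c("a", "b"), configuration = c("X", "X")), -1.2),
      energy_term(data.frame(site = c("b", "c"), configuration = c("X", "X")), -0.9)))
  list(model = model, cond = condition(c(X = conc, Y = conc)))
}

# closed forms for the alternating single-site chain with rates k1 (bind), k2
# (unbind): stationary persistence and self-exchange times
alt_tau_p <- function(k1, k2) (k1^2 + k2^2) / (k1 * k2 * (k1 + k2))
alt_tau_x <- function(k1, k2) 2 / (k1 + k2)
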