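test_that("the two-state masked chain reproduces every closed form", {
  k1 <- 3; k2 <- 1
  rm <- two_state_rm(k1, k2)
  ch <- masked_chain(rm, "a")
  # Q^a is diagonal with the exit rates, so N^a = diag(1/k1, 1/k2)
  mg <- masked_generator(rm, "a")
  expect_equal(mg$Qa, diag(c(-k1, -k2)))
  expect_equal(mg$Na, diag(c(1 / k1, 1 / k2)))
  # equal forward/backward flux makes the post-transition distribution uniform
  expect_equal(post_transition_distribution(ch), c(0.5, 0.5))
  expect_equal(ch$tau_mean, (1 / k1 + 1 / k2) / 2)
  expect_equal(analytic_persistence(ch), alt_tau_p(k1, k2))
  expect_equal(analytic_exchange(ch, ch), alt_tau_x(k1, k2))
  # equal rates: tau_p = 1/k and self-CA = 0
  rmEq <- two_state_rm(2, 2)
  chEq <- masked_chain(rmEq, "a")
  expect_equal(analytic_persistence(chEq), 0.5)
  expect_equal(analytic_exchange(chEq, chEq), analytic_persistence(chEq))
})

test_that("masked-chain invariants hold on every site of coupled models", {
  models <- list(coupled_triple(),
                 make_fixture("cooperative_pair"),
                 make_fixture("blocker_pair"))
  for (fx in models) {
    rm <- rate_matrix(equilibrium(fx$model, fx$cond))
    for (s in fx$model$site_names) {
      ch <- masked_chain(rm, s)
      expect_lt(ch$b_rowsum_max_dev, 1e-10)             # B^a rows sum to 1
      expect_true(all(ch$Ka >= 0))
      expect_equal(sum(ch$Ka), 1, tolerance = 1e-12)
      expect_gt(ch$tau_mean, 0)
      # K^a supported only on states reachable by an a-transition
      reach <- unique(ch$r_edges$to)
      expect_true(all(ch$Ka[setdiff(seq_len(ch$n), reach)] == 0))
      # tau^a is the reciprocal of the site's stationary transition frequency
      expect_equal(ch$tau_mean, 1 / ch$total_flux, tolerance = 1e-10)
      # masking never alters rates between states agreeing on the site
      mg <- masked_generator(rm, s)
      agree <- outer(fx$model$states[, s], fx$model$states[, s], "==")
      off <- row(agree) != col(agree)
      expect_equal(mg$Qa[agree & off], as.matrix(rm$Q)[agree & off])
      expect_true(all(mg$Qa[!agree] == 0))
      expect_true(all(mg$Na >= -1e-12))                 # fundamental matrix non-negative
      B <- mg$Na %*% mg$Ra
      expect_equal(rowSums(B), rep(1, ch$n), tolerance = 1e-10)
    }
  }
})

test_that("a frozen site raises a targeted singular-block error", {
  # site b can never change while a is bound (b's only ligand excluded) ->
  # make b's ligand concentration 0 so b never transitions at all
  fx <- make_fixture("independent_pair")
  eqz <- equilibrium(fx$model, condition(c(La = 1, Lb = 0)))
  # K = 0 states are refused upstream by rate_matrix
  expect_error(rate_matrix(eqz), "exactly 0")
  # zero-flux detection: strip b's transitions from a valid generator
  rm <- rate_matrix(equilibrium(fx$model, fx$cond))
  rm0 <- rm
  drop <- rm0$edges$site == 2
  rm0$Q[cbind(rm0$edges$from[drop], rm0$edges$to[drop])] <- 0
  rm0$edges <- rm0$edges[!drop, ]
  expect_error(masked_chain(rm0, "b"), "zero flux")

  # removing only b's binding edges leaves b unbinding flux but freezes the
  # b-empty block: the singular sub-generator is named, not inverted
  rm1 <- rm
  drop1 <- rm1$edges$site == 2 & rm1$edges$type == "binding"
  rm1$edges <- rm1$edges[!drop1, ]
  expect_error(masked_chain(rm1, "b"), "frozen in the subspace")
})

test_that("independent subsystems factorise: cross exchange equals persistence exactly", {
  fx <- make_fixture("independent_pair", bound_weight_a = 3, bound_weight_b = 0.5)
  rm <- rate_matrix(equilibrium(fx$model, fx$cond), D = 2)
  ca <- masked_chain(rm, "a"); cb <- masked_chain(rm, "b")
  expect_equal(analytic_exchange(ca, cb), analytic_persistence(ca), tolerance = 1e-12)
  expect_equal(analytic_exchange(cb, ca), analytic_persistence(cb), tolerance = 1e-12)
  tab <- ca_matrix(rm)
  expect_equal(tab$ca["a", "b"], 0)
  expect_equal(tab$ca["b", "a"], 0)
  # the product chain's self-CAs equal the single-site closed forms
  expect_equal(tab$ca["a", "a"], -log10(alt_tau_x(2, 2 / 3) / alt_tau_p(2, 2 / 3)),
               tolerance = 1e-12)
})

test_that("the analytic CA matrix is invariant under D rescaling and state relabelling", {
  trio <- coupled_triple()
  eq <- equilibrium(trio$model, trio$cond)
  rm1 <- rate_matrix(eq, D = 1)
  tab1 <- ca_matrix(rm1)
  tab10 <- ca_matrix(rate_matrix(eq, D = 10))
  expect_equal(tab10$ca, tab1$ca, tolerance = 1e-9)
  expect_equal(tab10$tau_p, tab1$tau_p / 10, tolerance = 1e-12)

  set.seed(42)
  perm <- sample(n_microstates(trio$model))
  tabp <- ca_matrix(permute_states(rm1, perm))
  expect_equal(tabp$ca, tab1$ca, tolerance = 1e-9)
})

test_that("analytic and empirical estimates agree on the coupled triple", {
  trio <- coupled_triple()
  rm <- rate_matrix(equilibrium(trio$model, trio$cond))
  ana <- ca_matrix(rm)
  tr <- simulate(rm, seed = 211, n_events = 1e6)
  emp <- ca_matrix(tr, n_boot = 100)
  for (a in trio$model$site_names) for (b in trio$model$site_names) {
    expect_lt(abs(emp$ca[a, b] - ana$ca[a, b]),
              3 * emp$se[a, b] + 1e-3)
  }
})

test_that("the printed contraction variant differs and the default matches simulation", {
  trio <- coupled_triple()
  rm <- rate_matrix(equilibrium(trio$model, trio$cond))
  occ <- ca_matrix(rm, form = "occupation")
  pri <- ca_matrix(rm, form = "printed")
  expect_false(isTRUE(all.equal(occ$tau_x, pri$tau_x)))
  # on the plain two-state chain the printed variant breaks the closed form
  rm2 <- two_state_rm(3, 1)
  ch <- masked_chain(rm2, "a")
  expect_equal(analytic_exchange(ch, ch, form = "occupation"), 0.5)
  expect_false(isTRUE(all.equal(analytic_exchange(ch, ch, form = "printed"), 0.5)))
})

test_that("analytic diagnostics export block counts and condition estimates", {
  trio <- coupled_triple()
  tab <- ca_matrix(rate_matrix(equilibrium(trio$model, trio$cond)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ca_diagnostics(tab, f)
  d <- read.delim(f)
  expect_named(d, c("site", "n_blocks", "cond_max", "tau_mean", "tau_p"))
  expect_true(all(d$n_blocks >= 2))
})
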