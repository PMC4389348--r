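test_that("persistence time matches hand-computed sums on tiny series", {
  # two events at times 1, 3 in a window of length 3: W = 2, tau_p = 4/6
  s <- site_events("a", c(1, 3), c("L", "empty"), c(0, 3))
  expect_equal(persistence_time(s), 4 / 6)

  # periodic events at spacing delta: ((N-1) delta^2) / (2 N delta)
  delta <- 0.5; N <- 101
  times <- delta * seq_len(N)
  cfg <- rep(c("L", "empty"), length.out = N)
  sp <- site_events("a", times, cfg, c(0, N * delta))
  expect_equal(persistence_time(sp), (N - 1) * delta^2 / (2 * N * delta))

  expect_true(is.na(persistence_time(site_events("a", 1, "L", c(0, 2)))))
})

test_that("exchange time matches the hand-computed single-term example", {
  # b-events at 1, 2; next a-event after 2 is at 2.5: term W(a,2) W(b,1) = 0.5 * 1
  tau_obs <- 4
  a <- site_events("a", c(0.5, 2.5), c("L", "empty"), c(0, tau_obs))
  b <- site_events("b", c(1, 2), c("M", "empty"), c(0, tau_obs))
  tx <- exchange_time(a, b)
  expect_equal(as.numeric(tx), 0.5 * 1 / tau_obs)
  expect_equal(attr(tx, "n_terms"), 1L)

  expect_error(exchange_time(a, site_events("b", 1, "M", c(0, 5))), "windows")
  expect_true(is.na(exchange_time(a, site_events("b", 1, "M", c(0, tau_obs)))))
})

test_that("truncated cross terms are dropped, counted, and warned about", {
  # b's last interval has no following a-event inside the window
  a <- site_events("a", 0.5, "L", c(0, 10))
  b <- site_events("b", c(1, 2, 3), c("M", "empty", "M"), c(0, 10))
  expect_warning(tx <- exchange_time(a, b), "truncated")
  expect_equal(attr(tx, "n_dropped"), 2L)
  expect_equal(as.numeric(tx), 0)  # no surviving terms
})

test_that("conditional activity handles ratio landmarks and undefined inputs", {
  # tau_x = tau_p  => CA = 0; tau_x = tau_p / 10 => CA = 1 (on synthetic sums)
  s <- site_events("a", c(1, 2, 3, 4), rep(c("L", "empty"), 2), c(0, 4))
  est <- suppressWarnings(conditional_activity(s, s))  # short record: terms truncate
  expect_s3_class(est, "ca_estimate")
  expect_equal(est$value, -log10(est$tau_x / est$tau_p))

  und <- suppressWarnings(conditional_activity(site_events("a", 1, "L", c(0, 4)), s))
  expect_false(und$defined)
  expect_true(is.na(und$value))
})

test_that("a Poisson-like (equal-rate) transition process has CA[a<-a] near 0", {
  rm <- two_state_rm(1, 1)
  tr <- simulate(rm, seed = 101, n_events = 2e5)
  ev <- project_events(tr, "a")
  est <- conditional_activity(ev, ev, n_boot = 200)
  expect_lt(abs(est$value), 3 * est$se + 0.005)
})

test_that("the alternating-rate chain reproduces its closed-form CA[a<-a]", {
  k1 <- 3; k2 <- 1
  rm <- two_state_rm(k1, k2)
  tr <- simulate(rm, seed = 103, n_events = 1e6)
  ev <- project_events(tr, "a")
  est <- conditional_activity(ev, ev, n_boot = 200)
  expect_equal(est$tau_p, alt_tau_p(k1, k2), tolerance = 0.02)
  expect_equal(est$tau_x, alt_tau_x(k1, k2), tolerance = 0.02)
  ca_exact <- -log10(alt_tau_x(k1, k2) / alt_tau_p(k1, k2))  # -log10(0.6)
  expect_lt(abs(est$value - ca_exact), 3 * est$se)
})

test_that("CA is invariant under global time rescaling of the event series", {
  rm <- two_state_rm(3, 1)
  tr <- simulate(rm, seed = 107, n_events = 5e4)
  ev <- project_events(tr, "a")
  scaled <- site_events(ev$site, ev$times * 7, ev$new_config, ev$window * 7)
  e1 <- conditional_activity(ev, ev)
  e2 <- conditional_activity(scaled, scaled)
  expect_equal(e2$value, e1$value, tolerance = 1e-12)
  expect_equal(e2$tau_p, 7 * e1$tau_p, tolerance = 1e-12)
})

test_that("independent sites give cross-CA consistent with 0", {
  fx <- make_fixture("independent_pair")
  rm <- rate_matrix(equilibrium(fx$model, fx$cond), D = 2)
  tr <- simulate(rm, seed = 109, n_events = 4e5)
  ev <- project_all_events(tr)
  ab <- conditional_activity(ev$a, ev$b, n_boot = 200)
  ba <- conditional_activity(ev$b, ev$a, n_boot = 200)
  expect_lt(abs(ab$value), 3 * ab$se)
  expect_lt(abs(ba$value), 3 * ba$se)
})

test_that("disjoint halves of a long record agree within combined standard errors", {
  rm <- two_state_rm(3, 1)
  tr <- simulate(rm, seed = 113, n_events = 4e5)
  ev <- project_events(tr, "a")
  half <- ev$window[2] / 2
  first <- site_events("a", ev$times[ev$times <= half],
                       ev$new_config[ev$times <= half], c(0, half))
  sec_t <- ev$times[ev$times > half] - half
  second <- site_events("a", sec_t, ev$new_config[ev$times > half],
                        c(0, ev$window[2] - half))
  e1 <- conditional_activity(first, first, n_boot = 200)
  e2 <- conditional_activity(second, second, n_boot = 200)
  expect_lt(abs(e1$value - e2$value), 3 * sqrt(e1$se^2 + e2$se^2))
})

test_that("the empirical CA matrix is complete, asymmetric-capable, and window-checked", {
  trio <- coupled_triple()
  rm <- rate_matrix(equilibrium(trio$model, trio$cond))
  tr <- simulate(rm, seed = 127, n_events = 2e5)
  tab <- ca_matrix(tr, n_boot = 50)
  expect_equal(dim(tab$ca), c(3, 3))
  expect_equal(rownames(tab$ca), trio$model$site_names)
  expect_true(all(is.finite(tab$ca)))
  expect_equal(unname(diag(tab$tau_x)[1]), as.numeric(exchange_time(
    project_events(tr, "a"), project_events(tr, "a"))), tolerance = 1e-12)

  evs <- project_all_events(tr)
  evs$b <- site_events("b", evs$b$times, evs$b$new_config, c(0, evs$b$window[2] * 2))
  expect_error(ca_matrix(evs), "windows")
})

test_that("CA tables export with 4 decimals and NA tokens", {
  rm <- two_state_rm()
  tab <- ca_matrix(simulate(rm, seed = 131, n_events = 1e4))
  f <- withr::local_tempfile(fileext = ".tsv")
  fl <- withr::local_tempfile(fileext = ".tsv")
  write_ca_table(tab, f, long_path = fl)
  m <- read.delim(f)
  expect_equal(m$site, "a")
  long <- read.delim(fl)
  expect_named(long, c("a", "b", "ca", "tau_x", "tau_p", "se"))
  expect_true(is.na(long$se[1]))
})
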