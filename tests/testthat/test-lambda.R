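test_that("the lambda switch has 1200 microstates factorising as 40 x 30", {
  m <- lambda_model()
  expect_equal(n_microstates(m), 1200)

  # right-operator submodel alone: 40 joint configurations
  right <- binding_model(
    m$sites[match(c("O_R1", "O_R2", "O_R3", "P_R", "P_RM"), m$site_names)],
    exclusions = Filter(function(ex) !grepl("L", ex$site_a) && !grepl("L", ex$site_b),
                        m$exclusions))
  expect_equal(n_microstates(right), 40)

  left <- binding_model(
    m$sites[match(c("O_L1", "O_L2", "O_L3", "P_L"), m$site_names)],
    exclusions = Filter(function(ex) grepl("L", ex$site_a) || grepl("L", ex$site_b),
                        m$exclusions))
  expect_equal(n_microstates(left), 30)

  # no cross-operator exclusions: the full count is the product
  expect_equal(n_microstates(m), 40 * 30)

  # removing all exclusions gives the unconstrained product 3^6 * 2^3
  free <- binding_model(m$sites, m$ligands)
  expect_equal(n_microstates(free), 3^6 * 2^3)
})

test_that("lambda exclusions implement the promoter/operator overlaps", {
  ms <- microstates(lambda_model())
  expect_false(any(ms$P_R == "RNAP" & (ms$O_R1 != "empty" | ms$O_R2 != "empty")))
  expect_false(any(ms$P_RM == "RNAP" & ms$O_R3 != "empty"))
  expect_false(any(ms$P_L == "RNAP" & (ms$O_L1 != "empty" | ms$O_L2 != "empty")))
  # both right-complex promoters may carry RNAP simultaneously
  expect_true(any(ms$P_R == "RNAP" & ms$P_RM == "RNAP"))
  # O_R1/O_R2 are unconstrained by P_RM (the overlap is with P_R only)
  expect_true(any(ms$P_RM == "RNAP" & ms$O_R1 == "CI2"))
})

test_that("each right-operator configuration aggregates exactly 30 microstates", {
  m <- lambda_model()
  eq <- equilibrium(m, condition(c(CI2 = 1e-7, Cro2 = 2e-8, RNAP = 3e-8)))
  proj <- project_to_right_operator(eq)
  expect_equal(nrow(proj), 40)
  expect_true(all(proj$n_aggregated == 30))
  expect_equal(sum(proj$probability), 1, tolerance = 1e-12)

  # uniform full distribution projects uniformly
  equ <- equilibrium(m, condition(c(CI2 = 1, Cro2 = 1, RNAP = 1)))
  proju <- project_to_right_operator(equ)
  expect_equal(proju$probability, rep(1 / 40, 40))

  fx <- make_fixture("single_site")
  expect_error(project_to_right_operator(equilibrium(fx$model, fx$cond)),
               "not a lambda model")
})

test_that("the placeholder parameter schema loads, is refused, and can be overridden", {
  f <- system.file("extdata", "lambda", "parameters_template.yaml", package = "condact")
  params <- read_lambda_params(f)
  expect_s3_class(params, "lambda_params")
  expect_equal(nrow(params$intrinsic), 15)           # 6 operators x 2 + 3 promoters
  expect_true(all(is.na(params$intrinsic$delta_g)))
  expect_gt(length(condact:::lambda_missing_entries(params)), 0)

  expect_error(lambda_model(params), "allow_placeholder")
  m <- lambda_model(params, allow_placeholder = TRUE)
  expect_equal(n_microstates(m), 1200)
  expect_true(attr(m, "placeholder"))
})

test_that("a complete parameter set passes the completeness check", {
  f <- system.file("extdata", "lambda", "parameters_template.yaml", package = "condact")
  params <- read_lambda_params(f)
  params$intrinsic$delta_g <- -10
  params$pairs$delta_g <- -2
  params$looping[[1]]$delta_g <- -4
  expect_length(condact:::lambda_missing_entries(params), 0)
  m <- lambda_model(params)
  expect_false(attr(m, "placeholder"))
  # octamer looping term contributes only when all four CI sites are bound
  ms <- microstates(m)
  oct <- ms$O_R1 == "CI2" & ms$O_R2 == "CI2" & ms$O_L1 == "CI2" & ms$O_L2 == "CI2"
  base <- with(ms, -10 * ((O_R1 != "empty") + (O_R2 != "empty") + (O_R3 != "empty") +
                            (O_L1 != "empty") + (O_L2 != "empty") + (O_L3 != "empty") +
                            (P_R == "RNAP") + (P_RM == "RNAP") + (P_L == "RNAP")))
  expect_true(all(ms$delta_g[oct] <= base[oct] - 4))
})

test_that("a zero-energy lambda model under unit concentrations is uniform with zero MI", {
  f <- system.file("extdata", "lambda", "parameters_template.yaml", package = "condact")
  params <- read_lambda_params(f)
  rep <- pathway_report(params, condition(c(CI2 = 1, Cro2 = 1, RNAP = 1)),
                        pathway = "lysogenic", allow_placeholder = TRUE)
  expect_equal(rep$equilibrium$probabilities, rep(1 / 1200, 1200))
  mi_off <- rep$mi; diag(mi_off) <- 0
  # exclusions still induce (structural) correlations between overlapping
  # sites; all non-overlapping pairs must carry no information
  expect_equal(mi_off["O_R1", "O_L1"], 0, tolerance = 1e-12)
  expect_equal(mi_off["O_R3", "O_L3"], 0, tolerance = 1e-12)
  expect_gt(mi_off["P_R", "O_R1"], 0)
  expect_equal(rep$p_rnap_pr, sum(microstates(rep$model)$P_R == "RNAP") / 1200,
               tolerance = 1e-12)
})

test_that("condition presets are schema-complete but refuse unset values", {
  f <- system.file("extdata", "lambda", "lysogenic.yaml", package = "condact")
  expect_error(read_condition(f), "unset concentrations.*CI2")
})

test_that("the pathway report is deterministic and writes its export bundle", {
  f <- system.file("extdata", "lambda", "parameters_template.yaml", package = "condact")
  params <- read_lambda_params(f)
  cond <- condition(c(CI2 = 1e-3, Cro2 = 1e-3, RNAP = 1e-3))
  d <- withr::local_tempdir()
  r1 <- pathway_report(params, cond, allow_placeholder = TRUE, out_dir = d)
  r2 <- pathway_report(params, cond, allow_placeholder = TRUE)
  expect_equal(r1$ca$ca, r2$ca$ca)
  expect_equal(r1$mi, r2$mi)
  for (fn in c("top_states.tsv", "mi.tsv", "ca.tsv", "ca_long.tsv", "entropies.tsv",
               "right_operator_occupancy.tsv", "microstates.dot",
               "microstates.graphml", "mi.graphml", "ca.graphml"))
    expect_true(file.exists(file.path(d, fn)), label = fn)
})
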