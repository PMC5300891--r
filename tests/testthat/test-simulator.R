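test_that("null dynamics leave the state constant", {
  p <- kinetic_parameters(0, 0, 0, 0, 0, 0)
  tc <- simulate_timecourse(p, mixture_conditions(2e-7, 4e-10),
                            integrator_settings(t_end = 10))
  expect_true(all(tc$R == 4e-10))
  expect_true(all(tc$P == 2e-7))
  expect_true(all(tc$C3 == 0 & tc$C4 == 0 & tc$CC == 0 & tc$D == 0))
})

test_that("single-reaction reduction matches the closed-form 1:1 relaxation", {
  # only R + P <-> C3 active, pseudo-first-order regime P_tot >> R_tot
  p <- kinetic_parameters(3.0e4, 0.046, 0, 0, 0, 0)
  # RNA kept far below protein so depletion stays under the tolerance
  P_tot <- 2e-6
  R_tot <- 1e-13
  tc <- simulate_timecourse(p, mixture_conditions(P_tot, R_tot),
                            integrator_settings(dt = 0.005, t_end = 120,
                                                store_every = 200L))
  kobs <- 3.0e4 * P_tot + 0.046
  c3_eq <- R_tot * 3.0e4 * P_tot / (3.0e4 * P_tot + 0.046)
  expected <- c3_eq * (1 - exp(-kobs * tc$time_s))
  expect_lt(max(abs(tc$C3[-1] - expected[-1]) / expected[-1]), 1e-6)
})

test_that("halving the step changes the solution below the convergence contract", {
  d <- zipcode_defaults()
  tc1 <- simulate_timecourse(d$params, d$conditions,
                             integrator_settings(dt = 0.01, t_end = 200,
                                                 store_every = 100L))
  tc2 <- simulate_timecourse(d$params, d$conditions,
                             integrator_settings(dt = 0.005, t_end = 200,
                                                 store_every = 200L))
  expect_lt(max_rel_diff(final_state(tc1), final_state(tc2), floor = 1e-15),
            1e-6)
})

test_that("trajectories conserve RNA and protein at every stored step", {
  d <- zipcode_defaults()
  tc <- simulate_timecourse(d$params, d$conditions,
                            integrator_settings(t_end = 300))
  r_tot <- tc$R + tc$C3 + tc$C4 + tc$CC + tc$D
  p_tot <- tc$P + tc$C3 + tc$C4 + tc$CC + 2 * tc$D
  expect_lt(max(abs(r_tot - 0.4e-9)) / 0.4e-9, 1e-9)
  expect_lt(max(abs(p_tot - 0.2e-6)) / 0.2e-6, 1e-9)
  expect_true(all(as.matrix(tc[, c("R", "P", "C3", "C4", "CC", "D")]) >= 0))
})

test_that("swapping the domain labels swaps C3 and C4 exactly", {
  d <- zipcode_defaults()
  p <- d$params
  swapped <- kinetic_parameters(p[["kon4"]], p[["koff4"]],
                                p[["kon3"]], p[["koff3"]],
                                kC3 = p[["kC4"]], kC4 = p[["kC3"]])
  s <- integrator_settings(t_end = 100)
  tc1 <- simulate_timecourse(p, d$conditions, s)
  tc2 <- simulate_timecourse(swapped, d$conditions, s)
  expect_identical(tc1$R, tc2$R)
  expect_identical(tc1$P, tc2$P)
  expect_identical(tc1$CC, tc2$CC)
  expect_identical(tc1$D, tc2$D)
  expect_identical(tc1$C3, tc2$C4)
  expect_identical(tc1$C4, tc2$C3)
})

test_that("unstable step sizes are refused with a diagnostic", {
  d <- zipcode_defaults()
  expect_error(
    simulate_timecourse(d$params, d$conditions,
                        integrator_settings(dt = 1, t_end = 10)),
    "unstable step")
})

test_that("RK4 trajectory agrees with an independent adaptive solver", {
  skip_if_not_installed("deSolve")
  d <- zipcode_defaults()
  tc <- simulate_timecourse(d$params, d$conditions,
                            integrator_settings(t_end = 200, store_every = 1000L))
  p <- d$params
  rhs <- function(t, y, parms) {
    list(as.numeric(mass_action_rhs(
      species_state(y[[1]], y[[2]], y[[3]], y[[4]], y[[5]], y[[6]]), p)))
  }
  y0 <- c(R = 0.4e-9, P = 0.2e-6, C3 = 0, C4 = 0, CC = 0, D = 0)
  ref <- deSolve::lsoda(y0, tc$time_s, rhs, NULL, rtol = 1e-10, atol = 1e-22)
  for (sp in c("R", "P", "C3", "C4", "CC", "D")) {
    expect_lt(max(abs(tc[[sp]] - ref[, sp]) / pmax(ref[, sp], 1e-15)), 1e-6)
  }
})

test_that("equilibrium run summarises the base case and handles edge cases", {
  d <- zipcode_defaults()
  eq <- run_to_equilibrium(d$params, d$conditions,
                           integrator_settings(t_end = 1000))
  expect_equal(eq$fraction_bound, 0.91, tolerance = 0.01)
  expect_equal(eq$Kd_app, 20.6e-9, tolerance = 0.01)
  expect_gt(eq$time_to_equilibrium, 100)
  expect_lt(eq$time_to_equilibrium, 150)

  # no protein: equilibrium immediately, all RNA free
  eq0 <- run_to_equilibrium(d$params, mixture_conditions(0, 0.4e-9))
  expect_equal(eq0$fraction_bound, 0)
  expect_equal(eq0$state[["R"]], 0.4e-9)

  # horizon too short: error carries the last state
  err <- tryCatch(
    run_to_equilibrium(d$params, d$conditions,
                       integrator_settings(t_end = 5)),
    zipkinetics_nonconvergence = function(e) e)
  expect_s3_class(err, "zipkinetics_nonconvergence")
  expect_length(err$last_state, 6)
})

test_that("dissociation with a single open channel decays at koff3", {
  p <- kinetic_parameters(3.0e4, 0.046, 1.4e5, 0.13, kC3 = 2, kC4 = 0)
  init <- species_state(C3 = 1e-9)
  tc <- dissociation_timecourse(p, init, integrator_settings(t_end = 100))
  expected <- 1e-9 * exp(-0.046 * tc$time_s)
  expect_lt(max(abs(tc$C3 - expected) / expected), 1e-8)
  expect_true(all(tc$P == 0))
  expect_true(all(tc$CC == 0))
})

test_that("fitted dissociation decay matches the analytic escape rate", {
  d <- zipcode_defaults()
  eq <- run_to_equilibrium(d$params, d$conditions,
                           integrator_settings(t_end = 1000))
  dis <- dissociation_timecourse(d$params, eq$state,
                                 integrator_settings(t_end = 600))
  bound <- dis$C3 + dis$C4 + dis$CC + dis$D
  rate <- exponential_fit(dis$time_s, bound, "decay")$rate
  expect_equal(rate, effective_dissociation_rate(d$params), tolerance = 0.05)
  expect_equal(rate, 0.0034, tolerance = 0.05)
})

test_that("time courses round-trip through CSV", {
  d <- zipcode_defaults()
  tc <- simulate_timecourse(d$params, d$conditions,
                            integrator_settings(t_end = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  expect_equal(as.data.frame(back), as.data.frame(tc),
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(read_timecourse(withr::local_tempfile(lines = "a,b\n1,2")),
               "header")
})
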