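test_that("direct solver and detailed-balance closed form agree at base conditions", {
  d <- zipcode_defaults()
  ss <- steady_state_solve(d$params, d$conditions)
  db <- detailed_balance_state(d$params, d$conditions)
  expect_lt(max_rel_diff(ss, db, floor = 1e-16), 1e-3)

  # closed complex dominates the bound pool
  bound <- ss[["C3"]] + ss[["C4"]] + ss[["CC"]] + ss[["D"]]
  expect_gt(ss[["CC"]] / bound, 0.9)
  expect_equal(fraction_bound(ss), 0.907, tolerance = 0.005)

  tot <- conserved_totals(ss)
  expect_equal(tot[["R_tot"]], 0.4e-9, tolerance = 1e-9)
  expect_equal(tot[["P_tot"]], 0.2e-6, tolerance = 1e-9)
})

test_that("detailed-balance closed form refuses inconsistent cycles", {
  bad <- kinetic_parameters(3.0e4, 0.046, 1.4e5, 0.13, kC3 = 0.2, kC4 = 9.333)
  expect_error(detailed_balance_state(bad, default_conditions()),
               "consistent cycle")
})

test_that("no-closure equilibrium reproduces the open-complex concentrations", {
  p <- kinetic_parameters(3.0e4, 0.046, 1.4e5, 0.13, 0, 0)
  cond <- mixture_conditions(200e-9, 0.4e-9)
  ss <- steady_state_solve(p, cond)

  # independent algebra: with no closed complex the species follow the
  # single-site equilibrium constants; R from RNA conservation
  P <- ss[["P"]]
  a3 <- P / (0.046 / 3.0e4)
  a4 <- P / (0.13 / 1.4e5)
  R_expected <- 0.4e-9 / (1 + a3 + a4 + a3 * a4)
  expect_equal(ss[["R"]], R_expected, tolerance = 1e-9)
  expect_equal(ss[["C3"]], a3 * R_expected, tolerance = 1e-9)
  expect_equal(ss[["D"]], a3 * a4 * R_expected, tolerance = 1e-9)
  expect_equal(ss[["CC"]], 0)

  # published concentrations: 38 pM, 63 pM, 8.2 pM
  expect_equal(ss[["C3"]] * 1e12, 38, tolerance = 0.05)
  expect_equal(ss[["C4"]] * 1e12, 63, tolerance = 0.05)
  expect_equal(ss[["D"]] * 1e12, 8.2, tolerance = 0.05)
})

test_that("degenerate mixtures solve trivially", {
  d <- zipcode_defaults()
  ss <- steady_state_solve(d$params, mixture_conditions(2e-7, 0))
  expect_equal(unname(unclass(ss)), c(0, 2e-7, 0, 0, 0, 0))
  ss2 <- steady_state_solve(d$params, mixture_conditions(0, 4e-10))
  expect_equal(ss2[["R"]], 4e-10)
  expect_equal(fraction_bound(ss2), 0)
})

test_that("apparent Kd reduces to koff/kon for a single 1:1 reaction", {
  # equilibrium of R + P <-> C3 alone: C3 = R*P/Kd3
  kon <- 3.0e4; koff <- 0.046
  R <- 2e-10; P <- 5e-8
  st <- species_state(R = R, P = P, C3 = R * P / (koff / kon))
  expect_equal(apparent_kd(st), koff / kon, tolerance = 1e-12)
  expect_error(apparent_kd(species_state(R = 1e-9, P = 1e-9)), "undefined")
})

test_that("fraction bound tracks protein concentration as published", {
  d <- zipcode_defaults()
  sw <- protein_sweep(d$params, c(5, 50, 100, 200) * 1e-9, 0.4e-9)
  expect_equal(sw$fraction_bound, c(0.19, 0.71, 0.83, 0.91), tolerance = 0.02)

  # fraction bound strictly increases with protein while the apparent Kd
  # stays essentially flat (it is a property of the complex, not the mixture)
  dense <- protein_sweep(d$params, c(1, 2, 5, 10, 20, 50, 100, 200, 500) * 1e-9,
                         0.4e-9)
  expect_true(all(diff(dense$fraction_bound) > 0))
  expect_lt(diff(range(dense$Kd_app_M)) / min(dense$Kd_app_M), 0.01)

  z <- protein_sweep(d$params, 0, 0.4e-9)
  expect_equal(z$fraction_bound, 0)

  expect_error(protein_sweep(d$params, numeric(0), 0.4e-9), "non-empty")
  expect_error(protein_sweep(d$params, c(1e-9, -1e-9), 0.4e-9), "non-negative")
})

test_that("saturation: fraction bound approaches 1 at high protein", {
  d <- zipcode_defaults()
  st <- detailed_balance_state(d$params, mixture_conditions(1e-3, 0.4e-9))
  expect_gt(fraction_bound(st), 0.9999)
})

test_that("reducing the closure rates weakens binding as published", {
  d <- zipcode_defaults()
  sw <- closing_rate_sweep(d$params, c(0.2, 2, 20), d$conditions,
                           preserve_ratio = TRUE)
  expect_equal(sw$kC4_per_s, sw$kC3_per_s * 9.333 / 2, tolerance = 1e-12)

  # tenfold reduction: ~91% -> ~57% bound, Kd ~150 nM
  expect_equal(sw$fraction_bound[1], 0.57, tolerance = 0.03)
  expect_equal(sw$Kd_app_M[1], 150e-9, tolerance = 0.05)

  # the response is asymmetric: a tenfold increase gains little (binding is
  # already nearly saturated) while a tenfold decrease loses a third of the
  # bound pool
  expect_lt(sw$fraction_bound[3] - sw$fraction_bound[2], 0.09)
  expect_gt(sw$fraction_bound[2] - sw$fraction_bound[1], 0.3)

  # the 2:1 complex stays a negligible share of bound RNA in every row
  bound <- sw$C3 + sw$C4 + sw$CC + sw$D
  expect_true(all(sw$D / bound < 0.03))

  # effective off-rate grows as closure slows
  expect_true(all(diff(sw$koff_effective_per_s) < 0))

  expect_error(closing_rate_sweep(d$params, c(-1, 2), d$conditions),
               "positive")
})

test_that("fraction bound is insensitive to RNA concentration at base parameters", {
  d <- zipcode_defaults()
  base <- fraction_bound(steady_state_solve(d$params, d$conditions))
  for (f in c(1 / 50, 50)) {
    st <- steady_state_solve(d$params, mixture_conditions(2e-7, 4e-10 * f))
    expect_lt(abs(fraction_bound(st) - base), 0.01)
  }
})

test_that("sweep tables serialise to CSV", {
  d <- zipcode_defaults()
  sw <- protein_sweep(d$params, c(5, 50) * 1e-9, 0.4e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_table(sw, path)
  back <- utils::read.csv(path)
  expect_equal(back$fraction_bound, sw$fraction_bound, tolerance = 1e-6)
})
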