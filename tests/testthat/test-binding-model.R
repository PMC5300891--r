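test_that("rate law reproduces hand-evaluated single-term derivatives", {
  p <- default_params()

  # empty system is inert
  d0 <- mass_action_rhs(species_state(), p)
  expect_identical(unname(unclass(d0)), rep(0, 6))

  # closed complex alone can only reopen through either domain
  st <- species_state(CC = 1e-9)
  d <- mass_action_rhs(st, p)
  expect_equal(d[["CC"]], -(0.046 + 0.13) * 1e-9)
  expect_equal(d[["C3"]], 0.13e-9)   # KH4 releases -> KH3-bound open complex
  expect_equal(d[["C4"]], 0.046e-9)  # KH3 releases -> KH4-bound open complex
  expect_equal(d[["R"]], 0)
  expect_equal(d[["D"]], 0)
})

test_that("rate law conserves RNA and protein for arbitrary states", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_consistent_params()
    st <- random_state()
    d <- mass_action_rhs(st, p)
    scale <- max(abs(d))
    expect_lt(abs(d[["R"]] + d[["C3"]] + d[["C4"]] + d[["CC"]] + d[["D"]]),
              1e-12 * max(scale, 1e-30))
    expect_lt(abs(d[["P"]] + d[["C3"]] + d[["C4"]] + d[["CC"]] + 2 * d[["D"]]),
              1e-12 * max(scale, 1e-30))
  }
})

test_that("rate law rejects invalid states", {
  p <- default_params()
  expect_error(species_state(R = -1e-9), "non-negative")
  bad <- species_state(R = 1e-9)
  bad[["P"]] <- NaN
  expect_error(mass_action_rhs(unclass(bad), p), "finite")
})

test_that("closure-rate derivation reproduces the published values", {
  kc <- derive_closing_rates(kon3 = 3.0e4, koff3 = 0.046,
                             kon4 = 1.4e5, koff4 = 0.13,
                             Kd_overall = 2.0e-8)
  # direct arithmetic: kC3 = (0.13/1.4e5)*0.046/2e-8, kC4 = (0.046/3e4)*0.13/2e-8
  expect_equal(kc[["kC3"]], (0.13 / 1.4e5) * 0.046 / 2e-8, tolerance = 1e-12)
  expect_equal(kc[["kC4"]], (0.046 / 3.0e4) * 0.13 / 2e-8, tolerance = 1e-12)
  expect_equal(kc[["kC3"]], 2.1357, tolerance = 1e-4)
  expect_equal(kc[["kC4"]], 9.9667, tolerance = 1e-4)
  expect_equal(signif(kc[["kC3"]], 1), 2)

  # cycle closure is automatic: kC4/kC3 = kon4/kon3
  expect_equal(kc[["kC4"]] / kc[["kC3"]], 1.4e5 / 3.0e4, tolerance = 1e-12)
})

test_that("closure-rate derivation obeys symmetry and scaling", {
  # symmetric domains with Kd_overall = Kd3 collapse to kC = koff
  kc <- derive_closing_rates(1e5, 0.05, 1e5, 0.05, Kd_overall = 0.05 / 1e5)
  expect_equal(unname(kc), c(0.05, 0.05))

  # both closure rates are inversely proportional to the overall Kd
  kc1 <- derive_closing_rates(3.0e4, 0.046, 1.4e5, 0.13, 2e-8)
  kc2 <- derive_closing_rates(3.0e4, 0.046, 1.4e5, 0.13, 4e-8)
  expect_equal(unname(kc2), unname(kc1) / 2)

  expect_error(derive_closing_rates(3e4, 0.046, 1.4e5, 0.13, -1e-8),
               "positive")
  expect_error(derive_closing_rates(0, 0.046, 1.4e5, 0.13, 2e-8), "positive")
})

test_that("cycle-consistency ratio flags balanced and unbalanced sets", {
  p <- default_params()  # kC4 = 9.333 was itself built for cycle closure
  expect_equal(cycle_consistency_ratio(p),
               (3.0e4 * 9.333) / (1.4e5 * 2), tolerance = 1e-12)
  expect_true(is_cycle_consistent(p, tol = 1e-3))

  bad <- kinetic_parameters(3.0e4, 0.046, 1.4e5, 0.13, kC3 = 0.2, kC4 = 9.333)
  expect_equal(cycle_consistency_ratio(bad), (3.0e4 * 9.333) / (1.4e5 * 0.2),
               tolerance = 1e-12)
  expect_false(is_cycle_consistent(bad))

  set.seed(4)
  for (i in 1:10) {
    kc <- derive_closing_rates(exp(runif(1, 9, 13)), exp(runif(1, -4, -1)),
                               exp(runif(1, 9, 13)), exp(runif(1, -4, -1)),
                               exp(runif(1, -20, -15)))
    # derive_closing_rates forces ratio kC4/kC3 = kon4/kon3 of ITS inputs,
    # so a set built with matching kons closes the cycle exactly
    q2 <- kinetic_parameters(1, 0.05, kc[["kC4"]] / kc[["kC3"]], 0.1,
                             kc[["kC3"]], kc[["kC4"]])
    expect_equal(cycle_consistency_ratio(q2), 1, tolerance = 1e-12)
  }

  zero_kc <- kinetic_parameters(3e4, 0.046, 1.4e5, 0.13, kC3 = 0, kC4 = 1)
  expect_error(cycle_consistency_ratio(zero_kc), "undefined|positive")
})

test_that("effective dissociation rate matches the escape formula and limits", {
  p <- default_params()
  expected <- 0.13 * 0.046 / (0.046 + 9.333) + 0.046 * 0.13 / (0.13 + 2)
  expect_equal(effective_dissociation_rate(p), expected, tolerance = 1e-12)
  expect_equal(round(effective_dissociation_rate(p), 4), 0.0034)

  # no reclosure: both open complexes release immediately
  open_only <- kinetic_parameters(3e4, 0.046, 1.4e5, 0.13, 0, 0)
  expect_equal(effective_dissociation_rate(open_only), 0.046 + 0.13)

  # infinite-avidity limit
  glued <- kinetic_parameters(3e4, 0.046, 1.4e5, 0.13, 1e9, 1e9)
  expect_lt(effective_dissociation_rate(glued), 1e-8)

  degenerate <- kinetic_parameters(3e4, 0, 1.4e5, 0.13, kC3 = 0, kC4 = 0)
  expect_error(effective_dissociation_rate(degenerate), "positive")
})

test_that("single-site Kds and parameter validation behave", {
  p <- default_params()
  kd <- single_site_kds(p)
  expect_equal(kd[["Kd3"]], 0.046 / 3.0e4)
  expect_equal(kd[["Kd4"]], 0.13 / 1.4e5)
  expect_error(kinetic_parameters(-1, 0.1, 1, 0.1), "non-negative")
  expect_error(kinetic_parameters(Inf, 0.1, 1, 0.1), "finite")
  expect_error(single_site_kds(kinetic_parameters(0, 0.1, 1, 0.1)),
               "positive")
})

test_that("parameter sets round-trip through unit-tagged JSON and YAML", {
  p <- kinetic_parameters(3.0e4, 0.046, 1.4e5, 0.13, 2.1357, 9.9667)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_parameters(p, path)
    q <- read_parameters(path)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  }
})
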