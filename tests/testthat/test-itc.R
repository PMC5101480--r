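test_that("thermodynamic interconversion honours all identities", {
  p <- derive_thermo(dH = -3.37, K_d = 16.1, T = 298)
  expect_equal(p$K_b, 1 / (16.1e-6), tolerance = 1e-9)
  expect_equal(p$dG, p$dH - p$T * p$dS / 1000, tolerance = 1e-9)
  expect_equal(p$dG, -1.9872e-3 * p$T * log(p$K_b), tolerance = 1e-9)

  # round trip: (dH, K_d) -> dS; (dH, dS) -> K_d returns the original
  p2 <- derive_thermo(dH = -3.37, dS = p$dS, T = 298)
  expect_equal(p2$K_d, 16.1, tolerance = 1e-9)
  p3 <- derive_thermo(K_d = 16.1, dS = p$dS, T = 298)
  expect_equal(p3$dH, -3.37, tolerance = 1e-9)

  # K_b = 1 (K_d = 1 M) has zero free energy
  expect_equal(derive_thermo(dH = -3, K_d = 1e6, T = 298)$dG, 0,
               tolerance = 1e-9)

  expect_error(derive_thermo(dH = -3), "exactly two")
  expect_error(derive_thermo(K_d = 1, dH = -3, dS = 10), "exactly two")
})

test_that("entropy and affinity derived from calorimetric enthalpies match
           the measured complex thermodynamics", {
  # TPR domain + full C-terminal domain: dH -3.37 kcal/mol, dS 10.6
  expect_equal(derive_thermo(dH = -3.37, dS = 10.6, T = 298)$K_d, 16.1,
               tolerance = 0.05)
  expect_equal(derive_thermo(dH = -3.37, K_d = 16.1, T = 298)$dS, 10.6,
               tolerance = 0.05)
  # TPR domain + pentapeptide: dH -4.97 kcal/mol, dS 2.34
  expect_equal(derive_thermo(dH = -4.97, dS = 2.34, T = 298)$K_d, 71.9,
               tolerance = 0.10)
})

test_that("simulated thermograms honour limiting-case oracles", {
  prot <- itc_protocol(cell_conc = 50, syringe_conc = 1000,
                       cell_volume = 200, injection_volumes = rep(2, 20))
  # zero enthalpy: only the dilution offset remains
  p0 <- derive_thermo(K_d = 16.1, dH = 0, T = 298)
  tg0 <- simulate_injection_heats(p0, prot, dilution_offset = -0.12)
  expect_true(all(abs(tg0$injection_heats + 0.12) < 1e-12))

  # stoichiometric limit: early heats = moles injected x dH = -6.74 ucal
  pt <- derive_thermo(K_d = 1e-3, dH = -3.37, T = 298)
  tgt <- simulate_injection_heats(pt, prot)
  expect_equal(tgt$injection_heats[1:3], rep(-6.74, 3), tolerance = 0.01)

  # saturation tail carries no heat
  expect_lt(abs(tgt$injection_heats[20]), 0.05)
})

test_that("cumulative heat converges to the cell's total binding enthalpy", {
  prot <- itc_protocol(50, 1000, 200, rep(2, 40))
  pt <- derive_thermo(K_d = 1e-3, dH = -3.37, T = 298)
  tg <- simulate_injection_heats(pt, prot)
  csum <- cumsum(tg$injection_heats)
  target <- -3.37 * 50 * 200 * 1e-3               # n dH P0 V0 = -33.7 ucal
  # monotone approach, never overshooting the total; the post-saturation
  # tail may drift by O((dv/V0)^2) per injection, the order to which the
  # mean-concentration displacement correction is exact
  drift <- abs(-3.37 * 50 * 200 * 1e-3) * (2 / 200)^2
  expect_true(all(diff(abs(csum)) >= -drift))
  expect_true(all(abs(csum) <= abs(target) + 1e-6))

  # independent bookkeeping oracle for the perfusion cell in the
  # stoichiometric limit: titrant binds instantly, each injection first
  # displaces a mixed average of cell contents; heat tracks moles newly
  # bound inside the cell plus the bound material carried out
  V0 <- 200; dv <- 2
  m <- 50; x <- 0; q_or <- numeric(40)
  for (i in 1:40) {
    f <- 1 - dv / V0
    m2 <- m * f; x2 <- x * f + 1000 * dv / V0
    b1 <- min(m, x); b2 <- min(m2, x2)
    q_or[i] <- -3.37 * V0 * 1e-3 * (b2 - b1 + (dv / V0) * (b2 + b1) / 2)
    m <- m2; x <- x2
  }
  # dilution-corrected comparison: both series agree and their common
  # limit is the total enthalpy minus the heat of protein displaced
  # unbound, which the oracle quantifies
  expect_equal(sum(tg$injection_heats), sum(q_or), tolerance = 0.01)
  expect_equal(sum(tg$injection_heats) / target, 1, tolerance = 0.05)
})

test_that("simulate-then-fit recovers noiseless parameters across c-values", {
  prot <- itc_protocol(50, 1000, 200, rep(2, 20))
  for (cval in c(0.5, 5, 50, 500)) {
    p <- derive_thermo(K_d = 50 / cval, dH = -3.37, T = 298)
    tg <- simulate_injection_heats(p, prot, dilution_offset = -0.05)
    fit <- fit_one_site(tg)
    expect_true(fit$converged)
    expect_equal(fit$params$K_d, 50 / cval, tolerance = 1e-3)
    expect_equal(fit$params$dH, -3.37, tolerance = 1e-3)
    expect_equal(fit$dilution_offset, -0.05, tolerance = 1e-3)
  }
})

test_that("fitted entropy follows from the fitted K_b and dH", {
  prot <- itc_protocol(50, 1000, 200, rep(2, 20))
  p <- derive_thermo(K_d = 16.1, dH = -3.37, T = 298)
  fit <- fit_one_site(simulate_injection_heats(p, prot))
  expect_equal(fit$params$dS, 10.6, tolerance = 0.05 * 10.6)
  expect_equal(fit$params$n, 1)
})

test_that("degenerate thermograms are flagged, not silently fitted", {
  prot <- itc_protocol(50, 1000, 200, rep(2, 20))
  zero <- simulate_injection_heats(derive_thermo(K_d = 16.1, dH = 0), prot)
  fit <- fit_one_site(zero)
  expect_false(fit$converged)
  short <- simulate_injection_heats(derive_thermo(K_d = 16.1, dH = -3.37),
                                    itc_protocol(50, 1000, 200, rep(2, 5)))
  expect_error(fit_one_site(short), "at least 5 usable")
})

test_that("thermograms round-trip through CSV and generators are seeded", {
  prot <- itc_protocol(50, 1000, 200, rep(2, 20))
  p <- derive_thermo(K_d = 16.1, dH = -3.37, T = 298)
  tg <- gen_itc_thermogram(p, prot, noise_q = 0.05, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_thermogram(tg, f)
  back <- read_thermogram(f, prot)
  expect_equal(back$injection_heats, tg$injection_heats)

  # seed contract: same seed identical, different seeds differ,
  # zero noise equals the deterministic simulation
  expect_identical(gen_itc_thermogram(p, prot, 0.05, seed = 8)$injection_heats,
                   tg$injection_heats)
  expect_false(identical(
    gen_itc_thermogram(p, prot, 0.05, seed = 9)$injection_heats,
    tg$injection_heats))
  expect_identical(gen_itc_thermogram(p, prot, 0, seed = 1)$injection_heats,
                   simulate_injection_heats(p, prot)$injection_heats)
})

test_that("protocol validation rejects unphysical settings", {
  expect_error(itc_protocol(-1, 1000), "cell_conc")
  expect_error(itc_protocol(50, 1000, temperature = 500), "temperature")
  expect_error(itc_protocol(50, 1000, injection_volumes = c(1, 0)), "positive")
})
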