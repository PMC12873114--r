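# Closed-form steady states, regime classification, stabilisation bound,
# and back-calculation of r and krem_M.

test_that("closed-form steady states match hand arithmetic in each branch", {
  # reassociation: Tst = r/krem_T, Mst = (kd*Tst/ka)^(1/4)
  st <- steady_state_closed_form(table1_reassoc(), "reassociation_dominated")
  expect_equal(unname(st["T"]), 6.44, tolerance = 1e-12)
  expect_equal(unname(st["M"]), MST_REASSOC, tolerance = 1e-12)

  # degradation: Tst = r/(krem_T + kd), Mst = 4*kd*Tst/krem_M
  pd <- table1_degradation() # r = 6.44 * 0.0184, krem_M = 100
  std <- steady_state_closed_form(pd, "degradation_dominated")
  expect_equal(unname(std["T"]), 6.44, tolerance = 1e-12)
  expect_equal(unname(std["M"]), 4 * 0.0024 * 6.44 / 100, tolerance = 1e-12)
  expect_equal(unname(std["M"]), 6.18e-4, tolerance = 1e-3)

  # intermediate: Tst = r/(krem_T + 0.5*kd), Mst = (0.5*kd*Tst/ka)^(1/4)
  pi_ <- ttr_parameters(r = 6.44 * (0.016 + 0.5 * 0.0024), kd = 0.0024,
                        ka = 3.6e5, krem_T = 0.016, krem_M = 1)
  sti <- steady_state_closed_form(pi_, "intermediate")
  expect_equal(unname(sti["T"]), 6.44, tolerance = 1e-12)
  expect_equal(unname(sti["M"]), (0.5 * 0.0024 * 6.44 / 3.6e5)^0.25,
               tolerance = 1e-12)

  # kd = 0: all branches coincide at Mst = 0, Tst = r/krem_T
  p0 <- ttr_parameters(r = 0.1, kd = 0, ka = 3.6e5, krem_T = 0.016, krem_M = 1)
  for (rg in ttr_regimes()) {
    s <- steady_state_closed_form(p0, rg)
    expect_equal(unname(s["T"]), 0.1 / 0.016)
    expect_equal(unname(s["M"]), 0)
  }

  expect_error(
    steady_state_closed_form(table1(krem_M = 0), "degradation_dominated"),
    "krem_M")
})

test_that("deep-regime closed forms agree with the numeric steady state to < 1%", {
  # deep reassociation (krem_M = 0 and small-but-positive krem_M)
  for (km in c(0, 1e-3)) {
    p <- ttr_table1(krem_M = km, r = 0.016 * 6.44)
    num <- steady_state_numeric(p)
    cf <- steady_state_closed_form(p, "reassociation_dominated")
    ratio <- classify_regime(p, num)$diagnostics["flux_ratio"]
    expect_true(ratio >= 1e3)
    expect_lt(abs(cf["T"] - num["T"]) / num["T"], 0.01)
    expect_lt(abs(cf["M"] - num["M"]) / num["M"], 0.01)
  }
  # deep degradation
  pd <- table1_degradation()
  num <- steady_state_numeric(pd)
  cf <- steady_state_closed_form(pd, "degradation_dominated")
  expect_lt(classify_regime(pd, num)$diagnostics["flux_ratio"], 1e-3)
  expect_lt(abs(cf["T"] - num["T"]) / num["T"], 0.01)
  expect_lt(abs(cf["M"] - num["M"]) / num["M"], 0.01)
})

test_that("flux-ratio classification identifies the three regimes", {
  # zero removal flux: infinite ratio, reassociation-dominated
  p <- table1_reassoc()
  cl <- classify_regime(p, ttr_state(6.44, MST_REASSOC))
  expect_identical(cl$regime, "reassociation_dominated")
  expect_identical(unname(cl$diagnostics["flux_ratio"]), Inf)
  expect_false(cl$degenerate)

  # degradation-dominated at its own steady state: tiny ratio
  pd <- table1_degradation()
  cld <- classify_regime(pd, steady_state_numeric(pd))
  expect_identical(cld$regime, "degradation_dominated")
  expect_equal(unname(cld$diagnostics["flux_ratio"]), 3.4e-6, tolerance = 0.02)

  # constructed equality 4*ka*M^3 = krem_M: ratio exactly 1 -> intermediate
  M <- 0.01
  km <- 4 * 3.6e5 * M^3
  pi_ <- ttr_parameters(r = 0.1, kd = 0.0024, ka = 3.6e5, krem_T = 0.016,
                        krem_M = km)
  cli <- classify_regime(pi_, ttr_state(1, M), threshold = 10)
  expect_identical(cli$regime, "intermediate")
  expect_equal(unname(cli$diagnostics["flux_ratio"]), 1)

  # degenerate: no monomers and no removal path
  cld0 <- classify_regime(table1(krem_M = 0), ttr_state(1, 0))
  expect_true(cld0$degenerate)
  expect_identical(cld0$regime, "reassociation_dominated")

  expect_error(classify_regime(p, ttr_state(1, 0.01), threshold = 0.5), ">= 1")
})

test_that("perfect-stabilisation gain is kd/krem_T, halved, or zero by regime", {
  expect_equal(stabilisation_gain(0.0024, 0.016, "degradation_dominated"), 0.15)
  expect_equal(stabilisation_gain(0.0024, 0.016, "intermediate"), 0.075)
  expect_equal(stabilisation_gain(0.0024, 0.016, "reassociation_dominated"), 0)
  expect_equal(stabilisation_gain(0.01, 0.016, "degradation_dominated"), 0.625)
  expect_error(stabilisation_gain(0.0024, 0, "intermediate"), "positive")
})

test_that("the gain bound dominates any finite stabiliser effect and ignores r", {
  kd <- 0.0024; krem_T <- 0.016
  bound <- stabilisation_gain(kd, krem_T, "degradation_dominated")
  for (kd_eff in c(0.9, 0.5, 0.1, 0.01, 1e-4) * kd) {
    realized <- (krem_T + kd) / (krem_T + kd_eff) - 1
    expect_lt(realized, bound)
    expect_gt(realized, 0)
  }
  # r-independence, checked numerically through the closed forms
  for (r in c(0.01, 0.1, 1)) {
    p1 <- ttr_parameters(r = r, kd = kd, ka = 3.6e5, krem_T = krem_T,
                         krem_M = 100)
    p0 <- ttr_parameters(r = r, kd = 0, ka = 3.6e5, krem_T = krem_T,
                         krem_M = 100)
    T1 <- steady_state_closed_form(p1, "degradation_dominated")["T"]
    T0 <- steady_state_closed_form(p0, "degradation_dominated")["T"]
    expect_equal(unname(T0 / T1 - 1), bound, tolerance = 1e-12)
  }
})

test_that("back-calculated rates reproduce the literature values", {
  # reassociation branch: r = krem_T * Tst = 0.10304 (printed as 0.1)
  ra <- infer_rates("reassociation_dominated", Tst = 6.44, krem_T = 0.016,
                    kd = 0.0024)
  expect_equal(ra$r, 0.10304, tolerance = 1e-12)
  expect_equal(round(ra$r, 1), 0.1)
  expect_true(is.na(ra$krem_M)) # negligible, explicitly absent

  # degradation branch: r = Tst*(krem_T + kd), krem_M = 4*kd*Tst/Mst
  rd <- infer_rates("degradation_dominated", Tst = 6.44, Mst = 6.1824e-4,
                    krem_T = 0.016, kd = 0.0024)
  expect_equal(rd$r, 6.44 * 0.0184, tolerance = 1e-12)
  expect_equal(rd$krem_M, 100, tolerance = 1e-10)

  expect_error(infer_rates("degradation_dominated", Tst = 6.44,
                           krem_T = 0.016, kd = 0.0024), "Mst")
})

test_that("infer_rates and closed-form steady states are mutual inverses", {
  kd <- 0.0024; ka <- 3.6e5; krem_T <- 0.016
  targets <- list(c(6.44, NA), c(3.2, NA), c(10, NA))
  for (rg in ttr_regimes()) {
    for (Tst in c(3.2, 6.44, 10)) {
      # construct a consistent observed pair from the branch's own formulas
      Mst <- switch(rg,
        reassociation_dominated = (kd * Tst / ka)^0.25,
        degradation_dominated = 4 * kd * Tst / 50,
        intermediate = (0.5 * kd * Tst / ka)^0.25)
      inf <- infer_rates(rg, Tst = Tst, Mst = Mst, krem_T = krem_T, kd = kd)
      p <- ttr_parameters(r = inf$r, kd = kd, ka = ka, krem_T = krem_T,
                          krem_M = if (is.na(inf$krem_M)) 0 else inf$krem_M)
      st <- steady_state_closed_form(p, rg)
      expect_lt(abs(st["T"] - Tst) / Tst, 1e-10)
      expect_lt(abs(st["M"] - Mst) / Mst, 1e-10)
    }
  }
})

test_that("regime report assembles inference, bounds and diagnostics", {
  rep <- regime_report(Tst = 6.44, Mst = 6.1824e-4, krem_T = 0.016,
                       kd = 0.0024, ka = 3.6e5)
  expect_named(rep, ttr_regimes())
  expect_equal(rep$degradation_dominated$gain_bound, 0.15)
  expect_equal(rep$intermediate$gain_bound, 0.075)
  expect_equal(rep$reassociation_dominated$gain_bound, 0)
  expect_equal(rep$reassociation_dominated$r_uM_per_h, 0.10304)
  expect_equal(rep$degradation_dominated$krem_M_per_h, 100, tolerance = 1e-10)
  expect_output(print(rep), "gain bound = 15.0%")
})
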