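# Subunit-exchange assay: species kinetics, conservation, binomial
# equilibrium, kd estimation.

test_that("exchange RHS conserves subunits and respects label closure", {
  kd <- 0.0024; ka <- 3.6e5
  states <- list(
    exchange_state(c(0.5, 0, 0, 0, 0.5)),
    exchange_state(c(0.1, 0.2, 0.3, 0.2, 0.1), 0.01, 0.02),
    exchange_state(c(0, 0, 0, 0, 1), 0.05, 0))
  for (s in states) {
    d <- exchange_rhs(s, kd, ka)
    # total subunits: sum(4*dT_i) + dM_L + dM_U = 0
    expect_equal(unname(4 * sum(d[1:5]) + d[6] + d[7]), 0, tolerance = 1e-12)
    # labelled subunits: sum(i*dT_i) + dM_L = 0
    expect_equal(unname(sum((0:4) * d[1:5]) + d[6]), 0, tolerance = 1e-12)
  }

  # an all-labelled pool cannot create unlabelled species
  s4 <- exchange_state(c(0, 0, 0, 0, 1), 0.05, 0)
  d <- exchange_rhs(s4, kd, ka)
  expect_equal(unname(d[7]), 0)              # dM_U
  expect_true(all(d[1:4] == 0))              # T0..T3 untouched

  expect_error(exchange_rhs(exchange_state(c(1, 0, 0, 0, 0)), -1, ka),
               "nonnegative")
})

test_that("label-exchange symmetry keeps M_L = M_U from a symmetric start", {
  sim <- simulate_exchange(0.0024, 3.6e5, equimolar_exchange_init(1),
                           times = c(0, 10^seq(0, 3.5, by = 0.25)))
  expect_equal(sim$M_L_uM, sim$M_U_uM, tolerance = 1e-9)
})

test_that("conservation sums drift by less than 1e-8 over 1e4 hours", {
  init <- exchange_state(c(0.2, 0, 0.1, 0, 0.7), 0.01, 0.03)
  sim <- simulate_exchange(0.0024, 3.6e5, init,
                           times = c(0, 10^seq(-1, 4, by = 0.25)),
                           rtol = 1e-11, atol = 1e-14)
  Tcols <- paste0("T", 0:4, "_uM")
  total <- 4 * rowSums(sim[, Tcols]) + sim$M_L_uM + sim$M_U_uM
  lab <- as.matrix(sim[, Tcols]) %*% (0:4) + sim$M_L_uM
  expect_lt(max(abs(total - total[1])) / total[1], 1e-8)
  expect_lt(max(abs(lab - lab[1])) / lab[1], 1e-8)
})

test_that("no exchange happens without dissociation", {
  init <- equimolar_exchange_init(1)
  sim <- simulate_exchange(0, 3.6e5, init, times = seq(0, 1000, by = 100))
  expect_equal(sim$f_T0, rep(0.5, nrow(sim)))
  expect_equal(sim$f_T4, rep(0.5, nrow(sim)))
  expect_true(all(sim$f_T1 == 0 & sim$f_T2 == 0 & sim$f_T3 == 0))
})

test_that("equilibrium species distribution is Binomial(4, labelled fraction)", {
  # the stationary distribution of drawing 4 subunits from a well-mixed pool
  # with labelled fraction p* is the independent oracle here
  starts <- list(
    list(init = exchange_state(c(0.75, 0, 0, 0, 0.25)), p = 0.25),
    list(init = equimolar_exchange_init(1), p = 0.5),
    list(init = exchange_state(c(0.25, 0, 0, 0, 0.75)), p = 0.75))
  for (s in starts) {
    sim <- simulate_exchange(0.0024, 3.6e5, s$init, times = c(0, 2000, 8000))
    eq <- unlist(sim[nrow(sim), paste0("f_T", 0:4)])
    expect_equal(unname(eq), dbinom(0:4, 4, s$p), tolerance = 1e-4)
  }
})

test_that("mixed-species appearance time scales inversely with kd", {
  init <- equimolar_exchange_init(1)
  half_time <- function(kd) {
    tt <- seq(0, 2400, by = 4)
    sim <- simulate_exchange(kd, 3.6e5, init, tt)
    mixed <- sim$f_T1 + sim$f_T2 + sim$f_T3
    eq <- 14 / 16 # binomial equilibrium mixed fraction at p = 1/2
    tt[which(mixed >= eq / 2)[1]]
  }
  t1 <- half_time(0.0024)
  t2 <- half_time(0.0048)
  expect_equal(t1 / t2, 2, tolerance = 0.05)
})

test_that("equilibrium free-monomer level matches the reassociation closed form", {
  # closed system: M_total ~ (kd*T_total/ka)^(1/4), well below 1% of subunits
  init <- equimolar_exchange_init(6.44)
  sim <- simulate_exchange(0.0024, 3.6e5, init, times = c(0, 4000, 8000))
  last <- nrow(sim)
  M_tot <- sim$M_L_uM[last] + sim$M_U_uM[last]
  T_tot <- sum(sim[last, paste0("T", 0:4, "_uM")])
  expect_equal(M_tot, (0.0024 * T_tot / 3.6e5)^0.25, tolerance = 1e-3)
  expect_lt(M_tot / (4 * T_tot), 0.01)
})

test_that("kd is recovered from a noiseless course to optimizer tolerance", {
  init <- equimolar_exchange_init(1)
  tt <- c(0, 25 * (1:20))
  sim <- simulate_exchange(0.0024, 3.6e5, init, tt)
  est <- estimate_kd(sim, 3.6e5, init)
  expect_equal(est$kd, 0.0024, tolerance = 1e-3)
  expect_lt(est$rss, 1e-8)
})

test_that("a course already at equilibrium is rejected as unidentifiable", {
  init <- equimolar_exchange_init(1)
  eqrow <- simulate_exchange(0.0024, 3.6e5, init, c(0, 20000, 20100, 20200,
                                                    20300))
  flat <- eqrow[-1, ]
  flat$time_h <- flat$time_h - flat$time_h[1]
  expect_error(estimate_kd(flat, 3.6e5, init), "unidentifiable")
})

test_that("exchange courses measured across stabiliser doses recover lambda", {
  # full loop: concentration -> effective kd -> assay course -> kd estimate
  # -> lambda fit
  rel <- rel_tafamidis()
  init <- equimolar_exchange_init(1)
  cs <- c(0, 5, 10, 20)
  kd_hat <- vapply(cs, function(cc) {
    kd_true <- kd_of_concentration(rel, cc)
    tt <- c(0, seq(50, 4000, length.out = 20))
    sim <- simulate_exchange(kd_true, 3.6e5, init, tt)
    estimate_kd(sim, 3.6e5, init)$kd
  }, 0)
  fit <- fit_lambda(data.frame(c1_uM = cs, kd_per_h = kd_hat))
  expect_equal(fit$lambda, 0.112, tolerance = 0.02)
})

test_that("exchange course CSV writer emits the documented columns", {
  sim <- simulate_exchange(0.0024, 3.6e5, equimolar_exchange_init(1),
                           c(0, 100, 200))
  f <- tempfile(fileext = ".csv")
  write_exchange_course(sim, f)
  x <- utils::read.csv(f)
  expect_named(x, c("time_h", paste0("f_T", 0:4), "M_L_uM", "M_U_uM"))
})
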