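# Shared fixtures: literature reference parameterisations and small utilities.

table1 <- function(krem_M = 0, r = 0.1) ttr_table1(krem_M = krem_M, r = r)

# self-consistent reassociation-regime parameter set (r = krem_T * Tst)
table1_reassoc <- function() ttr_table1(krem_M = 0, r = 0.016 * 6.44)

# degradation-dominated parameter set implied by the same observables
table1_degradation <- function() {
  ttr_parameters(r = 6.44 * (0.016 + 0.0024), kd = 0.0024, ka = 360000,
                 krem_T = 0.016, krem_M = 100)
}

TST_REF <- 6.44
MST_REASSOC <- (0.0024 * 6.44 / 360000)^0.25  # closed-form oracle, Eq.-10 type

rel_tafamidis <- function() stabiliser_relation(kd0 = 0.0024, lam = 0.112)

pk_truth <- function() default_pk_truth()

# trapezoid integral used as an independent averaging oracle
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# geometric grid reaching deep into steady state
ss_times <- function(t_end = 5000, n = 40) c(0, 10^seq(-2, log10(t_end), length.out = n))
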