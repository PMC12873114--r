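#' Two-compartment oral PK parameters
#'
#' First-order absorption from the gastro-intestinal tract into a central
#' (plasma) compartment of volume `V`, exchange with a peripheral compartment,
#' and first-order elimination from the central compartment. The peripheral
#' compartment is written in the same concentration units as the central one
#' (V2 implicitly equal to V), exactly as the model equations are stated;
#' conservation diagnostics therefore use V for both compartments.
#'
#' @param kAbs Absorption rate, 1/h.
#' @param k12,k21 Central-to-peripheral and peripheral-to-central transfer
#'   rates, 1/h.
#' @param kEl Elimination rate from the central compartment, 1/h.
#' @param V Central (plasma) volume, mL. Default 3000 mL (3/5 of 5 L blood).
#' @param M_drug Drug molecular weight, g/mol. Default tafamidis, 308.11.
#' @return Object of class `pk_parameters`.
#' @export
pk_parameters <- function(kAbs, k12, k21, kEl, V = 3000, M_drug = 308.11) {
  rates <- c(kAbs = kAbs, k12 = k12, k21 = k21, kEl = kEl)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and nonnegative", call. = FALSE)
  }
  if (!is.finite(V) || V <= 0) stop("V must be positive", call. = FALSE)
  if (!is.finite(M_drug) || M_drug <= 0) {
    stop("M_drug must be positive", call. = FALSE)
  }
  structure(list(kAbs = kAbs, k12 = k12, k21 = k21, kEl = kEl, V = V,
                 M_drug = M_drug),
            class = "pk_parameters")
}

#' Oral dosing regimen
#'
#' @param dose_mg Drug mass per administration, mg.
#' @param times_of_doses_h Dose times, hours; nonnegative, strictly
#'   increasing, within `duration_h`.
#' @param duration_h Total simulated duration, hours.
#' @return Object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose_mg, times_of_doses_h, duration_h) {
  if (!is.finite(dose_mg) || dose_mg <= 0) {
    stop("dose_mg must be positive", call. = FALSE)
  }
  t <- times_of_doses_h
  if (length(t) < 1 || any(!is.finite(t)) || any(t < 0)) {
    stop("dose times must be nonnegative", call. = FALSE)
  }
  if (any(duplicated(t))) stop("duplicate dose times", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("dose times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(duration_h) || duration_h <= max(t)) {
    stop("duration_h must exceed the last dose time", call. = FALSE)
  }
  structure(list(dose_mg = dose_mg, times_of_doses_h = t,
                 duration_h = duration_h),
            class = "dose_regimen")
}

#' Standard once-daily regimen (default: 61 mg tafamidis free acid)
#' @param dose_mg Dose per administration, mg.
#' @param n_days Number of daily doses.
#' @param interval_h Dosing interval, hours.
#' @export
daily_regimen <- function(dose_mg = 61, n_days = 7, interval_h = 24) {
  dose_regimen(dose_mg, seq(0, by = interval_h, length.out = n_days),
               n_days * interval_h)
}

#' Right-hand side of the two-compartment oral PK model
#'
#' dm_GI/dt = -kAbs*m_GI;
#' dc1/dt = kAbs*m_GI/V + k21*c2 - (k12 + kEl)*c1;
#' dc2/dt = k12*c1 - k21*c2.
#'
#' @param state Numeric vector `c(m_GI, c1, c2)`: GI drug mass (mg) and
#'   central/peripheral concentrations (mg/mL).
#' @param params A [pk_parameters()] object.
#' @return Named derivative vector, same ordering.
#' @export
pk_rhs <- function(state, params) {
  stopifnot(inherits(params, "pk_parameters"))
  s <- unclass(state)
  if (length(s) != 3 || any(!is.finite(s)) || any(s < 0)) {
    stop("state must be three finite nonnegative values", call. = FALSE)
  }
  c(dm_GI = -params$kAbs * s[[1]],
    dc1 = params$kAbs * s[[1]] / params$V + params$k21 * s[[3]] -
      (params$k12 + params$kEl) * s[[2]],
    dc2 = params$k12 * s[[2]] - params$k21 * s[[3]])
}

.pk_deriv <- function(t, y, p) {
  list(c(-p$kAbs * y[[1]],
         p$kAbs * y[[1]] / p$V + p$k21 * y[[3]] - (p$k12 + p$kEl) * y[[2]],
         p$k12 * y[[2]] - p$k21 * y[[3]]))
}

#' Simulate plasma drug concentration under a dosing regimen
#'
#' Each dose is an instantaneous bolus added to the GI compartment; between
#' doses the linear system is integrated with lsoda. Central concentration is
#' reported both as mass concentration (ug/mL) and molar (uM, via `M_drug`).
#'
#' @param params A [pk_parameters()] object.
#' @param regimen A [dose_regimen()].
#' @param times Output time grid, hours (within the regimen duration).
#' @param rtol,atol Solver tolerances.
#' @return data.frame `time_h, m_GI_mg, c1_ug_per_mL, c2_ug_per_mL, c1_uM,
#'   c2_uM`.
#' @export
simulate_pk <- function(params, regimen, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dose_regimen"))
  if (any(times < 0) || any(times > regimen$duration_h)) {
    stop("times must lie within the regimen duration", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  doses <- regimen$times_of_doses_h
  y0 <- c(m_GI = 0, c1 = 0, c2 = 0)
  if (doses[1] == 0) {
    y0["m_GI"] <- regimen$dose_mg
    doses <- doses[-1]
  }
  grid <- sort(unique(c(0, times, doses)))
  ev <- if (length(doses)) {
    list(data = data.frame(var = "m_GI", time = doses,
                           value = regimen$dose_mg, method = "add"))
  } else NULL
  out <- deSolve::lsoda(y = y0, times = grid, func = .pk_deriv, parms = params,
                        rtol = rtol, atol = atol, events = ev)
  .check_desolve(out, length(grid), "PK integration")
  res <- as.data.frame(out)
  res <- res[match(times, res$time), , drop = FALSE]
  data.frame(time_h = res$time,
             m_GI_mg = pmax(res$m_GI, 0),
             c1_ug_per_mL = pmax(res$c1, 0) * 1000,
             c2_ug_per_mL = pmax(res$c2, 0) * 1000,
             c1_uM = pmax(res$c1, 0) / params$M_drug * 1e6,
             c2_uM = pmax(res$c2, 0) / params$M_drug * 1e6,
             row.names = NULL)
}

#' Fit the two-compartment PK model to a plasma concentration profile
#'
#' Nonlinear least squares on the central concentration (Levenberg-Marquardt,
#' rates bounded to [1e-6, 100] 1/h). The central volume V is conventionally
#' held fixed (it only rescales dose to concentration and is not identifiable
#' from concentration data alone).
#'
#' @param data data.frame with columns `time_h` and `c1_ug_per_mL` (>= 5 rows).
#' @param regimen The [dose_regimen()] under which the data were collected.
#' @param init_guess Starting [pk_parameters()]; default kAbs = 1,
#'   k12 = k21 = 0.1, kEl = 0.01 (1/h).
#' @param fixed Names of rate parameters to hold at their `init_guess` value
#'   (V and M_drug are always fixed).
#' @return List: `params` (fitted [pk_parameters()]), `rss`, `sigma`,
#'   `se` (per-parameter standard errors), `convergence` message.
#' @export
fit_pk <- function(data, regimen,
                   init_guess = pk_parameters(kAbs = 1, k12 = 0.1, k21 = 0.1,
                                              kEl = 0.01),
                   fixed = character()) {
  if (!all(c("time_h", "c1_ug_per_mL") %in% names(data))) {
    stop("data must have columns time_h,c1_ug_per_mL", call. = FALSE)
  }
  if (nrow(data) < 5) stop("need at least 5 data points", call. = FALSE)
  if (all(data$c1_ug_per_mL == 0)) {
    stop("degenerate data: all concentrations are zero", call. = FALSE)
  }
  data <- data[order(data$time_h), ]
  rate_names <- c("kAbs", "k12", "k21", "kEl")
  free <- setdiff(rate_names, fixed)
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)
  start <- unlist(init_guess[rate_names])

  predict_c1 <- function(theta) {
    full <- start
    full[free] <- theta
    p <- pk_parameters(kAbs = full[["kAbs"]], k12 = full[["k12"]],
                       k21 = full[["k21"]], kEl = full[["kEl"]],
                       V = init_guess$V, M_drug = init_guess$M_drug)
    sim <- simulate_pk(p, regimen, times = sort(unique(data$time_h)),
                       rtol = 1e-8, atol = 1e-10)
    sim$c1_ug_per_mL[match(data$time_h, sim$time_h)]
  }
  resid_fn <- function(theta) data$c1_ug_per_mL - predict_c1(theta)

  fit <- minpack.lm::nls.lm(par = start[free], fn = resid_fn,
                            lower = rep(1e-6, length(free)),
                            upper = rep(1e2, length(free)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 5, 9)) {
    stop("PK fit did not converge (", fit$message, "); last iterate: ",
         paste(sprintf("%s=%.4g", free, fit$par), collapse = ", "),
         call. = FALSE)
  }
  est <- start
  est[free] <- fit$par
  dof <- nrow(data) - length(free)
  rss <- sum(fit$fvec^2)
  sigma2 <- if (dof > 0) rss / dof else NA_real_
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- rep(NA_real_, length(free))
  names(se) <- free
  if (!is.null(covm) && all(diag(covm) >= 0)) {
    se[] <- sqrt(diag(covm))
    # Flat residual surface along the k12/k21 exchange direction means the
    # two transfer rates are mutually unidentifiable from this profile.
    if (all(c("k12", "k21") %in% free)) {
      cr <- covm["k12", "k21"] / sqrt(covm["k12", "k12"] * covm["k21", "k21"])
      if (is.finite(cr) && abs(cr) > 0.999) {
        warning("k12 and k21 are nearly unidentifiable from these data ",
                "(parameter correlation ", format(cr, digits = 3), ")",
                call. = FALSE)
      }
    }
  }
  list(params = pk_parameters(kAbs = est[["kAbs"]], k12 = est[["k12"]],
                              k21 = est[["k21"]], kEl = est[["kEl"]],
                              V = init_guess$V, M_drug = init_guess$M_drug),
       rss = rss, sigma = sqrt(sigma2), se = se, convergence = fit$message)
}

#' Interval-average steady-state plasma concentration (uM)
#'
#' For repeated dosing of a linear model with complete oral absorption the
#' dosing-interval average of the central concentration at periodic steady
#' state is `F*D/(CL*tau)` with F = 1 and CL = kEl*V, independent of
#' absorption and distribution rates.
#'
#' @param params A [pk_parameters()] with `kEl > 0`.
#' @param regimen A [dose_regimen()] with equal dosing intervals.
#' @return Average central concentration at steady state, uM.
#' @export
average_steady_state_c1 <- function(params, regimen) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dose_regimen"))
  if (params$kEl <= 0) {
    stop("kEl must be positive: no steady state without elimination",
         call. = FALSE)
  }
  t <- regimen$times_of_doses_h
  tau <- if (length(t) > 1) unique(round(diff(t), 10)) else
    regimen$duration_h - t[1]
  if (length(tau) != 1) {
    stop("regimen must have a single fixed dosing interval", call. = FALSE)
  }
  avg_mg_per_mL <- regimen$dose_mg / (params$kEl * params$V * tau)
  avg_mg_per_mL / params$M_drug * 1e6
}

#' Write / read PK simulation output as CSV
#' (`time_h,m_GI_mg,c1_uM,c2_uM`)
#' @param pk_table Output of [simulate_pk()].
#' @param path File path.
#' @export
write_pk_table <- function(pk_table, path) {
  utils::write.csv(pk_table[, c("time_h", "m_GI_mg", "c1_uM", "c2_uM")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plasma concentration profile CSV (`time_h,c1_ug_per_mL`)
#' @param path File path.
#' @export
read_pk_profile <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_h", "c1_ug_per_mL") %in% names(x))) {
    stop("profile CSV must have columns time_h,c1_ug_per_mL", call. = FALSE)
  }
  x
}
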