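#' Monomer-fate regimes
#'
#' At steady state two fluxes remove free monomers from circulation:
#' reassociation into tetramers (4*ka*Mst^4) and first-order elimination
#' (krem_M*Mst). Which flux dominates determines the closed-form steady state
#' and how much the tetramer level can respond to kinetic stabilisation.
#'
#' @return Character vector of the three valid regime labels.
#' @export
ttr_regimes <- function() {
  c("reassociation_dominated", "degradation_dominated", "intermediate")
}

.check_regime <- function(regime) {
  if (!is.character(regime) || length(regime) != 1 ||
      !regime %in% ttr_regimes()) {
    stop("regime must be one of: ", paste(ttr_regimes(), collapse = ", "),
         call. = FALSE)
  }
  regime
}

#' Closed-form steady state for a given monomer-fate regime
#'
#' Reassociation-dominated (krem_M negligible): `Tst = r/krem_T`,
#' `Mst = (kd*Tst/ka)^(1/4)`. Degradation-dominated (reassociation
#' negligible): `Tst = r/(krem_T + kd)`, `Mst = 4*kd*Tst/krem_M`.
#' Intermediate (fluxes split 50/50): `Tst = r/(krem_T + 0.5*kd)`,
#' `Mst = (0.5*kd*Tst/ka)^(1/4)`.
#'
#' @param params A [ttr_parameters()] object.
#' @param regime One of [ttr_regimes()].
#' @return A [ttr_state()].
#' @export
steady_state_closed_form <- function(params, regime) {
  stopifnot(inherits(params, "ttr_parameters"))
  .check_regime(regime)
  if (params$kd == 0) {
    if (params$krem_T <= 0) stop("krem_T must be positive when kd = 0",
                                 call. = FALSE)
    return(ttr_state(params$r / params$krem_T, 0))
  }
  switch(regime,
    reassociation_dominated = {
      if (params$krem_T <= 0) stop("krem_T must be positive", call. = FALSE)
      if (params$ka <= 0) stop("ka must be positive", call. = FALSE)
      Tst <- params$r / params$krem_T
      ttr_state(Tst, (params$kd * Tst / params$ka)^0.25)
    },
    degradation_dominated = {
      if (params$krem_M <= 0) {
        stop("krem_M must be positive in the degradation-dominated branch",
             call. = FALSE)
      }
      Tst <- params$r / (params$krem_T + params$kd)
      ttr_state(Tst, 4 * params$kd * Tst / params$krem_M)
    },
    intermediate = {
      if (params$ka <= 0) stop("ka must be positive", call. = FALSE)
      Tst <- params$r / (params$krem_T + 0.5 * params$kd)
      ttr_state(Tst, (0.5 * params$kd * Tst / params$ka)^0.25)
    }
  )
}

#' Classify the monomer-fate regime at a (steady) state
#'
#' Compares the reassociation flux 4*ka*M^4 against the removal flux krem_M*M.
#' A flux ratio above `threshold` is called reassociation-dominated, below
#' `1/threshold` degradation-dominated, otherwise intermediate. The default
#' threshold of 10 (one decade) is the conventional dominance margin: each
#' limiting closed form neglects one flux, which is safe at a 10-fold ratio.
#'
#' @param params A [ttr_parameters()] object.
#' @param state The steady [ttr_state()] to classify (caller's responsibility
#'   that it is a steady state).
#' @param threshold Dominance margin, >= 1.
#' @return List with elements `regime`, `diagnostics` (reassociation_flux,
#'   removal_flux, flux_ratio, all uM/h except the dimensionless ratio) and
#'   `degenerate` (TRUE when M = 0 and krem_M = 0 so neither flux exists).
#' @export
classify_regime <- function(params, state, threshold = 10) {
  stopifnot(inherits(params, "ttr_parameters"))
  if (!is.numeric(threshold) || threshold < 1) {
    stop("threshold must be >= 1", call. = FALSE)
  }
  M <- unclass(state)[[2]]
  if (M < 0) stop("state must be nonnegative", call. = FALSE)
  reassoc <- 4 * params$ka * M^4
  removal <- params$krem_M * M
  degenerate <- (M == 0 && params$krem_M == 0) || (reassoc == 0 && removal == 0)
  ratio <- if (removal == 0) Inf else reassoc / removal
  regime <- if (degenerate || ratio > threshold) {
    "reassociation_dominated"
  } else if (ratio < 1 / threshold) {
    "degradation_dominated"
  } else {
    "intermediate"
  }
  list(regime = regime,
       diagnostics = c(reassociation_flux = reassoc, removal_flux = removal,
                       flux_ratio = ratio),
       degenerate = degenerate)
}

#' Maximal relative tetramer gain from perfect kinetic stabilisation
#'
#' The relative increase in steady-state tetramer concentration in the limit
#' of abolished dissociation (kd -> 0), `(Tst[kd=0] - Tst[kd]) / Tst[kd]`:
#' `kd/krem_T` in the degradation-dominated regime, half that in the
#' intermediate regime, and exactly 0 in the reassociation-dominated regime
#' where Tst = r/krem_T does not depend on kd. Independent of r in all
#' regimes.
#'
#' @param kd Dissociation rate, 1/h.
#' @param krem_T Tetramer removal rate, 1/h (> 0).
#' @param regime One of [ttr_regimes()].
#' @return Dimensionless fraction (0.15 means a 15% maximal rise).
#' @export
stabilisation_gain <- function(kd, krem_T, regime) {
  .check_regime(regime)
  if (!is.finite(krem_T) || krem_T <= 0) {
    stop("krem_T must be positive", call. = FALSE)
  }
  if (!is.finite(kd) || kd < 0) stop("kd must be nonnegative", call. = FALSE)
  switch(regime,
         degradation_dominated = kd / krem_T,
         intermediate = 0.5 * kd / krem_T,
         reassociation_dominated = 0)
}

#' Back-calculate synthesis and monomer-removal rates from observables
#'
#' Inverts the regime-specific steady-state formulas: given the observed
#' steady tetramer level Tst (and, where needed, monomer level Mst) plus the
#' independently measured krem_T, kd (and ka), solve for the two unmeasured
#' rates r and krem_M. In the reassociation-dominated branch krem_M is
#' negligible by assumption and is returned as `NA` (explicitly absent, not
#' zero). In the intermediate branch each monomer-removal flux carries half
#' of the dissociation flux 4*kd*Tst, so krem_M = 2*kd*Tst/Mst.
#'
#' @param regime One of [ttr_regimes()].
#' @param Tst Observed steady-state tetramer concentration, uM (> 0).
#' @param Mst Observed steady-state monomer concentration, uM; required (> 0)
#'   for the degradation and intermediate branches.
#' @param krem_T Tetramer removal rate, 1/h.
#' @param kd Dissociation rate, 1/h.
#' @param ka Tetramerisation rate, uM^-3/h (used only for reporting).
#' @return List with `r` (uM/h) and `krem_M` (1/h, `NA` when negligible).
#' @export
infer_rates <- function(regime, Tst, Mst = NULL, krem_T, kd, ka = NULL) {
  .check_regime(regime)
  if (!is.finite(Tst) || Tst <= 0) stop("Tst must be positive", call. = FALSE)
  if (regime != "reassociation_dominated") {
    if (is.null(Mst) || !is.finite(Mst) || Mst <= 0) {
      stop("Mst (> 0) is required for the ", regime, " branch", call. = FALSE)
    }
  }
  switch(regime,
    reassociation_dominated = list(r = krem_T * Tst, krem_M = NA_real_),
    degradation_dominated = list(r = Tst * (krem_T + kd),
                                 krem_M = 4 * kd * Tst / Mst),
    intermediate = list(r = Tst * (krem_T + 0.5 * kd),
                        krem_M = 2 * kd * Tst / Mst)
  )
}

#' Regime analysis report
#'
#' Runs the back-calculation and gain bound for each regime at the supplied
#' observables and returns a JSON-serialisable report: the branch formulas,
#' inferred r and krem_M, the stabilisation gain bound, and flux diagnostics
#' at each branch's implied steady state.
#'
#' @param Tst Observed tetramer steady state, uM.
#' @param Mst Observed monomer steady state, uM (for branches that need it).
#' @param krem_T,kd,ka Independently measured rates.
#' @param threshold Dominance margin for [classify_regime()].
#' @return List of per-regime entries, class `regime_report`.
#' @export
regime_report <- function(Tst, Mst, krem_T, kd, ka, threshold = 10) {
  formulas <- c(
    reassociation_dominated = "Tst = r/krem_T; Mst = (kd*Tst/ka)^(1/4)",
    degradation_dominated = "Tst = r/(krem_T + kd); Mst = 4*kd*Tst/krem_M",
    intermediate = "Tst = r/(krem_T + 0.5*kd); Mst = (0.5*kd*Tst/ka)^(1/4)")
  rep <- lapply(ttr_regimes(), function(rg) {
    rates <- infer_rates(rg, Tst = Tst, Mst = Mst, krem_T = krem_T, kd = kd,
                         ka = ka)
    p <- ttr_parameters(r = rates$r, kd = kd, ka = ka, krem_T = krem_T,
                        krem_M = if (is.na(rates$krem_M)) 0 else rates$krem_M)
    st <- steady_state_closed_form(p, rg)
    cls <- classify_regime(p, st, threshold = threshold)
    list(regime = rg, formula = unname(formulas[rg]), r_uM_per_h = rates$r,
         krem_M_per_h = rates$krem_M,
         gain_bound = stabilisation_gain(kd, krem_T, rg),
         Tst_uM = unclass(st)[[1]], Mst_uM = unclass(st)[[2]],
         flux_ratio = unname(cls$diagnostics["flux_ratio"]))
  })
  names(rep) <- ttr_regimes()
  class(rep) <- "regime_report"
  rep
}

#' @export
print.regime_report <- function(x, ...) {
  cat("Regime analysis:\n")
  for (e in x) {
    cat(sprintf("  %-25s r = %.5f uM/h, krem_M = %s /h, gain bound = %.1f%%\n",
                e$regime, e$r_uM_per_h,
                if (is.na(e$krem_M_per_h)) "negligible"
                else format(e$krem_M_per_h, digits = 4),
                100 * e$gain_bound))
  }
  invisible(x)
}
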