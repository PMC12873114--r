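#' Stabiliser concentration -> dissociation rate relation
#'
#' Exponential (Arrhenius-like) phenomenological relation
#' `kd(c1) = kd0 * exp(-lam * c1)` linking total plasma stabiliser
#' concentration to the net tetramer dissociation rate measured by subunit
#' exchange in full plasma. Because the assay reads the net rate directly,
#' the relation absorbs all binding competition (albumin, thyroxine, RBP)
#' without modelling it.
#'
#' @param kd0 Dissociation rate at zero drug, 1/h (> 0). Default 0.0024.
#' @param lam Decay constant, 1/uM (>= 0). Default 0.112 (tafamidis,
#'   physiological temperature).
#' @return Object of class `stabiliser_relation`.
#' @export
stabiliser_relation <- function(kd0 = 0.0024, lam = 0.112) {
  if (!is.finite(kd0) || kd0 <= 0) stop("kd0 must be positive", call. = FALSE)
  if (!is.finite(lam) || lam < 0) stop("lam must be nonnegative", call. = FALSE)
  structure(list(kd0 = kd0, lam = lam), class = "stabiliser_relation")
}

#' Effective dissociation rate at a stabiliser concentration
#'
#' @param rel A [stabiliser_relation()].
#' @param c1 Plasma stabiliser concentration(s), uM (>= 0).
#' @return Effective dissociation rate(s), 1/h.
#' @examples
#' kd_of_concentration(stabiliser_relation(), 25) # ~1.459e-4
#' @export
kd_of_concentration <- function(rel, c1) {
  stopifnot(inherits(rel, "stabiliser_relation"))
  if (any(!is.finite(c1)) || any(c1 < 0)) {
    stop("c1 must be nonnegative", call. = FALSE)
  }
  rel$kd0 * exp(-rel$lam * c1)
}

#' Estimate the decay constant lambda from (concentration, kd) pairs
#'
#' Fits `kd = kd0 * exp(-lam * c1)` to subunit-exchange measurements. By
#' default the fit is on log(kd) (linear regression, slope = -lam), which is
#' variance-stabilising for multiplicative assay error and exact for
#' noiseless model-consistent data; `method = "nls"` performs untransformed
#' least squares instead.
#'
#' @param pairs data.frame with columns `c1_uM` and `kd_per_h`
#'   (>= 2 distinct concentrations, all kd > 0).
#' @param kd0 Either a positive number (held fixed), `"data"` (fixed at the
#'   geometric mean of drug-free measurements when any `c1 == 0` exists,
#'   otherwise co-estimated) or `"free"` (always co-estimated).
#' @param method `"log"` (default) or `"nls"`.
#' @return List: `relation` (a [stabiliser_relation()]), `lambda`, `kd0`,
#'   `se_lambda`, `rss` (residual sum of squares on the fitted scale),
#'   `residuals`, `kd0_fixed`.
#' @export
fit_lambda <- function(pairs, kd0 = "data", method = c("log", "nls")) {
  method <- match.arg(method)
  if (!all(c("c1_uM", "kd_per_h") %in% names(pairs))) {
    stop("pairs must have columns c1_uM,kd_per_h", call. = FALSE)
  }
  c1 <- pairs$c1_uM
  kd <- pairs$kd_per_h
  if (any(!is.finite(c1)) || any(c1 < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("all measured kd must be positive", call. = FALSE)
  }
  if (length(unique(c1)) < 2) {
    stop("lambda is unidentifiable: need at least 2 distinct concentrations",
         call. = FALSE)
  }

  fix_kd0 <- NA_real_
  if (is.numeric(kd0)) {
    if (kd0 <= 0) stop("fixed kd0 must be positive", call. = FALSE)
    fix_kd0 <- kd0
  } else if (identical(kd0, "data")) {
    if (any(c1 == 0)) fix_kd0 <- exp(mean(log(kd[c1 == 0])))
  } else if (!identical(kd0, "free")) {
    stop("kd0 must be a number, \"data\" or \"free\"", call. = FALSE)
  }

  if (method == "log") {
    y <- log(kd)
    if (is.finite(fix_kd0)) {
      # regression through a fixed intercept: lam = -sum(x*(y-b))/sum(x^2)
      x <- c1
      yc <- y - log(fix_kd0)
      lam <- -sum(x * yc) / sum(x^2)
      res <- yc + lam * x
      dof <- length(x) - 1
      se <- sqrt(sum(res^2) / max(dof, 1) / sum(x^2))
      out_kd0 <- fix_kd0
    } else {
      fit <- stats::lm(y ~ c1)
      lam <- -unname(stats::coef(fit)[2])
      se <- unname(sqrt(diag(stats::vcov(fit)))[2])
      res <- stats::residuals(fit)
      out_kd0 <- exp(unname(stats::coef(fit)[1]))
    }
  } else {
    start_lam <- 0.1
    if (is.finite(fix_kd0)) {
      fit <- minpack.lm::nlsLM(kd_per_h ~ fix_kd0 * exp(-lam * c1_uM),
                               data = pairs, start = list(lam = start_lam),
                               lower = 0)
      lam <- unname(stats::coef(fit)["lam"])
      out_kd0 <- fix_kd0
      se <- unname(sqrt(diag(stats::vcov(fit)))["lam"])
    } else {
      fit <- minpack.lm::nlsLM(kd_per_h ~ k0 * exp(-lam * c1_uM), data = pairs,
                               start = list(k0 = max(kd), lam = start_lam),
                               lower = c(1e-12, 0))
      lam <- unname(stats::coef(fit)["lam"])
      out_kd0 <- unname(stats::coef(fit)["k0"])
      se <- unname(sqrt(diag(stats::vcov(fit)))["lam"])
    }
    res <- stats::residuals(fit)
  }
  lam <- max(lam, 0)
  list(relation = stabiliser_relation(kd0 = out_kd0, lam = lam),
       lambda = lam, kd0 = out_kd0, se_lambda = se, rss = sum(res^2),
       residuals = res, kd0_fixed = is.finite(fix_kd0))
}

#' Read (c1, kd) measurement pairs from CSV (`c1_uM,kd_per_h`)
#' @param path File path.
#' @export
read_kd_pairs <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("c1_uM", "kd_per_h") %in% names(x))) {
    stop("pairs CSV must have columns c1_uM,kd_per_h", call. = FALSE)
  }
  x
}

#' Serialise a lambda fit as JSON ({kd0, lambda, se_lambda, rss})
#' @param fit Output of [fit_lambda()].
#' @param path File path.
#' @export
write_lambda_fit <- function(fit, path) {
  jsonlite::write_json(list(kd0 = fit$kd0, lambda = fit$lambda,
                            se_lambda = fit$se_lambda, rss = fit$rss),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
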