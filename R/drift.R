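# Conversion between CCS and ion-mobility drift time via a Mason-Schamp-type
# relation, with least-squares calibration of the instrument parameters.

.N2_MASS <- 28.006  # monoisotopic-ish mass of N2, the default buffer gas (Da)

#' Reduced mass of an ion-gas pair
#'
#' @param M Ion mass in Da.
#' @param m Neutral gas molecule mass in Da (default nitrogen).
#' @return `m * M / (M + m)` in Da.
#' @export
reduced_mass <- function(M, m = .N2_MASS) {
  stopifnot(all(M > 0), all(m > 0))
  m * M / (M + m)
}

#' Drift calibration parameters
#'
#' Holds the slope `A`, intercept `B` (seconds), the neutral gas mass and the
#' functional form of the CCS-to-drift relation. The default form follows the
#' Mason-Schamp proportionality `t_d = A * CCS * sqrt(mu) / z + B`; the
#' literal linear-in-mu form `t_d = A * CCS * mu / z + B` is selectable
#' because `A` and `B` are refitted per instrument either way.
#'
#' @param A Slope parameter.
#' @param B Intercept in seconds.
#' @param gas_mass Neutral gas mass in Da.
#' @param form `"sqrt-mu"` (default) or `"linear-mu"`.
#' @return A `drift_calibration` object.
#' @export
drift_calibration <- function(A = 0.0248, B = 2.15, gas_mass = .N2_MASS,
                              form = c("sqrt-mu", "linear-mu")) {
  form <- match.arg(form)
  stopifnot(gas_mass > 0)
  structure(list(A = A, B = B, gas_mass = gas_mass, form = form),
            class = "drift_calibration")
}

.drift_regressor <- function(ccs, z, M, cal) {
  mu <- reduced_mass(M, cal$gas_mass)
  if (cal$form == "sqrt-mu") ccs * sqrt(mu) / z else ccs * mu / z
}

#' Convert CCS to drift time and back
#'
#' `ccs_to_drift()` maps CCS (squared angstroms) to drift time (seconds) for
#' a given charge state and ion mass under a calibration; `drift_to_ccs()` is
#' its exact inverse.
#'
#' @param ccs CCS values in squared angstroms (positive).
#' @param z Charge states (2, 3 or 4).
#' @param M Ion masses in Da.
#' @param cal A [drift_calibration()].
#' @return Drift times in seconds (or CCS values for the inverse).
#' @export
ccs_to_drift <- function(ccs, z, M, cal = drift_calibration()) {
  stopifnot(all(ccs > 0), all(z %in% 2:4))
  cal$A * .drift_regressor(ccs, z, M, cal) + cal$B
}

#' @rdname ccs_to_drift
#' @param td Drift times in seconds.
#' @export
drift_to_ccs <- function(td, z, M, cal = drift_calibration()) {
  stopifnot(all(z %in% 2:4), cal$A != 0)
  (td - cal$B) / (cal$A * .drift_regressor(1, z, M, cal))
}

#' Fit a drift calibration by ordinary least squares
#'
#' Regresses reference drift times on `x = CCS * sqrt(mu) / z` (or
#' `CCS * mu / z` for the linear-mu form) with an intercept, returning the
#' fitted slope `A` and intercept `B`. This is the route used when the
#' instrument parameters are unknown: predicted CCS values plus a set of
#' reference drift times suffice.
#'
#' @param ccs Predicted CCS values in squared angstroms.
#' @param z Charge states.
#' @param M Ion masses in Da.
#' @param td_ref Reference drift times in seconds.
#' @param gas_mass Neutral gas mass in Da.
#' @param form Functional form, as in [drift_calibration()].
#' @return A `drift_calibration` with fitted `A` and `B` and an `r2`
#'   attribute-like field for the fit.
#' @export
fit_drift_calibration <- function(ccs, z, M, td_ref, gas_mass = .N2_MASS,
                                  form = c("sqrt-mu", "linear-mu")) {
  form <- match.arg(form)
  stopifnot(length(ccs) >= 2L, length(z) == length(ccs),
            length(M) == length(ccs), length(td_ref) == length(ccs))
  cal0 <- drift_calibration(A = 1, B = 0, gas_mass = gas_mass, form = form)
  x <- .drift_regressor(ccs, z, M, cal0)
  if (stats::var(x) == 0) stop("degenerate design: all regressor values equal")
  fit <- stats::lm(td_ref ~ x)
  cal <- drift_calibration(A = unname(stats::coef(fit)[2L]),
                           B = unname(stats::coef(fit)[1L]),
                           gas_mass = gas_mass, form = form)
  cal$r2 <- 1 - sum(stats::residuals(fit)^2) / sum((td_ref - mean(td_ref))^2)
  cal
}

#' Per-charge drift-time accuracy report
#'
#' Fits a single global calibration from predicted CCS values and reference
#' drift times, then reports `R2` and mean squared error (seconds squared) of
#' the implied drift-time predictions within each charge-state group.
#'
#' @inheritParams fit_drift_calibration
#' @return List with the fitted `calibration` and a data.frame `by_charge`
#'   with columns `charge`, `n`, `r2`, `mse`. Charge groups with fewer than 2
#'   records are skipped with a warning.
#' @export
drift_report_by_charge <- function(ccs, z, M, td_ref, gas_mass = .N2_MASS,
                                   form = c("sqrt-mu", "linear-mu")) {
  form <- match.arg(form)
  cal <- fit_drift_calibration(ccs, z, M, td_ref, gas_mass, form)
  td_pred <- ccs_to_drift(ccs, z, M, cal)
  rows <- list()
  for (zz in sort(unique(z))) {
    i <- z == zz
    if (sum(i) < 2L) {
      warning("charge state ", zz, " has fewer than 2 records; skipped")
      next
    }
    res <- td_ref[i] - td_pred[i]
    sstot <- sum((td_ref[i] - mean(td_ref[i]))^2)
    rows[[length(rows) + 1L]] <- data.frame(
      charge = zz, n = sum(i),
      r2 = 1 - sum(res^2) / sstot,
      mse = mean(res^2))
  }
  list(calibration = cal, by_charge = do.call(rbind, rows))
}
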