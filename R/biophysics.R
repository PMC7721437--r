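#' Fit a saturation binding curve to a sodium calibration table
#'
#' Fits `I = Imax [Na] / (Kd + [Na])` by Levenberg-Marquardt nonlinear least
#' squares. The fitted curve is 0 at zero concentration, increases
#' monotonically, saturates at `Imax`, and reaches half-saturation at
#' `[Na] = Kd`.
#'
#' @param concentrations_mM sodium concentrations (mM, >= 0, at least 3
#'   distinct values).
#' @param intensities corrected mean droplet intensities (a.u., >= 0).
#' @param init optional `c(imax, kd)` starting values; defaults to
#'   `(max intensity, median concentration)`.
#' @return object of class `BindingCurveFit` with elements `i_max`, `kd_mM`,
#'   `residuals`, `covariance`, `converged`, and the underlying `fit`.
#' @export
fit_binding_curve <- function(concentrations_mM, intensities, init = NULL) {
  conc <- as.numeric(concentrations_mM)
  I <- as.numeric(intensities)
  stopifnot(length(conc) == length(I))
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct concentrations")
  if (any(I < 0)) stop("intensities must be >= 0")
  if (is.null(init)) init <- c(max(I), max(median(conc), 1e-3))
  df <- data.frame(conc = conc, I = I)
  try_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(I ~ imax * conc / (kd + conc), data = df,
                      start = list(imax = st[1], kd = st[2]),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  fit <- try_fit(init)
  if (inherits(fit, "error")) {
    # fall back to a small grid of starting points before giving up
    for (st in list(c(max(I), max(conc)), c(2 * max(I), max(conc) / 2),
                    c(max(I), max(conc) / 10))) {
      fit <- try_fit(st)
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error"))
    stop("binding-curve fit did not converge: ", conditionMessage(fit))
  cf <- coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  kd_se <- sqrt(vc[2, 2])
  flagged <- is.finite(kd_se) && kd_se > abs(cf[["kd"]])
  structure(list(i_max = unname(cf[["imax"]]), kd_mM = unname(cf[["kd"]]),
                 residuals = stats::residuals(fit), covariance = vc,
                 kd_se = kd_se, flagged_wide_ci = flagged,
                 converged = fit$convInfo$isConv %||% TRUE, fit = fit),
            class = "BindingCurveFit")
}

#' @export
print.BindingCurveFit <- function(x, ...) {
  cat(sprintf("Binding-curve fit: Imax = %.4g a.u., Kd = %.4g mM\n",
              x$i_max, x$kd_mM))
  if (isTRUE(x$flagged_wide_ci))
    cat("  warning: Kd poorly constrained (s.e. exceeds the estimate)\n")
  invisible(x)
}

#' Predicted intensity of a fitted binding curve
#' @param object a `BindingCurveFit`.
#' @param concentrations_mM concentrations at which to evaluate.
#' @param ... unused.
#' @export
predict.BindingCurveFit <- function(object, concentrations_mM, ...) {
  object$i_max * concentrations_mM / (object$kd_mM + concentrations_mM)
}

#' Invert a binding curve: corrected intensity to sodium concentration
#'
#' @param fit a `BindingCurveFit`.
#' @param corrected_intensity intensities in `[0, Imax)`.
#' @return concentrations in mM.
#' @export
intensity_to_concentration <- function(fit, corrected_intensity) {
  I <- as.numeric(corrected_intensity)
  if (any(I < 0)) stop("intensity must be >= 0")
  if (any(I >= fit$i_max))
    stop("intensity at or above Imax: outside the invertible range")
  fit$kd_mM * I / (fit$i_max - I)
}

#' Series-resistance model of transepithelial electrical stimulation
#'
#' Idealizes the stimulation setup as the series combination of the two
#' microelectrodes, the larva (with an optional shunt resistance in parallel,
#' infinite by default), and the 100 kOhm current-sensing resistor. If a
#' measured total circuit resistance is supplied it overrides the component
#' sum (measured totals include unmodelled contact resistances).
#'
#' @param r_electrodes_MOhm combined electrode resistance (MOhm).
#' @param r_larva_MOhm larval resistance (MOhm).
#' @param r_shunt_MOhm shunt resistance in parallel with the larva (MOhm);
#'   `Inf` for none.
#' @param series_resistor_kOhm current-sensing resistor (kOhm).
#' @param r_total_MOhm optional measured total resistance (MOhm).
#' @return object of class `CircuitModel`.
#' @export
circuit_model <- function(r_electrodes_MOhm = 18.5, r_larva_MOhm = 11,
                          r_shunt_MOhm = Inf, series_resistor_kOhm = 100,
                          r_total_MOhm = NULL) {
  vals <- c(r_electrodes_MOhm, r_larva_MOhm, r_shunt_MOhm)
  if (any(vals <= 0)) stop("resistances must be > 0")
  r_larva_eff <- 1 / (1 / r_larva_MOhm + 1 / r_shunt_MOhm)
  r_sum <- r_electrodes_MOhm + r_larva_eff + series_resistor_kOhm / 1000
  structure(list(r_electrodes_MOhm = r_electrodes_MOhm,
                 r_larva_MOhm = r_larva_MOhm,
                 r_shunt_MOhm = r_shunt_MOhm,
                 series_resistor_kOhm = series_resistor_kOhm,
                 r_larva_eff_MOhm = r_larva_eff,
                 r_total_MOhm = r_total_MOhm %||% r_sum,
                 r_components_MOhm = r_sum),
            class = "CircuitModel")
}

#' Solve the stimulation circuit for the unknown of current or voltage
#'
#' Given exactly one of the applied current or the applied voltage, computes
#' the other through the total resistance, the current actually flowing
#' through the larva (current divider with the shunt), the voltage drop
#' across each component, and the fraction of the applied voltage dropping
#' across the larva.
#'
#' @param model a [circuit_model()].
#' @param current_uA applied current (uA), or `NULL`.
#' @param voltage_V applied voltage (V), or `NULL`.
#' @return the model with elements `applied_current_uA`, `applied_voltage_V`,
#'   `larva_current_uA`, `larva_voltage_V`, `voltage_drops_V`, and
#'   `larva_voltage_fraction` filled in.
#' @export
circuit_solve <- function(model, current_uA = NULL, voltage_V = NULL) {
  stopifnot(inherits(model, "CircuitModel"))
  if (is.null(current_uA) == is.null(voltage_V))
    stop("give exactly one of `current_uA` or `voltage_V`")
  rt <- model$r_total_MOhm
  if (is.null(current_uA)) current_uA <- voltage_V / rt
  if (is.null(voltage_V)) voltage_V <- current_uA * rt
  # the measured total may exceed the modelled component sum; the residual
  # (contact/junction) resistance absorbs the difference
  r_resid <- max(rt - model$r_components_MOhm, 0)
  v_larva <- current_uA * model$r_larva_eff_MOhm
  i_larva <- if (is.infinite(model$r_shunt_MOhm)) current_uA else
    current_uA * model$r_shunt_MOhm / (model$r_shunt_MOhm + model$r_larva_MOhm)
  drops <- c(electrodes = current_uA * model$r_electrodes_MOhm,
             larva = v_larva,
             series_resistor = current_uA * model$series_resistor_kOhm / 1000,
             residual = current_uA * r_resid)
  model$applied_current_uA <- current_uA
  model$applied_voltage_V <- voltage_V
  model$larva_current_uA <- i_larva
  model$larva_voltage_V <- v_larva
  model$voltage_drops_V <- drops
  model$larva_voltage_fraction <- model$r_larva_eff_MOhm / rt
  model
}

#' @export
print.CircuitModel <- function(x, ...) {
  cat(sprintf(
    "CircuitModel: R_electrodes %.3g MOhm, R_larva %.3g MOhm, R_shunt %s, total %.3g MOhm\n",
    x$r_electrodes_MOhm, x$r_larva_MOhm,
    if (is.infinite(x$r_shunt_MOhm)) "Inf" else
      sprintf("%.3g MOhm", x$r_shunt_MOhm),
    x$r_total_MOhm))
  if (!is.null(x$applied_current_uA))
    cat(sprintf("  I = %.3g uA, V = %.3g V, larval fraction %.1f%%\n",
                x$applied_current_uA, x$applied_voltage_V,
                100 * x$larva_voltage_fraction))
  invisible(x)
}

#' Current density through a cross-section
#'
#' `density = current / area`, with the effective area optionally reduced by
#' a factor (e.g. when current is confined to interstitial spaces rather
#' than the full larval cross-section).
#'
#' @param current_uA current (uA).
#' @param cross_section_cm2 cross-sectional area (cm^2, > 0).
#' @param area_reduction_factor divide the area by this factor (> 0).
#' @return object of class `CurrentDensityEstimate`; `density_mA_cm2` is the
#'   current density in mA/cm^2.
#' @export
current_density <- function(current_uA, cross_section_cm2,
                            area_reduction_factor = 1) {
  if (cross_section_cm2 <= 0) stop("cross_section_cm2 must be > 0")
  if (area_reduction_factor <= 0) stop("area_reduction_factor must be > 0")
  dens <- (current_uA * 1e-3) / (cross_section_cm2 / area_reduction_factor)
  structure(list(current_uA = current_uA,
                 cross_section_cm2 = cross_section_cm2,
                 area_reduction_factor = area_reduction_factor,
                 density_mA_cm2 = dens),
            class = "CurrentDensityEstimate")
}

#' @export
print.CurrentDensityEstimate <- function(x, ...) {
  cat(sprintf("Current density: %.4g mA/cm^2 (%.3g uA over %.3g cm^2%s)\n",
              x$density_mA_cm2, x$current_uA, x$cross_section_cm2,
              if (x$area_reduction_factor != 1)
                sprintf(", area / %g", x$area_reduction_factor) else ""))
  invisible(x)
}
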