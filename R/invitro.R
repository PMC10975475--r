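# In-vitro and tissue-distribution parameter derivation: apparent
# permeability, efflux ratio, unbound plasma fraction, matrix concentration
# ratios (blood:plasma, tissue:plasma) and hepatocyte intrinsic clearance with
# well-stirred scaling to whole-organ hepatic clearance.

#' Apparent permeability from a transwell transport experiment
#'
#' Computes Papp = (dQ/dt) / (A * C0) from receiver-compartment amounts under
#' sink conditions, with the slope taken by ordinary least squares over the
#' sampling window (a single interval degrades to a two-point slope).
#'
#' Unit bookkeeping: receiver amounts in nmol over hours, area in cm2, donor
#' concentration in uM (= nmol/cm3), so slope/(A*C0) is in cm/h and is
#' divided by 3600 to give cm/s.
#'
#' @param times sampling times, h.
#' @param amounts receiver amounts, nmol (same length as `times`).
#' @param area monolayer area, cm2.
#' @param c0 initial donor concentration, uM.
#' @param window optional `c(lo, hi)` time window (h) restricting the fit.
#' @return Papp in 1e-6 cm/s.
#' @examples
#' # 0.06 nmol/h across 1.12 cm2 at 1 uM -> 14.9e-6 cm/s
#' papp(c(0, 1, 2), c(0, 0.06, 0.12), area = 1.12, c0 = 1)
#' @export
papp <- function(times, amounts, area, c0, window = NULL) {
  stopifnot_scalar_positive(area, "area")
  stopifnot_scalar_positive(c0, "c0")
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    times <- times[keep]; amounts <- amounts[keep]
  }
  if (length(times) < 2L) abort_validation("need at least 2 receiver samples in window")
  slope <- stats::coef(stats::lm(amounts ~ times))[["times"]]  # nmol/h
  if (slope <= 0) abort_validation("no measurable transport (non-positive slope)")
  papp_cm_s <- slope / (area * c0) / 3600   # (nmol/h)/(cm2 * nmol/cm3) -> cm/s
  papp_cm_s * 1e6
}

#' Efflux ratio
#'
#' @param papp_ab apical-to-basolateral Papp (any unit).
#' @param papp_ba basolateral-to-apical Papp (same unit).
#' @return papp_ba / papp_ab.
#' @export
efflux_ratio <- function(papp_ab, papp_ba) {
  if (papp_ab <= 0 || papp_ba <= 0) abort_validation("Papp values must be > 0")
  papp_ba / papp_ab
}

#' Unbound plasma fraction from equilibrium dialysis
#'
#' fup = C_buffer / C_plasma per replicate; replicates aggregate by arithmetic
#' mean. A buffer concentration exceeding plasma indicates a binding artifact
#' and is rejected.
#'
#' @param c_plasma plasma-side concentrations (any unit).
#' @param c_buffer buffer-side concentrations (same unit, same length).
#' @return mean unbound fraction.
#' @examples
#' fup(c_plasma = 1000, c_buffer = 2)  # 0.002
#' @export
fup <- function(c_plasma, c_buffer) {
  if (length(c_plasma) != length(c_buffer)) {
    abort_validation("plasma and buffer replicates differ in length")
  }
  if (any(c_plasma <= 0)) abort_validation("plasma concentration must be > 0")
  if (any(c_buffer < 0)) abort_validation("buffer concentration must be >= 0")
  if (any(c_buffer > c_plasma)) {
    abort_validation("binding artifact: buffer concentration exceeds plasma")
  }
  mean(c_buffer / c_plasma)
}

#' Matrix concentration ratio over shared timepoints
#'
#' Per-time ratios of two concentration profiles sampled at the same times,
#' plus their arithmetic mean. Used identically for blood:plasma and
#' tissue:plasma coefficients. Timepoints where the denominator is zero (or
#' either profile is flagged below the quantification limit) are excluded with
#' a warning rather than contaminating the mean.
#'
#' @param numerator,denominator numeric profiles at `times` (e.g. blood and
#'   plasma concentrations, ng/mL).
#' @param times sampling times, h.
#' @param exclude logical vector flagging timepoints to drop (e.g. BLQ), or
#'   NULL.
#' @return list with `times`, `ratios` and `mean`.
#' @examples
#' matrix_ratio(c(0.54, 0.55, 0.66), c(1, 1, 1), times = c(0.5, 2, 8))$mean
#' @export
matrix_ratio <- function(numerator, denominator, times, exclude = NULL) {
  n <- length(times)
  if (length(numerator) != n || length(denominator) != n) {
    abort_validation("profiles must be sampled at the requested times")
  }
  drop <- denominator == 0
  if (!is.null(exclude)) drop <- drop | exclude
  if (any(drop)) {
    warn_flag(sprintf("%d timepoint(s) excluded from matrix ratio", sum(drop)))
  }
  if (all(drop)) abort_validation("all timepoints excluded; no ratio computable")
  ratios <- numerator[!drop] / denominator[!drop]
  list(times = times[!drop], ratios = ratios, mean = mean(ratios))
}

#' Intrinsic clearance from a hepatocyte substrate-depletion curve
#'
#' Standard substrate-depletion analysis: the elimination rate constant k is
#' the negative slope of ln(fraction remaining) vs time; in-vitro intrinsic
#' clearance is k scaled by the incubation cell density, then scaled to the
#' whole body via hepatocellularity and liver weight; predicted in-vivo
#' hepatic clearance follows the well-stirred model
#' CL_h = Q_h * fu_b * CLint / (Q_h + fu_b * CLint) with fu_b = fup / BP.
#'
#' @param times incubation times, min.
#' @param fraction_remaining fraction of parent remaining, in (0, 1].
#' @param cell_density incubation density, 1e6 cells/mL.
#' @param species a [species_profile()] supplying hepatic blood flow,
#'   hepatocellularity and liver weight fraction.
#' @param fup_value unbound plasma fraction for the species.
#' @param bp_ratio blood:plasma concentration ratio.
#' @return list of class `clint_result`: `k` (1/min), `t_half` (min),
#'   `clint_invitro` (uL/min/1e6 cells), `clint_scaled` (mL/min/kg),
#'   `cl_hepatic_predicted` (mL/min/kg), `r_squared`, `poor_fit` flag.
#' @export
clint_from_depletion <- function(times, fraction_remaining, cell_density,
                                 species, fup_value, bp_ratio) {
  if (length(times) < 3L) abort_validation("need >= 3 depletion timepoints")
  if (any(fraction_remaining <= 0) || any(fraction_remaining > 1 + 1e-9)) {
    abort_validation("fraction_remaining must lie in (0, 1]")
  }
  stopifnot_scalar_positive(cell_density, "cell_density")
  fit <- stats::lm(log(fraction_remaining) ~ times)
  k <- -stats::coef(fit)[["times"]]
  if (k <= 0) abort_validation("no depletion (non-negative slope)")
  y <- log(fraction_remaining)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  poor_fit <- r2 < 0.8
  if (poor_fit) warn_flag(sprintf("depletion fit R^2 = %.3f < 0.8", r2))
  clint_invitro <- k * 1000 / cell_density          # uL/min/1e6 cells
  # scale: uL/min/1e6 cells * 1e6 cells/g * g liver/kg BW -> uL/min/kg -> mL/min/kg
  liver_g_per_kg <- species$liver_weight_fraction * 1000
  clint_scaled <- clint_invitro * species$hepatocellularity * liver_g_per_kg / 1000
  fu_b <- fup_value / bp_ratio
  q_h <- species$q_hepatic                           # mL/min/kg
  cl_h <- q_h * fu_b * clint_scaled / (q_h + fu_b * clint_scaled)
  structure(list(
    k = k, t_half = log(2) / k, clint_invitro = clint_invitro,
    clint_scaled = clint_scaled, cl_hepatic_predicted = cl_h,
    r_squared = r2, poor_fit = poor_fit
  ), class = "clint_result")
}

#' @export
print.clint_result <- function(x, ...) {
  cat(sprintf(
    "<clint_result: t1/2 %.3g min, CLint %.3g uL/min/1e6 cells, CLint,scaled %.3g mL/min/kg, CL_h %.3g mL/min/kg>\n",
    x$t_half, x$clint_invitro, x$clint_scaled, x$cl_hepatic_predicted))
  invisible(x)
}
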