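# Interspecies allometric scaling: five clearance predictors (SSS, SSAS,
# TSAS, FCIM, HBF), two Vss predictors (per-kg scaling and Oie-Tozer) and the
# aggregation policies that turn per-method predictions into a single human
# value.

#' Single-species simple scaling of clearance (SSS)
#'
#' CL_human = CL_animal x (BW_human / BW_animal)^b.
#'
#' @param cl_animal per-animal clearance, L/h.
#' @param bw_animal,bw_human body weights, kg.
#' @param exponent allometric exponent b, in (0, 1.2]; default 0.66 (the
#'   package default for simple scaling, 0.75 selectable).
#' @return predicted human clearance, mL/min.
#' @examples
#' cl_sss(1.9 * 0.245, 0.245, 60)  # rat-based, ~293 mL/min
#' @export
cl_sss <- function(cl_animal, bw_animal, bw_human, exponent = 0.66) {
  stopifnot_scalar_positive(cl_animal, "cl_animal")
  if (exponent <= 0 || exponent > 1.2) abort_validation("exponent must lie in (0, 1.2]")
  cl_h_l_h <- cl_animal * (bw_human / bw_animal)^exponent
  cl_h_l_h * 1000 / 60
}

#' Single-species allometric scaling with fu correction (SSAS)
#'
#' Scales unbound clearance with exponent 0.75 and rebinds with the human
#' unbound fraction: CL_human = (CL_a / fup_a) x (BW_h / BW_a)^0.75 x fup_h.
#'
#' @param cl_animal per-animal clearance, L/h.
#' @param bw_animal,bw_human body weights, kg.
#' @param fup_animal,fup_human unbound plasma fractions, (0, 1].
#' @param exponent allometric exponent, default 0.75.
#' @return predicted human clearance, mL/min.
#' @export
cl_ssas_fu <- function(cl_animal, bw_animal, bw_human, fup_animal, fup_human,
                       exponent = 0.75) {
  stopifnot_fraction(fup_animal, "fup_animal")
  stopifnot_fraction(fup_human, "fup_human")
  cl_h_l_h <- (cl_animal / fup_animal) * (bw_human / bw_animal)^exponent * fup_human
  cl_h_l_h * 1000 / 60
}

#' Two-species allometric scaling (TSAS)
#'
#' Least-squares fit of log CL = log a + b log BW across species; with two
#' species this is the exact interpolation. Prediction a x BW_human^b.
#'
#' @param cl_animals per-animal clearances, L/h (length >= 2).
#' @param bw_animals body weights, kg (distinct).
#' @param bw_human human body weight, kg.
#' @return list: `value` (mL/min), `a` (L/h/kg^b), `b`.
#' @export
cl_tsas <- function(cl_animals, bw_animals, bw_human) {
  if (length(cl_animals) < 2L || length(bw_animals) != length(cl_animals)) {
    abort_validation("TSAS needs >= 2 (CL, BW) pairs")
  }
  if (length(unique(bw_animals)) < 2L) {
    abort_validation("TSAS needs distinct body weights")
  }
  fit <- stats::lm(log(cl_animals) ~ log(bw_animals))
  b <- stats::coef(fit)[[2]]
  a <- exp(stats::coef(fit)[[1]])
  list(value = a * bw_human^b * 1000 / 60, a = a, b = b)
}

#' Fu-corrected intercept method (FCIM)
#'
#' The Tang-Mayersohn form CL_human = 33.35 x (a / Rfu)^0.77 mL/min, where a
#' is the allometric coefficient in mL/min/kg^0.75 (for a single species,
#' a = CL_a / BW_a^0.75) and Rfu = fup_animal / fup_human.
#'
#' @param cl_animal per-animal clearance, L/h.
#' @param bw_animal body weight, kg.
#' @param fup_animal,fup_human unbound plasma fractions.
#' @return predicted human clearance, mL/min.
#' @export
cl_fcim <- function(cl_animal, bw_animal, fup_animal, fup_human) {
  stopifnot_fraction(fup_animal, "fup_animal")
  stopifnot_fraction(fup_human, "fup_human")
  a <- (cl_animal * 1000 / 60) / bw_animal^0.75   # mL/min/kg^0.75
  rfu <- fup_animal / fup_human
  33.35 * (a / rfu)^0.77
}

#' Hepatic blood flow method (HBF)
#'
#' Transfers the hepatic extraction ratio: CL_human = (CL_a / Q_h,a) x Q_h,h.
#' An animal clearance above its hepatic blood flow is physiologically
#' implausible for a hepatically cleared drug and is flagged (not capped).
#'
#' @param cl_animal per-animal blood-flow-comparable clearance, mL/min.
#' @param q_animal animal hepatic blood flow, mL/min.
#' @param q_human human hepatic blood flow, mL/min.
#' @return list: `value` (mL/min), `extraction`, `implausible` flag.
#' @export
cl_hbf <- function(cl_animal, q_animal, q_human) {
  stopifnot_scalar_positive(q_animal, "q_animal")
  stopifnot_scalar_positive(q_human, "q_human")
  e <- cl_animal / q_animal
  implausible <- e > 1
  if (implausible) warn_flag("animal clearance exceeds hepatic blood flow")
  list(value = e * q_human, extraction = e, implausible = implausible)
}

#' Per-kg scaling of steady-state volume of distribution
#'
#' Vss_human = (Vss_animal / BW_animal) x BW_human, i.e. allometric exponent 1.
#'
#' @param vss_per_kg animal Vss, L/kg.
#' @param bw_human human body weight, kg.
#' @return predicted human Vss, L.
#' @examples
#' vss_perkg(1.05, 60)  # 63 L
#' @export
vss_perkg <- function(vss_per_kg, bw_human) {
  stopifnot_scalar_positive(vss_per_kg, "vss_per_kg")
  vss_per_kg * bw_human
}

#' Oie-Tozer prediction of steady-state volume of distribution
#'
#' Partitions the drug between plasma, extracellular and remainder spaces.
#' Per animal species the unbound tissue fraction is back-calculated:
#' fut = fup x Vr / (Vss/BW - Vp - fup Ve - (1 - fup) (RE/I) Vp),
#' then the human Vss per kg is
#' Vp + fup_h Ve + (1 - fup_h)(RE/I) Vp + Vr fup_h / mean(fut), scaled by the
#' human body weight. Physiological volumes come from the species profiles.
#'
#' @param vss_per_kg named numeric vector of animal Vss values, L/kg (names =
#'   species).
#' @param fup_by_species named unbound fractions covering the animal species
#'   and `"human"`.
#' @param human a human [species_profile()].
#' @param profiles optional named list of animal species profiles (defaults to
#'   the library profiles).
#' @return list: `value` (L), `fut` (per-species), `fut_mean`, `vss_per_kg`
#'   (human, L/kg).
#' @export
vss_oie_tozer <- function(vss_per_kg, fup_by_species, human, profiles = NULL) {
  if (is.null(names(vss_per_kg))) abort_validation("vss_per_kg must be named by species")
  fut <- vapply(names(vss_per_kg), function(sp) {
    prof <- profiles[[sp]] %||% species_profile(sp)
    ot <- prof$oie_tozer
    fu <- fup_by_species[[sp]]
    if (is.null(fu)) abort_validation(sprintf("fup missing for species '%s'", sp))
    denom <- vss_per_kg[[sp]] - ot$vp - fu * ot$ve - (1 - fu) * ot$re_i * ot$vp
    if (denom <= 0) abort_validation("Vss below plasma space: non-positive fut")
    fu * ot$vr / denom
  }, numeric(1))
  fut_mean <- mean(fut)
  ot_h <- human$oie_tozer
  fu_h <- fup_by_species[["human"]]
  if (is.null(fu_h)) abort_validation("fup missing for species 'human'")
  v_kg <- ot_h$vp + fu_h * ot_h$ve + (1 - fu_h) * ot_h$re_i * ot_h$vp +
    ot_h$vr * fu_h / fut_mean
  list(value = v_kg * human$body_weight, fut = fut, fut_mean = fut_mean,
       vss_per_kg = v_kg)
}

#' Aggregate per-method allometric predictions
#'
#' Aggregation policies for the human headline values. `"dog_single_species"`
#' averages the dog-sourced single-species clearance predictions (SSS, SSAS,
#' FCIM, HBF) -- the non-rodent-only policy used when rodent metabolism is
#' known to diverge; `"all_methods_mean"` averages every supplied prediction
#' (the Vss policy). The returned provenance records the members aggregated.
#'
#' @param predictions data.frame with columns `method`, `source_species`,
#'   `value` (see [xzp5610_scaling_reference()] for the layout).
#' @param policy `"dog_single_species"` or `"all_methods_mean"`.
#' @return list: `value` (mean), `n`, `members` (data.frame of aggregated
#'   rows).
#' @export
aggregate_predictions <- function(predictions,
                                  policy = c("dog_single_species",
                                             "all_methods_mean")) {
  policy <- match.arg(policy)
  if (!is.data.frame(predictions) || nrow(predictions) == 0L) {
    abort_validation("no predictions to aggregate")
  }
  members <- if (policy == "dog_single_species") {
    predictions[predictions$source_species == "dog" &
                  predictions$method %in% c("SSS", "SSAS", "FCIM", "HBF"), ,
                drop = FALSE]
  } else {
    predictions
  }
  if (nrow(members) == 0L) abort_validation("policy filter left no predictions")
  list(value = mean(members$value), n = nrow(members), members = members)
}
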