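# First-in-human dose mathematics: human equivalent dose by body surface area
# (Km conversion), unbound-exposure matching, safety factors and the dose-plan
# assembly (MRSD / MABEL / MTD).

#' Human equivalent dose by the body-surface-area method
#'
#' HED (mg) = NOAEL (mg/kg) x (Km_animal / Km_human) x BW_human (kg).
#'
#' @param noael animal NOAEL dose, mg/kg.
#' @param km_animal,km_human body-surface-area conversion factors.
#' @param bw_human human body weight, kg.
#' @return HED, mg.
#' @examples
#' hed_bsa(0.05, 20, 37, 60)  # dog NOAEL -> 1.62 mg
#' @export
hed_bsa <- function(noael, km_animal, km_human, bw_human) {
  stopifnot_scalar_positive(noael, "noael")
  stopifnot_scalar_positive(km_animal, "km_animal")
  stopifnot_scalar_positive(km_human, "km_human")
  stopifnot_scalar_positive(bw_human, "bw_human")
  noael * (km_animal / km_human) * bw_human
}

#' Human-equivalent exposure by unbound-AUC matching
#'
#' Matches unbound exposures across species:
#' AUC_human = AUC_animal x fup_animal / fup_human.
#'
#' @param auc_animal animal steady-state AUC, ng*h/mL.
#' @param fup_animal,fup_human unbound plasma fractions, (0, 1].
#' @return human-equivalent AUC, ng*h/mL.
#' @examples
#' auc_human_equivalent(75.2, 0.013, 0.002)  # ~489
#' @export
auc_human_equivalent <- function(auc_animal, fup_animal, fup_human) {
  stopifnot_scalar_positive(auc_animal, "auc_animal")
  stopifnot_fraction(fup_animal, "fup_animal")
  stopifnot_fraction(fup_human, "fup_human")
  auc_animal * fup_animal / fup_human
}

#' Dose achieving a target human exposure
#'
#' Dose (mg) = AUC x CL / F, using ng*h/mL = ug*h/L so that
#' AUC (ug*h/L) x CL (L/h) is in ug, divided by 1000 to mg.
#'
#' @param auc_human target human AUC, ng*h/mL.
#' @param cl_human predicted human clearance, L/h.
#' @param f_human predicted human oral bioavailability, fraction (0, 1].
#' @return dose, mg.
#' @examples
#' dose_from_exposure(489, 8.3, 0.574)  # ~7.07 mg
#' @export
dose_from_exposure <- function(auc_human, cl_human, f_human) {
  stopifnot_scalar_positive(auc_human, "auc_human")
  stopifnot_scalar_positive(cl_human, "cl_human")
  if (f_human > 1) abort_validation("bioavailability fraction cannot exceed 1")
  stopifnot_fraction(f_human, "f_human")
  auc_human * cl_human / f_human / 1000
}

#' Apply a safety factor to a human equivalent dose
#'
#' MRSD = HED / SF.
#'
#' @param hed human equivalent dose, mg.
#' @param sf safety factor, >= 1.
#' @return MRSD, mg.
#' @export
apply_safety_factor <- function(hed, sf) {
  stopifnot_scalar_positive(hed, "hed")
  if (sf < 1) abort_validation("safety factor must be >= 1")
  hed / sf
}

#' MRSD table by the body-surface-area method
#'
#' @param noael data.frame with columns `species`, `sex`, `noael_mg_kg` (see
#'   [xzp5610_noael()]).
#' @param human a human [species_profile()].
#' @param sf safety factor (default 10).
#' @param profiles optional named list of animal profiles overriding the
#'   library Km factors.
#' @return data.frame with columns `species`, `sex`, `noael_mg_kg`, `hed_mg`,
#'   `sf`, `mrsd_mg`.
#' @export
mrsd_bsa_table <- function(noael, human, sf = 10, profiles = NULL) {
  rows <- lapply(seq_len(nrow(noael)), function(i) {
    sp <- noael$species[i]
    prof <- profiles[[sp]] %||% species_profile(sp)
    hed <- hed_bsa(noael$noael_mg_kg[i], prof$km_factor, human$km_factor,
                   human$body_weight)
    data.frame(species = sp, sex = noael$sex[i],
               noael_mg_kg = noael$noael_mg_kg[i], hed_mg = hed, sf = sf,
               mrsd_mg = apply_safety_factor(hed, sf),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' MRSD table by the systemic-exposure method
#'
#' Converts animal steady-state exposures at the NOAEL into human-equivalent
#' unbound exposures, then into the dose producing them given the predicted
#' human clearance and bioavailability.
#'
#' @param noael data.frame with columns `species`, `sex`, `noael_mg_kg`,
#'   `steady_auc_0_24` (ng*h/mL).
#' @param fup_by_species named unbound fractions covering the animal species
#'   and `"human"`.
#' @param cl_human predicted human clearance, L/h.
#' @param f_human predicted human bioavailability, fraction.
#' @param sf safety factor (default 10).
#' @return data.frame with columns `species`, `sex`, `noael_mg_kg`,
#'   `steady_auc_0_24`, `auc_human_equivalent`, `hed_mg`, `sf`, `mrsd_mg`.
#' @export
mrsd_exposure_table <- function(noael, fup_by_species, cl_human, f_human,
                                sf = 10) {
  rows <- lapply(seq_len(nrow(noael)), function(i) {
    sp <- noael$species[i]
    fu_a <- fup_by_species[[sp]]
    if (is.null(fu_a)) abort_validation(sprintf("fup missing for species '%s'", sp))
    auc_h <- auc_human_equivalent(noael$steady_auc_0_24[i], fu_a,
                                  fup_by_species[["human"]])
    hed <- dose_from_exposure(auc_h, cl_human, f_human)
    data.frame(species = sp, sex = noael$sex[i],
               noael_mg_kg = noael$noael_mg_kg[i],
               steady_auc_0_24 = noael$steady_auc_0_24[i],
               auc_human_equivalent = auc_h, hed_mg = hed, sf = sf,
               mrsd_mg = apply_safety_factor(hed, sf),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a first-in-human dose plan
#'
#' The MRSD is the minimum across method recommendations, rounded down to the
#' plan granularity. MABEL and MTD are judgment calls pinned by policy (they
#' are set from pharmacology and tolerability review, not by a formula); the
#' computed efficacy-dose range is attached as provenance so the judgment is
#' auditable.
#'
#' @param mrsd_mg vector of MRSD recommendations, mg (from both methods).
#' @param efficacy_heds_mg vector of efficacy-derived human equivalent doses,
#'   mg (provenance only).
#' @param mabel_mg,mtd_mg policy-pinned MABEL and MTD, mg.
#' @param granularity rounding-down granularity for the chosen MRSD, mg.
#' @return object of class `dose_plan`: `mrsd_chosen`, `mabel`, `mtd`,
#'   `mrsd_range`, `efficacy_range`, `rationale`.
#' @export
build_dose_plan <- function(mrsd_mg, efficacy_heds_mg = numeric(),
                            mabel_mg, mtd_mg, granularity = 0.01) {
  if (length(mrsd_mg) == 0L) abort_validation("no MRSD recommendations supplied")
  mrsd <- floor(min(mrsd_mg) / granularity) * granularity
  if (!(mrsd <= mabel_mg && mabel_mg <= mtd_mg)) {
    abort_validation("dose plan must satisfy MRSD <= MABEL <= MTD")
  }
  structure(list(
    mrsd_chosen = mrsd, mabel = mabel_mg, mtd = mtd_mg,
    mrsd_range = range(mrsd_mg),
    efficacy_range = if (length(efficacy_heds_mg)) range(efficacy_heds_mg) else NULL,
    rationale = paste0(
      "MRSD = min of method recommendations rounded down to ",
      granularity, " mg; MABEL/MTD pinned by policy with computed ranges attached"
    )
  ), class = "dose_plan")
}

#' @export
print.dose_plan <- function(x, ...) {
  cat(sprintf("<dose_plan: MRSD %.3g mg, MABEL %.3g mg, MTD %.3g mg>\n",
              x$mrsd_chosen, x$mabel, x$mtd))
  cat(sprintf("  MRSD recommendations spanned %.3g-%.3g mg\n",
              x$mrsd_range[1], x$mrsd_range[2]))
  if (!is.null(x$efficacy_range)) {
    cat(sprintf("  efficacy-derived HEDs spanned %.3g-%.3g mg\n",
                x$efficacy_range[1], x$efficacy_range[2]))
  }
  invisible(x)
}
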