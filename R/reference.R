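# Reference datasets from the XZP-5610 preclinical development program.
# These printed study summaries are inputs to the translation pipeline
# (per-kg clearances, volumes, bioavailabilities, NOAELs, steady-state
# exposures and the independently reported allometric predictions used for
# aggregation). All values are group mean summaries.

#' XZP-5610 preclinical PK summary tables
#'
#' Group-mean PK parameters from the single-dose rat and dog studies
#' (1 IV arm + 3 oral dose arms per species, n = 3/sex/group). Units follow
#' the package conventions: dose mg/kg, Cmax ng/mL, AUC h*ng/mL, CL L/h/kg,
#' Vss L/kg, F percent.
#'
#' @param species `"rat"` or `"dog"`.
#' @return data.frame, one row per (route, dose, sex) group.
#' @export
xzp5610_pk_summary <- function(species = c("rat", "dog")) {
  species <- match.arg(species)
  if (species == "rat") {
    data.frame(
      route = c("iv_bolus", "iv_bolus", rep("oral", 6)),
      dose = c(1, 1, 2, 1, 6, 3, 20, 10),
      sex = c("M", "F", "M", "F", "M", "F", "M", "F"),
      tmax_h = c(NA, NA, 0.5, 0.5, 0.5, 0.8, 1.0, 0.5),
      t_half_h = c(2.9, 2.2, 1.3, 1.3, 1.0, 1.2, 1.4, 1.9),
      cmax_ng_ml = c(NA, NA, 56.6, 50.4, 255.8, 175.6, 762.9, 1014.0),
      auc_0_t = c(488.3, 569.8, 94.9, 89.0, 293.8, 271.1, 1276.6, 1367.8),
      cl_l_h_kg = c(2.0, 1.8, NA, NA, NA, NA, NA, NA),
      vss_l_kg = c(0.9, 0.6, NA, NA, NA, NA, NA, NA),
      f_pct = c(NA, NA, 9.6, 15.6, 9.9, 15.9, 12.9, 24.1),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      route = c("iv_bolus", "iv_bolus", rep("oral", 6)),
      dose = c(0.2, 0.2, 0.05, 0.05, 0.2, 0.2, 0.8, 0.8),
      sex = c("M", "F", "M", "F", "M", "F", "M", "F"),
      tmax_h = c(NA, NA, 1.7, 1.7, 2.0, 1.3, 1.0, 1.3),
      t_half_h = c(7.9, 5.5, 10.1, 13.1, 6.1, 6.5, 5.8, 7.0),
      cmax_ng_ml = c(NA, NA, 15.8, 21.1, 126.0, 67.3, 533.7, 626.7),
      auc_0_t = c(864.4, 871.4, 88.2, 125.9, 508.3, 319.4, 2140.0, 2279.2),
      cl_l_h_kg = c(0.2, 0.2, NA, NA, NA, NA, NA, NA),
      vss_l_kg = c(1.1, 1.0, NA, NA, NA, NA, NA, NA),
      f_pct = c(NA, NA, 43.4, 82.9, 51.2, 38.2, 61.4, 67.1),
      stringsAsFactors = FALSE
    )
  }
}

#' Reported allometric predictions for XZP-5610
#'
#' The independently reported human CL_iv and Vss predictions per scaling
#' method, used as inputs to the aggregation policies (some of the originating
#' method variants are not reproducible from the printed per-species inputs,
#' so the reported values themselves serve as the aggregation inputs).
#'
#' @return data.frame with columns `parameter` (`"cl_iv"` mL/min or `"vss"`
#'   L), `method`, `source_species`, `value`.
#' @export
xzp5610_scaling_reference <- function() {
  data.frame(
    parameter = c(rep("cl_iv", 9), rep("vss", 3)),
    method = c("SSS", "SSS", "SSAS", "SSAS", "TSAS", "FCIM", "FCIM", "HBF",
               "HBF", "OieTozer", "PerKgVss", "PerKgVss"),
    source_species = c("rat", "dog", "rat", "dog", "rat+dog", "rat", "dog",
                       "rat", "dog", "rat+dog", "rat", "dog"),
    value = c(293, 96.4, 75.4, 92.3, 177, 58.6, 181, 845, 184,
              17.1, 45.3, 63.0),
    stringsAsFactors = FALSE
  )
}

#' Toxicology and toxicokinetic inputs for FIH dosing
#'
#' NOAEL doses from the pivotal toxicity studies and the corresponding
#' steady-state AUC(0-24) exposures used by the systemic-exposure dose method.
#'
#' @return data.frame with columns `species`, `sex`, `noael_mg_kg`,
#'   `steady_auc_0_24` (ng*h/mL; NA where not used).
#' @export
xzp5610_noael <- function() {
  data.frame(
    species = c("rat", "rat", "dog", "dog"),
    sex = c("M", "F", "M", "F"),
    noael_mg_kg = c(1.5, 1, 0.05, 0.05),
    steady_auc_0_24 = c(75.2, 46.4, 127.6, 152.1),
    stringsAsFactors = FALSE
  )
}

#' Blood:plasma ratio observations for XZP-5610
#'
#' Per-timepoint whole-blood to plasma concentration ratios from the rat
#' radiolabel distribution study. The 24 h timepoint was below the
#' quantification limit and is excluded, so ratios are reported at 0.5, 2 and
#' 8 h.
#'
#' @return data.frame with columns `time_h`, `bp_ratio`.
#' @export
xzp5610_bp_observations <- function() {
  data.frame(time_h = c(0.5, 2, 8), bp_ratio = c(0.54, 0.55, 0.66))
}
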