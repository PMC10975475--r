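#' Species physiology profiles
#'
#' A small physiology library used throughout the package: representative body
#' weights, body-surface-area conversion (Km) factors, hepatic blood flows,
#' Oie-Tozer distribution volumes, liver scaling constants, cardiac output and
#' per-tissue volume/flow fractions for whole-body PBPK model construction.
#'
#' Constants are drawn from the standard compilations used in drug-development
#' practice (FDA 2005 starting-dose guidance for Km factors; Davies & Morris
#' 1993 / Obach 1997 for Oie-Tozer volumes and hepatic flows; Brown 1997 for
#' tissue volumes and perfusion). Every value can be overridden through the
#' `overrides` argument, and each profile carries a provenance string.
#'
#' @param species one of `"mouse"`, `"rat"`, `"dog"`, `"human"`.
#' @param body_weight body weight in kg; defaults to the representative weight
#'   of the species used in the supported study designs (rat 0.245 kg, dog
#'   7.21 kg, human 60 kg).
#' @param overrides named list replacing individual profile entries
#'   (e.g. `list(q_hepatic = 21)`).
#' @return An object of class `species_profile`: a list with elements `name`,
#'   `body_weight` (kg), `km_factor`, `q_hepatic` (mL/min/kg),
#'   `cardiac_output` (L/h/kg), `oie_tozer` (list `vp`, `ve`, `vr` in L/kg and
#'   `re_i`), `liver_weight_fraction`, `hepatocellularity` (1e6 cells/g
#'   liver), `tissue_volumes` and `tissue_flows` (named fractions of body
#'   weight and cardiac output), and `provenance`.
#' @examples
#' rat <- species_profile("rat")
#' rat$q_hepatic  # mL/min/kg
#' @export
species_profile <- function(species = c("rat", "dog", "human", "mouse"),
                            body_weight = NULL, overrides = list()) {
  species <- match.arg(species)
  lib <- .physiology_library[[species]]
  prof <- lib
  prof$name <- species
  prof$body_weight <- body_weight %||% lib$body_weight
  stopifnot_scalar_positive(prof$body_weight, "body_weight")
  for (nm in names(overrides)) prof[[nm]] <- overrides[[nm]]
  stopifnot_scalar_positive(prof$km_factor, "km_factor")
  structure(prof, class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile: %s, %.3g kg>\n", x$name, x$body_weight))
  cat(sprintf("  Km %.3g | Q_h %.3g mL/min/kg | CO %.3g L/h/kg | liver %.3g%% BW\n",
              x$km_factor, x$q_hepatic, x$cardiac_output,
              100 * x$liver_weight_fraction))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Oie-Tozer physiological volumes (L/kg) and extracellular/intracellular
# protein ratio, per the Obach 1997 compilation.
.oie_tozer <- list(
  mouse = list(vp = 0.0500, ve = 0.2650, vr = 0.3640, re_i = 0.165),
  rat   = list(vp = 0.0313, ve = 0.2650, vr = 0.3640, re_i = 0.182),
  dog   = list(vp = 0.0515, ve = 0.2160, vr = 0.4500, re_i = 0.666),
  human = list(vp = 0.0436, ve = 0.1510, vr = 0.3800, re_i = 1.400)
)

# Whole-body tissue volumes as fractions of body weight and regional blood
# flows as fractions of cardiac output (Brown 1997). The hepatic total flow is
# taken from q_hepatic (not the CO fraction) for internal consistency; `rest`
# absorbs the remainder so that flows and volumes balance exactly.
.tissue_volumes_rat <- c(
  lung = 0.0050, heart = 0.0033, brain = 0.0057, muscle = 0.4040,
  adipose = 0.0700, skin = 0.1900, bone = 0.0730, kidney = 0.0073,
  spleen = 0.0020, gut = 0.0270, liver = 0.0400,
  arterial_blood = 0.0247, venous_blood = 0.0493
)
.tissue_flows_rat <- c(
  heart = 0.051, brain = 0.020, muscle = 0.278, adipose = 0.070,
  skin = 0.058, bone = 0.122, kidney = 0.141
)
.tissue_volumes_human <- c(
  lung = 0.0076, heart = 0.0047, brain = 0.0200, muscle = 0.4000,
  adipose = 0.2136, skin = 0.0371, bone = 0.0856, kidney = 0.0044,
  spleen = 0.0026, gut = 0.0171, liver = 0.0257,
  arterial_blood = 0.0263, venous_blood = 0.0527
)
.tissue_flows_human <- c(
  heart = 0.040, brain = 0.120, muscle = 0.170, adipose = 0.050,
  skin = 0.050, bone = 0.050, kidney = 0.190
)

.physiology_library <- list(
  mouse = list(
    body_weight = 0.020, km_factor = 3, q_hepatic = 90, cardiac_output = 30.0,
    oie_tozer = .oie_tozer$mouse, liver_weight_fraction = 0.0549,
    hepatocellularity = 120,
    tissue_volumes = .tissue_volumes_rat, tissue_flows = .tissue_flows_rat,
    provenance = "FDA 2005 Km; Davies & Morris 1993; Brown 1997 (rat fractions reused)"
  ),
  rat = list(
    body_weight = 0.245, km_factor = 6, q_hepatic = 55.2, cardiac_output = 26.4,
    oie_tozer = .oie_tozer$rat, liver_weight_fraction = 0.0400,
    hepatocellularity = 120,
    tissue_volumes = .tissue_volumes_rat, tissue_flows = .tissue_flows_rat,
    provenance = "FDA 2005 Km; Obach 1997 Oie-Tozer volumes; Brown 1997 tissues"
  ),
  dog = list(
    body_weight = 7.21, km_factor = 20, q_hepatic = 30.9, cardiac_output = 7.2,
    oie_tozer = .oie_tozer$dog, liver_weight_fraction = 0.0320,
    hepatocellularity = 120,
    tissue_volumes = .tissue_volumes_rat, tissue_flows = .tissue_flows_rat,
    provenance = "FDA 2005 Km; Obach 1997 Oie-Tozer volumes; Brown 1997 (rat fractions reused)"
  ),
  human = list(
    body_weight = 60, km_factor = 37, q_hepatic = 20.7, cardiac_output = 4.8,
    oie_tozer = .oie_tozer$human, liver_weight_fraction = 0.0257,
    hepatocellularity = 120,
    tissue_volumes = .tissue_volumes_human, tissue_flows = .tissue_flows_human,
    provenance = "FDA 2005 Km; Obach 1997 Oie-Tozer volumes; Brown 1997 tissues"
  )
)

# Rodgers-Rowland tissue composition: fractional extracellular water (f_ew),
# intracellular water (f_iw), neutral lipid (f_nl), neutral phospholipid
# (f_npl) and tissue:plasma albumin ratio (ar). Rat-derived composition data
# applied across species, as is standard practice.
.rr_tissue_composition <- data.frame(
  tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
             "lung", "muscle", "skin", "spleen", "rest"),
  f_ew  = c(0.135, 0.100, 0.162, 0.282, 0.320, 0.273, 0.161, 0.336, 0.118,
            0.382, 0.207, 0.118),
  f_iw  = c(0.017, 0.346, 0.620, 0.475, 0.456, 0.483, 0.573, 0.446, 0.630,
            0.291, 0.579, 0.630),
  f_nl  = c(0.8530, 0.0170, 0.0390, 0.0380, 0.0140, 0.0120, 0.0140, 0.0220,
            0.0100, 0.0600, 0.0077, 0.0100),
  f_npl = c(0.0016, 0.0017, 0.0015, 0.0125, 0.0111, 0.0242, 0.0240, 0.0128,
            0.0072, 0.0044, 0.0113, 0.0072),
  ar    = c(0.049, 0.100, 0.048, 0.158, 0.157, 0.130, 0.086, 0.212, 0.064,
            0.277, 0.097, 0.064),
  stringsAsFactors = FALSE
)

.rr_plasma_composition <- c(f_w = 0.945, f_nl = 0.0023, f_npl = 0.0013)

#' Rodgers-Rowland tissue composition table
#'
#' Fractional tissue water, neutral lipid, neutral phospholipid and albumin
#' ratio per tissue, as used by [rodgers_rowland_kp()].
#'
#' @return data.frame with columns `tissue`, `f_ew`, `f_iw`, `f_nl`, `f_npl`,
#'   `ar`.
#' @export
rr_tissue_composition <- function() .rr_tissue_composition
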