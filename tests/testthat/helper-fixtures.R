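# Shared fixtures built in code.

# minimal valid single-subject plasma record set
small_records <- function(n = 6) {
  data.frame(
    subject_id = "r1", species = "rat", sex = "M", group = "iv",
    route = "iv_bolus", dose = 1, dose_units = "mg/kg", matrix = "plasma",
    time_h = seq_len(n) / 2, conc_ng_per_ml = 1000 * exp(-0.5 * seq_len(n) / 2),
    stringsAsFactors = FALSE
  )
}

# Table-1/2-style group-mean observations interpolated to a dose (M/F average
# of dose-normalised values), used for PBPK validation checks
observed_rat_at_dose <- function(dose_mg_kg) {
  tab <- xzp5610_pk_summary("rat")
  po <- tab[tab$route == "oral", ]
  list(
    cmax = mean(po$cmax_ng_ml / po$dose) * dose_mg_kg,
    auc = mean(po$auc_0_t / po$dose) * dose_mg_kg
  )
}

rat_reference_model <- function(...) {
  build_model(xzp5610_properties(), species_profile("rat"),
              cl_per_kg = 1.93, ka = 2.34, f_target = 0.147, ...)
}

human_reference_model <- function(...) {
  build_model(xzp5610_properties(), species_profile("human"),
              cl_per_kg = 0.138, ka = 1.46, f_target = 0.574, ...)
}
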