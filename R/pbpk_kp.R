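# Rodgers-Rowland tissue:plasma partition coefficients from tissue
# composition, drug lipophilicity, ionization and plasma protein binding.

# Ionization denominator Z(pH) = total/neutral for up to two acid pKa values
# and weak-base pKa values (additive cumulative form).
ionization_factor <- function(ph, pka) {
  z <- 1
  if (!is.null(pka)) {
    acids <- sort(pka$value[pka$type == "acid"])
    if (length(acids) >= 1L) z <- z + 10^(ph - acids[1])
    if (length(acids) >= 2L) z <- z + 10^(2 * ph - acids[1] - acids[2])
    bases <- pka$value[pka$type == "base"]
    for (b in bases) z <- z + 10^(b - ph)
  }
  z
}

#' Rodgers-Rowland tissue:plasma partition coefficients
#'
#' Mechanistic tissue partitioning for acids, very weak bases and neutrals
#' (the extracellular-protein binding class): the unbound tissue:plasma
#' coefficient sums partitioning into extracellular water, intracellular water
#' (with the intracellular/plasma ionization ratio at pH 7.0 vs 7.4), neutral
#' lipid and neutral phospholipid (octanol surrogate; vegetable-oil surrogate
#' for adipose), plus albumin-type binding inferred from the plasma unbound
#' fraction and the tissue:plasma albumin ratio. Kp = Kpu x fup.
#'
#' Strong bases (base pKa >= 7), whose partitioning is dominated by acidic
#' phospholipid binding, are outside this equation set and are rejected.
#'
#' @param drug a [drug_properties()] object.
#' @param species species name or [species_profile()] (selects the unbound
#'   fraction from `drug$fup`).
#' @param apply_overrides apply `drug$kp_overrides` on top of the computed
#'   values (default TRUE).
#' @return named numeric vector of Kp values, one per tissue of
#'   [rr_tissue_composition()].
#' @export
rodgers_rowland_kp <- function(drug, species, apply_overrides = TRUE) {
  sp_name <- if (inherits(species, "species_profile")) species$name else species
  fu <- unname(drug$fup[sp_name])
  if (length(fu) != 1L || is.na(fu)) {
    abort_validation(sprintf("fup missing for species '%s'", sp_name))
  }
  if (!is.null(drug$pka) && any(drug$pka$type == "base" & drug$pka$value >= 7)) {
    abort_validation("strong bases are outside this equation set")
  }
  comp <- .rr_tissue_composition
  pl <- .rr_plasma_composition
  p_ow <- 10^drug$logp
  y <- ionization_factor(7.4, drug$pka)   # plasma
  x <- ionization_factor(7.0, drug$pka)   # intracellular water
  # adipose: vegetable oil:water distribution coefficient at plasma pH
  logd_74 <- drug$logp - log10(y)
  d_vow <- 10^(1.115 * logd_74 - 1.35)

  plasma_lipid <- (p_ow * pl[["f_nl"]] + (0.3 * p_ow + 0.7) * pl[["f_npl"]]) / y
  kpu <- vapply(seq_len(nrow(comp)), function(i) {
    lipid <- if (comp$tissue[i] == "adipose") {
      d_vow * comp$f_nl[i] + (0.3 * d_vow + 0.7) * comp$f_npl[i]
    } else {
      (p_ow * comp$f_nl[i] + (0.3 * p_ow + 0.7) * comp$f_npl[i]) / y
    }
    protein <- (1 / fu - 1 - plasma_lipid) * comp$ar[i]
    comp$f_ew[i] + (x / y) * comp$f_iw[i] + lipid + protein
  }, numeric(1))
  kp <- kpu * fu
  names(kp) <- comp$tissue
  if (any(kp <= 0)) abort_validation("non-positive computed Kp; check inputs")
  if (apply_overrides && length(drug$kp_overrides)) {
    unknown <- setdiff(names(drug$kp_overrides), names(kp))
    if (length(unknown)) {
      abort_validation(paste0("Kp override for unknown tissue: ",
                              paste(unknown, collapse = ", ")))
    }
    kp[names(drug$kp_overrides)] <- drug$kp_overrides
  }
  kp
}
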