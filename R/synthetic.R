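# Seeded synthetic study generators emulating the supported preclinical
# designs: single-dose IV+PO PK studies (1 IV + 3 oral dose arms, 3/sex/arm),
# a 4-timepoint destructive tissue-distribution study, and the in-vitro
# designs (transwell transport, equilibrium dialysis, hepatocyte depletion).
# Every generator takes a seed and returns the generating truth alongside the
# data, so downstream estimators can be checked by inversion.

# Disposition models ---------------------------------------------------------

onecomp_iv_conc <- function(t, cl, v, dose) {
  (dose / v) * exp(-(cl / v) * t) * 1000          # mg/kg, L/kg -> ng/mL
}

twocomp_macro <- function(cl, v1, q, v2) {
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(alpha = alpha, beta = beta, k21 = k21)
}

twocomp_iv_conc <- function(t, cl, v1, q, v2, dose) {
  m <- twocomp_macro(cl, v1, q, v2)
  a <- (dose / v1) * (m$alpha - m$k21) / (m$alpha - m$beta)
  b <- (dose / v1) * (m$k21 - m$beta) / (m$alpha - m$beta)
  (a * exp(-m$alpha * t) + b * exp(-m$beta * t)) * 1000
}

twocomp_oral_conc <- function(t, cl, v1, q, v2, ka, f, dose) {
  m <- twocomp_macro(cl, v1, q, v2)
  al <- m$alpha; be <- m$beta; k21 <- m$k21
  coefs <- c(
    (k21 - al) / ((ka - al) * (be - al)),
    (k21 - be) / ((ka - be) * (al - be)),
    (k21 - ka) / ((al - ka) * (be - ka))
  )
  conc <- (f * dose * ka / v1) *
    (coefs[1] * exp(-al * t) + coefs[2] * exp(-be * t) + coefs[3] * exp(-ka * t))
  conc * 1000
}

# Study designs: 1 IV group + 3 oral dose groups, 3 per sex per group, with
# the sex-specific oral doses of the supported rat design.
.pk_designs <- list(
  rat = list(iv_dose = c(M = 1, F = 1),
             oral_doses = list(M = c(2, 6, 20), F = c(1, 3, 10))),
  dog = list(iv_dose = c(M = 0.2, F = 0.2),
             oral_doses = list(M = c(0.05, 0.2, 0.8), F = c(0.05, 0.2, 0.8)))
)

#' Generate a synthetic single-dose PK study
#'
#' Emulates the supported preclinical design: one IV bolus group and three
#' oral dose groups, each with `n_per_sex` males and females, sampled at the
#' given timepoints. Per-subject parameters are lognormally perturbed
#' (between-subject variability) and a lognormal residual is applied to each
#' concentration.
#'
#' @param species `"rat"` or `"dog"` (selects the dose design).
#' @param model `"one_compartment"` or `"two_compartment"` disposition with
#'   first-order oral input.
#' @param true_params named list: `cl` (L/h/kg), `v` (L/kg; for the
#'   two-compartment model `v1`, `q`, `v2` instead), `ka` (1/h), `f`
#'   (fraction).
#' @param n_per_sex subjects per sex per group (default 3).
#' @param timepoints sampling times, h.
#' @param bsv_cv between-subject CV on CL, V and Ka (default 0).
#' @param noise_cv residual lognormal CV on concentrations (default 0.15).
#' @param seed RNG seed.
#' @return list with `dataset` (a [study_dataset()]) and `truth` (the
#'   generating manifest, including the seed).
#' @export
gen_pk_study <- function(species = c("rat", "dog"),
                         model = c("one_compartment", "two_compartment"),
                         true_params, n_per_sex = 3,
                         timepoints = c(0.083, 0.25, 0.5, 1, 2, 4, 8, 24),
                         bsv_cv = 0, noise_cv = 0.15, seed = NULL) {
  species <- match.arg(species)
  model <- match.arg(model)
  if (noise_cv < 0 || bsv_cv < 0) abort_validation("CVs must be >= 0")
  design <- .pk_designs[[species]]

  conc_fun <- function(t, pars, dose, route) {
    if (model == "one_compartment") {
      if (route == "iv_bolus") onecomp_iv_conc(t, pars$cl, pars$v, dose)
      else onecomp_oral_conc(t, pars$ka, pars$cl / pars$v, pars$v / pars$f, dose)
    } else {
      if (route == "iv_bolus") twocomp_iv_conc(t, pars$cl, pars$v1, pars$q, pars$v2, dose)
      else twocomp_oral_conc(t, pars$cl, pars$v1, pars$q, pars$v2, pars$ka,
                             pars$f, dose)
    }
  }
  perturb <- function(pars) {
    if (bsv_cv == 0) return(pars)
    sd <- lognormal_sdlog(bsv_cv)
    for (nm in intersect(names(pars), c("cl", "v", "v1", "v2", "q", "ka"))) {
      pars[[nm]] <- pars[[nm]] * stats::rlnorm(1, 0, sd)
    }
    pars
  }

  rows <- with_seed(seed, {
    out <- list(); id <- 0L
    groups <- c(list(list(route = "iv_bolus", doses = design$iv_dose)),
                lapply(seq_along(design$oral_doses$M), function(i) {
                  list(route = "oral",
                       doses = c(M = design$oral_doses$M[i],
                                 F = design$oral_doses$F[i]))
                }))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      for (sex in c("M", "F")) {
        for (k in seq_len(n_per_sex)) {
          id <- id + 1L
          pars <- perturb(true_params)
          conc <- conc_fun(timepoints, pars, g$doses[[sex]], g$route)
          if (noise_cv > 0) {
            conc <- conc * stats::rlnorm(length(conc), 0, lognormal_sdlog(noise_cv))
          }
          out[[id]] <- data.frame(
            subject_id = sprintf("%s%03d", toupper(substr(species, 1, 1)), id),
            species = species, sex = sex, group = sprintf("G%d", gi),
            route = g$route, dose = g$doses[[sex]], dose_units = "mg/kg",
            matrix = "plasma", time_h = timepoints, conc_ng_per_ml = conc,
            stringsAsFactors = FALSE)
        }
      }
    }
    out
  })
  dataset <- study_dataset(do.call(rbind, rows),
                           label = sprintf("synthetic %s PK study", species))
  truth <- list(design = "pk_study", species = species, model = model,
                true_params = true_params, n_per_sex = n_per_sex,
                timepoints = timepoints, bsv_cv = bsv_cv, noise_cv = noise_cv,
                seed = seed,
                n_subjects = 2L * n_per_sex * 4L,
                n_records = 2L * n_per_sex * 4L * length(timepoints))
  list(dataset = dataset, truth = truth)
}

#' Generate a synthetic tissue-distribution study
#'
#' Destructive-sampling design: `n_per_time` rats per timepoint (different
#' animals at each time), each contributing plasma, whole blood and the
#' requested tissues. Tissue concentration = plasma x Kp (time-independent),
#' blood = plasma x BP, with lognormal residual noise.
#'
#' @param kp named vector of true tissue:plasma coefficients (e.g.
#'   `c(liver = 12.9)`).
#' @param bp_ratio true blood:plasma ratio.
#' @param plasma_params list `cl` (L/h/kg), `v` (L/kg), `ka` (1/h), `f` for
#'   the underlying oral plasma profile.
#' @param dose oral dose, mg/kg (default 3, the radiolabel study dose).
#' @param timepoints sampling times, h (default 0.5, 2, 8, 24).
#' @param n_per_time animals per timepoint (default 6).
#' @param noise_cv residual lognormal CV (default 0.15).
#' @param seed RNG seed.
#' @return list with `dataset` (multi-matrix [study_dataset()]) and `truth`.
#' @export
gen_tissue_study <- function(kp, bp_ratio, plasma_params, dose = 3,
                             timepoints = c(0.5, 2, 8, 24), n_per_time = 6,
                             noise_cv = 0.15, seed = NULL) {
  if (is.null(names(kp))) abort_validation("kp must be named by tissue")
  rows <- with_seed(seed, {
    out <- list(); id <- 0L
    for (ti in seq_along(timepoints)) {
      t <- timepoints[ti]
      for (k in seq_len(n_per_time)) {
        id <- id + 1L
        cp <- onecomp_oral_conc(t, plasma_params$ka,
                                plasma_params$cl / plasma_params$v,
                                plasma_params$v / plasma_params$f, dose)
        matrices <- c(plasma = cp, blood = cp * bp_ratio, cp * kp)
        names(matrices) <- c("plasma", "blood", names(kp))
        if (noise_cv > 0) {
          matrices <- matrices * stats::rlnorm(length(matrices), 0,
                                               lognormal_sdlog(noise_cv))
        }
        out[[id]] <- data.frame(
          subject_id = sprintf("T%03d", id), species = "rat",
          sex = if (k <= n_per_time / 2) "M" else "F",
          group = sprintf("T%gh", t), route = "oral", dose = dose,
          dose_units = "mg/kg", matrix = names(matrices), time_h = t,
          conc_ng_per_ml = unname(matrices), stringsAsFactors = FALSE)
      }
    }
    out
  })
  dataset <- study_dataset(do.call(rbind, rows),
                           label = "synthetic tissue distribution study")
  truth <- list(design = "tissue_study", kp = kp, bp_ratio = bp_ratio,
                plasma_params = plasma_params, dose = dose,
                timepoints = timepoints, n_per_time = n_per_time,
                noise_cv = noise_cv, seed = seed)
  list(dataset = dataset, truth = truth)
}

#' Generate synthetic in-vitro fixtures
#'
#' Transwell transport, equilibrium dialysis and hepatocyte depletion
#' datasets at the supported assay designs, each returned with its generating
#' truth.
#'
#' @param design `"transwell"`, `"dialysis"` or `"depletion"`.
#' @param true_params design-specific truth: transwell `papp` (1e-6 cm/s),
#'   optional `area` (cm2, default 1.12), `c0_um` (default `c(1, 5, 30)`);
#'   dialysis `fup`, optional `conc_um` (default `c(0.2, 2, 10)`),
#'   `replicates` (default 3); depletion `t_half_min` (or `k_min`), optional
#'   `cell_density` (1e6 cells/mL, default 1).
#' @param noise_cv residual lognormal CV (default 0.15).
#' @param seed RNG seed.
#' @return list with `data` (design-specific data.frame) and `truth`.
#' @export
gen_invitro <- function(design = c("transwell", "dialysis", "depletion"),
                        true_params, noise_cv = 0.15, seed = NULL) {
  design <- match.arg(design)
  noisy <- function(x) {
    if (noise_cv > 0) x * stats::rlnorm(length(x), 0, lognormal_sdlog(noise_cv))
    else x
  }
  out <- with_seed(seed, switch(design,
    transwell = {
      area <- true_params$area %||% 1.12
      c0 <- true_params$c0_um %||% c(1, 5, 30)
      times <- true_params$times_h %||% c(0.5, 1, 1.5, 2)
      rows <- lapply(c0, function(cc) {
        # Papp (1e-6 cm/s) * area (cm2) * C0 (nmol/cm3) * 3600 -> nmol/h
        rate <- true_params$papp * 1e-6 * area * cc * 3600
        data.frame(c0_um = cc, time_h = times,
                   amount_nmol = noisy(rate * times))
      })
      do.call(rbind, rows)
    },
    dialysis = {
      reps <- true_params$replicates %||% 3
      conc <- true_params$conc_um %||% c(0.2, 2, 10)
      mw <- true_params$mw %||% 556.46
      rows <- lapply(conc, function(cc) {
        cp <- rep(cc * mw, reps)          # uM -> ng/mL
        data.frame(conc_um = cc, replicate = seq_len(reps),
                   c_plasma = noisy(cp),
                   c_buffer = noisy(cp * true_params$fup))
      })
      do.call(rbind, rows)
    },
    depletion = {
      k <- true_params$k_min %||% (log(2) / true_params$t_half_min)
      times <- true_params$times_min %||% c(0, 5, 15, 30, 60, 90, 120)
      frac <- exp(-k * times)
      frac[times > 0] <- noisy(frac[times > 0])
      data.frame(time_min = times,
                 fraction_remaining = pmin(frac, 1),
                 cell_density = true_params$cell_density %||% 1)
    }
  ))
  list(data = out,
       truth = c(list(design = design, noise_cv = noise_cv, seed = seed),
                 true_params))
}
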