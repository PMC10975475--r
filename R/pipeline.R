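# End-to-end pipeline: reads a structured configuration, runs the
# translation stages in order (studies -> NCA -> Ka -> allometry -> FIH dose
# -> PBPK), writes TSV reports, simulation exports and a JSON run manifest.

#' Read a pipeline configuration
#'
#' YAML configuration with sections `drug`, `species`, `studies`,
#' `allometry`, `dose`, `pbpk` (all optional except `dose`'s policy values
#' when the dose stage runs). See `inst/extdata/demo-config.yaml` for the
#' bundled demonstration configuration carrying the reference program values.
#'
#' @param path path to a YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_io(paste0("config not found: ", path))
  yaml::read_yaml(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full translation pipeline
#'
#' Executes, in order: synthetic study generation + NCA + Ka fitting (stage
#' `studies`), allometric extrapolation (stage `allometry`), FIH dose
#' prediction (stage `dose`) and, when configured, PBPK simulation (stage
#' `pbpk`). Each stage's outputs are written as TSV reports under `out_dir`
#' along with a JSON manifest recording the seed and a configuration hash;
#' rerunning with the same configuration and seed reproduces the outputs
#' byte for byte. A stage failure aborts with the stage name and cause. When
#' the configuration has no `pbpk` section the pipeline stops after the dose
#' stage.
#'
#' @param config a configuration list or a path to a YAML file
#'   (see [read_config()]).
#' @param out_dir output directory.
#' @param seed integer seed for all stochastic stages.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  if (!is.list(config)) abort_validation("config must be a list or a file path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            "pktranslate_pipeline_error")
    })
  }

  drug <- stage("drug", {
    if (isTRUE(config$drug$xzp5610) || is.null(config$drug)) xzp5610_properties()
    else do.call(drug_properties, config$drug)
  })
  profiles <- stage("species", {
    bw <- config$species %||% list()
    list(rat = species_profile("rat", bw$rat_bw),
         dog = species_profile("dog", bw$dog_bw),
         human = species_profile("human", bw$human_bw))
  })

  # --- studies: synthetic generation, NCA, Ka fitting -----------------------
  st <- config$studies %||% list()
  studies <- stage("studies", {
    # one-compartment emulations of the mean oral profiles: V chosen so the
    # terminal slope matches the observed oral half-life (the oral V/F is
    # not the IV Vss; with V = Vss the rat would sit in flip-flop, ke > ka)
    truths <- list(
      rat = st$rat %||% list(cl = 1.9, v = 3.6, ka = 2.34, f = 0.147),
      dog = st$dog %||% list(cl = 0.2, v = 1.05, ka = 0.589, f = 0.574)
    )
    noise <- st$noise_cv %||% 0
    bsv <- st$bsv_cv %||% 0
    out <- list()
    for (sp in c("rat", "dog")) {
      gen <- gen_pk_study(sp, "one_compartment", truths[[sp]],
                          bsv_cv = bsv, noise_cv = noise, seed = seed)
      res <- nca(gen$dataset)
      # mean oral profile (pooled across sexes and doses, dose-normalised)
      df <- as.data.frame(gen$dataset)
      df <- df[df$route == "oral", ]
      dn <- df$conc_ng_per_ml / df$dose
      prof <- stats::aggregate(dn, list(time_h = df$time_h), mean)
      fit <- fit_onecomp(prof$time_h, prof$x, dose = 1)
      out[[sp]] <- list(truth = gen$truth, nca = res, ka_fit = fit)
    }
    out
  })
  results$studies <- studies
  write_report(list(nca_rat = studies$rat$nca$summary,
                    nca_dog = studies$dog$nca$summary), out_dir)

  # --- allometry ------------------------------------------------------------
  allo <- stage("allometry", {
    cfg <- config$allometry %||% list()
    inputs <- lapply(c("rat", "dog"), function(sp) {
      ref <- xzp5610_pk_summary(sp)
      iv <- ref[ref$route == "iv_bolus", ]
      list(species = sp,
           cl_per_kg = mean(iv$cl_l_h_kg), vss_per_kg = mean(iv$vss_l_kg),
           f = ref$f_pct[!is.na(ref$f_pct)],
           bw = profiles[[sp]]$body_weight)
    })
    names(inputs) <- c("rat", "dog")
    human <- profiles$human
    fups <- drug$fup
    preds <- list()
    for (sp in c("rat", "dog")) {
      x <- inputs[[sp]]
      cl_a <- x$cl_per_kg * x$bw
      preds[[length(preds) + 1]] <- data.frame(
        parameter = "cl_iv", method = "SSS", source_species = sp,
        value = cl_sss(cl_a, x$bw, human$body_weight,
                       cfg$sss_exponent %||% 0.66))
      preds[[length(preds) + 1]] <- data.frame(
        parameter = "cl_iv", method = "SSAS", source_species = sp,
        value = cl_ssas_fu(cl_a, x$bw, human$body_weight, fups[[sp]],
                           fups[["human"]]))
      preds[[length(preds) + 1]] <- data.frame(
        parameter = "cl_iv", method = "FCIM", source_species = sp,
        value = cl_fcim(cl_a, x$bw, fups[[sp]], fups[["human"]]))
      q_a <- profiles[[sp]]$q_hepatic * x$bw
      q_h <- human$q_hepatic * human$body_weight
      preds[[length(preds) + 1]] <- data.frame(
        parameter = "cl_iv", method = "HBF", source_species = sp,
        value = cl_hbf(cl_a * 1000 / 60, q_a, q_h)$value)
      preds[[length(preds) + 1]] <- data.frame(
        parameter = "vss", method = "PerKgVss", source_species = sp,
        value = vss_perkg(x$vss_per_kg, human$body_weight))
    }
    tsas <- cl_tsas(c(inputs$rat$cl_per_kg * inputs$rat$bw,
                      inputs$dog$cl_per_kg * inputs$dog$bw),
                    c(inputs$rat$bw, inputs$dog$bw), human$body_weight)
    preds[[length(preds) + 1]] <- data.frame(
      parameter = "cl_iv", method = "TSAS", source_species = "rat+dog",
      value = tsas$value)
    ot <- vss_oie_tozer(c(rat = inputs$rat$vss_per_kg,
                          dog = inputs$dog$vss_per_kg),
                        fups, human)
    preds[[length(preds) + 1]] <- data.frame(
      parameter = "vss", method = "OieTozer", source_species = "rat+dog",
      value = ot$value)
    computed <- do.call(rbind, preds)

    agg_src <- cfg$aggregate_source %||% "reference"
    agg_tab <- if (agg_src == "reference") xzp5610_scaling_reference() else computed
    cl_agg <- aggregate_predictions(agg_tab[agg_tab$parameter == "cl_iv", ],
                                    "dog_single_species")
    vss_agg <- aggregate_predictions(agg_tab[agg_tab$parameter == "vss", ],
                                     "all_methods_mean")
    fpol <- f_policy(list(rat = inputs$rat$f, dog = inputs$dog$f))
    kapol <- ka_policy(list(rat = studies$rat$ka_fit, dog = studies$dog$ka_fit))
    list(computed = computed, cl_ml_min = cl_agg$value, vss_l = vss_agg$value,
         cl_aggregate = cl_agg, vss_aggregate = vss_agg,
         f = fpol, ka = kapol, oie_tozer = ot)
  })
  results$allometry <- allo
  write_report(list(allometry_predictions = allo$computed), out_dir)
  writeLines(jsonlite::toJSON(list(
    cl_ml_min = allo$cl_ml_min, vss_l = allo$vss_l,
    cl_members = allo$cl_aggregate$members$value,
    vss_members = allo$vss_aggregate$members$value,
    f_pct = allo$f, ka_per_h = allo$ka
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE),
  file.path(out_dir, "human_predictions.json"))

  # --- FIH dose -------------------------------------------------------------
  dose_res <- stage("dose", {
    cfg <- config$dose %||% list()
    noael <- xzp5610_noael()
    sf <- cfg$safety_factor %||% 10
    bsa <- mrsd_bsa_table(noael, profiles$human, sf = sf)
    expo <- mrsd_exposure_table(noael, drug$fup,
                                cl_human = allo$cl_ml_min * 60 / 1000,
                                f_human = allo$f$typical / 100, sf = sf)
    plan <- build_dose_plan(
      mrsd_mg = c(bsa$mrsd_mg, expo$mrsd_mg),
      efficacy_heds_mg = cfg$efficacy_heds_mg %||% numeric(),
      mabel_mg = cfg$mabel_mg %||% 2, mtd_mg = cfg$mtd_mg %||% 3,
      granularity = cfg$granularity %||% 0.05
    )
    list(bsa = bsa, exposure = expo, plan = plan)
  })
  results$dose <- dose_res
  write_report(list(mrsd_bsa = dose_res$bsa, mrsd_exposure = dose_res$exposure),
               out_dir)
  writeLines(jsonlite::toJSON(unclass(dose_res$plan), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "dose_plan.json"))

  # --- PBPK (optional) ------------------------------------------------------
  if (!is.null(config$pbpk)) {
    pb <- stage("pbpk", {
      cfg <- config$pbpk
      human_model <- build_model(
        drug, profiles$human,
        cl_per_kg = (allo$cl_ml_min * 60 / 1000) / profiles$human$body_weight,
        ka = allo$ka$typical, f_target = allo$f$typical / 100
      )
      doses <- as.numeric(unlist(cfg$human_doses_mg %||% c(0.15, 0.5, 1, 3)))
      t_end <- cfg$t_end_h %||% 48
      dt <- cfg$dt_h %||% 0.05
      sims <- lapply(doses, function(d) {
        simulate_pbpk(human_model,
                      data.frame(time = 0, route = "oral", dose_mg = d),
                      t_end = t_end, dt = dt)
      })
      ratios <- data.frame(
        dose_mg = doses,
        liver_plasma_auc = vapply(sims, liver_plasma_ratio, numeric(1), basis = "auc"),
        liver_plasma_cmax = vapply(sims, liver_plasma_ratio, numeric(1), basis = "cmax")
      )
      export <- do.call(rbind, lapply(seq_along(doses), function(i) {
        s <- sims[[i]]
        data.frame(dose_mg = doses[i], time_h = s$times,
                   plasma_ng_ml = s$conc[, "plasma"],
                   liver_ng_ml = s$conc[, "liver"])
      }))
      utils::write.csv(export, file.path(out_dir, "human_profiles.csv"),
                       row.names = FALSE)
      list(model = human_model, sims = sims, ratios = ratios)
    })
    results$pbpk <- pb
    write_report(list(liver_plasma_ratios = pb$ratios), out_dir)
  }

  manifest <- list(
    package = "pktranslate",
    version = as.character(utils::packageVersion("pktranslate")),
    seed = seed, config_hash = config_hash(config),
    stages = names(results)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(results)
}
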