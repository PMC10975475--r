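# a degenerate two-compartment table (lung + one lumped tissue) with very
# fast flows collapses to a well-mixed single volume
degenerate_model <- function(cl = 0.5, v_tissue = 0.6, ehc = FALSE) {
  tiss <- data.frame(
    name = c("lung", "liver"),
    volume_l = c(0.1, v_tissue),
    flow_l_h = c(1e5, 1e5),
    kp = c(1, 1), stringsAsFactors = FALSE
  )
  pbpk_model(tiss, v_art = 0.1, v_ven = 0.2, bp = 1, fup = 1,
             cl_met = cl, cl_biliary = 0, ka = 1, f_abs = 1,
             ehc_enabled = ehc, reabsorption_fraction = 0)
}

test_that("degenerate one-tissue model matches the one-compartment closed form", {
  m <- degenerate_model(cl = 0.5, v_tissue = 0.6)
  v_tot <- 0.1 + 0.6 + 0.1 + 0.2
  s <- simulate_pbpk(m, data.frame(time = 0, route = "iv_bolus", dose_mg = 2),
                     t_end = 10, dt = 0.1)
  analytic <- 2 / v_tot * exp(-0.5 / v_tot * s$times) * 1000
  keep <- s$times >= 0.5  # past the (fast) mixing transient
  expect_equal(s$conc[keep, "plasma"], analytic[keep], tolerance = 1e-3)
  expect_lt(s$mass_balance_error, 1e-6)
})

test_that("zero clearance conserves the dose exactly", {
  m <- degenerate_model(cl = 0)
  s <- simulate_pbpk(m, data.frame(time = c(0, 2), route = "iv_bolus",
                                   dose_mg = c(1, 0.5)), t_end = 6, dt = 0.1)
  in_system <- rowSums(s$amounts[, c("lung", "liver", "arterial_blood",
                                     "venous_blood")])
  expect_equal(in_system[s$times > 2.01], rep(1.5, sum(s$times > 2.01)),
               tolerance = 1e-8)
})

test_that("whole-body model balances mass and flows", {
  m <- rat_reference_model()
  expect_equal(sum(m$tissues$flow_l_h[m$tissues$name != "lung"]) -
                 sum(m$tissues$flow_l_h[m$tissues$name %in% c("gut", "spleen")]),
               m$cardiac_output, tolerance = 1e-9)
  s <- simulate_pbpk(m, data.frame(time = 0, route = "oral", dose_mg = 0.735),
                     t_end = 24)
  expect_lt(s$mass_balance_error, 1e-6)
  expect_true(all(s$amounts >= -1e-9))
})

test_that("the model is linear in dose", {
  m <- rat_reference_model()
  reg <- function(d) data.frame(time = 0, route = "oral", dose_mg = d)
  s1 <- simulate_pbpk(m, reg(0.5), t_end = 12, dt = 0.1)
  s2 <- simulate_pbpk(m, reg(1.0), t_end = 12, dt = 0.1)
  keep <- s1$conc[, "plasma"] > 1e-6
  expect_equal(s2$conc[keep, "plasma"] / s1$conc[keep, "plasma"],
               rep(2, sum(keep)), tolerance = 1e-5)
})

test_that("halving integrator tolerances leaves AUC essentially unchanged", {
  m <- rat_reference_model()
  reg <- data.frame(time = 0, route = "oral", dose_mg = 0.735)
  s1 <- simulate_pbpk(m, reg, t_end = 24, dt = 0.1)
  s2 <- simulate_pbpk(m, reg, t_end = 24, dt = 0.1, rtol = 5e-9, atol = 5e-11)
  a1 <- auc_trapezoid(s1$times, s1$conc[, "plasma"])
  a2 <- auc_trapezoid(s2$times, s2$conc[, "plasma"])
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("enterohepatic recirculation delays or preserves Tmax", {
  m <- rat_reference_model()
  m_off <- m
  m_off$ehc_enabled <- FALSE   # same parameters, recycling switched off
  reg <- data.frame(time = 0, route = "oral", dose_mg = 0.735)
  s_on <- simulate_pbpk(m, reg, t_end = 24, dt = 0.02)
  s_off <- simulate_pbpk(m_off, reg, t_end = 24, dt = 0.02)
  tmax_on <- s_on$times[which.max(s_on$conc[, "plasma"])]
  tmax_off <- s_off$times[which.max(s_off$conc[, "plasma"])]
  expect_gte(tmax_on, tmax_off)
})

test_that("rat model with the calibrated liver coefficient stays in band", {
  m <- rat_reference_model()
  s <- simulate_pbpk(m, data.frame(time = 0, route = "oral", dose_mg = 3 * 0.245),
                     t_end = 48)
  ratio <- liver_plasma_ratio(s, "auc")
  expect_gt(ratio, 6.5)
  expect_lt(ratio, 25.8)
  # equilibrium check: all-ones partition, no elimination -> ratio near 1
  tiss <- data.frame(name = c("lung", "liver"), volume_l = c(0.1, 0.6),
                     flow_l_h = c(10, 10), kp = c(1, 1))
  m1 <- pbpk_model(tiss, v_art = 0.1, v_ven = 0.2, bp = 1, fup = 1,
                   cl_met = 0, cl_biliary = 0, ka = 1, f_abs = 1,
                   ehc_enabled = FALSE, reabsorption_fraction = 0)
  s1 <- simulate_pbpk(m1, data.frame(time = 0, route = "iv_bolus", dose_mg = 1),
                      t_end = 50, dt = 0.5)
  expect_equal(tail(s1$conc[, "liver"], 1) / tail(s1$conc[, "plasma"], 1), 1,
               tolerance = 1e-6)
})

test_that("validation report computes fold errors with band logic", {
  rep <- validate_predictions(c(a = 10, b = 7, c = 1),
                              c(a = 5, b = 7, c = 10), band = c(0.5, 2))
  expect_equal(rep$fold_error, c(2, 1, 0.1))
  expect_equal(rep$pass, c(TRUE, TRUE, FALSE))
  expect_warning(validate_predictions(c(a = 1, b = 2), c(a = 0, b = 2)),
                 "excluded")
  expect_error(validate_predictions(c(x = 1), c(y = 1)), "no matched")
})

test_that("self-consistent validation passes everywhere at zero noise", {
  truth <- list(cl = 1.9, v = 0.75, ka = 2.34, f = 0.15)
  gen <- gen_pk_study("rat", "one_compartment", truth, noise_cv = 0, seed = 5)
  res <- nca(gen$dataset, method = "linear_up_log_down")
  iv <- res$summary[res$summary$route == "iv_bolus", ]
  rep <- validate_predictions(
    c(cl = truth$cl, vss = truth$v),
    c(cl = mean(iv$cl_mean), vss = mean(iv$vss_mean))
  )
  expect_true(all(rep$pass))
  expect_equal(rep$fold_error, rep(1, 2), tolerance = 0.02)
})

test_that("population bands collapse at zero CV and reproduce under a seed", {
  m <- rat_reference_model()
  reg <- data.frame(time = 0, route = "oral", dose_mg = 0.735)
  p0 <- population_simulate(m, reg, t_end = 12, dt = 0.25, n = 3,
                            cv = c(cl = 0, kp = 0, ka = 0), seed = 9)
  expect_equal(p0$bands[, "p5"], p0$bands[, "p95"], tolerance = 1e-10)
  det <- simulate_pbpk(m, reg, t_end = 12, dt = 0.25)
  expect_equal(p0$bands[, "p50"],
               det$conc[match(p0$times, det$times), "plasma"],
               tolerance = 1e-8, ignore_attr = TRUE)

  pa <- population_simulate(m, reg, t_end = 12, dt = 0.5, n = 10,
                            cv = c(cl = 0.3, kp = 0.3, ka = 0.5), seed = 11)
  pb <- population_simulate(m, reg, t_end = 12, dt = 0.5, n = 10,
                            cv = c(cl = 0.3, kp = 0.3, ka = 0.5), seed = 11)
  expect_identical(pa$bands, pb$bands)
})

test_that("median population AUC matches the lognormal-median prediction", {
  m <- rat_reference_model()
  reg <- data.frame(time = 0, route = "oral", dose_mg = 0.735)
  pop <- population_simulate(m, reg, t_end = 24, dt = 0.25, n = 300,
                             cv = c(cl = 0.3, kp = 0, ka = 0), seed = 17,
                             probs = c(0.05, 0.5, 0.95))
  det <- simulate_pbpk(m, reg, t_end = 24, dt = 0.25)
  # AUC ~ 1/CL and median(CL multiplier) = 1, so the AUC of the median
  # profile tracks the deterministic AUC
  auc_med <- auc_trapezoid(pop$times, pop$bands[, "p50"])
  auc_det <- auc_trapezoid(det$times, det$conc[, "plasma"])
  expect_equal(auc_med, auc_det, tolerance = 0.05)
})
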