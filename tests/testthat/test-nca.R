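test_that("trapezoid AUC handles simple shapes exactly", {
  expect_equal(auc_trapezoid(c(0, 1), c(0, 2)), 1.0)
  expect_equal(auc_trapezoid(c(0, 2, 4), c(5, 5, 5)), 20)
  expect_error(auc_trapezoid(1, 5), "at least 2")
  expect_error(auc_trapezoid(c(1, 1), c(2, 2)), "strictly increasing")
})

test_that("dense sampling of an exponential matches the closed form", {
  tt <- seq(0, 24, by = 0.1)
  cc <- 100 * exp(-0.5 * tt)
  analytic <- 200 * (1 - exp(-12))
  expect_equal(auc_trapezoid(tt, cc), analytic, tolerance = 0.005)
  # log-down interpolation is exact for exponentials even at coarse sampling
  tc <- c(0, 1, 2, 4, 8, 24)
  expect_equal(auc_trapezoid(tc, 100 * exp(-0.5 * tc), "linear_up_log_down"),
               200 * (1 - exp(-12)), tolerance = 1e-10)
})

test_that("AUC is additive over contiguous intervals and scale-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    tt <- sort(runif(12, 0, 24))
    cc <- runif(12, 0, 100)
    k <- sample(3:9, 1)
    whole <- auc_trapezoid(tt, cc)
    parts <- auc_trapezoid(tt[1:k], cc[1:k]) +
      auc_trapezoid(tt[k:12], cc[k:12])
    expect_equal(whole, parts, tolerance = 1e-12)
    expect_equal(auc_trapezoid(tt, 3.7 * cc), 3.7 * whole, tolerance = 1e-12)
  }
})

test_that("terminal fit recovers exact mono-exponential decay", {
  tt <- c(0.5, 1, 2, 4, 8, 12)
  fit <- terminal_fit(tt, 500 * exp(-0.3 * tt))
  expect_true(fit$defined)
  expect_equal(fit$lambda_z, 0.3, tolerance = 1e-8)
  expect_equal(fit$t_half, log(2) / 0.3, tolerance = 1e-8)

  rising <- terminal_fit(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(rising$defined)
  expect_true(is.na(rising$t_half))
})

test_that("IV NCA matches analytic one-compartment values within 2%", {
  # truth: CL 2 L/h/kg, V 1 L/kg, dose 1 mg/kg -> C0 1000 ng/mL, k = 2/h
  tt <- seq(0.05, 10, by = 0.05)
  cc <- 1000 * exp(-2 * tt)
  p <- pktranslate:::nca_profile(tt, cc, dose = 1, route = "iv_bolus")
  expect_equal(p$cl, 2, tolerance = 0.02)
  expect_equal(p$mrt, 0.5, tolerance = 0.02)
  expect_equal(p$vss, 1, tolerance = 0.02)
  expect_equal(p$t_half, log(2) / 2, tolerance = 0.02)
})

test_that("group NCA summarises a synthetic study and flags heavy tails", {
  gen <- gen_pk_study("rat", "one_compartment",
                      list(cl = 1.9, v = 0.75, ka = 2.34, f = 0.15),
                      noise_cv = 0, seed = 11)
  res <- nca(gen$dataset, method = "linear_up_log_down")
  iv <- res$summary[res$summary$route == "iv_bolus", ]
  expect_equal(nrow(iv), 2)  # one row per sex
  expect_equal(iv$cl_mean, c(1.9, 1.9), tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(iv$vss_mean, c(0.75, 0.75), tolerance = 0.02,
               ignore_attr = TRUE)
  # Tmax tie reports the earliest time
  p <- pktranslate:::nca_profile(c(0, 1, 2, 3, 4), c(0, 5, 5, 3, 1),
                                 dose = 1, route = "oral")
  expect_equal(p$tmax, 1)
})

test_that("bioavailability and its summaries reproduce the study arithmetic", {
  expect_equal(bioavailability(94.9, 2, 488.3, 1), 9.7, tolerance = 0.005)
  expect_equal(bioavailability(100, 2, 50, 1), 100)
  expect_equal(bioavailability(508.3, 0.2, 864.4, 0.2), 58.8, tolerance = 0.002)
  expect_error(bioavailability(10, 1, 0, 1), class = "pktranslate_validation_error")

  dog_f <- xzp5610_pk_summary("dog")$f_pct
  rat_f <- xzp5610_pk_summary("rat")$f_pct
  expect_equal(summarize_f(dog_f[!is.na(dog_f)])$mean, 57.4, tolerance = 0.001)
  expect_equal(summarize_f(rat_f[!is.na(rat_f)])$mean, 14.7, tolerance = 0.005)
  expect_equal(summarize_f(42)$mean, 42)
  pol <- f_policy(list(rat = rat_f[!is.na(rat_f)], dog = dog_f[!is.na(dog_f)]))
  expect_equal(pol$typical, 57.4, tolerance = 0.001)
  expect_equal(pol$low, 14.7, tolerance = 0.005)
})
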