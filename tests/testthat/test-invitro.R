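test_that("papp converts receiver slope to cm/s correctly", {
  # slope 0.06 nmol/h over 1.12 cm2 at 1 uM (= 1 nmol/cm3):
  # 0.06/3600 nmol/s / 1.12 = 1.488e-5 cm/s = 14.88e-6 cm/s
  p <- papp(c(0, 1, 2), c(0, 0.06, 0.12), area = 1.12, c0 = 1)
  expect_equal(p, 0.06 / 3600 / 1.12 * 1e6, tolerance = 1e-10)

  expect_error(papp(c(0, 1, 2), c(0.1, 0.1, 0.1), area = 1, c0 = 1),
               "no measurable transport")
  expect_error(papp(c(0), c(0), area = 1, c0 = 1), "at least 2")
})

test_that("papp inverts the transwell generator at zero noise", {
  gen <- gen_invitro("transwell", list(papp = 10.1), noise_cv = 0, seed = 1)
  for (cc in unique(gen$data$c0_um)) {
    sub <- gen$data[gen$data$c0_um == cc, ]
    est <- papp(c(0, sub$time_h), c(0, sub$amount_nmol), area = 1.12, c0 = cc)
    expect_equal(est, 10.1, tolerance = 1e-6)
  }
})

test_that("efflux ratio is the BA/AB quotient", {
  expect_equal(efflux_ratio(5.29, 7.51), 7.51 / 5.29)
  expect_equal(efflux_ratio(3.3, 3.3), 1.0)
  expect_equal(efflux_ratio(14.7, 6.09), 6.09 / 14.7)
  expect_error(efflux_ratio(0, 1), class = "pktranslate_validation_error")
})

test_that("fup is buffer/plasma with artifact rejection", {
  expect_equal(fup(1000, 2), 0.002)
  expect_equal(fup(5, 5), 1.0)
  expect_error(fup(10, 11), "binding artifact")
  # triplicate recovery and unit invariance
  gen <- gen_invitro("dialysis", list(fup = 0.013), noise_cv = 0, seed = 2)
  expect_equal(fup(gen$data$c_plasma, gen$data$c_buffer), 0.013,
               tolerance = 1e-9)
  expect_equal(fup(gen$data$c_plasma * 7, gen$data$c_buffer * 7), 0.013,
               tolerance = 1e-9)
})

test_that("matrix_ratio averages per-time ratios and handles exclusions", {
  r <- matrix_ratio(c(0.54, 0.55, 0.66), c(1, 1, 1), times = c(0.5, 2, 8))
  expect_equal(r$mean, mean(c(0.54, 0.55, 0.66)))
  expect_equal(matrix_ratio(c(3, 2), c(3, 2), c(1, 2))$mean, 1.0)
  expect_warning(
    r2 <- matrix_ratio(c(1, 2), c(1, 0), c(1, 2)),
    "excluded")
  expect_equal(r2$mean, 1)
  expect_error(suppressWarnings(matrix_ratio(1, 0, 1)), "all timepoints")
})

test_that("matrix_ratio inverts the tissue-distribution generator", {
  gen <- gen_tissue_study(kp = c(liver = 12.9), bp_ratio = 0.58,
                          plasma_params = list(cl = 1.9, v = 0.75, ka = 2.34,
                                               f = 0.15),
                          noise_cv = 0, seed = 3)
  df <- as.data.frame(gen$dataset)
  prof <- function(mat) {
    agg <- aggregate(conc_ng_per_ml ~ time_h, df[df$matrix == mat, ], mean)
    agg$conc_ng_per_ml[agg$time_h %in% c(0.5, 2, 8)]
  }
  expect_equal(matrix_ratio(prof("liver"), prof("plasma"), c(0.5, 2, 8))$mean,
               12.9, tolerance = 1e-9)
  expect_equal(matrix_ratio(prof("blood"), prof("plasma"), c(0.5, 2, 8))$mean,
               0.58, tolerance = 1e-9)
})

test_that("hepatocyte depletion yields CLint and well-stirred CL_h", {
  rat <- species_profile("rat")
  tt <- c(0, 5, 15, 30, 60, 90, 120)
  res <- clint_from_depletion(tt, exp(-0.01 * tt), cell_density = 1,
                              species = rat, fup_value = 0.013,
                              bp_ratio = 0.58)
  expect_equal(res$k, 0.01, tolerance = 1e-10)
  expect_equal(res$t_half, log(2) / 0.01, tolerance = 1e-10)
  expect_equal(res$clint_invitro, 10)     # k * 1000 / density
  expect_false(res$poor_fit)
  # CL_h bounded above by hepatic blood flow and monotone in CLint
  fast <- clint_from_depletion(tt, exp(-0.5 * tt)[seq_along(tt)] + 1e-12,
                               cell_density = 1, species = rat,
                               fup_value = 0.9, bp_ratio = 1)
  expect_lt(res$cl_hepatic_predicted, rat$q_hepatic)
  expect_lt(fast$cl_hepatic_predicted, rat$q_hepatic)
  expect_gt(fast$cl_hepatic_predicted, res$cl_hepatic_predicted)
  # flow limit: fu_b * CLint >> Q_h drives CL_h towards Q_h
  expect_equal(fast$cl_hepatic_predicted / rat$q_hepatic, 1, tolerance = 0.05)
})

test_that("depletion generator inverts for a 60 min half-life", {
  rat <- species_profile("rat")
  gen <- gen_invitro("depletion", list(t_half_min = 60, cell_density = 1),
                     noise_cv = 0, seed = 4)
  res <- clint_from_depletion(gen$data$time_min, gen$data$fraction_remaining,
                              cell_density = 1, species = rat,
                              fup_value = 0.013, bp_ratio = 0.58)
  expect_equal(res$t_half, 60, tolerance = 1e-6)
})
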