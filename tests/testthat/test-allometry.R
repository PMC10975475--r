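# Per-animal clearances from the study group means: per-kg CL x representative
# body weight (0.245 kg rat, 7.21 kg dog, 60 kg human).
cl_rat <- 1.9 * 0.245   # L/h
cl_dog <- 0.2 * 7.21

test_that("single-species scaling reproduces hand arithmetic", {
  expect_equal(cl_sss(cl_rat, 0.245, 60, 0.66),
               cl_rat * (60 / 0.245)^0.66 * 1000 / 60, tolerance = 1e-12)
  expect_equal(cl_sss(cl_rat, 0.245, 60, 0.66), 292.9, tolerance = 0.001)
  expect_equal(cl_sss(2, 5, 5, 0.75), 2 * 1000 / 60)          # identity
  expect_equal(cl_sss(2, 5, 10, 1), 2 * cl_sss(2, 5, 5, 1))   # linearity
})

test_that("fu-corrected single-species scaling matches its oracle", {
  expect_equal(cl_ssas_fu(cl_rat, 0.245, 60, 0.013, 0.002),
               (cl_rat / 0.013) * (60 / 0.245)^0.75 * 0.002 * 1000 / 60,
               tolerance = 1e-12)
  expect_equal(cl_ssas_fu(cl_rat, 0.245, 60, 0.013, 0.002), 73.9,
               tolerance = 0.001)
  # reduces to SSS at matched fup and exponent
  expect_equal(cl_ssas_fu(2, 1, 60, 0.01, 0.01, exponent = 0.75),
               cl_sss(2, 1, 60, exponent = 0.75))
  # invariant under joint fup rescaling
  expect_equal(cl_ssas_fu(2, 1, 60, 0.02, 0.004),
               cl_ssas_fu(2, 1, 60, 0.01, 0.002))
})

test_that("two-species regression interpolates and recovers power laws", {
  fit <- cl_tsas(c(cl_rat, cl_dog), c(0.245, 7.21), 60)
  expect_equal(fit$b, log(cl_dog / cl_rat) / log(7.21 / 0.245),
               tolerance = 1e-10)
  expect_equal(fit$b, 0.334, tolerance = 0.002)
  expect_equal(fit$value, 48.8, tolerance = 0.001)
  # exact power law through 3 points
  bw <- c(0.02, 0.25, 10)
  fit2 <- cl_tsas(0.9 * bw^0.75, bw, 60)
  expect_equal(fit2$b, 0.75, tolerance = 1e-10)
  # interpolation at a source body weight returns its own clearance
  expect_equal(cl_tsas(c(cl_rat, cl_dog), c(0.245, 7.21), 7.21)$value,
               cl_dog * 1000 / 60, tolerance = 1e-9)
  expect_error(cl_tsas(c(1, 2), c(5, 5), 60), "distinct")
})

test_that("FCIM follows the Tang-Mayersohn form", {
  a <- (cl_rat * 1000 / 60) / 0.245^0.75
  expect_equal(a, 22.28, tolerance = 0.001)
  expect_equal(cl_fcim(cl_rat, 0.245, 0.013, 0.002),
               33.35 * (a / 6.5)^0.77, tolerance = 1e-12)
  expect_equal(cl_fcim(cl_rat, 0.245, 0.013, 0.002), 86.1, tolerance = 0.001)
  # intercept definition: a = 1, Rfu = 1 -> 33.35
  expect_equal(cl_fcim(60 / 1000, 1, 0.5, 0.5), 33.35, tolerance = 1e-9)
  # homogeneity: a x 2^(1/0.77) doubles the prediction
  base <- cl_fcim(cl_rat, 0.245, 0.013, 0.002)
  expect_equal(cl_fcim(cl_rat * 2^(1 / 0.77), 0.245, 0.013, 0.002), 2 * base,
               tolerance = 1e-9)
})

test_that("hepatic blood flow method transfers the extraction ratio", {
  h <- cl_hbf(cl_rat * 1000 / 60, 55.2 * 0.245, 1450)
  expect_equal(h$value, 831.8, tolerance = 0.001)
  expect_false(h$implausible)
  expect_equal(cl_hbf(10, 10, 99)$value, 99)       # extraction 1
  expect_equal(cl_hbf(1e-9, 10, 99)$extraction, 1e-10)
  expect_warning(cl_hbf(12, 10, 99), "exceeds")
})

test_that("Vss predictors reproduce the per-kg and Oie-Tozer arithmetic", {
  expect_equal(vss_perkg(1.05, 60), 63.0)
  expect_equal(vss_perkg(0.75, 60), 45.0)
  expect_equal(vss_perkg(1.05, 7.21), 1.05 * 7.21)

  hum <- species_profile("human")
  ot <- vss_oie_tozer(c(rat = 0.75, dog = 1.05),
                      c(rat = 0.013, dog = 0.003, human = 0.002), hum)
  # independent arithmetic oracle from the library volumes
  fut_rat <- 0.013 * 0.364 /
    (0.75 - 0.0313 - 0.013 * 0.265 - (1 - 0.013) * 0.182 * 0.0313)
  fut_dog <- 0.003 * 0.450 /
    (1.05 - 0.0515 - 0.003 * 0.216 - (1 - 0.003) * 0.666 * 0.0515)
  vkg <- 0.0436 + 0.002 * 0.151 + (1 - 0.002) * 1.4 * 0.0436 +
    0.380 * 0.002 / mean(c(fut_rat, fut_dog))
  expect_equal(ot$fut, c(rat = fut_rat, dog = fut_dog), tolerance = 1e-12)
  expect_equal(ot$value, vkg * 60, tolerance = 1e-12)
  expect_equal(ot$value, 17.1, tolerance = 0.05)

  # Vss below plasma space is rejected
  expect_error(vss_oie_tozer(c(rat = 0.02),
                             c(rat = 0.013, human = 0.002), hum),
               "plasma space")
})

test_that("clearance predictors are homogeneous of degree 1 in CL", {
  for (s in c(0.5, 2, 10)) {
    expect_equal(cl_sss(s * cl_rat, 0.245, 60), s * cl_sss(cl_rat, 0.245, 60))
    expect_equal(cl_ssas_fu(s * cl_rat, 0.245, 60, 0.013, 0.002),
                 s * cl_ssas_fu(cl_rat, 0.245, 60, 0.013, 0.002))
    expect_equal(cl_hbf(s * 1, 50, 1242)$value, s * cl_hbf(1, 50, 1242)$value)
  }
})

test_that("aggregation policies average the right members", {
  ref <- xzp5610_scaling_reference()
  cl <- aggregate_predictions(ref[ref$parameter == "cl_iv", ],
                              "dog_single_species")
  expect_equal(cl$n, 4)
  expect_equal(sort(cl$members$value), sort(c(96.4, 92.3, 181, 184)))
  expect_equal(cl$value, mean(c(96.4, 92.3, 181, 184)))
  expect_equal(signif(cl$value, 3), 138)

  vss <- aggregate_predictions(ref[ref$parameter == "vss", ],
                               "all_methods_mean")
  expect_equal(vss$value, 41.8)
  # permutation invariance
  shuffled <- ref[sample(nrow(ref)), ]
  expect_equal(aggregate_predictions(shuffled[shuffled$parameter == "cl_iv", ],
                                     "dog_single_species")$value, cl$value)
  expect_equal(aggregate_predictions(ref[1, ], "all_methods_mean")$value,
               ref$value[1])
  expect_error(aggregate_predictions(ref[ref$method == "TSAS", ],
                                     "dog_single_species"), "filter")
})
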