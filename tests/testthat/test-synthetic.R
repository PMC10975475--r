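test_that("zero-noise PK study is inverted by NCA within 2%", {
  truth <- list(cl = 1.9, v = 0.75, ka = 2.34, f = 0.12)
  gen <- gen_pk_study("rat", "one_compartment", truth, noise_cv = 0, seed = 21)
  expect_equal(nrow(gen$dataset), gen$truth$n_records)
  res <- nca(gen$dataset, method = "linear_up_log_down")
  iv <- res$summary[res$summary$route == "iv_bolus", ]
  expect_equal(mean(iv$cl_mean), truth$cl, tolerance = 0.02)
  expect_equal(mean(iv$vss_mean), truth$v, tolerance = 0.02)
})

test_that("noisy studies differ by seed but share the truth manifest", {
  truth <- list(cl = 1.9, v = 0.75, ka = 2.34, f = 0.12)
  g1 <- gen_pk_study("rat", "one_compartment", truth, noise_cv = 0.2, seed = 1)
  g2 <- gen_pk_study("rat", "one_compartment", truth, noise_cv = 0.2, seed = 2)
  expect_false(identical(g1$dataset$conc_ng_per_ml, g2$dataset$conc_ng_per_ml))
  t1 <- g1$truth; t2 <- g2$truth
  t1$seed <- t2$seed <- NULL
  expect_identical(t1, t2)
  # same seed reproduces exactly
  g1b <- gen_pk_study("rat", "one_compartment", truth, noise_cv = 0.2, seed = 1)
  expect_identical(g1$dataset$conc_ng_per_ml, g1b$dataset$conc_ng_per_ml)
})

test_that("two-compartment dog-like study shows long oral terminal phase", {
  truth <- list(cl = 0.2, v1 = 0.3, q = 0.25, v2 = 1.2, ka = 0.589, f = 0.5)
  gen <- gen_pk_study("dog", "two_compartment", truth, noise_cv = 0, seed = 31,
                      timepoints = c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 36, 48))
  df <- as.data.frame(gen$dataset)
  one <- df[df$subject_id == df$subject_id[df$route == "oral"][1], ]
  term <- terminal_fit(one$time_h, one$conc_ng_per_ml)
  # independent macro-rate oracle
  k10 <- truth$cl / truth$v1; k12 <- truth$q / truth$v1; k21 <- truth$q / truth$v2
  s <- k10 + k12 + k21
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  expect_equal(term$lambda_z, beta, tolerance = 0.05)
  expect_gt(log(2) / term$lambda_z, 4)          # long oral half-life
  expect_gt(log(2) / beta, log(2) / alpha)      # exceeds distribution phase
})

test_that("tissue study respects the destructive 24-animal design", {
  gen <- gen_tissue_study(kp = c(liver = 12.9, kidney = 1), bp_ratio = 0.58,
                          plasma_params = list(cl = 1.9, v = 0.75, ka = 2.34,
                                               f = 0.15),
                          noise_cv = 0, seed = 41)
  df <- as.data.frame(gen$dataset)
  expect_equal(length(unique(df$subject_id)), 24)
  expect_equal(unname(table(df$matrix)["liver"]), 24L)
  # each animal sampled at exactly one timepoint
  per_subject <- tapply(df$time_h, df$subject_id, function(x) length(unique(x)))
  expect_true(all(per_subject == 1))
  # unity partition -> unity ratios at zero noise
  g1 <- gen_tissue_study(kp = c(liver = 1), bp_ratio = 1,
                         plasma_params = list(cl = 1.9, v = 0.75, ka = 2.34,
                                              f = 0.15),
                         noise_cv = 0, seed = 42)
  d1 <- as.data.frame(g1$dataset)
  liver <- aggregate(conc_ng_per_ml ~ time_h, d1[d1$matrix == "liver", ], mean)
  plasma <- aggregate(conc_ng_per_ml ~ time_h, d1[d1$matrix == "plasma", ], mean)
  expect_equal(liver$conc_ng_per_ml / plasma$conc_ng_per_ml,
               rep(1, 4), tolerance = 1e-12)
})

test_that("noisy tissue studies recover the liver coefficient on average", {
  ests <- vapply(seq_len(100), function(s) {
    gen <- gen_tissue_study(kp = c(liver = 12.9), bp_ratio = 0.58,
                            plasma_params = list(cl = 1.9, v = 0.75,
                                                 ka = 2.34, f = 0.15),
                            noise_cv = 0.1, seed = s)
    df <- as.data.frame(gen$dataset)
    prof <- function(mat) {
      agg <- aggregate(conc_ng_per_ml ~ time_h, df[df$matrix == mat, ], mean)
      agg$conc_ng_per_ml[agg$time_h %in% c(0.5, 2, 8)]
    }
    matrix_ratio(prof("liver"), prof("plasma"), c(0.5, 2, 8))$mean
  }, numeric(1))
  expect_equal(mean(ests), 12.9, tolerance = 0.03)
})
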