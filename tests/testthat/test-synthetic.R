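test_that("parameter sampling is seeded, bounded, and log-uniform", {
  cfg <- synthetic_config(n_subjects = 50, group = "SGLT2i", seed = 14)
  a <- sample_parameters(cfg)
  b <- sample_parameters(cfg)
  expect_identical(a, b)
  for (nm in names(cfg$ranges)) {
    expect_true(all(a[[nm]] >= cfg$ranges[[nm]][1] - 1e-12))
    expect_true(all(a[[nm]] <= cfg$ranges[[nm]][2] + 1e-12))
  }
  # degenerate range gives deterministic parameters
  cfg2 <- synthetic_config(n_subjects = 5, seed = 3,
                           ranges = list(k1 = c(0.1, 0.1)))
  expect_true(all(sample_parameters(cfg2)$k1 == 0.1))
  # distributional check against log-uniform on a larger draw
  cfg3 <- synthetic_config(n_subjects = 4000, group = "control", seed = 15)
  big <- sample_parameters(cfg3)
  r <- cfg3$ranges$k7
  ks <- stats::ks.test(log10(big$k7), "punif", log10(r[1]), log10(r[2]))
  expect_gt(ks$p.value, 0.01)
  expect_error(synthetic_config(5, ranges = list(k4 = c(2, 1))), "invalid")
})

test_that("the clamp controller holds glycemia at target, including the
          no-insulin-action edge case", {
  cfg <- synthetic_config(n_subjects = 1, group = "SGLT2i", seed = 16)
  p <- ref_gig_params()
  cl <- simulate_clamp_with_controller(p, cfg, body_weight = 70)
  expect_false(cl$diverged)
  final30 <- cl$trajectory[cl$trajectory$t > 90, ]
  expect_lt(max(abs(final30$Gc / cfg$clamp$target - 1)), 0.05)
  expect_equal(cl$fg, mean(cl$f1[92:121]), tolerance = 1e-12)
  # zero insulin sensitivity and secretion: regulation by infusion alone
  p0 <- ref_gig_params(k4 = 0, k5 = 0, kGN = 0, k1 = 0.05)
  cl0 <- simulate_clamp_with_controller(p0, cfg, body_weight = 70)
  f0 <- cl0$trajectory[cl0$trajectory$t > 90, ]
  expect_lt(max(abs(f0$Gc / cfg$clamp$target - 1)), 0.05)
})

test_that("a target equal to the unforced steady state needs no
          infusion", {
  p <- ref_gig_params()
  ss <- fasting_steady_state(p)
  cfg <- synthetic_config(n_subjects = 1, seed = 17,
                          clamp = list(duration = 120, f2 = 0,
                                       target = unname(ss["Gc"])))
  cl <- simulate_clamp_with_controller(p, cfg, body_weight = 70)
  expect_lt(cl$fg, 0.05)
})

test_that("OGTT glycemia responds monotonically to glucagon and insulin
          sensitivity", {
  cfg <- synthetic_config(n_subjects = 1, seed = 18)
  pg120_kgn <- vapply(seq(0.002, 0.008, length.out = 5), function(kgn) {
    simulate_ogtt(ref_gig_params(kGN = kgn), cfg, 70)$PG120
  }, 0)
  expect_true(all(diff(pg120_kgn) > 0))
  pg120_k4 <- vapply(seq(1.4e-4, 3.2e-4, length.out = 5), function(k4) {
    simulate_ogtt(ref_gig_params(k4 = k4), cfg, 70)$PG120
  }, 0)
  expect_true(all(diff(pg120_k4) < 0))
  # zero dose leaves glycemia at the fasting steady state
  cfg0 <- synthetic_config(n_subjects = 1, seed = 18,
                           ogtt = list(dose_mg = 0, bioavailability = 0.8,
                                       shape_k = 2, shape_theta = 30,
                                       duration = 180))
  og0 <- simulate_ogtt(ref_gig_params(), cfg0, 70)
  expect_equal(og0$PG120, unname(fasting_steady_state(ref_gig_params())["Gc"]),
               tolerance = 1e-6)
})

test_that("measurement noise is seeded, unbiased, and CV-calibrated", {
  ser <- tibble::tibble(variable = "I", t_min = 1:10000,
                        value = rep(100, 10000))
  noisy <- add_noise(ser, c(I = 0.07), seed = 19)
  expect_identical(noisy, add_noise(ser, c(I = 0.07), seed = 19))
  expect_equal(sd(noisy$value) / mean(noisy$value), 0.07,
               tolerance = 0.05)
  expect_equal(mean(noisy$value), 100, tolerance = 0.5)
  expect_identical(add_noise(ser, c(I = 0), seed = 19)$value, ser$value)
  expect_true(all(noisy$value > 0))
})

test_that("generated cohorts parse through the readers and join one-to-one
          with ground truth", {
  coh <- small_cohort(n = 4, group = "SGLT2i", model = "gig", seed = 20,
                      noise_cv = c(Gc = 0.02, I = 0.07, Gg = 0.1,
                                   CP = 0.07))
  expect_setequal(coh$subjects$subject_id, coh$ground_truth$subject_id)
  expect_setequal(unique(coh$series$variable),
                  c("Gc", "I", "Gg", "CP", "f1", "f2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clamp_series(coh$series, path)
  back <- read_clamp_series(path)
  expect_equal(nrow(back), nrow(coh$series))
  # ground-truth composite metrics recompute bit-identically
  expect_identical(coh$ground_truth$di_cle,
                   di_cle(coh$ground_truth$k4, coh$ground_truth$k5,
                          coh$ground_truth$k7))
  expect_identical(coh$ground_truth$pi_cle_numeric,
                   pi_cle_numeric(coh$ground_truth$kGN,
                                  coh$ground_truth$kGgS,
                                  coh$ground_truth$kGgC, 2))
  # same seed regenerates the identical cohort, noise included
  coh2 <- small_cohort(n = 4, group = "SGLT2i", model = "gig", seed = 20,
                       noise_cv = c(Gc = 0.02, I = 0.07, Gg = 0.1,
                                    CP = 0.07))
  expect_identical(coh$series, coh2$series)
  expect_identical(coh$subjects, coh2$subjects)
})

test_that("cohort-level variance structure has the designed sign
          pattern", {
  sg <- small_cohort(n = 40, group = "SGLT2i", model = "gig", seed = 24)
  an <- pi_cle_analytic(sg$subjects$Gg0, sg$subjects$G0, sg$subjects$fg,
                        sg$subjects$Gss, sg$subjects$Iss)
  expect_gt(spearman_test(an$pi_cle, sg$subjects$PG120)$r, 0)
  ct <- small_cohort(n = 40, group = "control", model = "gig", seed = 25)
  expect_lt(spearman_test(ct$ground_truth$di_cle, ct$subjects$PG120)$r, 0)
})
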