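test_that("composite indices follow their defining algebra", {
  expect_equal(di_cle(1, 1, 1), 1)
  expect_equal(di_cle(2, 3, 2), 1.5)
  expect_equal(di_cle(2, 3, 4), di_cle(2, 3, 2) / 4)  # k7 homogeneity
  expect_error(di_cle(1, 1, 0), "positive")

  expect_equal(pi_cle_numeric(1, 1, 1, 1), 1)
  expect_equal(pi_cle_numeric(2, 2, 2, 2), 1)
  vals <- vapply(1:3, function(e) pi_cle_numeric(2, 3, 1.7, e), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(pi_cle_numeric(1, 1, 1, 4), "exponent")
})

test_that("analytic PI/cle obeys its grouping, homogeneity and product
          identity", {
  expect_equal(pi_cle_analytic(1, 1, 1, 1, 1)$pi_cle, 1)
  base <- pi_cle_analytic(20, 7, 4, 5.2, 300)
  expect_equal(pi_cle_analytic(20, 7, 8, 5.2, 300)$pi_cle,
               2 * base$pi_cle)
  expect_equal(pi_cle_analytic(20, 7, 4, 5.2, 600)$pi_cle,
               base$pi_cle / 2)
  set.seed(6)
  for (i in 1:25) {
    v <- runif(5, 0.1, 50)
    a <- pi_cle_analytic(v[1], v[2], v[3], v[4], v[5])
    expect_equal(a$ggsen * a$ggsec_cle, a$pi_cle, tolerance = 1e-15)
    expect_equal(a$pi_cle, v[1] * v[2] * v[3] / (v[4] * v[5]),
                 tolerance = 1e-15)
  }
  expect_error(pi_cle_analytic(0, 1, 1, 1, 1), "positive")
})

test_that("ISI and TGUR follow the clamp-table definitions", {
  expect_equal(isi(1, 1, 1), 100)
  expect_equal(isi(1, 100, 50), 50)
  expect_error(isi(0, 1, 1), "positive")
  expect_equal(tgur(4.17, 0.68), 3.49)
  expect_equal(tgur(5, 0), 5)
  expect_equal(tgur(1, 1), 0)
  expect_warning(tgur(1, 2), "exceeds")
})

test_that("simulated and measured ISI agree on a noiseless self-fitted
          subject", {
  coh <- small_cohort(n = 1, group = "SGLT2i", seed = 31)
  fit <- fit_subject(subject_series(coh, 1), coh$subjects[1, ],
                     model = "gi", config = quick_fit_config(seed = 4))
  rec <- coh$subjects[1, ]
  uger <- rec$urinary_glucose_0_120 / rec$body_weight / 120
  meas <- isi(tgur(rec$fg, uger), glucose_mmoll_to_mgdl(rec$Gss),
              insulin_pmoll_to_uuml(rec$Iss))
  expect_equal(isi_simulated(fit), meas, tolerance = 0.01)
})

test_that("OGTT indices reproduce their standard formulas", {
  og <- tibble::tibble(t_min = c(0, 30, 60, 90, 120),
                       glucose = c(100, 100, 100, 100, 100),
                       insulin = c(10, 10, 10, 10, 10))
  out <- ogtt_indices(og)
  expect_true(is.na(out$insulinogenic_index))
  expect_equal(out$matsuda_index, 10)      # 10000 / sqrt(100*10*100*10)
  expect_equal(out$PG120, 100)
  og2 <- tibble::tibble(t_min = c(0, 30, 120),
                        glucose = c(90, 150, 130), insulin = c(8, 50, 30))
  out2 <- ogtt_indices(og2)
  expect_equal(out2$insulinogenic_index, (50 - 8) / (150 - 90))
  expect_error(ogtt_indices(og2[-1, ]), "include")
})

test_that("insulin half-life is ln 2 over the clearance constant", {
  expect_equal(insulin_half_life(log(2)), 1)
  expect_equal(insulin_half_life(0.0693), 10.00212, tolerance = 1e-6)
  expect_error(insulin_half_life(0), "positive")
})

test_that("the subject metric row assembles fit- and record-derived
          indices", {
  coh <- small_cohort(n = 1, group = "SGLT2i", model = "gig", seed = 33)
  fit <- fit_subject(subject_series(coh, 1), coh$subjects[1, ],
                     model = "gig", config = quick_fit_config(seed = 5))
  m <- subject_metrics(fit, coh$subjects[1, ])
  expect_equal(nrow(m), 1)
  p <- unclass(fit$params)
  expect_equal(m$di_cle, di_cle(p[["k4"]], p[["k5"]], p[["k7"]]))
  expect_equal(m$pi_cle_numeric_exp2,
               pi_cle_numeric(p[["kGN"]], p[["kGgS"]], p[["kGgC"]], 2))
  expect_equal(m$pi_cle_analytic, m$ggsen * m$ggsec_cle, tolerance = 1e-12)
  expect_true(m$PG120 > 0)
})
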