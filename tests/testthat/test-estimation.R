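test_that("GI objective matches the printed weighting and a brute-force
          oracle", {
  expect_equal(rss_gi(c(1, 1), c(1, 1), c(2, 2), c(2, 2)), 0)
  # two glucose residuals of 1, no insulin residuals, nGc = nI = 2
  expect_equal(rss_gi(c(1, 2), c(0, 1), c(5, 5), c(5, 5)), 1.0)
  set.seed(3)
  for (rep in 1:100) {
    ngc <- sample(5:120, 1); ni <- sample(3:20, 1)
    og <- runif(ngc); sg <- runif(ngc)
    oi <- runif(ni); si <- runif(ni)
    brute <- 0
    for (i in seq_len(ngc)) brute <- brute +
        ni / (ngc + ni) * (og[i] - sg[i])^2
    for (i in seq_len(ni)) brute <- brute +
        ngc / (ngc + ni) * (oi[i] - si[i])^2
    expect_equal(rss_gi(og, sg, oi, si), brute, tolerance = 1e-12)
  }
})

test_that("GIG objective weights are the printed complements and sum to 3", {
  n <- c(8, 8, 8, 8)
  tot <- sum(n)
  w <- (tot - n) / tot
  expect_equal(w, rep(3 / 4, 4))
  expect_equal(sum(w), 3)
  set.seed(4)
  for (rep in 1:100) {
    n <- c(sample(5:120, 1), sample(3:20, 1), sample(3:20, 1),
           sample(3:20, 1))
    obs <- lapply(n, runif)
    sim <- lapply(n, runif)
    tot <- sum(n)
    brute <- sum(vapply(1:4, function(v) {
      (tot - n[v]) / tot * sum((obs[[v]] - sim[[v]])^2)
    }, 0))
    got <- rss_gig(obs[[1]], sim[[1]], obs[[2]], sim[[2]], obs[[3]],
                   sim[[3]], obs[[4]], sim[[4]])
    expect_equal(got, brute, tolerance = 1e-12)
  }
  expect_error(rss_gi(1:3, 1:2, 1, 1), "aligned")
})

test_that("meta-EP finds a known minimum, respects bounds, and is seed
          deterministic", {
  centre <- c(1.3, -2.1)
  sphere <- function(X) rowSums((X - rep(centre, each = nrow(X)))^2)
  out <- meta_ep(sphere, lower = c(-4, -4), upper = c(4, 4),
                 n_parents = 40, n_generations = 200, seed = 11)
  expect_lt(max(abs(out$par - centre)), 1e-2)
  # bounds respected for every survivor and a tight box
  seen <- new.env(); seen$bad <- FALSE
  watcher <- function(X) {
    if (any(X < -1 - 1e-12) || any(X > 1 + 1e-12)) seen$bad <- TRUE
    rowSums(X^2)
  }
  meta_ep(watcher, lower = c(-1, -1), upper = c(1, 1), n_parents = 10,
          n_generations = 50, seed = 2)
  expect_false(seen$bad)
  a <- meta_ep(sphere, c(-4, -4), c(4, 4), 20, 80, seed = 5)
  b <- meta_ep(sphere, c(-4, -4), c(4, 4), 20, 80, seed = 5)
  expect_identical(a$par, b$par)
  expect_identical(a$value, b$value)
  # non-finite objective values are tolerated, not fatal
  spiky <- function(X) ifelse(X[, 1] > 0, NaN, rowSums(X^2))
  expect_silent(out2 <- meta_ep(spiky, c(-2, -2), c(2, 2), 10, 40,
                                seed = 3))
  expect_true(is.finite(out2$value))
})

test_that("local refinement never worsens a candidate and stays in
          bounds", {
  resid <- function(th) c(th[1] - 0.3, 2 * (th[2] + 0.4))
  # already optimal
  at_opt <- local_refine(c(0.3, -0.4), resid, c(-1, -1), c(1, 1))
  expect_equal(at_opt$par, c(0.3, -0.4), tolerance = 1e-8)
  # perturbed start improves
  ref <- local_refine(c(0.5, 0.1), resid, c(-1, -1), c(1, 1))
  expect_lt(ref$value, sum(resid(c(0.5, 0.1))^2))
  expect_lt(ref$value, 1e-12)
  # bound-touching stays feasible
  ref2 <- local_refine(c(1, 1), resid, c(0.9, 0.9), c(1, 1))
  expect_true(all(ref2$par >= 0.9 - 1e-12 & ref2$par <= 1 + 1e-12))
  expect_lte(ref2$value, sum(resid(c(1, 1))^2))
})

test_that("fitting the generating model to its own noiseless output drives
          the objective to zero", {
  coh <- small_cohort(n = 1, seed = 21)
  fit <- fit_subject(subject_series(coh, 1), coh$subjects[1, ],
                     model = "gi", config = quick_fit_config(seed = 31))
  expect_lt(fit$rss, 1e-6)
  truth <- coh$ground_truth[1, ]
  p <- unclass(fit$params)
  expect_equal(di_cle(p[["k4"]], p[["k5"]], p[["k7"]]), truth$di_cle,
               tolerance = 0.05)
  # provenance recorded
  expect_identical(fit$seed, 31L)
  expect_identical(unname(fit$budget), c(16, 60))
  expect_true(all(fit$theta >= -4 & fit$theta <= 4))
})

test_that("fit results are reproducible given the seed and stable across
          seeds on noisy data", {
  coh <- small_cohort(n = 1, seed = 22, noise_cv = c(Gc = 0.02, I = 0.07,
                                                     Gg = 0.1, CP = 0.07))
  ser <- subject_series(coh, 1)
  f1 <- fit_subject(ser, coh$subjects[1, ], model = "gi",
                    config = quick_fit_config(seed = 9))
  f2 <- fit_subject(ser, coh$subjects[1, ], model = "gi",
                    config = quick_fit_config(seed = 9))
  expect_identical(f1$rss, f2$rss)
  expect_identical(unclass(f1$params), unclass(f2$params))
  f3 <- fit_subject(ser, coh$subjects[1, ], model = "gi",
                    config = quick_fit_config(seed = 10))
  # two seeds land on objective values of the same magnitude
  expect_lt(abs(log10(f3$rss / f1$rss)), 0.5)
})

test_that("tidy and glance expose estimates and the reduced-form AIC", {
  coh <- small_cohort(n = 1, seed = 23)
  fit <- fit_subject(subject_series(coh, 1), coh$subjects[1, ],
                     model = "gi", config = quick_fit_config(seed = 1))
  td <- tidy(fit)
  expect_setequal(td$term, paste0("k", 1:8))
  expect_false(td$estimated[td$term == "k8"])
  gl <- glance(fit)
  expect_equal(gl$aic, sum(fit$n_points) * log(fit$rss) + 2 * fit$K)
  ft <- fitted_trajectories(fit)
  expect_true(all(c("observed", "simulated") %in% names(ft)))
  expect_lt(max(abs(ft$observed - ft$simulated)), 0.05)
})
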