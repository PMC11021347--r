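test_that("GI right-hand side honours its steady-state identities", {
  p <- ref_gi_params(k5 = 0)
  pr <- clamp_protocol(duration = 60)
  gc_ss <- unclass(p)[["k1"]] / (unclass(p)[["k2"]] + unclass(p)[["k8"]])
  d <- gi_rhs(c(gc_ss, gc_ss, 0), 10, p, pr)
  expect_equal(unname(d[1]), 0, tolerance = 1e-12)
  # Y tracking glucose is stationary
  expect_equal(unname(d[2]), 0, tolerance = 1e-12)
  # below the secretion threshold insulin sees only infusion and clearance
  p2 <- ref_gi_params()
  d2 <- gi_rhs(c(2, 2, 10), 0, p2, pr)  # Y = 2 < k6 = 3
  expect_equal(unname(d2[3]), -unclass(p2)[["k7"]] * 10, tolerance = 1e-12)
})

test_that("rhs functions reject invalid states and times", {
  p <- ref_gi_params()
  pr <- clamp_protocol(duration = 60)
  expect_error(gi_rhs(c(-1, 5, 5), 0, p, pr), "negative")
  expect_error(gi_rhs(c(5, 5, 5), 100, p, pr), "duration")
  pg <- ref_gig_params()
  expect_error(gig_rhs(c(5, 5, 5, -2, 0.4), 0, pg, pr), "negative")
})

test_that("GIG nests the GI model when glucagon action is removed", {
  pg <- ref_gig_params(kGN = 0, kratio = 1)
  pgi <- ref_gi_params(k5 = unclass(pg)[["k5"]])
  pr <- clamp_protocol(duration = 120, f1 = 1.5, f2 = 1.25)
  init_g <- fasting_steady_state(pg)
  tg <- simulate_model(pg, pr, init = init_g, rtol = 1e-11, atol = 1e-13)
  ti <- simulate_model(pgi, pr, init = init_g[c("Gc", "Y", "I")],
                       rtol = 1e-11, atol = 1e-13)
  expect_lt(max(abs(tg$Gc - ti$Gc)), 1e-8)
  expect_lt(max(abs(tg$Y - ti$Y)), 1e-8)
  expect_lt(max(abs(tg$I - ti$I) / pmax(ti$I, 1)), 1e-8)
  # the pure-R rhs agrees with the nesting too
  d_g <- gig_rhs(c(6, 6, 50, 20, 0.4), 10, pg, pr)
  d_i <- gi_rhs(c(6, 6, 50), 10, pgi, pr)
  expect_equal(unname(d_g[1:3]), unname(d_i), tolerance = 1e-14)
})

test_that("simulation from the fasting steady state stays constant", {
  for (p in list(ref_gi_params(), ref_gig_params())) {
    pr <- clamp_protocol(duration = 90)
    ss <- fasting_steady_state(p)
    traj <- simulate_model(p, pr)
    for (v in names(ss)) {
      expect_lt(max(abs(traj[[v]] / ss[[v]] - 1)), 1e-6)
    }
  }
})

test_that("compiled integrator matches the matrix-exponential solution in
          the linear regime", {
  skip_if_not_installed("Matrix")
  # X forced to zero (huge threshold) and k4 = 0 make the system linear
  p <- ref_gi_params(k4 = 0, k6 = 1e6)
  pr <- clamp_protocol(duration = 120, f1 = 2, f2 = 1.25, body_weight = 70)
  up <- unclass(p)
  cf <- list(cf1 = (70 / 52.5) / 18.016, cf2 = (70 / 52.5) * 60)
  A <- matrix(c(-(up[["k2"]] + up[["k8"]]), 0, 0,
                up[["k3"]], -up[["k3"]], 0,
                0, 0, -up[["k7"]]), 3, 3, byrow = TRUE)
  b <- c(cf$cf1 * 2 + up[["k1"]], 0, cf$cf2 * 1.25)
  y0 <- c(4, 4, 20)
  traj <- simulate_model(p, pr, init = y0)
  zp <- solve(A, -b)
  for (tt in c(10, 45, 120)) {
    expected <- as.numeric(Matrix::expm(A * tt) %*% (y0 - zp) + zp)
    got <- as.numeric(traj[traj$t == tt, c("Gc", "Y", "I")])
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("doubling the glucose infusion doubles the linear-regime
          deviation from baseline", {
  p <- ref_gi_params(k4 = 0, k5 = 0)
  base <- unclass(p)[["k1"]] / (unclass(p)[["k2"]] + unclass(p)[["k8"]])
  dev <- function(f1) {
    pr <- clamp_protocol(duration = 60, f1 = f1)
    traj <- simulate_model(p, pr, init = c(base, base, 0))
    traj$Gc - base
  }
  d1 <- dev(1); d2 <- dev(2)
  expect_equal(d2[-1], 2 * d1[-1], tolerance = 1e-6)
})

test_that("compiled core agrees with an independent lsoda integration", {
  skip_if_not_installed("deSolve")
  p <- ref_gig_params()
  pr <- clamp_protocol(duration = 120, f1 = 1.2, f2 = 1.25)
  y0 <- fasting_steady_state(p)
  traj <- simulate_model(p, pr)
  rhs_ds <- function(t, y, parms) {
    list(as.numeric(gig_rhs(y, min(max(t, 0), 120), p, pr)))
  }
  ref <- deSolve::lsoda(y = unname(y0), times = 0:120, func = rhs_ds,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  for (j in 1:5) {
    expect_lt(max(abs(traj[[j + 1]] - ref[, j + 1]) /
                    pmax(abs(ref[, j + 1]), 1e-6)), 1e-6)
  }
})

test_that("raising the urinary rate constant lowers the open-loop steady
          state as k1/(k2+k8)", {
  k8s <- c(0, 0.005, 0.02, 0.08)
  gc <- vapply(k8s, function(k8) {
    p <- ref_gi_params(k5 = 0, k8 = k8)
    fasting_steady_state(p)[["Gc"]]
  }, 0)
  expect_true(all(diff(gc) < 0))
  expect_equal(gc, 0.09 / (0.005 + k8s), tolerance = 1e-9)
})

test_that("trajectory reshaping and protocol validation behave", {
  p <- ref_gi_params()
  traj <- simulate_model(p, clamp_protocol(duration = 10))
  long <- trajectory_long(traj, subject_id = "s1")
  expect_setequal(unique(long$variable), c("Gc", "Y", "I", "X"))
  expect_equal(nrow(long), 11 * 4)
  expect_error(clamp_protocol(duration = 10, f1 = rep(-1, 11)),
               "non-negative")
  expect_error(clamp_protocol(duration = 10, f1 = 1:5), "length")
  # an extreme clearance rate far from equilibrium exhausts the step cap
  expect_error(simulate_model(ref_gig_params(kGgC = 1e6),
                              clamp_protocol(duration = 30),
                              init = c(Gc = 7, Y = 7, I = 50, Gg = 20,
                                       CP = 0.4)),
               "integration|magnitude")
})
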