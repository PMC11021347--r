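#' Clamp infusion protocol
#'
#' Describes the infusion inputs of a simulated or measured
#' hyperinsulinemic-euglycemic clamp: glucose infusion `f1` and insulin
#' infusion `f2` sampled on a 1-minute grid (piecewise linear between knots),
#' plus the anthropometrics that convert per-kg infusion rates into
#' concentration fluxes. Blood volume defaults to 0.75 dL per kg body weight.
#'
#' @param duration Clamp duration in minutes.
#' @param f1 Glucose infusion, mg/kg/min: scalar or vector of length
#'   `duration + 1` (knots at integer minutes).
#' @param f2 Insulin infusion, mU/kg/min: scalar or vector as `f1`.
#' @param target_glucose Target glycemia of the clamp controller, mmol/L
#'   (used only when generating synthetic clamps).
#' @param body_weight Body weight, kg.
#' @param blood_volume Blood volume, dL.
#' @return An object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(duration = 120, f1 = 0, f2 = 0,
                           target_glucose = 5.2, body_weight = 70,
                           blood_volume = 0.75 * body_weight) {
  stopifnot(duration > 0, body_weight > 0, blood_volume > 0,
            target_glucose > 0)
  expand <- function(f, name) {
    if (length(f) == 1) f <- rep(f, duration + 1)
    if (length(f) != duration + 1) {
      stop(name, " must be a scalar or have length duration + 1",
           call. = FALSE)
    }
    if (anyNA(f) || any(f < 0)) {
      stop(name, " must be non-negative everywhere", call. = FALSE)
    }
    f
  }
  structure(list(duration = as.integer(duration),
                 f1 = expand(f1, "f1"), f2 = expand(f2, "f2"),
                 target_glucose = target_glucose,
                 body_weight = body_weight, blood_volume = blood_volume),
            class = "clamp_protocol")
}

# Conversion factors from per-kg infusion rates to concentration fluxes:
# glucose mg/kg/min -> mmol/L/min, insulin mU/kg/min -> pmol/L/min.
infusion_factors <- function(protocol) {
  wt_over_bv <- protocol$body_weight / protocol$blood_volume
  list(cf1 = wt_over_bv / 18.016, cf2 = wt_over_bv * 10 * 6.0)
}

# Piecewise constant per minute, matching the compiled core and the
# synthetic generator: f(t) = f[floor(t)].
interp_infusion <- function(f, t) {
  n <- length(f)
  if (t <= 0) return(f[1])
  i <- floor(t)
  if (i >= n - 1) return(f[n])
  f[i + 1]
}

check_rhs_inputs <- function(state, t, protocol) {
  if (any(state < 0)) stop("negative state component", call. = FALSE)
  if (t < 0 || t > protocol$duration) {
    stop("time outside the protocol duration", call. = FALSE)
  }
}

#' Right-hand side of the GI model
#'
#' Derivatives of the glucose-insulin feedback system at one instant:
#' \deqn{dGc/dt = f_1(t)/BV_{norm} + k_1 - (k_2 + k_4 I + k_8)\,Gc}
#' \deqn{dY/dt = k_3 (Gc - Y)}
#' \deqn{dI/dt = f_2(t)/BV_{norm} + k_5 X - k_7 I, \quad X = \max(Y - k_6, 0)}
#' This reference implementation in R is cross-checked against the compiled
#' core used by [simulate_model()].
#'
#' @param state Named or positional numeric vector `(Gc, Y, I)` in internal
#'   units (mmol/L, mmol/L, pmol/L).
#' @param t Time in minutes within the protocol.
#' @param params A [gi_params()] object.
#' @param protocol A [clamp_protocol()].
#' @return Named numeric vector of derivatives `(Gc, Y, I)`.
#' @export
gi_rhs <- function(state, t, params, protocol) {
  check_rhs_inputs(state, t, protocol)
  cf <- infusion_factors(protocol)
  p <- unclass(params)
  Gc <- state[[1]]; Y <- state[[2]]; I <- state[[3]]
  X <- max(Y - p[["k6"]], 0)
  c(Gc = cf$cf1 * interp_infusion(protocol$f1, t) + p[["k1"]] -
      (p[["k2"]] + p[["k4"]] * I + p[["k8"]]) * Gc,
    Y = p[["k3"]] * (Gc - Y),
    I = cf$cf2 * interp_infusion(protocol$f2, t) + p[["k5"]] * X -
      p[["k7"]] * I)
}

#' Right-hand side of the GIG model
#'
#' Extends [gi_rhs()] with glucagon and C-peptide. Glucose gains a production
#' term `kGN * Gg`; insulin and C-peptide share the pre-hepatic secretion
#' `S = k5 * X`, insulin scaled by `kratio` (posthepatic fraction), C-peptide
#' appearing equimolarly (nmol/L, hence the factor 1000):
#' \deqn{dGg/dt = sec(I, Gc) - k_{GgC} Gg, \qquad
#'       dCP/dt = S/1000 - k_{CPC} CP}
#' where the secretion term `sec` is set by [model_structure()]; the default
#' is the saturable insulin inhibition `kGgS / (1 + I/I_half)`.
#'
#' @param state Numeric vector `(Gc, Y, I, Gg, CP)` in internal units.
#' @inheritParams gi_rhs
#' @param params A [gig_params()] object.
#' @param structure A [model_structure()].
#' @return Named numeric vector of derivatives `(Gc, Y, I, Gg, CP)`.
#' @export
gig_rhs <- function(state, t, params, protocol,
                    structure = model_structure()) {
  check_rhs_inputs(state, t, protocol)
  cf <- infusion_factors(protocol)
  p <- unclass(params)
  Gc <- state[[1]]; Y <- state[[2]]; I <- state[[3]]
  Gg <- state[[4]]; CP <- state[[5]]
  X <- max(Y - p[["k6"]], 0)
  S <- p[["k5"]] * X
  sec <- switch(structure$glucagon_suppression,
    saturable_insulin = p[["kGgS"]] / (1 + I / structure$I_half),
    inverse_insulin = p[["kGgS"]] / max(I, structure$eps_I),
    saturable_glucose = p[["kGgS"]] / (1 + Gc / structure$G_half),
    both = p[["kGgS"]] / ((1 + I / structure$I_half) *
                            (1 + Gc / structure$G_half)),
    constant = p[["kGgS"]])
  c(Gc = cf$cf1 * interp_infusion(protocol$f1, t) + p[["k1"]] +
      p[["kGN"]] * Gg - (p[["k2"]] + p[["k4"]] * I + p[["k8"]]) * Gc,
    Y = p[["k3"]] * (Gc - Y),
    I = cf$cf2 * interp_infusion(protocol$f2, t) + p[["kratio"]] * S -
      p[["k7"]] * I,
    Gg = sec - p[["kGgC"]] * Gg,
    CP = S / 1000 - p[["kCPC"]] * CP)
}

#' Simulate a clamp model on the 1-minute grid
#'
#' Integrates the GI or GIG system (inferred from the class of `params`)
#' under a [clamp_protocol()] with an adaptive embedded Runge-Kutta 4(5)
#' method (piecewise integration between minute knots, where the infusions
#' are linear). Negative undershoots at solver-tolerance scale are clipped
#' to zero.
#'
#' @param params A [gi_params()] or [gig_params()] object.
#' @param protocol A [clamp_protocol()].
#' @param init Initial state in internal units (named as the state
#'   variables); `NULL` starts from the fasting steady state.
#' @param structure A [model_structure()] (GIG only).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param max_steps Step cap; exceeding it signals an integration error.
#' @return A tibble with columns `t`, the state variables, and the derived
#'   secretion drive `X`.
#' @examples
#' p <- gi_params(k1 = 0.1, k2 = 0.005, k3 = 0.05, k4 = 2e-4, k5 = 4,
#'                k6 = 3, k7 = 0.1, k8 = 0.01)
#' traj <- simulate_model(p, clamp_protocol(duration = 60, f2 = 1.25))
#' @export
simulate_model <- function(params, protocol, init = NULL,
                           structure = model_structure(), rtol = 1e-8,
                           atol = 1e-10, max_steps = 2e5) {
  model <- model_id(params)
  if (is.null(init)) init <- fasting_steady_state(params, structure)
  ns <- state_names(model)
  if (!is.null(names(init))) init <- init[ns]
  if (length(init) != length(ns) || anyNA(init)) {
    stop("init must supply the state variables ", paste(ns, collapse = ", "),
         call. = FALSE)
  }
  cf <- infusion_factors(protocol)
  out <- sim_core(model, param_vector(params, structure), as.numeric(init),
                  protocol$f1, protocol$f2, cf$cf1, cf$cf2,
                  protocol$duration, rtol, atol, max_steps)
  if (nrow(out) == 1 && is.na(out[1, 1])) {
    stop("integration failed (step cap or non-finite derivatives); ",
         "check parameter magnitudes", call. = FALSE)
  }
  colnames(out) <- ns
  res <- tibble::as_tibble(out)
  res <- tibble::add_column(res, t = 0:protocol$duration, .before = 1)
  res$X <- pmax(res$Y - unclass(params)[["k6"]], 0)
  res
}

#' Fasting steady state of a clamp model
#'
#' Solves the infusion-free steady state: glucose balances production
#' (basal plus glucagon-driven for the GIG model) against removal, insulin
#' balances secretion against clearance, glucagon balances suppressed
#' secretion against clearance. Used as the default initial condition and as
#' the source of the synthetic fasting observables (G0, I0, Gg0).
#'
#' @inheritParams simulate_model
#' @return Named numeric vector of the steady state.
#' @export
fasting_steady_state <- function(params, structure = model_structure()) {
  p <- unclass(params)
  model <- model_id(params)
  i0_of <- function(G) {
    s <- if (model == 2L) p[["kratio"]] * p[["k5"]] else p[["k5"]]
    s * max(G - p[["k6"]], 0) / p[["k7"]]
  }
  gg0_of <- function(G, I) {
    switch(structure$glucagon_suppression,
      saturable_insulin = p[["kGgS"]] / (1 + I / structure$I_half),
      inverse_insulin = p[["kGgS"]] / max(I, structure$eps_I),
      saturable_glucose = p[["kGgS"]] / (1 + G / structure$G_half),
      both = p[["kGgS"]] / ((1 + I / structure$I_half) *
                              (1 + G / structure$G_half)),
      constant = p[["kGgS"]]) / p[["kGgC"]]
  }
  resid <- function(G) {
    I <- i0_of(G)
    prod <- p[["k1"]]
    if (model == 2L) prod <- prod + p[["kGN"]] * gg0_of(G, I)
    prod - (p[["k2"]] + p[["k4"]] * I + p[["k8"]]) * G
  }
  root <- stats::uniroot(resid, lower = 1e-9, upper = 1e7, tol = 1e-12)$root
  I0 <- i0_of(root)
  if (model == 1L) {
    c(Gc = root, Y = root, I = I0)
  } else {
    CP0 <- p[["k5"]] * max(root - p[["k6"]], 0) / 1000 / p[["kCPC"]]
    c(Gc = root, Y = root, I = I0, Gg = gg0_of(root, I0), CP = CP0)
  }
}

#' Reshape a simulated trajectory to the long tidy format
#'
#' @param trajectory A tibble from [simulate_model()].
#' @param subject_id Identifier recorded in the output.
#' @return Long tibble with columns `subject_id`, `t_min`, `variable`,
#'   `value`, `units`.
#' @export
trajectory_long <- function(trajectory, subject_id = "subject") {
  units_map <- c(Gc = "mmol/L", Y = "mmol/L", I = "pmol/L", X = "mmol/L",
                 Gg = "ng/L", CP = "nmol/L")
  out <- tidyr::pivot_longer(trajectory, -"t", names_to = "variable",
                             values_to = "value")
  tibble::tibble(subject_id = subject_id, t_min = out$t,
                 variable = out$variable, value = out$value,
                 units = unname(units_map[out$variable]))
}
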