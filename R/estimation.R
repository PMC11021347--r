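#' Weighted residual sum of squares for the GI model
#'
#' The objective weights the per-variable squared-error sums by the opposite
#' variable's share of time points, so that the sparsely sampled hormone is
#' not swamped by the quasi-continuous glucose trace:
#' `RSS_GI = nI/(nGc+nI) * sum((Gc - Gc_sim)^2) +
#'           nGc/(nGc+nI) * sum((I - I_sim)^2)`.
#' The two weights sum to 1.
#'
#' @param obs_gc,sim_gc Observed and simulated normalized glucose at the same
#'   time points.
#' @param obs_i,sim_i Observed and simulated normalized insulin at the same
#'   time points.
#' @param n_gc,n_i Numbers of time points (defaults: series lengths).
#' @return The weighted RSS (non-negative scalar).
#' @export
rss_gi <- function(obs_gc, sim_gc, obs_i, sim_i, n_gc = length(obs_gc),
                   n_i = length(obs_i)) {
  if (length(obs_gc) != length(sim_gc) || length(obs_i) != length(sim_i)) {
    stop("observed and simulated series are not aligned", call. = FALSE)
  }
  tot <- n_gc + n_i
  n_i / tot * sum((obs_gc - sim_gc)^2) +
    n_gc / tot * sum((obs_i - sim_i)^2)
}

#' Weighted residual sum of squares for the GIG model
#'
#' Four squared-error sums, each weighted by the share of time points
#' belonging to the *other* three variables: the glucose term carries
#' `(nI+nGg+nCP)/total`, and so on. The four weights sum to 3.
#'
#' @inheritParams rss_gi
#' @param obs_gg,sim_gg Observed and simulated normalized glucagon.
#' @param obs_cp,sim_cp Observed and simulated normalized C-peptide.
#' @param n_gg,n_cp Numbers of time points.
#' @return The weighted RSS.
#' @export
rss_gig <- function(obs_gc, sim_gc, obs_i, sim_i, obs_gg, sim_gg, obs_cp,
                    sim_cp, n_gc = length(obs_gc), n_i = length(obs_i),
                    n_gg = length(obs_gg), n_cp = length(obs_cp)) {
  if (length(obs_gc) != length(sim_gc) || length(obs_i) != length(sim_i) ||
      length(obs_gg) != length(sim_gg) || length(obs_cp) != length(sim_cp)) {
    stop("observed and simulated series are not aligned", call. = FALSE)
  }
  tot <- n_gc + n_i + n_gg + n_cp
  (tot - n_gc) / tot * sum((obs_gc - sim_gc)^2) +
    (tot - n_i) / tot * sum((obs_i - sim_i)^2) +
    (tot - n_gg) / tot * sum((obs_gg - sim_gg)^2) +
    (tot - n_cp) / tot * sum((obs_cp - sim_cp)^2)
}

#' Self-adaptive meta-evolutionary programming
#'
#' Global minimization over a box. Each individual carries per-coordinate
#' mutation scales that are themselves mutated (the "meta" level of the
#' evolutionary program); survivor selection is (mu + mu) by stochastic
#' q-tournament. The initial population is uniform within the bounds, which
#' for the model objectives are expressed in log10 parameter space.
#'
#' @param objective Function taking a matrix (one candidate per row) and
#'   returning a numeric vector of objective values; non-finite values are
#'   treated as +Inf.
#' @param lower,upper Finite bounds, one per coordinate.
#' @param n_parents Population size (>= 2).
#' @param n_generations Number of generations.
#' @param seed Integer seed; identical seeds give identical results.
#' @param q Tournament size.
#' @param init Optional matrix of initial candidates (rows recycled or
#'   truncated to `n_parents`); remaining rows are drawn uniformly.
#' @return List with `par` (best-ever candidate), `value`, `trace` (best
#'   objective per generation), and `n_evaluations`.
#' @export
meta_ep <- function(objective, lower, upper, n_parents = 40,
                    n_generations = 300, seed = 1, q = 10, init = NULL) {
  stopifnot(n_parents >= 2, n_generations >= 1,
            length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower < upper))
  set.seed(seed)
  d <- length(lower)
  rng <- upper - lower
  mu <- n_parents
  pop <- matrix(stats::runif(mu * d, rep(lower, each = mu),
                             rep(upper, each = mu)), nrow = mu)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), mu)
    pop[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
  }
  sig <- matrix(rep(rng / 10, each = mu), nrow = mu)
  sanitize <- function(v) ifelse(is.finite(v), v, Inf)
  fit <- sanitize(objective(pop))
  n_eval <- mu
  tau <- 1 / sqrt(2 * sqrt(d))
  tau_p <- 1 / sqrt(2 * d)
  sig_min <- rng * 1e-8
  sig_max <- rng
  best_i <- which.min(fit)
  best <- list(par = pop[best_i, ], value = fit[best_i])
  trace <- numeric(n_generations)
  lo <- rep(lower, each = mu)
  hi <- rep(upper, each = mu)
  for (g in seq_len(n_generations)) {
    common <- stats::rnorm(mu)
    sig_off <- sig * exp(tau_p * common + tau * matrix(stats::rnorm(mu * d),
                                                       nrow = mu))
    sig_off <- pmin(pmax(sig_off, rep(sig_min, each = mu)),
                    rep(sig_max, each = mu))
    off <- pop + sig_off * matrix(stats::rnorm(mu * d), nrow = mu)
    off <- pmin(pmax(off, lo), hi)
    fit_off <- sanitize(objective(off))
    n_eval <- n_eval + mu
    i <- which.min(fit_off)
    if (fit_off[i] < best$value) best <- list(par = off[i, ],
                                              value = fit_off[i])
    all_pop <- rbind(pop, off)
    all_sig <- rbind(sig, sig_off)
    all_fit <- c(fit, fit_off)
    # stochastic q-tournament: wins against q random opponents
    n_all <- 2 * mu
    opp <- matrix(sample.int(n_all, n_all * q, replace = TRUE), nrow = n_all)
    wins <- rowSums(matrix(all_fit, n_all, q) <= all_fit[opp])
    keep <- order(-wins, all_fit)[seq_len(mu)]
    pop <- all_pop[keep, , drop = FALSE]
    sig <- all_sig[keep, , drop = FALSE]
    fit <- all_fit[keep]
    trace[g] <- best$value
  }
  ord <- order(fit)
  list(par = best$par, value = best$value, trace = trace,
       n_evaluations = n_eval, population = pop[ord, , drop = FALSE],
       population_values = fit[ord])
}

#' Local refinement by bound-constrained nonlinear least squares
#'
#' Polishes a candidate with a Levenberg-Marquardt fit on the stacked
#' weighted residual vector (whose squared norm equals the estimation
#' objective). Never worsens the candidate: on failure or deterioration the
#' input is returned.
#'
#' @param par Starting candidate (within bounds).
#' @param residuals Function mapping a candidate to the stacked weighted
#'   residual vector.
#' @param lower,upper Bounds.
#' @param maxiter Iteration cap for the Levenberg-Marquardt loop.
#' @return List with `par`, `value` (RSS), and `converged`.
#' @export
local_refine <- function(par, residuals, lower, upper, maxiter = 100) {
  value0 <- sum(residuals(par)^2)
  out <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par, fn = residuals, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter))),
    error = function(e) NULL)
  if (is.null(out)) {
    return(list(par = par, value = value0, converged = FALSE))
  }
  value1 <- sum(residuals(out$par)^2)
  if (is.finite(value1) && value1 <= value0) {
    list(par = pmin(pmax(out$par, lower), upper), value = value1,
         converged = out$info %in% 1:4)
  } else {
    list(par = par, value = value0, converged = FALSE)
  }
}

#' Estimation configuration
#'
#' @param budget `"desk"` (40 parents x 300 generations, suitable for
#'   interactive use and simulation studies) or `"full"` (400 x 4000, the
#'   full-scale budget).
#' @param n_parents,n_generations Explicit overrides of the budget.
#' @param seed Integer seed for the stochastic global search.
#' @param q Tournament size of the meta-EP survivor selection.
#' @param refine Run the local least-squares refinement after the global
#'   search.
#' @param rtol,atol,max_steps Integrator controls (see [simulate_model()]).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(budget = c("desk", "full"), n_parents = NULL,
                       n_generations = NULL, seed = 1, q = 10, refine = TRUE,
                       rtol = 1e-6, atol = 1e-8, max_steps = 2e4) {
  budget <- match.arg(budget)
  sizes <- if (budget == "full") c(400, 4000) else c(40, 300)
  structure(list(budget = budget,
                 n_parents = if (is.null(n_parents)) sizes[1] else n_parents,
                 n_generations = if (is.null(n_generations)) sizes[2]
                                 else n_generations,
                 seed = as.integer(seed), q = q, refine = refine,
                 rtol = rtol, atol = atol, max_steps = max_steps),
            class = "fit_config")
}

# Free-parameter table for a model/variant: names, bounds (log10).
free_parameter_spec <- function(model, variant = NULL) {
  if (model == 1L) {
    nm <- paste0("k", 1:7)
    return(tibble::tibble(name = nm, lower = rep(-4, 7), upper = rep(4, 7)))
  }
  if (is.null(variant)) variant <- variant_family()[1, ]
  nm <- c("k1", "k2", "k3", "k4", "k5",
          if (variant$k6_free) "k6", "k7",
          if (variant$kGN_free) "kGN", "kGgS", "kGgC", "kratio", "kCPC")
  lo <- ifelse(nm == "kratio", -10, -4)
  hi <- ifelse(nm == "kratio", 0, 6)
  tibble::tibble(name = nm, lower = lo, upper = hi)
}

# Assemble the observation set of one subject in the layout the compiled
# objective expects. `series` is the subject's long tibble; glucose is
# window-averaged, all variables are max-normalized.
build_objective_data <- function(series, record, model,
                                 structure = model_structure()) {
  get_var <- function(v) {
    x <- series[series$variable == v, c("t_min", "value")]
    x[order(x$t_min), ]
  }
  gc_raw <- get_var("Gc")
  iv <- get_var("I")
  duration <- as.integer(max(gc_raw$t_min))
  gc_avg <- window_average_glucose(gc_raw)
  f1 <- get_var("f1"); f2 <- get_var("f2")
  if (nrow(f1) != duration + 1 || nrow(f2) != duration + 1) {
    stop("f1/f2 infusion records must cover every minute of the clamp",
         call. = FALSE)
  }
  protocol <- clamp_protocol(duration = duration, f1 = f1$value,
                             f2 = f2$value,
                             body_weight = record$body_weight,
                             blood_volume = record$blood_volume)
  k8 <- estimate_k8(record$urinary_glucose_0_120,
                    glucose_mmoll_to_mgdl(gc_raw$value), gc_raw$t_min,
                    record$blood_volume)
  scale <- c(Gc = max(gc_avg$value), I = max(iv$value), Gg = 1, CP = 1)
  obs <- list(tGc = as.integer(gc_avg$t_min), oGc = gc_avg$value / scale[1],
              tI = as.integer(iv$t_min), oI = iv$value / scale[2],
              tGg = integer(0), oGg = numeric(0), tCP = integer(0),
              oCP = numeric(0))
  n <- c(nGc = nrow(gc_avg), nI = nrow(iv), nGg = 0, nCP = 0)
  if (model == 2L) {
    gg <- get_var("Gg"); cp <- get_var("CP")
    scale["Gg"] <- max(gg$value); scale["CP"] <- max(cp$value)
    obs$tGg <- as.integer(gg$t_min); obs$oGg <- gg$value / scale[3]
    obs$tCP <- as.integer(cp$t_min); obs$oCP <- cp$value / scale[4]
    n["nGg"] <- nrow(gg); n["nCP"] <- nrow(cp)
    structure$eps_I <- max(1e-6 * max(iv$value), .Machine$double.eps)
  }
  tot <- sum(n)
  w <- if (model == 1L) {
    c((tot - n[["nGc"]]) / tot, (tot - n[["nI"]]) / tot, 0, 0)
  } else {
    (tot - n) / tot
  }
  y0 <- c(gc_raw$value[1], gc_raw$value[1], iv$value[1])
  if (model == 2L) {
    y0 <- c(y0, obs$oGg[1] * scale[["Gg"]], obs$oCP[1] * scale[["CP"]])
  }
  list(protocol = protocol, k8 = k8, scale = scale, obs = obs, n = n, w = w,
       y0 = y0, structure = structure, duration = duration)
}

# Data-driven starting candidates from the steady-state identities of the
# model: insulin clearance from the clamp insulin plateau, insulin
# sensitivity from the steady-state glucose balance, secretion gain from the
# fasting insulin level at a small grid of threshold guesses, and the
# glucagon branch from the fasting/steady-state glucagon balance. These seed
# the global search population (the rest of which is log-uniform) and the
# local refinement.
heuristic_seeds <- function(dat, spec, model) {
  cf <- infusion_factors(dat$protocol)
  dur <- dat$duration
  G0 <- dat$y0[1]; I0 <- max(dat$y0[3], 1e-3)
  last30 <- function(t, v) mean(v[t > dur - 30])
  Gss <- last30(dat$obs$tGc, dat$obs$oGc) * dat$scale[["Gc"]]
  Iss <- max(last30(dat$obs$tI, dat$obs$oI) * dat$scale[["I"]], 1e-3)
  fg <- mean(dat$protocol$f1[seq_len(dur + 1) > dur - 30])
  f2bar <- mean(dat$protocol$f2)
  k1_0 <- 0.1; k2_0 <- 0.005; k3_0 <- 0.05
  k7_0 <- if (f2bar > 0) max(cf$cf2 * f2bar / Iss, 1e-3) else 0.1
  k4_0 <- max((cf$cf1 * fg + k1_0 - (k2_0 + dat$k8) * Gss) / (Iss * Gss),
              1.5e-4)
  kratio_0 <- 0.4
  k6_grid <- c(0.4, 0.6, 0.8) * G0
  rows <- list()
  for (k6_0 in k6_grid) {
    x0 <- max(G0 - k6_0, 0.2)
    sec_ratio <- if (model == 2L) kratio_0 else 1
    k5_0 <- I0 * k7_0 / x0 / sec_ratio
    base <- c(k1 = k1_0, k2 = k2_0, k3 = k3_0, k4 = k4_0, k5 = k5_0,
              k6 = k6_0, k7 = k7_0)
    if (model == 1L) {
      rows[[length(rows) + 1]] <- base
    } else {
      Gg0 <- max(dat$y0[4], 1e-3)
      CP0 <- max(dat$y0[5], 1e-4)
      st <- dat$structure
      supp0 <- switch(st$glucagon_suppression,
        saturable_insulin = 1 + I0 / st$I_half,
        inverse_insulin = max(I0, st$eps_I),
        saturable_glucose = 1 + G0 / st$G_half,
        both = (1 + I0 / st$I_half) * (1 + G0 / st$G_half),
        constant = 1)
      kGN_0 <- max(((k2_0 + k4_0 * I0 + dat$k8) * G0 - k1_0) / Gg0, 1e-4)
      kCPC_0 <- k5_0 * x0 / 1000 / CP0
      for (kGgC_0 in c(0.05, 0.1, 0.2)) {
        rows[[length(rows) + 1]] <-
          c(base, kGN = kGN_0, kGgS = Gg0 * kGgC_0 * supp0, kGgC = kGgC_0,
            kratio = kratio_0, kCPC = kCPC_0)
      }
    }
  }
  seeds <- do.call(rbind, rows)
  theta <- log10(pmax(seeds[, spec$name, drop = FALSE], 1e-12))
  theta <- pmin(pmax(theta, rep(spec$lower, each = nrow(theta))),
                rep(spec$upper, each = nrow(theta)))
  theta
}

# Map a free-parameter candidate (log10) plus fixed values onto the 17-slot
# vector rows consumed by the compiled core.
expand_candidates <- function(theta, spec, model, k8, structure) {
  theta <- matrix(theta, ncol = nrow(spec))
  n <- nrow(theta)
  full <- matrix(0, n, 17)
  slot <- c(k1 = 1, k2 = 2, k3 = 3, k4 = 4, k5 = 5, k6 = 6, k7 = 7, k8 = 8,
            kGN = 9, kGgS = 10, kGgC = 11, kratio = 12, kCPC = 13)
  for (j in seq_len(nrow(spec))) {
    full[, slot[[spec$name[j]]]] <- 10^theta[, j]
  }
  full[, 8] <- k8
  full[, 14] <- structure$I_half
  full[, 15] <- structure$G_half
  full[, 16] <- structure$eps_I
  full[, 17] <- suppression_code(structure)
  full
}

#' Fit one subject's clamp series
#'
#' Composes the pipeline the estimation follows for each subject: fix `k8`
#' from the urinary glucose integral, window-average and max-normalize the
#' observations, run the global meta-EP search in log10 parameter space
#' within the estimation bounds, then polish the best candidates by
#' bound-constrained least squares. Deterministic given `config$seed`.
#'
#' @param series Long tibble of one subject's clamp measurements: `Gc` on the
#'   1-minute grid, `I` (and for the GIG model `Gg`, `CP`) at the sampling
#'   times, plus per-minute infusion records `f1`, `f2`.
#' @param record One-row subject tibble (see [read_subject_table()]).
#' @param model `"gi"` or `"gig"`.
#' @param variant One row of [variant_family()] (GIG only; default is the
#'   full model).
#' @param structure A [model_structure()]; the suppression mode is taken
#'   from `variant` when one is given.
#' @param config A [fit_config()].
#' @return An object of class `clamp_fit`: estimated parameters, RSS, AIC
#'   inputs (`n_points`, `K`), optimizer provenance (seed, budget), and the
#'   data needed to reproduce the fitted trajectories.
#' @export
fit_subject <- function(series, record, model = c("gi", "gig"),
                        variant = NULL, structure = model_structure(),
                        config = fit_config()) {
  model_chr <- match.arg(model)
  model <- if (model_chr == "gig") 2L else 1L
  if (model == 2L) {
    if (is.null(variant)) variant <- variant_family()[1, ]
    structure$glucagon_suppression <- variant$suppression
  }
  dat <- build_objective_data(series, record, model, structure)
  spec <- free_parameter_spec(model, variant)
  cf <- infusion_factors(dat$protocol)
  eval_batch <- function(theta) {
    full <- expand_candidates(theta, spec, model, dat$k8, dat$structure)
    objective_batch(model, full, dat$y0, dat$protocol$f1, dat$protocol$f2,
                    cf$cf1, cf$cf2, dat$duration, dat$obs$tGc, dat$obs$oGc,
                    dat$obs$tI, dat$obs$oI, dat$obs$tGg, dat$obs$oGg,
                    dat$obs$tCP, dat$obs$oCP, dat$scale, dat$w, config$rtol,
                    config$atol, config$max_steps)
  }
  resid_fn <- function(theta) {
    full <- expand_candidates(theta, spec, model, dat$k8, dat$structure)
    objective_residuals(model, full[1, ], dat$y0, dat$protocol$f1,
                        dat$protocol$f2, cf$cf1, cf$cf2, dat$duration,
                        dat$obs$tGc, dat$obs$oGc, dat$obs$tI, dat$obs$oI,
                        dat$obs$tGg, dat$obs$oGg, dat$obs$tCP, dat$obs$oCP,
                        dat$scale, dat$w, config$rtol, config$atol,
                        config$max_steps)
  }
  seeds <- heuristic_seeds(dat, spec, model)
  ep <- meta_ep(eval_batch, spec$lower, spec$upper,
                n_parents = config$n_parents,
                n_generations = config$n_generations, seed = config$seed,
                q = config$q, init = seeds)
  best <- list(par = ep$par, value = ep$value, converged = NA)
  if (config$refine) {
    seed_vals <- eval_batch(seeds)
    starts <- rbind(ep$par, ep$population[seq_len(min(4,
                      nrow(ep$population))), , drop = FALSE],
                    seeds[order(seed_vals)[seq_len(min(2,
                      length(seed_vals)))], , drop = FALSE])
    starts <- unique(round(starts, 10))
    for (s in seq_len(nrow(starts))) {
      ref <- local_refine(starts[s, ], resid_fn, spec$lower, spec$upper)
      if (ref$value < best$value) {
        best <- list(par = ref$par, value = ref$value,
                     converged = ref$converged)
      } else if (s == 1 && is.na(best$converged)) {
        best$converged <- ref$converged
      }
    }
  }
  full <- expand_candidates(best$par, spec, model, dat$k8, dat$structure)[1, ]
  params <- if (model == 1L) {
    gi_params(full[1], full[2], full[3], full[4], full[5], full[6], full[7],
              full[8])
  } else {
    gig_params(full[1], full[2], full[3], full[4], full[5], full[6], full[7],
               full[8], full[9], full[10], full[11], full[12], full[13])
  }
  structure(list(
    subject_id = record$subject_id, model = model_chr,
    variant_id = if (model == 2L) variant$variant_id else NA_character_,
    params = params, theta = stats::setNames(best$par, spec$name),
    free = spec$name, K = nrow(spec), rss = best$value, n_points = dat$n,
    weights = dat$w, scales = dat$scale, k8 = dat$k8,
    seed = config$seed, budget = c(parents = config$n_parents,
                                   generations = config$n_generations),
    converged = isTRUE(best$converged), trace = ep$trace,
    structure = dat$structure, protocol = dat$protocol, y0 = dat$y0,
    obs = dat$obs), class = "clamp_fit")
}

#' @export
print.clamp_fit <- function(x, ...) {
  cat("<clamp_fit> subject", x$subject_id, "-", toupper(x$model), "model")
  if (!is.na(x$variant_id)) cat(" (variant", x$variant_id, ")")
  cat("\n  RSS =", format(x$rss, digits = 6), " K =", x$K,
      " N =", sum(x$n_points), "\n  budget:", x$budget[1], "parents x",
      x$budget[2], "generations, seed", x$seed, "\n")
  invisible(x)
}

#' Simulated trajectory of a fitted subject
#'
#' Re-simulates the fitted model under the subject's recorded infusions and
#' returns the trajectory at the measurement times on the normalized scale of
#' the objective, alongside the observations.
#'
#' @param object A `clamp_fit`.
#' @param ... Unused.
#' @return Long tibble with columns `variable`, `t_min`, `observed`,
#'   `simulated` (both normalized).
#' @export
fitted_trajectories <- function(object, ...) {
  traj <- simulate_model(object$params, object$protocol,
                         init = object$y0, structure = object$structure)
  gc_avg <- window_average_glucose(traj$Gc)
  sim_at <- function(var, t) {
    if (var == "Gc") {
      gc_avg[match(t, 5:object$protocol$duration)] / object$scales[["Gc"]]
    } else {
      traj[[var]][match(t, traj$t)] / object$scales[[var]]
    }
  }
  vars <- list(c("Gc", "tGc", "oGc"), c("I", "tI", "oI"),
               c("Gg", "tGg", "oGg"), c("CP", "tCP", "oCP"))
  purrr::map_dfr(vars, function(v) {
    t <- object$obs[[v[2]]]
    if (length(t) == 0) return(NULL)
    tibble::tibble(variable = v[1], t_min = t,
                   observed = object$obs[[v[3]]],
                   simulated = sim_at(v[1], t))
  })
}
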