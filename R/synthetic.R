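#' Configuration of a synthetic clamp + OGTT cohort
#'
#' Defines the virtual study conditions: cohort size and arm, generating
#' model, per-parameter log-uniform sampling ranges (physiologic sub-ranges
#' of the estimation bounds), measurement noise, the clamp protocol
#' (120 min, constant insulin infusion, euglycemic target held by a discrete
#' PI glucose-infusion controller standing in for the bedside closed-loop
#' device), and the 75-g OGTT (gamma-shaped glucose appearance). The
#' SGLT2i arm draws the urinary rate constant `k8` from an elevated range
#' and disperses the glucagon parameters widely while keeping the insulin
#' parameters narrow, so its glycemic variance is glucagon-driven; the
#' control arm does the reverse.
#'
#' @param n_subjects Number of subjects.
#' @param group `"control"` or `"SGLT2i"`.
#' @param model Generating model, `"gig"` or `"gi"`.
#' @param seed Integer seed; every emitted quantity is reproducible from it.
#' @param noise_cv Named coefficients of variation of the multiplicative
#'   lognormal measurement noise for `Gc`, `I`, `Gg`, `CP`.
#' @param ranges Optional named list of `c(lower, upper)` overrides of the
#'   per-parameter sampling ranges.
#' @param clamp,ogtt,controller Protocol settings (see Details in the
#'   package vignette).
#' @param weight_range Body-weight range, kg (uniform draw).
#' @param sampling_times Hormone sampling schedule of the clamp, minutes.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects, group = c("control", "SGLT2i"),
                             model = c("gig", "gi"), seed = 1,
                             noise_cv = c(Gc = 0.02, I = 0.07, Gg = 0.10,
                                          CP = 0.07),
                             ranges = list(),
                             clamp = list(duration = 120, f2 = 1.25,
                                          target = 5.2),
                             ogtt = list(dose_mg = 75000,
                                         bioavailability = 0.8,
                                         shape_k = 2, shape_theta = 30,
                                         duration = 180),
                             controller = list(kp = 2.0, ki = 2.0,
                                               interval = 5),
                             weight_range = c(55, 90),
                             sampling_times = c(0, 5, 10, 15, 20, 30, 45,
                                                60, 75, 90, 105, 120)) {
  group <- match.arg(group)
  model <- match.arg(model)
  stopifnot(n_subjects >= 1, all(noise_cv >= 0))
  base <- default_ranges(group, model)
  for (nm in names(ranges)) base[[nm]] <- ranges[[nm]]
  bad <- vapply(base, function(r) r[1] > r[2] || r[1] <= 0, TRUE)
  if (any(bad)) stop("invalid parameter range(s): ",
                     paste(names(base)[bad], collapse = ", "),
                     call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), group = group,
                 model = model, seed = as.integer(seed),
                 noise_cv = noise_cv, ranges = base, clamp = clamp,
                 ogtt = ogtt, controller = controller,
                 weight_range = weight_range,
                 sampling_times = sampling_times),
            class = "synthetic_config")
}

# Physiologic sampling ranges (log-uniform) by study arm. The arm contrast
# carries the cohort-level variance structure: glucagon-driven glycemic
# variance under SGLT2i, insulin-driven in the control arm.
default_ranges <- function(group, model) {
  r <- list(
    k1 = c(0.05, 0.15),      # basal production, mmol/L/min
    k2 = c(0.003, 0.008),    # insulin-independent removal, 1/min
    k3 = c(0.03, 0.10),      # glucose sensing, 1/min
    k6 = c(2.0, 4.0),        # secretion threshold, mmol/L
    kratio = c(0.25, 0.55),  # posthepatic insulin fraction
    kCPC = c(0.02, 0.05))    # C-peptide clearance, 1/min
  if (group == "SGLT2i") {
    r$k8 <- c(0.006, 0.014)          # elevated urinary excretion
    r$k4 <- c(1.6e-4, 2.8e-4)        # narrow insulin axis
    r$k5 <- c(2.8, 4.8)
    r$k7 <- c(0.09, 0.15)
    r$kGN <- c(0.0012, 0.0080)       # wide glucagon axis
    r$kGgS <- c(0.8, 5.5)
    r$kGgC <- c(0.04, 0.28)
  } else {
    r$k8 <- c(1e-4, 4e-4)            # near-zero urinary excretion
    r$k4 <- c(1.1e-4, 4.0e-4)        # wide insulin axis
    r$k5 <- c(1.6, 8.0)
    r$k7 <- c(0.08, 0.22)
    r$kGN <- c(0.0028, 0.0042)       # narrow glucagon axis
    r$kGgS <- c(1.6, 2.8)
    r$kGgC <- c(0.08, 0.14)
  }
  if (model == "gi") {
    # GI secretion is posthepatic: fold the insulin/C-peptide ratio into k5
    r$k5 <- r$k5 * c(0.25, 0.55)
    r <- r[c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8")]
  }
  r
}

#' Draw true parameter sets for a synthetic cohort
#'
#' Log-uniform draws within the configured physiologic ranges, plus body
#' weight (uniform) and blood volume (0.75 dL/kg).
#'
#' @param config A [synthetic_config()].
#' @return Tibble with one row per subject: `subject_id`, `body_weight`,
#'   `blood_volume`, and the model parameters.
#' @export
sample_parameters <- function(config) {
  set.seed(config$seed)
  n <- config$n_subjects
  draws <- purrr::map(config$ranges, function(r) {
    10^stats::runif(n, log10(r[1]), log10(r[2]))
  })
  tibble::tibble(
    subject_id = sprintf("%s%03d", if (config$group == "SGLT2i") "S" else
      "C", seq_len(n)),
    body_weight = stats::runif(n, config$weight_range[1],
                               config$weight_range[2]),
    blood_volume = NA_real_, !!!draws) |>
    dplyr::mutate(blood_volume = 0.75 * .data$body_weight)
}

params_from_row <- function(row, model) {
  if (model == "gi") {
    gi_params(row$k1, row$k2, row$k3, row$k4, row$k5, row$k6, row$k7,
              row$k8)
  } else {
    gig_params(row$k1, row$k2, row$k3, row$k4, row$k5, row$k6, row$k7,
               row$k8, row$kGN, row$kGgS, row$kGgC, row$kratio, row$kCPC)
  }
}

#' Simulate a hyperinsulinemic-euglycemic clamp under feedback control
#'
#' Insulin is infused at a fixed rate; the glucose infusion is recomputed
#' every `interval` minutes by a discrete proportional-integral rule pushing
#' glycemia toward the target, emulating the artificial endocrine pancreas.
#' The steady-state window is the final 30 minutes.
#'
#' @param params A [gi_params()] or [gig_params()] object.
#' @param config A [synthetic_config()] (clamp and controller settings).
#' @param body_weight,blood_volume Subject anthropometrics.
#' @param structure A [model_structure()].
#' @return List with `trajectory` (per-minute tibble), `f1` (per-minute
#'   infusion record), `fg`, `Gss`, `Iss` (steady-state summaries),
#'   `urinary_glucose` (mg excreted over 0-120 min), and `diverged`.
#' @export
simulate_clamp_with_controller <- function(params, config, body_weight,
                                           blood_volume = 0.75 * body_weight,
                                           structure = model_structure()) {
  cl <- config$clamp
  ctl <- config$controller
  duration <- cl$duration
  target <- cl$target
  model <- model_id(params)
  y <- fasting_steady_state(params, structure)
  step <- ctl$interval
  n_seg <- duration / step
  stopifnot(n_seg == round(n_seg))
  states <- matrix(NA_real_, duration + 1, length(y))
  states[1, ] <- y
  f1_rec <- numeric(duration + 1)
  cf <- infusion_factors(clamp_protocol(duration = duration,
                                        body_weight = body_weight,
                                        blood_volume = blood_volume))
  pvec <- param_vector(params, structure)
  int_term <- 0
  f1_now <- 0
  for (seg in seq_len(n_seg)) {
    t0 <- (seg - 1) * step
    err <- target - y[1]
    int_term <- min(max(int_term + ctl$ki * err, 0), 20)
    f1_now <- min(max(ctl$kp * err + int_term, 0), 50)
    f1_seg <- rep(f1_now, step + 1)
    f2_seg <- rep(cl$f2, step + 1)
    out <- sim_core(model, pvec, as.numeric(y), f1_seg, f2_seg, cf$cf1,
                    cf$cf2, step, 1e-8, 1e-10, 2e5)
    if (nrow(out) == 1) {
      return(list(trajectory = NULL, diverged = TRUE))
    }
    states[t0 + seq_len(step) + 1, ] <- out[-1, ]
    f1_rec[t0 + seq_len(step)] <- f1_now
    y <- out[nrow(out), ]
  }
  f1_rec[duration + 1] <- f1_now
  colnames(states) <- state_names(model)
  traj <- tibble::as_tibble(states)
  traj <- tibble::add_column(traj, t = 0:duration, .before = 1)
  ss <- traj$t > duration - 30
  gss <- mean(traj$Gc[ss])
  diverged <- abs(gss - target) / target > 0.15
  gc_mgdl <- glucose_mmoll_to_mgdl(traj$Gc)
  k8 <- unclass(params)[["k8"]]
  ug <- k8 * blood_volume *
    sum(diff(traj$t) * (utils::head(gc_mgdl, -1) +
                          utils::tail(gc_mgdl, -1)) / 2)
  list(trajectory = traj, f1 = f1_rec, fg = mean(f1_rec[ss]), Gss = gss,
       Iss = mean(traj$I[ss]), urinary_glucose = ug, diverged = diverged)
}

#' Simulate a 75-g oral glucose tolerance test
#'
#' Oral glucose appears in blood as a gamma-shaped flux integrating to
#' `dose * bioavailability`, starting from the fasting steady state with no
#' insulin infusion.
#'
#' @inheritParams simulate_clamp_with_controller
#' @return List with `series` (tibble `t_min`, `glucose` mg/dL, `insulin`
#'   uU/mL at 0/30/60/90/120 min), `trajectory` (per-minute, internal
#'   units), and `PG120` (mmol/L).
#' @export
simulate_ogtt <- function(params, config, body_weight,
                          blood_volume = 0.75 * body_weight,
                          structure = model_structure()) {
  og <- config$ogtt
  duration <- og$duration
  tt <- 0:duration
  flux <- stats::dgamma(tt, shape = og$shape_k, scale = og$shape_theta) *
    og$dose_mg * og$bioavailability / body_weight   # mg/kg/min appearance
  y0 <- fasting_steady_state(params, structure)
  protocol <- clamp_protocol(duration = duration, f1 = flux, f2 = 0,
                             body_weight = body_weight,
                             blood_volume = blood_volume)
  traj <- simulate_model(params, protocol, init = y0,
                         structure = structure)
  keep <- c(0, 30, 60, 90, 120)
  idx <- match(keep, traj$t)
  series <- tibble::tibble(
    t_min = keep,
    glucose = glucose_mmoll_to_mgdl(traj$Gc[idx]),
    insulin = insulin_pmoll_to_uuml(traj$I[idx]))
  list(series = series, trajectory = traj, PG120 = traj$Gc[match(120,
                                                                 traj$t)])
}

#' Apply multiplicative lognormal measurement noise
#'
#' Each sample is multiplied by a lognormal factor with unit mean and the
#' per-variable coefficient of variation, so non-negativity is preserved by
#' construction and `cv = 0` is the identity.
#'
#' @param series Long tibble (`variable`, `value`, ...).
#' @param noise_cv Named CVs per variable; variables without an entry are
#'   untouched.
#' @param seed Integer seed.
#' @return The series with noisy values.
#' @export
add_noise <- function(series, noise_cv, seed) {
  set.seed(seed)
  out <- series
  for (v in names(noise_cv)) {
    cv <- noise_cv[[v]]
    if (cv <= 0) next
    idx <- which(out$variable == v)
    if (length(idx) == 0) next
    sdlog <- sqrt(log(1 + cv^2))
    out$value[idx] <- out$value[idx] *
      stats::rlnorm(length(idx), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' End-to-end composition: draw true parameters, run the controlled clamp
#' and the OGTT per subject, apply measurement noise, and assemble the
#' subject record table, the long-format clamp series, the OGTT table and a
#' ground-truth sidecar (true parameters and composite indices, noiseless
#' realized observables). Subjects whose controller diverges are flagged and
#' excluded from the emitted tables.
#'
#' @param config A [synthetic_config()].
#' @param structure A [model_structure()].
#' @return A list of class `synthetic_cohort` with tibbles `subjects`,
#'   `series`, `ogtt`, `ground_truth`, and the `config`.
#' @export
generate_cohort <- function(config, structure = model_structure()) {
  pars <- sample_parameters(config)
  model <- config$model
  rows <- split(pars, seq_len(nrow(pars)))
  per_subject <- purrr::imap(rows, function(row, i) {
    i <- as.integer(i)
    p <- params_from_row(row, model)
    clamp <- simulate_clamp_with_controller(p, config, row$body_weight,
                                            row$blood_volume, structure)
    if (isTRUE(clamp$diverged)) {
      return(list(flagged = TRUE, subject_id = row$subject_id))
    }
    og <- simulate_ogtt(p, config, row$body_weight, row$blood_volume,
                        structure)
    traj <- clamp$trajectory
    smp <- config$sampling_times
    vars <- list(
      tibble::tibble(variable = "Gc", t_min = traj$t, value = traj$Gc,
                     units = "mmol/L"),
      tibble::tibble(variable = "I", t_min = smp,
                     value = traj$I[match(smp, traj$t)], units = "pmol/L"))
    if (model == "gig") {
      vars <- c(vars, list(
        tibble::tibble(variable = "Gg", t_min = smp,
                       value = traj$Gg[match(smp, traj$t)], units = "ng/L"),
        tibble::tibble(variable = "CP", t_min = smp,
                       value = traj$CP[match(smp, traj$t)],
                       units = "nmol/L")))
    }
    meas <- dplyr::bind_rows(vars)
    meas <- add_noise(meas, config$noise_cv, seed = config$seed + 1000L + i)
    ogtt_noisy <- og$series
    gcv <- config$noise_cv[["Gc"]]; icv <- config$noise_cv[["I"]]
    if (gcv > 0 || icv > 0) {
      set.seed(config$seed + 5000L + i)
      ng <- nrow(ogtt_noisy)
      if (gcv > 0) {
        sdg <- sqrt(log(1 + gcv^2))
        ogtt_noisy$glucose <- ogtt_noisy$glucose *
          stats::rlnorm(ng, -sdg^2 / 2, sdg)
      }
      if (icv > 0) {
        sdi <- sqrt(log(1 + icv^2))
        ogtt_noisy$insulin <- ogtt_noisy$insulin *
          stats::rlnorm(ng, -sdi^2 / 2, sdi)
      }
    }
    infusions <- dplyr::bind_rows(
      tibble::tibble(variable = "f1", t_min = traj$t, value = clamp$f1,
                     units = "mg/kg/min"),
      tibble::tibble(variable = "f2", t_min = traj$t,
                     value = rep(config$clamp$f2, nrow(traj)),
                     units = "mU/kg/min"))
    series <- dplyr::bind_rows(meas, infusions)
    series <- tibble::add_column(series, subject_id = row$subject_id,
                                 .before = 1)
    series <- series[, c("subject_id", "t_min", "variable", "value",
                         "units")]
    pick <- function(v, t) {
      x <- meas[meas$variable == v, ]
      if (nrow(x) == 0) return(NA_real_)
      x$value[match(t, x$t_min)]
    }
    ss <- traj$t > config$clamp$duration - 30
    meas_gc <- meas[meas$variable == "Gc", ]
    record <- tibble::tibble(
      subject_id = row$subject_id, group = config$group,
      body_weight = row$body_weight, blood_volume = row$blood_volume,
      urinary_glucose_0_120 = clamp$urinary_glucose,
      G0 = pick("Gc", 0), I0 = pick("I", 0), Gg0 = pick("Gg", 0),
      CP0 = pick("CP", 0),
      Gss = mean(meas_gc$value[meas_gc$t_min > config$clamp$duration - 30]),
      Iss = mean(pick("I", c(90, 105, 120))), fg = clamp$fg,
      PG120 = glucose_mgdl_to_mmoll(
        ogtt_noisy$glucose[match(120, ogtt_noisy$t_min)]))
    truth <- dplyr::bind_cols(
      row,
      tibble::tibble(
        di_cle = di_cle(row$k4, row$k5, row$k7),
        pi_cle_numeric = if (model == "gig") {
          pi_cle_numeric(row$kGN, row$kGgS, row$kGgC, 2)
        } else NA_real_,
        G0_true = traj$Gc[1], I0_true = traj$I[1],
        Gg0_true = if (model == "gig") traj$Gg[1] else NA_real_,
        Gss_true = clamp$Gss, Iss_true = clamp$Iss, fg_true = clamp$fg,
        urinary_glucose = clamp$urinary_glucose, PG120_true = og$PG120,
        flagged = FALSE))
    list(flagged = FALSE, record = record, series = series,
         ogtt = tibble::add_column(ogtt_noisy, subject_id = row$subject_id,
                                   .before = 1),
         truth = truth)
  })
  flagged <- purrr::map_lgl(per_subject, "flagged")
  if (any(flagged)) {
    message(sum(flagged), " subject(s) excluded: controller divergence")
  }
  kept <- per_subject[!flagged]
  structure(list(
    subjects = purrr::map_dfr(kept, "record"),
    series = purrr::map_dfr(kept, "series"),
    ogtt = purrr::map_dfr(kept, "ogtt"),
    ground_truth = purrr::map_dfr(kept, "truth"),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$subjects), "subjects,",
      x$config$group, "arm,", toupper(x$config$model), "model, seed",
      x$config$seed, "\n")
  invisible(x)
}
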