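#' Disposition index over clearance
#'
#' `DI/cle = k4 * k5 / k7^2`: insulin sensitivity times insulin secretion
#' divided by the square of insulin clearance. Reflects the glucose-handling
#' ability of insulin after adjusting the classical disposition index for
#' insulin clearance.
#'
#' @param k4 Insulin sensitivity.
#' @param k5 Insulin secretion gain.
#' @param k7 Insulin clearance (> 0).
#' @return DI/cle.
#' @export
di_cle <- function(k4, k5, k7) {
  if (any(k7 <= 0)) stop("k7 must be positive", call. = FALSE)
  k4 * k5 / k7^2
}

#' Numerically estimated production index over clearance
#'
#' `PI/cle = kGN * kGgS / kGgC^exponent`: glucagon sensitivity times
#' glucagon secretion divided by a power of glucagon clearance. The default
#' exponent 2 mirrors DI/cle; exponents 1 and 3 are the sensitivity
#' alternatives.
#'
#' @param kGN Glucagon sensitivity.
#' @param kGgS Glucagon secretion gain.
#' @param kGgC Glucagon clearance (> 0).
#' @param exponent 1, 2 or 3.
#' @return Numeric PI/cle.
#' @export
pi_cle_numeric <- function(kGN, kGgS, kGgC, exponent = 2) {
  if (!exponent %in% c(1, 2, 3)) {
    stop("exponent must be 1, 2 or 3", call. = FALSE)
  }
  if (any(kGgC <= 0)) stop("kGgC must be positive", call. = FALSE)
  kGN * kGgS / kGgC^exponent
}

#' Analytic production index over clearance from clamp observables
#'
#' `PI/cle = (Gg0 * G0 * fg) / (Gss * Iss)`, computed purely from fasting
#' and clamp steady-state observables, decomposed as glucagon sensitivity
#' `Ggsen = G0 * fg / (Gss * Iss^2)` (whose numerator carries the fasting
#' glycemia) times the secretion-to-clearance ratio `Ggsec/cle = Gg0 * Iss`
#' (no glycemia-related index in its numerator); the product identity holds
#' exactly.
#'
#' @param Gg0 Fasting blood glucagon, ng/L.
#' @param G0 Fasting blood glucose, mmol/L.
#' @param fg Glucose infusion rate at clamp steady state, mg/kg/min.
#' @param Gss Blood glucose at clamp steady state, mmol/L.
#' @param Iss Blood insulin at clamp steady state, pmol/L.
#' @return Tibble with columns `pi_cle`, `ggsen`, `ggsec_cle`.
#' @export
pi_cle_analytic <- function(Gg0, G0, fg, Gss, Iss) {
  vals <- cbind(Gg0, G0, fg, Gss, Iss)
  if (any(vals <= 0)) {
    stop("all inputs of the analytic PI/cle must be positive",
         call. = FALSE)
  }
  ggsen <- G0 * fg / (Gss * Iss^2)
  ggsec_cle <- Gg0 * Iss
  tibble::tibble(pi_cle = ggsen * ggsec_cle, ggsen = ggsen,
                 ggsec_cle = ggsec_cle)
}

#' Insulin sensitivity index
#'
#' `ISI = 100 * uptake / (G_end / I_end)` where the uptake is the tissue
#' glucose uptake rate (TGUR) for subjects with urinary glucose loss and the
#' glucose infusion rate (GIR) otherwise, `G_end` is the plasma glucose at
#' the end of the clamp in mg/dL and `I_end` the serum insulin in uU/mL.
#'
#' @param uptake_rate TGUR or GIR, mg/kg/min.
#' @param g_end End-of-clamp glucose, mg/dL.
#' @param i_end End-of-clamp insulin, uU/mL.
#' @return ISI.
#' @export
isi <- function(uptake_rate, g_end, i_end) {
  if (any(c(uptake_rate, g_end, i_end) <= 0)) {
    stop("ISI inputs must be positive", call. = FALSE)
  }
  100 * uptake_rate / (g_end / i_end)
}

#' Tissue glucose uptake rate
#'
#' `TGUR = GIR - UGER`: glucose infusion rate minus urinary glucose
#' excretion rate. A negative difference is physiologically implausible and
#' triggers a warning, not an error, since measured data may violate it.
#'
#' @param gir Glucose infusion rate, mg/kg/min.
#' @param uger Urinary glucose excretion rate, mg/kg/min.
#' @return TGUR, mg/kg/min.
#' @export
tgur <- function(gir, uger) {
  if (any(uger < 0) || any(gir < 0)) {
    stop("GIR and UGER must be non-negative", call. = FALSE)
  }
  if (any(gir < uger)) warning("UGER exceeds GIR; TGUR is negative")
  gir - uger
}

#' OGTT-derived indices
#'
#' From a 75-g oral glucose tolerance test series: `PG120` (glucose at 120
#' min), the insulinogenic index `(I30 - I0) / (G30 - G0)` (flagged `NA`
#' when the glucose increment vanishes), and the Matsuda index
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` with the means taken over the
#' available samples in 0-120 min. Inputs are in the conventional OGTT units
#' (glucose mg/dL, insulin uU/mL).
#'
#' @param ogtt Tibble with columns `t_min`, `glucose`, `insulin`; must
#'   contain `t_min` 0, 30 and 120.
#' @return One-row tibble: `PG120` (mg/dL), `insulinogenic_index`,
#'   `matsuda_index`.
#' @export
ogtt_indices <- function(ogtt) {
  stopifnot(all(c("t_min", "glucose", "insulin") %in% names(ogtt)))
  need <- c(0, 30, 120)
  if (!all(need %in% ogtt$t_min)) {
    stop("OGTT series must include t = 0, 30 and 120 min", call. = FALSE)
  }
  at <- function(v, t) ogtt[[v]][match(t, ogtt$t_min)]
  g0 <- at("glucose", 0); g30 <- at("glucose", 30)
  i0 <- at("insulin", 0); i30 <- at("insulin", 30)
  igi <- if (abs(g30 - g0) < .Machine$double.eps^0.5) NA_real_ else
    (i30 - i0) / (g30 - g0)
  in_window <- ogtt$t_min >= 0 & ogtt$t_min <= 120
  gm <- mean(ogtt$glucose[in_window])
  im <- mean(ogtt$insulin[in_window])
  matsuda <- 10000 / sqrt(g0 * i0 * gm * im)
  tibble::tibble(PG120 = at("glucose", 120), insulinogenic_index = igi,
                 matsuda_index = matsuda)
}

#' Insulin half-life from the clearance rate constant
#'
#' First-order elimination gives `t_half = ln(2) / k7` minutes.
#'
#' @param k7 Insulin clearance, 1/min (> 0).
#' @return Half-life in minutes.
#' @export
insulin_half_life <- function(k7) {
  if (any(k7 <= 0)) stop("k7 must be positive", call. = FALSE)
  log(2) / k7
}

#' Simulated insulin sensitivity index of a fitted subject
#'
#' Re-simulates the fitted model under the subject's recorded infusions and
#' evaluates the ISI from the simulated end-of-clamp glucose and insulin and
#' the simulated tissue uptake (steady-state glucose infusion minus the
#' model's urinary flux `k8 * Gc * BV / weight`).
#'
#' @param fit A `clamp_fit`.
#' @return Simulated ISI.
#' @export
isi_simulated <- function(fit) {
  traj <- simulate_model(fit$params, fit$protocol, init = fit$y0,
                         structure = fit$structure)
  dur <- fit$protocol$duration
  last30 <- traj$t > dur - 30
  g_end <- mean(traj$Gc[last30])
  i_end <- mean(traj$I[last30])
  fg <- mean(fit$protocol$f1[seq_len(dur + 1) > dur - 30])
  uger_sim <- fit$k8 * glucose_mmoll_to_mgdl(g_end) *
    fit$protocol$blood_volume / fit$protocol$body_weight
  uptake <- fg - uger_sim
  isi(max(uptake, .Machine$double.eps), glucose_mmoll_to_mgdl(g_end),
      insulin_pmoll_to_uuml(i_end))
}

#' Composite metric set for one fitted subject
#'
#' Joins the fit-derived indices (DI/cle, numeric PI/cle, insulin half-life)
#' with the observable-derived ones (analytic PI/cle, ISI, TGUR) from the
#' subject record.
#'
#' @param fit A `clamp_fit` (GI or GIG).
#' @param record One-row subject tibble with the clamp observables.
#' @return One-row tibble of metrics with provenance columns.
#' @export
subject_metrics <- function(fit, record) {
  p <- unclass(fit$params)
  out <- tibble::tibble(
    subject_id = fit$subject_id, model = fit$model,
    variant_id = fit$variant_id, seed = fit$seed,
    di_cle = di_cle(p[["k4"]], p[["k5"]], p[["k7"]]),
    insulin_half_life = insulin_half_life(p[["k7"]]))
  if (fit$model == "gig") {
    out$pi_cle_numeric_exp1 <- pi_cle_numeric(p[["kGN"]], p[["kGgS"]],
                                              p[["kGgC"]], 1)
    out$pi_cle_numeric_exp2 <- pi_cle_numeric(p[["kGN"]], p[["kGgS"]],
                                              p[["kGgC"]], 2)
    out$pi_cle_numeric_exp3 <- pi_cle_numeric(p[["kGN"]], p[["kGgS"]],
                                              p[["kGgC"]], 3)
  }
  if (!is.null(record)) {
    obs <- c(record$Gg0, record$G0, record$fg, record$Gss, record$Iss)
    if (!anyNA(obs) && all(obs > 0)) {
      an <- pi_cle_analytic(record$Gg0, record$G0, record$fg, record$Gss,
                            record$Iss)
      out$pi_cle_analytic <- an$pi_cle
      out$ggsen <- an$ggsen
      out$ggsec_cle <- an$ggsec_cle
    }
    uger <- record$urinary_glucose_0_120 / record$body_weight / 120
    out$tgur <- tgur(record$fg, uger)
    out$isi_measured <- isi(if (uger > 1e-6) out$tgur else record$fg,
                            glucose_mmoll_to_mgdl(record$Gss),
                            insulin_pmoll_to_uuml(record$Iss))
    if ("PG120" %in% names(record)) out$PG120 <- record$PG120
  }
  out
}
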