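#' Parameters of the GI (glucose-insulin) model
#'
#' Rate constants of the two-hormone feedback model. Estimated parameters are
#' bounded in `[1e-4, 1e4]`; `k8` is fixed from the urinary glucose integral
#' (see [estimate_k8()]) and is never estimated.
#'
#' @param k1 Basal (glucagon-independent) glucose production, mmol/L/min.
#' @param k2 Insulin-independent glucose removal, 1/min.
#' @param k3 Glucose-sensing rate of the effective-glucose state Y, 1/min.
#' @param k4 Insulin sensitivity: glucose uptake per unit insulin,
#'   1/(pmol/L)/min.
#' @param k5 Insulin secretion gain: secretion flux per unit of the
#'   thresholded drive `X = max(Y - k6, 0)`, (pmol/L)/(mmol/L)/min.
#' @param k6 Glucose threshold of the secretion drive, mmol/L.
#' @param k7 Insulin clearance, 1/min.
#' @param k8 Urinary glucose excretion rate constant (alias `ku`), 1/min.
#' @return An object of class `gi_params`: a named numeric vector.
#' @seealso [gig_params()], [simulate_model()]
#' @export
gi_params <- function(k1, k2, k3, k4, k5, k6, k7, k8 = 0) {
  p <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
         k8 = k8)
  if (anyNA(p) || any(p < 0)) {
    stop("all GI parameters must be non-negative and non-missing",
         call. = FALSE)
  }
  structure(p, class = c("gi_params", "gigclamp_params"))
}

#' Parameters of the GIG (glucose-insulin-glucagon) model
#'
#' Extends [gi_params()] with the glucagon and C-peptide branch. Estimated
#' parameters are bounded in `[1e-4, 1e6]` except `kratio` in `[1e-10, 1]`
#' (the molar ratio of posthepatic insulin to C-peptide); `k8` is fixed.
#'
#' @inheritParams gi_params
#' @param kGN Glucagon sensitivity: glucose production per unit glucagon,
#'   (mmol/L)/(ng/L)/min.
#' @param kGgS Glucagon secretion gain, ng/L/min (modulated by the structural
#'   suppression term, see [model_structure()]).
#' @param kGgC Glucagon clearance, 1/min.
#' @param kratio Molar ratio of posthepatic insulin to C-peptide,
#'   dimensionless in `[0, 1]`.
#' @param kCPC C-peptide clearance, 1/min.
#' @return An object of class `gig_params`.
#' @export
gig_params <- function(k1, k2, k3, k4, k5, k6, k7, k8 = 0, kGN, kGgS, kGgC,
                       kratio, kCPC) {
  p <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
         k8 = k8, kGN = kGN, kGgS = kGgS, kGgC = kGgC, kratio = kratio,
         kCPC = kCPC)
  if (anyNA(p) || any(p < 0)) {
    stop("all GIG parameters must be non-negative and non-missing",
         call. = FALSE)
  }
  if (kratio > 1) stop("kratio must lie in [0, 1]", call. = FALSE)
  structure(p, class = c("gig_params", "gigclamp_params"))
}

#' Structural (non-estimated) constants of the GIG model
#'
#' The glucagon secretion term is pluggable. The default is a saturable
#' insulin inhibition `kGgS / (1 + I / I_half)`: nearly unsuppressed at
#' fasting insulin, strongly suppressed during clamp hyperinsulinemia.
#' Alternatives cover inverse-insulin suppression `kGgS / max(I, eps_I)`,
#' saturable glucose suppression, combined suppression, and constant
#' (unsuppressed) secretion; these are the toggles the model-variant family
#' enumerates.
#'
#' @param glucagon_suppression One of `"saturable_insulin"`,
#'   `"inverse_insulin"`, `"saturable_glucose"`, `"both"`, `"constant"`.
#' @param I_half Insulin concentration halving glucagon secretion, pmol/L.
#' @param G_half Glucose concentration halving glucagon secretion, mmol/L.
#' @param eps_I Floor for the inverse-insulin form, pmol/L; conventionally
#'   `1e-6` times the subject's maximum insulin.
#' @return An object of class `model_structure`.
#' @export
model_structure <- function(glucagon_suppression = c("saturable_insulin",
                                                     "inverse_insulin",
                                                     "saturable_glucose",
                                                     "both", "constant"),
                            I_half = 400, G_half = 10, eps_I = 1e-3) {
  glucagon_suppression <- match.arg(glucagon_suppression)
  stopifnot(I_half > 0, G_half > 0, eps_I > 0)
  structure(list(glucagon_suppression = glucagon_suppression,
                 I_half = I_half, G_half = G_half, eps_I = eps_I),
            class = "model_structure")
}

suppression_code <- function(structure) {
  c(saturable_insulin = 0, inverse_insulin = 1, saturable_glucose = 2,
    both = 3, constant = 4)[[structure$glucagon_suppression]]
}

# Full 17-slot parameter vector consumed by the compiled core.
param_vector <- function(params, structure = model_structure()) {
  p <- numeric(17)
  p[seq_len(8)] <- unclass(params)[paste0("k", 1:8)]
  if (inherits(params, "gig_params")) {
    p[9:13] <- unclass(params)[c("kGN", "kGgS", "kGgC", "kratio", "kCPC")]
  }
  p[14] <- structure$I_half
  p[15] <- structure$G_half
  p[16] <- structure$eps_I
  p[17] <- suppression_code(structure)
  p
}

model_id <- function(params) if (inherits(params, "gig_params")) 2L else 1L

state_names <- function(model) {
  if (model == 1L) c("Gc", "Y", "I") else c("Gc", "Y", "I", "Gg", "CP")
}
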