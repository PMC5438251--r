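#' Calibrate the toxicity threshold from the step adaptation limit
#'
#' Experimentally, stepwise exposure beyond about 0.6 mM external H2O2
#' arrests growth. The toxicity threshold `H_tox` is therefore defined as
#' the peak internal concentration reached during a step of the limit
#' amplitude, simulated from the pre-stress equilibrium.
#'
#' @param params a [feedbackParams()] object.
#' @param step_level step amplitude (mM); 0.6 by default.
#' @param horizon integration horizon (min); the transient peaks within
#'   minutes, the default leaves a wide margin.
#' @param ... passed to [simulateModel()].
#' @return `H_tox` (mM).
#' @examples
#' \donttest{calibrateHtox(linearParams("slow"))}
#' @export
calibrateHtox <- function(params, step_level = 0.6, horizon = 1000, ...) {
  traj <- simulateModel(params, stepProtocol(step_level, horizon = horizon),
                        ...)
  peakInternal(traj)$H_max
}

# ramp-to-amplitude-then-hold protocol; rate Inf is the exact step limit
.ramp_hold_protocol <- function(params, I, delta, settle = NULL) {
  settle <- settle %||% if (params$mu_prime > 0)
    5 / params$mu_prime else 5 / params$mu + 500
  if (is.infinite(delta))
    stepProtocol(I, horizon = settle)
  else
    rampProtocol(delta, amplitude = I, horizon = I / delta + settle)
}

#' Peak internal H2O2 for a ramp-to-amplitude stimulus
#'
#' Simulates a linear ramp of rate `delta` from 0 up to amplitude `I`
#' followed by a hold, and returns the global peak of internal H2O2.
#' `delta = Inf` is the step limit, represented as an exact discontinuity.
#'
#' @param params a [feedbackParams()] object.
#' @param I stimulus amplitude (mM).
#' @param delta ramp rate (mM/min) or `Inf`.
#' @param settle hold duration after the ramp tops out (min); defaults to
#'   five protein-dilution time constants.
#' @param ... passed to [simulateModel()].
#' @return `H_max` (mM).
#' @export
hmaxRamp <- function(params, I, delta, settle = NULL, ...) {
  if (I == 0) return(preStressState(params)[["H"]])
  traj <- simulateModel(params, .ramp_hold_protocol(params, I, delta, settle),
                        ...)
  peakInternal(traj)$H_max
}

#' Phase diagram of peak internal H2O2 over (amplitude, rate)
#'
#' Computes `H_max` for every combination of stimulus amplitude `I` and
#' ramp rate `delta` (use `Inf` for the step column) and, when `H_tox` is
#' supplied, classifies each cell as adapted (`H_max < H_tox`) or arrested.
#'
#' @param params a [feedbackParams()] object.
#' @param I_values amplitudes (mM), positive and sorted.
#' @param delta_values ramp rates (mM/min), positive and sorted, may end
#'   with `Inf`.
#' @param H_tox optional toxicity threshold (mM) for fate classification.
#' @param ... passed to [simulateModel()].
#' @return An object of class `phase_diagram`: list with `I`, `delta`,
#'   `H_max` (matrix, rows = amplitudes, columns = rates), `H_tox`, and
#'   `adapted` (logical matrix, if `H_tox` given).
#' @export
hmaxGrid <- function(params, I_values, delta_values, H_tox = NULL, ...) {
  stopifnot(all(I_values > 0), all(delta_values > 0),
            !is.unsorted(I_values), !is.unsorted(delta_values))
  M <- matrix(NA_real_, length(I_values), length(delta_values),
              dimnames = list(I = signif(I_values, 6),
                              delta = signif(delta_values, 6)))
  for (j in seq_along(delta_values))
    for (i in seq_along(I_values))
      M[i, j] <- tryCatch(
        hmaxRamp(params, I_values[i], delta_values[j], ...),
        error = function(e) {
          warning("grid cell (I = ", I_values[i], ", delta = ",
                  delta_values[j], ") failed: ", conditionMessage(e))
          NA_real_
        })
  out <- list(I = I_values, delta = delta_values, H_max = M,
              H_tox = H_tox, params = params)
  if (!is.null(H_tox)) out$adapted <- M < H_tox
  structure(out, class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram>", length(x$I), "amplitudes x", length(x$delta),
      "rates; variant:", x$params$variant, "\n")
  if (!is.null(x$H_tox))
    cat("  H_tox =", signif(x$H_tox, 6), "mM;",
        sum(x$adapted, na.rm = TRUE), "adapted cells\n")
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  df <- expand.grid(I_mM = x$I, delta_mM_per_min = x$delta,
                    KEEP.OUT.ATTRS = FALSE)
  df$H_max_mM <- as.vector(x$H_max)
  if (!is.null(x$H_tox)) df$adapted_bool <- as.vector(x$adapted)
  df
}

#' Critical amplitude of the adaptation boundary at fixed ramp rate
#'
#' Bisects the amplitude I at which the peak internal H2O2 of a
#' ramp-to-I-then-hold stimulus crosses `H_tox`. By construction of the
#' calibration, the step limit (`delta = Inf`) returns the calibration step
#' amplitude, and for `delta -> 0` the critical amplitude approaches the
#' absolute adaptation concentration `I_abs`.
#'
#' @param params a [feedbackParams()] object.
#' @param H_tox toxicity threshold (mM).
#' @param delta ramp rate (mM/min) or `Inf`.
#' @param I_range search bracket (mM); defaults to `(0, 4 I_abs]` (or
#'   `(0, 4 H_tox]` when `I_abs` is undefined).
#' @param tol bisection tolerance on I (mM).
#' @param ... passed to [simulateModel()].
#' @return Critical amplitude `I_crit` (mM). If the peak never exceeds
#'   `H_tox` on the search range the upper bound is returned with attribute
#'   `open = TRUE`.
#' @export
adaptationBoundary <- function(params, H_tox, delta, I_range = NULL,
                               tol = 1e-3, ...) {
  if (H_tox <= 0) stop("H_tox must be > 0")
  I_range <- I_range %||% c(tol,
    4 * if (params$mu_prime > 0) iAbs(params, H_tox) else H_tox)
  f <- function(I) hmaxRamp(params, I, delta, ...) - H_tox
  lo <- I_range[1]; hi <- I_range[2]
  if (f(hi) < 0)
    return(structure(hi, open = TRUE))
  if (f(lo) > 0) stop("H_max exceeds H_tox at the lower search bound")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Peak internal H2O2 during a challenge after pretreatment
#'
#' Simulates a sustained pretreatment at `I0` long enough to equilibrate,
#' followed by a step of additional magnitude `delta_I`, and returns the
#' peak internal H2O2 within the challenge window. Under the linear
#' variant the burst (peak minus the pretreatment equilibrium) is
#' independent of `I0` by superposition; under the nonlinear variant the
#' burst decreases strictly with `I0` — the signature of acquired
#' tolerance. (The absolute peak is not monotone: the pretreatment
#' baseline itself grows with `I0`.)
#'
#' @param params a [feedbackParams()] object.
#' @param I0 pretreatment level (mM).
#' @param delta_I challenge step magnitude (mM).
#' @param t_challenge challenge onset (min); defaults to five
#'   protein-dilution time constants so the pretreatment has equilibrated.
#' @param settle challenge observation window (min).
#' @param ... passed to [simulateModel()].
#' @return List with `H_max_challenge` (mM), `H_eq_pre` (mM, the
#'   pretreatment equilibrium) and `t_at_peak` (min).
#' @export
pretreatmentPeak <- function(params, I0, delta_I,
                             t_challenge = NULL, settle = 400, ...) {
  t_challenge <- t_challenge %||% if (params$mu_prime > 0)
    5 / params$mu_prime else 2000
  proto <- makePretreatmentProtocol(I0, delta_I = delta_I,
                                    t_challenge = t_challenge,
                                    horizon = t_challenge + settle)
  traj <- simulateModel(params, proto, ...)
  pk <- peakInternal(traj, window = c(t_challenge, t_challenge + settle))
  H_pre <- traj$H[max(which(traj$time <= t_challenge))]
  list(H_max_challenge = pk$H_max, H_eq_pre = H_pre,
       t_at_peak = pk$t_at_peak)
}

#' Maximal tolerated challenge after pretreatment
#'
#' Bisects the largest challenge step `delta_I` whose peak internal H2O2
#' stays below `H_tox` after a sustained pretreatment at `I0`. Under the
#' nonlinear variant the threshold increases with the pretreatment level
#' (acquired tolerance); under the linear variant the shift is bounded by
#' the pretreatment equilibrium concentration.
#'
#' @inheritParams pretreatmentPeak
#' @param H_tox toxicity threshold (mM).
#' @param dI_range search bracket for `delta_I` (mM).
#' @param tol bisection tolerance (mM).
#' @return Threshold `delta_I` (mM); attribute `open = TRUE` if the peak
#'   never reaches `H_tox` on the search range.
#' @export
toleranceThreshold <- function(params, I0, H_tox, dI_range = c(1e-3, 5),
                               tol = 1e-3, ...) {
  f <- function(dI)
    pretreatmentPeak(params, I0, dI, ...)$H_max_challenge - H_tox
  lo <- dI_range[1]; hi <- dI_range[2]
  if (f(hi) < 0) return(structure(hi, open = TRUE))
  if (f(lo) > 0) stop("peak exceeds H_tox at the smallest challenge")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Classify a stimulus as adapted or arrested
#'
#' @param H_max peak internal concentration (mM).
#' @param H_tox toxicity threshold (mM).
#' @return Factor with levels `adapted`, `arrested`.
#' @export
fateCall <- function(H_max, H_tox) {
  factor(ifelse(H_max < H_tox, "adapted", "arrested"),
         levels = c("adapted", "arrested"))
}
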