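#' Closed-form steady state of the linear-family variants
#'
#' For f = 1, g = H the equilibrium is
#' `H_eq = mu mu' (epsilon + alpha I) / (alpha mu mu' + beta gamma gamma')`,
#' with the transcript and protein levels following from the linear chain.
#' In the integral limit (`mu_prime = 0`) the internal concentration is
#' exactly zero for any input, the signature of perfect adaptation.
#'
#' @param params a [feedbackParams()] with variant `"linear"` or
#'   `"integral"`.
#' @param I external concentration (mM), vectorised.
#' @return A data frame with columns `I`, `H_eq`, `A_mRNA_eq`, `A_eq`.
#' @examples
#' steadyStateLinear(linearParams("slow"), 0.4)$H_eq  # ~0.02966 mM
#' @export
steadyStateLinear <- function(params, I) {
  stopifnot(inherits(params, "feedback_params"))
  if (!params$variant %in% c("linear", "integral"))
    stop("closed form applies to the linear-family variants only")
  if (any(I < 0)) stop("I must be >= 0")
  mu <- params$mu; mup <- params$mu_prime; al <- params$alpha
  drive <- params$epsilon + al * I
  den <- al * mu * mup + params$beta * params$gamma * params$gamma_prime
  data.frame(I = I,
             H_eq = mu * mup * drive / den,
             A_mRNA_eq = params$gamma * mup * drive / den,
             A_eq = params$gamma * params$gamma_prime * drive / den)
}

#' Composite constants of the feedback model
#'
#' `Z = gamma gamma' beta / (mu mu' alpha)` (mM): the scavenging-to-dilution
#' scale; of the order of the absolute adaptation concentration.
#' `sigma = alpha mu mu' K W / (beta gamma gamma')` (mM^2 on the model's
#' unit convention): controls the sublinearity of the nonlinear steady
#' state at low dose. When `H_tox` is supplied, also `I_abs` (see [iAbs()])
#' and, for integral feedback, `delta_max` (see [deltaMax()]).
#'
#' @param params a [feedbackParams()] object.
#' @param H_tox toxicity threshold (mM), optional.
#' @return Named list with `Z`, `sigma` (NA unless both K and W are set),
#'   and, if `H_tox` given, `H_tox`, `I_abs`, `delta_max` (the last two NA
#'   where undefined).
#' @export
derivedConstants <- function(params, H_tox = NULL) {
  fb <- params$beta * params$gamma * params$gamma_prime
  Z <- if (params$mu_prime > 0)
    fb / (params$mu * params$mu_prime * params$alpha) else Inf
  sigma <- if (!is.na(params$K) && !is.na(params$W) && fb > 0)
    params$alpha * params$mu * params$mu_prime * params$K * params$W / fb
  else NA_real_
  out <- list(Z = Z, sigma = sigma)
  if (!is.null(H_tox)) {
    out$H_tox <- H_tox
    out$I_abs <- if (params$mu_prime > 0) iAbs(params, H_tox) else NA_real_
    out$delta_max <- H_tox * fb / (params$alpha * params$mu)
  }
  out
}

#' Steady state of the saturating and nonlinear variants
#'
#' Methods:
#' * `"exact"`: bracketed root of the full balance (any variant; for the
#'   nonlinear variant this is the admissible root of the underlying cubic
#'   on `[0, I + epsilon/alpha]`).
#' * `"saturating"`: closed form for the transcription-saturating variant
#'   (f = 1, g = H/(H+K)); with `epsilon = 0` this is
#'   `H_eq = (-(Z + K - I) + sqrt((Z + K - I)^2 + 4 I K)) / 2`.
#' * `"low_dose"`: leading-order behaviour well below the saturation
#'   scales. Transcription-saturating: `H_eq ~ I K / Z`. Nonlinear:
#'   `H_eq = (-sigma + sqrt(sigma^2 + 4 sigma (I + epsilon/alpha))) / 2`,
#'   with `A_eq = gamma gamma' H_eq / (mu mu' K)`.
#' * `"high_dose"`: saturated-feedback asymptote of the
#'   transcription-saturating variant, `H_eq ~ I - Z`,
#'   `A_eq ~ gamma gamma' / (mu mu')`.
#'
#' The low-dose approximations are flagged invalid when the computed
#' `H_eq` exceeds a tenth of the relevant saturation constant.
#'
#' @param params a [feedbackParams()] with a saturating variant.
#' @param I external concentration (mM), vectorised.
#' @param method see above.
#' @return A data frame with columns `I`, `H_eq`, `A_eq`, `valid`.
#' @examples
#' steadyStateNonlinear(nonlinearParams(), 0, method = "low_dose")
#' @export
steadyStateNonlinear <- function(params, I,
                                 method = c("exact", "saturating",
                                            "low_dose", "high_dose")) {
  stopifnot(inherits(params, "feedback_params"))
  method <- match.arg(method)
  if (any(I < 0)) stop("I must be >= 0")
  v <- params$variant
  if (!v %in% c("transcription_saturating", "nonlinear"))
    stop("use steadyStateLinear() for the linear-family variants")
  if (method %in% c("saturating", "high_dose") && v != "transcription_saturating")
    stop("method '", method,
         "' applies to the transcription_saturating variant")
  mu <- params$mu; mup <- params$mu_prime; al <- params$alpha
  ga <- params$gamma; gp <- params$gamma_prime; K <- params$K
  amp <- ga * gp / (mu * mup)      # A_eq at full transcription drive
  Z <- derivedConstants(params)$Z
  valid <- TRUE
  if (method == "exact") {
    H <- .steadyH(params, I)
    A <- amp * H / (H + K)
  } else if (method == "saturating") {
    a <- params$epsilon / al + I   # reduces to I when epsilon = 0
    H <- ((a - K - Z) + sqrt((a - K - Z)^2 + 4 * a * K)) / 2
    A <- amp * H / (H + K)
  } else if (method == "high_dose") {
    H <- I - Z
    A <- rep(amp, length(I))
  } else if (v == "transcription_saturating") {  # low_dose, saturating g only
    H <- I * K / Z
    A <- I * al / params$beta * (1 - K / Z)
    valid <- H <= K / 10
  } else {                                        # low_dose, full nonlinear
    sigma <- derivedConstants(params)$sigma
    drive <- I + params$epsilon / al
    H <- (-sigma + sqrt(sigma^2 + 4 * sigma * drive)) / 2
    A <- amp * H / K
    valid <- H <= pmin(K, params$W) / 10
  }
  data.frame(I = I, H_eq = H, A_eq = A, valid = valid)
}

# Vectorised equilibrium H for any variant (mu_prime > 0 required).
# Nonlinear case: damped Newton on the monotone-decreasing scalar balance,
# initialised from the low-dose closed form, iterates confined to
# [0, I + eps/alpha].
.steadyH <- function(params, I) {
  eps <- params$epsilon; al <- params$alpha
  mu <- params$mu; mup <- params$mu_prime
  if (mup == 0) stop("no finite steady state with mu_prime = 0")
  cc <- params$beta * params$gamma * params$gamma_prime / (mu * mup)
  a <- eps + al * I
  switch(params$variant,
    linear = ,
    integral = a / (al + cc),
    transcription_saturating = {
      K <- params$K
      ((a - al * K - cc) + sqrt((a - al * K - cc)^2 + 4 * al * a * K)) /
        (2 * al)
    },
    nonlinear = {
      K <- params$K; W <- params$W
      sigma <- al * mu * mup * K * W / (params$beta * params$gamma *
                                          params$gamma_prime)
      H <- pmax((-sigma + sqrt(sigma^2 + 4 * sigma * a / al)) / 2, 1e-300)
      hi <- a / al
      for (iter in 1:100) {
        den <- (H + K) * (H + W)
        r <- a - al * H - cc * H * H / den
        dr <- -al - cc * H * (H * (K + W) + 2 * K * W) / den^2
        Hn <- H - r / dr
        bad <- !is.finite(Hn) | Hn < 0 | Hn > hi
        Hn[bad] <- (H[bad] + ifelse(r[bad] > 0, hi[bad], 0)) / 2
        if (max(abs(Hn - H)) < 1e-15 * max(1, max(H))) { H <- Hn; break }
        H <- Hn
      }
      H
    },
    stop("unknown variant"))
}

#' Ramp response of the integral-feedback variant
#'
#' Under a linear input ramp of rate `delta`, integral feedback locks the
#' internal concentration onto a constant plateau proportional to the ramp
#' rate: `H = alpha mu delta / (beta gamma gamma')`, while the antioxidant
#' grows linearly, `A ~ alpha delta t / beta`, fed by the transcript
#' plateau `A_mRNA ~ alpha delta / (beta gamma')`.
#'
#' @param params a [feedbackParams()] with variant `"integral"`.
#' @param delta ramp rate (mM/min).
#' @param t time since ramp start (min), vectorised.
#' @return List with `H_plateau`, `A_mRNA_plateau` and `A` (vector over
#'   `t`).
#' @export
rampResponseIntegral <- function(params, delta, t = numeric(0)) {
  stopifnot(inherits(params, "feedback_params"))
  if (params$variant != "integral")
    stop("ramp plateau applies to the integral variant")
  if (delta < 0) stop("delta must be >= 0")
  be <- params$beta; ga <- params$gamma; gp <- params$gamma_prime
  list(H_plateau = params$alpha * params$mu * delta / (be * ga * gp),
       A_mRNA_plateau = params$alpha * delta / (be * gp),
       A = params$alpha * delta * t / be)
}

#' Maximal tolerable ramp rate of the integral variant
#'
#' The ramp-rate threshold at which the integral-feedback plateau reaches
#' the toxicity threshold:
#' `delta_max = H_tox beta gamma gamma' / (alpha mu)`. Below it the
#' integral variant adapts to arbitrarily high stress levels; above it the
#' internal plateau exceeds `H_tox` regardless of amplitude.
#'
#' @param params a [feedbackParams()] with variant `"integral"`.
#' @param H_tox toxicity threshold (mM).
#' @return Ramp rate (mM/min).
#' @export
deltaMax <- function(params, H_tox) {
  stopifnot(inherits(params, "feedback_params"))
  if (params$variant != "integral")
    stop("delta_max is defined for the integral variant")
  if (H_tox < 0) stop("H_tox must be >= 0")
  H_tox * params$beta * params$gamma * params$gamma_prime /
    (params$alpha * params$mu)
}

#' Late-time ramp response of the linear variant
#'
#' With antioxidant dilution (`mu_prime > 0`) the internal concentration
#' under a ramp grows linearly once transients decay:
#' `H ~ mu mu' alpha delta t / (alpha mu mu' + beta gamma gamma')`. The
#' growth rate equals the equilibrium sensitivity `dH_eq/dI` times `delta`,
#' i.e. the system tracks its quasi-static equilibrium.
#'
#' @param params a [feedbackParams()] with variant `"linear"`,
#'   `mu_prime > 0`.
#' @param delta ramp rate (mM/min).
#' @param t time since ramp start (min), vectorised.
#' @return Internal concentration H (mM), same length as `t`.
#' @export
rampResponseLinear <- function(params, delta, t) {
  stopifnot(inherits(params, "feedback_params"))
  if (params$variant != "linear" || params$mu_prime <= 0)
    stop("late-time ramp growth applies to the linear variant with ",
         "mu_prime > 0")
  if (delta < 0) stop("delta must be >= 0")
  mm <- params$mu * params$mu_prime
  mm * params$alpha * delta * t /
    (params$alpha * mm + params$beta * params$gamma * params$gamma_prime)
}

#' Absolute adaptation concentration
#'
#' The external level beyond which no adaptation is possible even under
#' arbitrarily slow ramping:
#' `I_abs = H_tox (1 + beta gamma gamma' / (alpha mu mu'))`. Undefined for
#' integral feedback (`mu_prime = 0`), which adapts without amplitude limit
#' for sub-threshold ramp rates.
#'
#' @param params a [feedbackParams()] object with `mu_prime > 0`.
#' @param H_tox toxicity threshold (mM).
#' @return Concentration (mM).
#' @examples
#' iAbs(linearParams("slow"), H_tox = 0.59)  # about 8 mM
#' @export
iAbs <- function(params, H_tox) {
  stopifnot(inherits(params, "feedback_params"))
  if (params$mu_prime <= 0)
    stop("I_abs is undefined for integral feedback (mu_prime = 0): ",
         "adaptation is unlimited below delta_max")
  if (H_tox < 0) stop("H_tox must be >= 0")
  H_tox * (1 + params$beta * params$gamma * params$gamma_prime /
             (params$alpha * params$mu * params$mu_prime))
}

#' Slow-ramp asymptote of the adaptation boundary
#'
#' For slow ramps the boundary between adaptation and arrest in the
#' (amplitude, rate) plane approaches the line
#' `delta = mu' (I_abs - I)`, clipped at zero beyond `I_abs`.
#'
#' @param params a [feedbackParams()] with `mu_prime > 0`.
#' @param H_tox toxicity threshold (mM).
#' @param I amplitudes (mM), vectorised.
#' @return Boundary ramp rates (mM/min).
#' @export
isoToleranceAsymptote <- function(params, H_tox, I) {
  pmax(0, params$mu_prime * (iAbs(params, H_tox) - I))
}
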