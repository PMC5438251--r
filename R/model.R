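#' Sensitivity functions of the feedback variants
#'
#' Evaluates the scavenging sensitivity `f(H)` and the transcription drive
#' `g(H)` for a model variant. Integral and linear variants use f = 1,
#' g = H; the transcription-saturating variant uses f = 1, g = H/(H+K); the
#' nonlinear variant uses f = H/(H+W), g = H/(H+K). For the saturating
#' forms g is bounded in \[0, 1\] and f in \[0, 1).
#'
#' @param variant variant name (see [feedbackParams()]).
#' @param H internal H2O2 concentration (mM), vectorised.
#' @param K transcription half-saturation (mM), needed by saturating
#'   variants.
#' @param W scavenging half-saturation (mM), needed by the nonlinear
#'   variant.
#' @return A list with numeric components `f` and `g`, each the length of
#'   `H`.
#' @examples
#' feedbackFunctions("linear", 0.3)
#' feedbackFunctions("nonlinear", 0.01, K = 0.01, W = 0.01) # (0.5, 0.5)
#' @export
feedbackFunctions <- function(variant, H, K = NA_real_, W = NA_real_) {
  if (any(H < 0)) stop("H must be >= 0")
  saturating_g <- variant %in% c("transcription_saturating", "nonlinear")
  if (saturating_g && (!is.finite(K) || K <= 0))
    stop("variant '", variant, "' requires K > 0")
  if (variant == "nonlinear" && (!is.finite(W) || W <= 0))
    stop("variant 'nonlinear' requires W > 0")
  f <- if (variant == "nonlinear") H / (H + W) else rep(1, length(H))
  g <- if (saturating_g) H / (H + K) else H
  # H = Inf probes the saturation limit of the hyperbolic forms
  f[is.nan(f)] <- 1
  g[is.nan(g)] <- 1
  list(f = f, g = g)
}

#' Right-hand side of the homeostasis ODE system
#'
#' Time derivatives of the state (H, A_mRNA, A) under an instantaneous
#' external concentration `input_level`:
#' dH/dt = epsilon + alpha (I - H) - beta A f(H),
#' dA_mRNA/dt = gamma g(H) - mu A_mRNA,
#' dA/dt = gamma' A_mRNA - mu' A.
#'
#' @param state numeric vector `c(H, A_mRNA, A)` (named or positional).
#' @param t time (min); the autonomous system ignores it, kept for solver
#'   compatibility.
#' @param params a [feedbackParams()] object.
#' @param input_level external H2O2 concentration I (mM).
#' @return Numeric vector of derivatives `c(dH, dA_mRNA, dA)`.
#' @examples
#' p <- linearParams("slow")
#' modelDerivatives(c(0, 0, 0), 0, p, input_level = 0)
#' @export
modelDerivatives <- function(state, t = 0, params, input_level) {
  stopifnot(inherits(params, "feedback_params"), length(state) == 3)
  if (input_level < 0) stop("input_level must be >= 0")
  if (any(state < 0)) stop("state components must be >= 0")
  H <- state[[1]]; Am <- state[[2]]; A <- state[[3]]
  fg <- feedbackFunctions(params$variant, H, params$K, params$W)
  c(params$epsilon + params$alpha * (input_level - H) - params$beta * A * fg$f,
    params$gamma * fg$g - params$mu * Am,
    params$gamma_prime * Am - params$mu_prime * A)
}

# Unchecked RHS in deSolve calling convention; I(t) supplied as a function.
.rhs_desolve <- function(params) {
  eps <- params$epsilon; al <- params$alpha; be <- params$beta
  ga <- params$gamma; gp <- params$gamma_prime
  mu <- params$mu; mup <- params$mu_prime
  K <- params$K; W <- params$W
  variant <- params$variant
  sat_g <- variant %in% c("transcription_saturating", "nonlinear")
  sat_f <- variant == "nonlinear"
  function(t, y, parms, input_fun) {
    H <- y[1]
    f <- if (sat_f) H / (H + W) else 1
    g <- if (sat_g) H / (H + K) else H
    list(c(eps + al * (input_fun(t) - H) - be * y[3] * f,
           ga * g - mu * y[2],
           gp * y[2] - mup * y[3]))
  }
}
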