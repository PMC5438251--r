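#' Kinetic parameters of the H2O2 homeostasis feedback model
#'
#' Bundles the kinetic constants of the three-variable feedback model
#' (internal H2O2 `H`, antioxidant transcript `A_mRNA`, antioxidant protein
#' `A`) together with a variant selector. The four variants differ only in
#' the two sensitivity functions `f` (scavenging) and `g` (transcription
#' drive), see [feedbackFunctions()]:
#'
#' * `"integral"`: f = 1, g = H, with `mu_prime = 0` and `epsilon = 0`
#'   (perfectly adapting limit; any other value of these two leaves the
#'   system without a stable steady state).
#' * `"linear"`: f = 1, g = H.
#' * `"transcription_saturating"`: f = 1, g = H/(H+K).
#' * `"nonlinear"`: f = H/(H+W), g = H/(H+K).
#'
#' Note on units: `beta`, `gamma` and `gamma_prime` are expressed per-minute
#' in the linear-family variants but per-millimolar-per-minute in the
#' nonlinear variant; the two published calibrations are not dimensionally
#' reconcilable, so parameter values are taken verbatim per variant and the
#' transcript and protein variables are treated as being on an arbitrary
#' model concentration scale.
#'
#' @param variant one of `"integral"`, `"linear"`,
#'   `"transcription_saturating"`, `"nonlinear"`.
#' @param epsilon basal internal H2O2 production rate (mM/min).
#' @param alpha membrane transport rate constant (1/min).
#' @param beta scavenging rate constant.
#' @param gamma antioxidant transcription rate constant.
#' @param gamma_prime antioxidant translation rate constant.
#' @param mu transcript decay rate (1/min).
#' @param mu_prime antioxidant protein dilution rate (1/min); 0 selects the
#'   integral-feedback limit.
#' @param K transcription half-saturation concentration (mM); required by the
#'   saturating variants.
#' @param W scavenging half-saturation concentration (mM); required by the
#'   nonlinear variant.
#' @return An object of class `feedback_params` (a named list).
#' @seealso [linearParams()], [integralParams()], [nonlinearParams()],
#'   [saturatingParams()] for the calibrated default sets.
#' @examples
#' p <- feedbackParams("linear", alpha = 1, beta = 5, gamma = 0.03,
#'                     gamma_prime = 0.01, mu = log(2) / 40,
#'                     mu_prime = log(2) / 100)
#' p
#' @export
feedbackParams <- function(variant = c("linear", "integral",
                                       "transcription_saturating",
                                       "nonlinear"),
                           epsilon = 0, alpha = 1, beta = 5,
                           gamma = 0.03, gamma_prime = 0.01,
                           mu = log(2) / 40, mu_prime = log(2) / 100,
                           K = NA_real_, W = NA_real_) {
  variant <- match.arg(variant)
  rates <- c(epsilon = epsilon, alpha = alpha, beta = beta, gamma = gamma,
             gamma_prime = gamma_prime, mu = mu, mu_prime = mu_prime)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (variant %in% c("transcription_saturating", "nonlinear")) {
    if (!is.finite(K) || K <= 0)
      stop("variant '", variant, "' requires K > 0")
  }
  if (variant == "nonlinear") {
    if (!is.finite(W) || W <= 0)
      stop("variant 'nonlinear' requires W > 0")
  }
  if (variant == "integral" && (mu_prime != 0 || epsilon != 0))
    stop("the integral variant requires mu_prime = 0 and epsilon = 0 ",
         "(otherwise there is no stable steady state)")
  structure(list(variant = variant, epsilon = epsilon, alpha = alpha,
                 beta = beta, gamma = gamma, gamma_prime = gamma_prime,
                 mu = mu, mu_prime = mu_prime, K = K, W = W),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat("<feedback_params> variant:", x$variant, "\n")
  vals <- unlist(x[c("epsilon", "alpha", "beta", "gamma", "gamma_prime",
                     "mu", "mu_prime", "K", "W")])
  vals <- vals[!is.na(vals)]
  cat(paste0("  ", format(names(vals), width = 12), signif(vals, 6),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Calibrated linear-model parameter set
#'
#' The published calibration of the linear feedback variant. Two transcript
#' kinetics are available: the `"slow"` pairing (gamma = 0.03/min with an
#' mRNA half-life of 40 min, matching measured peroxiredoxin transcript
#' stability) and the `"fast"` pairing (gamma = 0.53/min with a 2.5 min
#' half-life). Both pairings keep the absolute adaptation concentration
#' fixed. Common constants: epsilon = 0, alpha = 1/min, beta = 5/min,
#' gamma_prime = 0.01/min, mu_prime = log(2)/100 /min.
#'
#' @param mrna `"slow"` (mRNA half-life 40 min) or `"fast"` (2.5 min).
#' @param epsilon basal production rate (mM/min); 0 by default for all
#'   linear-family computations.
#' @return A `feedback_params` object with `variant = "linear"`.
#' @export
linearParams <- function(mrna = c("slow", "fast"), epsilon = 0) {
  mrna <- match.arg(mrna)
  if (mrna == "slow")
    feedbackParams("linear", epsilon = epsilon, alpha = 1, beta = 5,
                   gamma = 0.03, gamma_prime = 0.01,
                   mu = log(2) / 40, mu_prime = log(2) / 100)
  else
    feedbackParams("linear", epsilon = epsilon, alpha = 1, beta = 5,
                   gamma = 0.53, gamma_prime = 0.01,
                   mu = log(2) / 2.5, mu_prime = log(2) / 100)
}

#' Integral-feedback parameter set
#'
#' The linear calibration restricted to the perfectly adapting limit
#' (mu_prime = 0, epsilon = 0), in which antioxidant production integrates
#' the internal H2O2 signal and the steady-state internal concentration is
#' exactly zero for any sustained input.
#'
#' @inheritParams linearParams
#' @return A `feedback_params` object with `variant = "integral"`.
#' @export
integralParams <- function(mrna = c("slow", "fast")) {
  p <- linearParams(match.arg(mrna))
  feedbackParams("integral", epsilon = 0, alpha = p$alpha, beta = p$beta,
                 gamma = p$gamma, gamma_prime = p$gamma_prime, mu = p$mu,
                 mu_prime = 0)
}

#' Calibrated nonlinear-model parameter set
#'
#' The published calibration of the fully nonlinear variant (saturating
#' transcription drive and H-limited scavenging): epsilon = 0.06 mM/min,
#' alpha = 1/min, beta = 10 /mM/min, gamma = 0.1 /mM/min, mu = log(2)/40
#' /min, gamma_prime = 0.005 /mM/min, mu_prime = log(2)/100 /min,
#' K = W = 0.01 mM.
#'
#' @return A `feedback_params` object with `variant = "nonlinear"`.
#' @export
nonlinearParams <- function() {
  feedbackParams("nonlinear", epsilon = 0.06, alpha = 1, beta = 10,
                 gamma = 0.1, gamma_prime = 0.005, mu = log(2) / 40,
                 mu_prime = log(2) / 100, K = 0.01, W = 0.01)
}

#' Transcription-saturating parameter set
#'
#' Intermediate variant with saturating transcription drive g = H/(H+K) but
#' non-saturating scavenging (f = 1). Defaults reuse the nonlinear-model
#' rate constants without W; epsilon defaults to 0 so the closed-form steady
#' state applies exactly.
#'
#' @param epsilon basal production rate (mM/min).
#' @param K transcription half-saturation concentration (mM).
#' @return A `feedback_params` object with
#'   `variant = "transcription_saturating"`.
#' @export
saturatingParams <- function(epsilon = 0, K = 0.01) {
  feedbackParams("transcription_saturating", epsilon = epsilon, alpha = 1,
                 beta = 10, gamma = 0.1, gamma_prime = 0.005,
                 mu = log(2) / 40, mu_prime = log(2) / 100, K = K)
}

#' Read or write a parameter set as a flat key-value config file
#'
#' The format is a flat TOML-style dialect, one `key = value` pair per line
#' (`#` starts a comment); keys are `variant`, `epsilon`, `alpha`, `beta`,
#' `gamma`, `gamma_prime`, `mu`, `mu_prime`, `K`, `W`. `variant` is a bare
#' or quoted string, all other values are numbers.
#'
#' @param path file path.
#' @param params a `feedback_params` object (for writing).
#' @return `readParams()` returns a `feedback_params` object;
#'   `writeParams()` returns `path` invisibly.
#' @export
readParams <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  named <- stats::setNames(as.list(vals), keys)
  variant <- gsub("\"|'", "", named$variant %||% "linear")
  num <- function(key, default) {
    if (is.null(named[[key]])) default else as.numeric(named[[key]])
  }
  feedbackParams(variant,
                 epsilon = num("epsilon", 0), alpha = num("alpha", 1),
                 beta = num("beta", 5), gamma = num("gamma", 0.03),
                 gamma_prime = num("gamma_prime", 0.01),
                 mu = num("mu", log(2) / 40),
                 mu_prime = num("mu_prime", log(2) / 100),
                 K = num("K", NA_real_), W = num("W", NA_real_))
}

#' @rdname readParams
#' @export
writeParams <- function(params, path) {
  stopifnot(inherits(params, "feedback_params"))
  nums <- c("epsilon", "alpha", "beta", "gamma", "gamma_prime", "mu",
            "mu_prime", "K", "W")
  lines <- sprintf("variant = \"%s\"", params$variant)
  for (key in nums) {
    v <- params[[key]]
    if (!is.na(v))
      lines <- c(lines, sprintf("%s = %.17g", key, v))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
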