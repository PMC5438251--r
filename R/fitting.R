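#' Steady-state dose-response dataset
#'
#' Holds observed or synthetic steady-state readouts as a function of
#' external H2O2 dose. Two readout kinds are supported: `"H_proxy"` (a
#' nuclear-localization-like reporter proportional to internal H2O2) and
#' `"A_proxy"` (an antioxidant-expression-like reporter proportional to the
#' antioxidant level).
#'
#' @param dose doses (mM), distinct and `>= 0`.
#' @param mean readout means (arbitrary units).
#' @param sem readout uncertainties, same units, `> 0`; when omitted, unit
#'   weights are used with a warning.
#' @param kind `"A_proxy"` or `"H_proxy"`.
#' @return An object of class `dose_response` (a data frame with a `kind`
#'   attribute).
#' @export
doseResponseDataset <- function(dose, mean, sem = NULL,
                                kind = c("A_proxy", "H_proxy")) {
  kind <- match.arg(kind)
  if (anyDuplicated(dose) || any(dose < 0))
    stop("doses must be distinct and >= 0")
  if (length(mean) != length(dose)) stop("dose/mean length mismatch")
  if (is.null(sem)) {
    warning("no uncertainties supplied; using unit weights")
    sem <- rep(1, length(dose))
  }
  if (any(sem <= 0)) stop("sem must be > 0")
  structure(data.frame(dose = dose, mean = mean, sem = sem),
            kind = kind, class = c("dose_response", "data.frame"))
}

#' Read a dose-response table from delimited text
#'
#' Expects columns `dose_mM`, `mean` and (optionally) `sem`.
#'
#' @param path file path.
#' @param kind readout kind, see [doseResponseDataset()].
#' @param sep field separator.
#' @return A `dose_response` object.
#' @export
readDoseResponse <- function(path, kind = c("A_proxy", "H_proxy"),
                             sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  doseResponseDataset(df$dose_mM, df$mean, df$sem, kind = match.arg(kind))
}

#' Observable map from model units to readout units
#'
#' Experimental readouts are proportional to the model variables up to an
#' arbitrary-unit scale; the offset defaults to 0 because readouts are
#' reported as increase over the pre-stress level.
#'
#' @param scale readout units per model unit, `> 0`.
#' @param offset readout units.
#' @return An object of class `observable_map`.
#' @export
observableMap <- function(scale = 1, offset = 0) {
  if (scale <= 0) stop("scale must be > 0")
  structure(list(scale = scale, offset = offset), class = "observable_map")
}

#' Predicted steady-state readout
#'
#' Maps the model's steady state at dose `I` through an observable map:
#' `H_proxy` readouts are `scale * H_eq + offset`, `A_proxy` readouts are
#' `scale * A_eq + offset`, using the exact steady state of the parameter
#' set's variant.
#'
#' @param params a [feedbackParams()] object.
#' @param map an [observableMap()].
#' @param I doses (mM), vectorised.
#' @param kind `"A_proxy"` or `"H_proxy"`.
#' @return Readout values, same length as `I`.
#' @export
predictReadout <- function(params, map = observableMap(), I,
                           kind = c("A_proxy", "H_proxy")) {
  kind <- match.arg(kind)
  ss <- .steadyCurve(params, I)
  map$scale * (if (kind == "H_proxy") ss$H else ss$A) + map$offset
}

# vectorised (H_eq, A_eq) for any variant with mu_prime > 0
.steadyCurve <- function(params, I) {
  if (params$variant %in% c("linear", "integral")) {
    ss <- steadyStateLinear(params, I)
    list(H = ss$H_eq, A = ss$A_eq)
  } else {
    H <- .steadyH(params, I)
    list(H = H, A = params$gamma * params$gamma_prime /
           (params$mu * params$mu_prime) * H / (H + params$K))
  }
}

#' Fit a dose-response dataset by weighted chi-square minimization
#'
#' Minimizes `sum(((y - prediction) / sem)^2)` over a chosen subset of free
#' parameters. Positive parameters (`epsilon`, `K`, `W`, `s`) are optimized
#' on a log scale; `offset` (if freed) on the natural scale. Optimization
#' is multistarted from a grid of log-spaced initial points (at least 8)
#' around the supplied values and the best converged start is returned.
#'
#' @param data a [doseResponseDataset()].
#' @param params fixed parameter set supplying the variant and every
#'   non-free constant (also the starting point of free kinetic
#'   parameters).
#' @param free character vector, subset of
#'   `c("epsilon", "K", "W", "s", "offset")`.
#' @param map starting observable map.
#' @param n_starts number of multistart points (>= 8 recommended).
#' @param span multiplicative half-width of the start grid (each free
#'   positive parameter is started between value/span and value*span).
#' @return List with `estimates` (named vector over `free`), `chi2`,
#'   `params` (the fitted parameter object), `map` (fitted map),
#'   `residuals`, `starts` (per-start chi2 diagnostics), and `n_free`.
#' @examples
#' p <- nonlinearParams()
#' d <- generateDoseResponse(p, doses = c(0, 0.01, 0.025, 0.05, 0.1, 0.2,
#'                                        0.4), noise_cv = 0, seed = 1)
#' fitDoseResponse(d, p, free = c("epsilon", "K"))$chi2  # ~0
#' @export
fitDoseResponse <- function(data, params, free = c("epsilon", "K", "s"),
                            map = observableMap(), n_starts = 9,
                            span = 10) {
  stopifnot(inherits(data, "dose_response"),
            inherits(params, "feedback_params"))
  bad <- setdiff(free, c("epsilon", "K", "W", "s", "offset"))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  if (length(free) == 0) stop("no free parameters")
  if (nrow(data) < length(free) + 2)
    stop("need at least as many doses as free parameters plus 2")
  if (stats::sd(data$mean) == 0) stop("degenerate data: zero variance")
  kind <- attr(data, "kind")
  y <- data$mean; sem <- data$sem; doses <- data$dose

  pos <- setdiff(free, "offset")
  start0 <- c(epsilon = if (params$epsilon > 0) params$epsilon else 1e-2,
              K = if (!is.na(params$K)) params$K else 1e-2,
              W = if (!is.na(params$W)) params$W else 1e-2,
              s = map$scale)[pos]
  build <- function(theta) {
    v <- exp(theta[pos])
    p <- params
    for (nm in intersect(pos, c("epsilon", "K", "W"))) p[[nm]] <- v[[nm]]
    m <- observableMap(scale = if ("s" %in% pos) v[["s"]] else map$scale,
                       offset = if ("offset" %in% free)
                         theta[["offset"]] else map$offset)
    list(p = p, m = m)
  }
  chi2 <- function(theta) {
    pm <- build(theta)
    pred <- tryCatch(predictReadout(pm$p, pm$m, doses, kind),
                     error = function(e) rep(NA_real_, length(doses)))
    if (anyNA(pred)) return(1e12)
    sum(((y - pred) / sem)^2)
  }

  # log-spaced multistart grid around the supplied values
  n_starts <- max(n_starts, 8L)
  set <- lapply(seq_len(n_starts), function(k) {
    frac <- (k - 1) / max(n_starts - 1, 1)
    th <- log(start0) + log(span) * (2 * frac - 1) *
      rep_len(c(1, -1, 0.5), length(pos))
    names(th) <- pos
    if ("offset" %in% free) th <- c(th, offset = map$offset)
    th
  })
  fits <- lapply(set, function(th) {
    r <- stats::optim(th, chi2, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-14))
    stats::optim(r$par, chi2, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
  })
  vals <- vapply(fits, `[[`, 0, "value")
  if (all(vals >= 1e12)) stop("no start converged; chi2 trace: ",
                              paste(signif(vals, 3), collapse = ", "))
  best <- fits[[which.min(vals)]]
  pm <- build(best$par)
  est <- c(exp(best$par[pos]),
           if ("offset" %in% free) c(offset = best$par[["offset"]]))
  pred <- predictReadout(pm$p, pm$m, doses, kind)
  list(estimates = est, chi2 = best$value, params = pm$p, map = pm$m,
       residuals = (y - pred) / sem, starts = vals, n_free = length(free))
}

#' Profile chi-square of one parameter (diagnostic)
#'
#' Re-fits the remaining free parameters over a grid of fixed values of one
#' parameter, returning the chi-square profile. No confidence intervals are
#' derived from it.
#'
#' @inheritParams fitDoseResponse
#' @param profile name of the parameter to profile (must be in `free`).
#' @param values grid of values to profile over.
#' @return Data frame with columns `value` and `chi2`.
#' @export
profileChi2 <- function(data, params, free, profile, values,
                        map = observableMap()) {
  if (!profile %in% free) stop("'", profile, "' is not free")
  rest <- setdiff(free, profile)
  vapply(values, function(v) {
    p <- params; m <- map
    if (profile == "s") m <- observableMap(v, map$offset)
    else if (profile == "offset") m <- observableMap(map$scale, v)
    else p[[profile]] <- v
    if (length(rest))
      fitDoseResponse(data, p, free = rest, map = m)$chi2
    else {
      pred <- predictReadout(p, m, data$dose, attr(data, "kind"))
      sum(((data$mean - pred) / data$sem)^2)
    }
  }, 0) -> chi2
  data.frame(value = values, chi2 = chi2)
}
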