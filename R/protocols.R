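#' Piecewise temporal stress protocols I(t)
#'
#' A stress protocol is an ordered set of non-overlapping segments, each one
#' constant, a linear ramp, or a mixing-tank ramp, defining the external
#' H2O2 concentration I(t) (mM) over a finite horizon (min). Discontinuities
#' (steps) are allowed only at segment boundaries.
#'
#' @param segments a data frame with columns `t_start` (min), `kind`
#'   (`"constant"`, `"linear_ramp"` or `"tank_ramp"`), `level` (mM, value at
#'   the segment start) and `rate` (mM/min, linear ramps only).
#' @param horizon total duration (min).
#' @param tank a [tankConfig()] object for `tank_ramp` segments.
#' @param tank_mode evaluation mode for tank segments, see
#'   [tankConcentration()].
#' @return An object of class `stress_protocol`.
#' @seealso [constantProtocol()], [stepProtocol()], [rampProtocol()],
#'   [makePretreatmentProtocol()], [inputConcentration()]
#' @export
stressProtocol <- function(segments, horizon, tank = NULL,
                           tank_mode = "exact") {
  stopifnot(is.data.frame(segments),
            all(c("t_start", "kind", "level", "rate") %in% names(segments)))
  if (nrow(segments) == 0) stop("protocol needs at least one segment")
  if (is.unsorted(segments$t_start, strictly = TRUE))
    stop("segments must be strictly time-ordered")
  if (segments$t_start[1] > 0)
    stop("first segment must start at t = 0")
  if (!all(segments$kind %in% c("constant", "linear_ramp", "tank_ramp")))
    stop("unknown segment kind")
  if (any(segments$level < 0)) stop("I(t) must be >= 0")
  if (any(segments$kind == "linear_ramp" & !is.finite(segments$rate)))
    stop("linear_ramp segments need a finite rate")
  if (any(segments$kind == "tank_ramp") && is.null(tank))
    stop("tank_ramp segments need a tank config")
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  structure(list(segments = segments, horizon = horizon, tank = tank,
                 tank_mode = tank_mode),
            class = "stress_protocol")
}

#' @export
print.stress_protocol <- function(x, ...) {
  cat("<stress_protocol>", nrow(x$segments), "segment(s), horizon",
      x$horizon, "min\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Constant, step, and ramp-then-hold protocol constructors
#'
#' `constantProtocol()` holds a fixed level. `stepProtocol()` holds
#' `baseline` until `t_on`, then steps to `amplitude` (the step is an exact
#' discontinuity). `rampProtocol()` increases linearly at rate `rate` from 0
#' starting at `t_on` until `amplitude` is reached, then holds; `rate = Inf`
#' gives the step limit as a true discontinuity rather than a steep ramp.
#'
#' @param level,amplitude,baseline concentrations (mM).
#' @param rate ramp rate (mM/min), possibly `Inf`.
#' @param t_on onset time (min).
#' @param horizon protocol duration (min).
#' @return A `stress_protocol`.
#' @examples
#' stepProtocol(0.4, t_on = 300, horizon = 1000)
#' rampProtocol(1.1e-3, amplitude = 1.1, t_on = 100, horizon = 1500)
#' @export
constantProtocol <- function(level, horizon) {
  stressProtocol(data.frame(t_start = 0, kind = "constant", level = level,
                            rate = 0), horizon)
}

#' @rdname constantProtocol
#' @export
stepProtocol <- function(amplitude, t_on = 0, baseline = 0, horizon) {
  if (t_on <= 0)
    return(constantProtocol(amplitude, horizon))
  seg <- data.frame(t_start = c(0, t_on), kind = "constant",
                    level = c(baseline, amplitude), rate = 0)
  stressProtocol(seg, horizon)
}

#' @rdname constantProtocol
#' @export
rampProtocol <- function(rate, amplitude, t_on = 0, horizon = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  if (is.infinite(rate))
    return(stepProtocol(amplitude, t_on = t_on,
                        horizon = horizon %||% (t_on + 1000)))
  t_top <- t_on + amplitude / rate
  horizon <- horizon %||% (t_top + 1000)
  seg <- if (t_on > 0)
    data.frame(t_start = c(0, t_on, t_top), kind = c("constant",
               "linear_ramp", "constant"), level = c(0, 0, amplitude),
               rate = c(0, rate, 0))
  else
    data.frame(t_start = c(0, t_top), kind = c("linear_ramp", "constant"),
               level = c(0, amplitude), rate = c(rate, 0))
  if (t_top >= horizon)
    seg <- seg[seg$t_start < horizon, ]
  stressProtocol(seg, horizon)
}

#' Pretreatment/challenge protocols
#'
#' Builds the two-phase stress patterns used in acquired-tolerance assays.
#' In sustained mode (`pre_duration = Inf`) the input holds the
#' pretreatment level `I0` from `t_pre` until `t_challenge`, then steps to
#' `I0 + delta_I`. In pulse mode (finite `pre_duration`) the input is `I0`
#' on `[t_pre, t_pre + pre_duration)`, returns to 0 during the recovery
#' interval, and steps to `delta_I` at `t_challenge`.
#'
#' @param I0 pretreatment level (mM).
#' @param t_pre pretreatment onset (min).
#' @param pre_duration pretreatment duration (min); `Inf` for sustained
#'   pretreatment.
#' @param delta_I challenge step magnitude (mM).
#' @param t_challenge challenge onset (min); must exceed `t_pre` (and the
#'   pulse end in pulse mode).
#' @param horizon protocol duration (min).
#' @return A `stress_protocol`.
#' @examples
#' # 0.2 mM sustained pretreatment, 0.8 mM extra challenge at t = 400 min
#' makePretreatmentProtocol(0.2, delta_I = 0.8, t_challenge = 400,
#'                          horizon = 1200)
#' @export
makePretreatmentProtocol <- function(I0, t_pre = 0, pre_duration = Inf,
                                     delta_I, t_challenge, horizon = NULL) {
  if (I0 < 0 || delta_I < 0) stop("levels must be >= 0")
  if (t_pre < 0 || pre_duration <= 0) stop("negative duration")
  if (t_challenge <= t_pre) stop("t_challenge must exceed t_pre")
  horizon <- horizon %||% (t_challenge + 1000)
  if (is.infinite(pre_duration)) {
    starts <- c(0, t_pre, t_challenge)
    levels <- c(0, I0, I0 + delta_I)
  } else {
    t_off <- t_pre + pre_duration
    if (t_challenge < t_off)
      stop("challenge must come after the pretreatment pulse")
    starts <- c(0, t_pre, t_off, t_challenge)
    levels <- c(0, I0, 0, delta_I)
  }
  # coincident starts (e.g. t_pre = 0) resolve to the later phase's level
  keep <- !duplicated(starts, fromLast = TRUE)
  seg <- data.frame(t_start = starts[keep], kind = "constant",
                    level = levels[keep], rate = 0)
  stressProtocol(seg, horizon)
}

#' Evaluate a protocol at given times
#'
#' Piecewise evaluation of I(t). At a segment boundary the value of the new
#' segment applies (steps are right-continuous).
#'
#' @param protocol a `stress_protocol`.
#' @param t times (min), vectorised; must lie in `[0, horizon]`.
#' @return Concentrations (mM), same length as `t`.
#' @export
inputConcentration <- function(protocol, t) {
  stopifnot(inherits(protocol, "stress_protocol"))
  if (any(t < 0 | t > protocol$horizon))
    stop("t outside the protocol horizon")
  seg <- protocol$segments
  idx <- findInterval(t, seg$t_start)
  idx[idx < 1L] <- 1L
  out <- numeric(length(t))
  for (i in unique(idx)) {
    sel <- idx == i
    dt <- t[sel] - seg$t_start[i]
    out[sel] <- switch(seg$kind[i],
      constant    = seg$level[i],
      linear_ramp = seg$level[i] + seg$rate[i] * dt,
      tank_ramp   = seg$level[i] +
        tankConcentration(protocol$tank, dt, mode = protocol$tank_mode))
  }
  out
}

#' Segment boundaries of a protocol
#'
#' Times at which the input may be discontinuous or change functional form;
#' numerical integration is restarted at each of these.
#'
#' @param protocol a `stress_protocol`.
#' @return Sorted numeric vector of times (min) including 0 and the horizon.
#' @export
protocolBreakpoints <- function(protocol) {
  sort(unique(c(0, protocol$segments$t_start, protocol$horizon)))
}

#' Mixing-tank configuration for physical H2O2 ramps
#'
#' Describes the ramp-generation hardware: a stock solution of
#' concentration `C0` pumped at rate `mu0` into a stirred medium tank of
#' initial volume `V1_0`, which perfuses the flow chamber at rate `mu1`.
#' When inflow and outflow match, the tank concentration follows the
#' saturating exponential `C0 (1 - exp(-delta t))` with
#' `delta = mu0 / V1_0`; for small `delta t` this is the linear ramp
#' `C0 delta t`. An empirical dimensionless factor (default 0.785) corrects
#' the linearized slope for stressor degradation in the unchilled tank.
#'
#' @param C0 stock concentration (mM).
#' @param V1_0 initial tank volume (L).
#' @param mu0 stock inflow rate (L/min).
#' @param mu1 perfusion outflow rate (L/min).
#' @param correction dimensionless slope correction for `corrected` mode.
#' @return An object of class `tank_config`.
#' @examples
#' cfg <- tankConfig(C0 = 100, V1_0 = 1, mu0 = 30e-6, mu1 = 30e-6)
#' tankSlope(cfg)              # 3e-3 mM/min = 3 uM/min
#' tankSlope(cfg, corrected = TRUE)
#' @export
tankConfig <- function(C0, V1_0, mu0, mu1 = mu0, correction = 0.785) {
  vals <- c(C0, V1_0, mu0, mu1, correction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all tank parameters must be finite and > 0")
  structure(list(C0 = C0, V1_0 = V1_0, mu0 = mu0, mu1 = mu1,
                 correction = correction, delta = mu0 / V1_0),
            class = "tank_config")
}

#' @export
print.tank_config <- function(x, ...) {
  cat(sprintf(paste0("<tank_config> C0 = %g mM, V1_0 = %g L, mu0 = %g L/min,",
                     " mu1 = %g L/min\n  delta = %g /min, nominal slope = %g",
                     " mM/min (corrected %g)\n"),
              x$C0, x$V1_0, x$mu0, x$mu1, x$delta, tankSlope(x),
              tankSlope(x, corrected = TRUE)))
  invisible(x)
}

#' Nominal (linearized) slope of a tank ramp
#'
#' @param cfg a [tankConfig()].
#' @param corrected apply the empirical correction factor.
#' @return Slope in mM/min.
#' @export
tankSlope <- function(cfg, corrected = FALSE) {
  s <- cfg$C0 * cfg$delta
  if (corrected) s * cfg$correction else s
}

#' Tank concentration over time
#'
#' `exact` mode uses the constant-volume closed form
#' `C0 (1 - exp(-delta t))`, valid only when `mu0 == mu1`; with unequal flow
#' rates the mass-balance ODE
#' `dC1/dt = mu0 / (V1_0 + (mu0 - mu1) t) (C0 - C1)` is integrated
#' numerically instead (the closed form is never silently applied).
#' `linearized` returns `C0 delta t`; `corrected` additionally multiplies by
#' the correction factor.
#'
#' @param cfg a [tankConfig()].
#' @param t time since ramp start (min), vectorised, `>= 0`.
#' @param mode `"exact"`, `"linearized"` or `"corrected"`.
#' @return Concentrations (mM).
#' @export
tankConcentration <- function(cfg, t, mode = c("exact", "linearized",
                                               "corrected")) {
  stopifnot(inherits(cfg, "tank_config"))
  mode <- match.arg(mode)
  if (any(t < 0)) stop("t must be >= 0")
  switch(mode,
    linearized = cfg$C0 * cfg$delta * t,
    corrected  = cfg$correction * cfg$C0 * cfg$delta * t,
    exact = {
      if (isTRUE(all.equal(cfg$mu0, cfg$mu1))) {
        cfg$C0 * (1 - exp(-cfg$delta * t))
      } else {
        # volume changes over time; integrate the mass balance
        rhs <- function(tt, y, p)
          list(cfg$mu0 / (cfg$V1_0 + (cfg$mu0 - cfg$mu1) * tt) *
                 (cfg$C0 - y[1]))
        times <- sort(unique(c(0, t)))
        sol <- deSolve::ode(c(C1 = 0), times, rhs, parms = NULL,
                            method = "lsoda", rtol = 1e-10, atol = 1e-12)
        sol[match(t, times), "C1"]
      }
    })
}

#' Tank-ramp protocol
#'
#' Stress protocol that follows the physical tank concentration from
#' `t_on` onwards (zero before).
#'
#' @param cfg a [tankConfig()].
#' @param t_on ramp start (min).
#' @param horizon protocol duration (min).
#' @param mode tank evaluation mode, see [tankConcentration()].
#' @return A `stress_protocol`.
#' @export
tankRampProtocol <- function(cfg, t_on = 0, horizon, mode = "exact") {
  seg <- if (t_on > 0)
    data.frame(t_start = c(0, t_on), kind = c("constant", "tank_ramp"),
               level = 0, rate = 0)
  else
    data.frame(t_start = 0, kind = "tank_ramp", level = 0, rate = 0)
  stressProtocol(seg, horizon, tank = cfg, tank_mode = mode)
}

#' Read or write a protocol as a CSV schedule
#'
#' Columns: `t_start_min`, `kind`, `level_mM`, `rate_mM_per_min`. Tank
#' segments are not representable in this schedule format and are refused.
#'
#' @param protocol a `stress_protocol`.
#' @param path file path.
#' @param horizon horizon (min) used when reading.
#' @return `readProtocol()` returns a `stress_protocol`; `writeProtocol()`
#'   returns `path` invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stress_protocol"))
  if (any(protocol$segments$kind == "tank_ramp"))
    stop("tank segments cannot be serialized to a schedule; ",
         "emit a (time, concentration) table instead")
  seg <- protocol$segments
  utils::write.csv(data.frame(t_start_min = seg$t_start, kind = seg$kind,
                              level_mM = seg$level,
                              rate_mM_per_min = seg$rate),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path, horizon = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seg <- data.frame(t_start = df$t_start_min, kind = df$kind,
                    level = df$level_mM, rate = df$rate_mM_per_min)
  stressProtocol(seg, horizon %||% (max(seg$t_start) + 1000))
}
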