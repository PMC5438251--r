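#' Generate a synthetic steady-state dose-response dataset
#'
#' Emulates population-averaged steady-state reporter measurements: the
#' model prediction at each dose plus Gaussian noise with standard
#' deviation `noise_cv * max(prediction) / sqrt(n_cells_per_dose)` (the
#' standard error of a mean over `n_cells_per_dose` cells whose single-cell
#' scatter is `noise_cv` of the dynamic range). The `sem` column is set to
#' that same standard deviation (unit weights when `noise_cv = 0`). Fully
#' reproducible for a fixed seed.
#'
#' @param params a [feedbackParams()] object.
#' @param map an [observableMap()].
#' @param doses dose grid (mM), non-empty.
#' @param noise_cv noise coefficient, `>= 0`.
#' @param n_cells_per_dose cells averaged per dose.
#' @param seed integer seed (mandatory).
#' @param kind readout kind, see [doseResponseDataset()].
#' @return A [doseResponseDataset()].
#' @export
generateDoseResponse <- function(params, map = observableMap(), doses,
                                 noise_cv = 0.05, n_cells_per_dose = 100,
                                 seed, kind = c("A_proxy", "H_proxy")) {
  kind <- match.arg(kind)
  if (length(doses) == 0) stop("empty dose list")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (missing(seed)) stop("an explicit seed is required")
  pred <- predictReadout(params, map, doses, kind)
  sd <- noise_cv * max(pred) / sqrt(n_cells_per_dose)
  y <- pred
  if (sd > 0) {
    withr_seed <- .with_seed(seed)
    on.exit(withr_seed())
    y <- pred + stats::rnorm(length(doses), 0, sd)
  }
  # noiseless datasets get unit weights: a zero sem would be degenerate
  doseResponseDataset(doses, y, sem = rep(if (sd > 0) sd else 1,
                                          length(doses)),
                      kind = kind)
}

# set the RNG seed, returning a restorer for the previous state
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate synthetic single-cell volume/budding traces
#'
#' Emulates segmented time-lapse volume traces sampled every 3 minutes.
#' Before stress onset every cell cycles through unbudded and budded
#' phases; volume grows linearly in time (growth rate is uncorrelated with
#' volume in these cells, so no exponential scaling is imposed), faster in
#' the budded phase, and drops by the daughter fraction at division. At
#' stress onset each cell draws one of three fates:
#'
#' * `adapted`: pauses growth for `pause_duration` minutes (the order of
#'   the observed adaptation timescale), then resumes normal cycling;
#' * `prolonged_cycle_arrest`: stays budded without dividing but keeps
#'   growing;
#' * `permanent_growth_arrest`: volume frozen (budded state retained).
#'
#' Fate fractions default to all-adapted at dose 0 and to the measured
#' (0.22, 0.36, 0.42) split at 0.5 mM; any other dose requires explicit
#' fractions.
#'
#' @param n_cells number of cells.
#' @param dose step amplitude (mM), used to pick default fate fractions.
#' @param fate_fractions numeric length-3 vector (adapted, prolonged,
#'   permanent), summing to 1; overrides the dose defaults.
#' @param growth_rate_budded budded-phase volume growth rate (fL/min).
#' @param growth_rate_unbudded unbudded-phase rate (fL/min).
#' @param t_stress stress onset (min).
#' @param horizon trace duration (min).
#' @param dt sampling interval (min); 3 by default.
#' @param pause_duration adapted-cell growth pause after onset (min).
#' @param budded_duration,unbudded_duration cell-cycle phase lengths (min).
#' @param v0 birth volume (fL).
#' @param daughter_fraction volume fraction lost to the bud at division.
#' @param noise_sd additive Gaussian volume noise (fL), 0 for noiseless
#'   traces.
#' @param seed integer seed (mandatory).
#' @return An object of class `cell_traces`: long-format data frame with
#'   columns `cell_id`, `t_min`, `volume_fL`, `budded`, `fate`,
#'   `parent_id`.
#' @export
generateCellTraces <- function(n_cells, dose = 0.5, fate_fractions = NULL,
                               growth_rate_budded = 1,
                               growth_rate_unbudded = 0.2,
                               t_stress = 300, horizon = 900, dt = 3,
                               pause_duration = 90,
                               budded_duration = 60, unbudded_duration = 40,
                               v0 = 30, daughter_fraction = 0.35,
                               noise_sd = 0, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (is.null(fate_fractions)) {
    fate_fractions <- if (dose == 0) c(1, 0, 0)
    else if (dose == 0.5) c(0.22, 0.36, 0.42)
    else stop("no default fate fractions for dose ", dose,
              " mM; supply fate_fractions explicitly")
  }
  if (length(fate_fractions) != 3 ||
      abs(sum(fate_fractions) - 1) > 1e-8 || any(fate_fractions < 0))
    stop("fate_fractions must be 3 nonnegative values summing to 1")
  fates <- c("adapted", "prolonged_cycle_arrest", "permanent_growth_arrest")
  restore <- .with_seed(seed)
  on.exit(restore())
  fate_draw <- if (dose > 0)
    sample(fates, n_cells, replace = TRUE, prob = fate_fractions)
  else rep("adapted", n_cells)
  tgrid <- seq(0, horizon, by = dt)
  n_t <- length(tgrid)
  cycle <- unbudded_duration + budded_duration
  traces <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    phase0 <- stats::runif(1, 0, cycle)   # desynchronised cycles
    fate <- fate_draw[i]
    # state at each sample; volume advances per interval at the rate set
    # by the interval's start state, so budded intervals carry exactly the
    # budded-phase slope
    state_at <- function(t) {
      stressed <- dose > 0 && t >= t_stress
      if (stressed && fate == "permanent_growth_arrest")
        return(list(b = TRUE, rate = 0, cycling = FALSE))
      if (stressed && fate == "prolonged_cycle_arrest")
        return(list(b = TRUE, rate = growth_rate_budded, cycling = FALSE))
      paused <- stressed && t < t_stress + pause_duration
      b <- ((t + phase0) %% cycle) >= unbudded_duration
      rate <- if (paused) 0
      else if (b) growth_rate_budded else growth_rate_unbudded
      list(b = b, rate = rate, cycling = !paused)
    }
    V <- numeric(n_t); budded <- logical(n_t)
    st <- state_at(tgrid[1])
    V[1] <- v0; budded[1] <- st$b
    for (k in 2:n_t) {
      v <- V[k - 1] + st$rate * dt
      st_next <- state_at(tgrid[k])
      # cytokinesis scored at the unbudded -> budded transition, so the
      # volume drop always falls in an unbudded-start interval
      if (st_next$b && !st$b && st$cycling && st_next$cycling)
        v <- v * (1 - daughter_fraction)
      V[k] <- v; budded[k] <- st_next$b
      st <- st_next
    }
    if (noise_sd > 0) V <- pmax(V + stats::rnorm(n_t, 0, noise_sd), 0.1)
    traces[[i]] <- data.frame(cell_id = i, t_min = tgrid, volume_fL = V,
                              budded = budded, fate = fate,
                              parent_id = NA_integer_)
  }
  out <- do.call(rbind, traces)
  structure(out, class = c("cell_traces", "data.frame"),
            t_stress = t_stress, dt = dt)
}

#' Population growth rate from budded cells
#'
#' The growth-rate readout used on time-lapse volume data: the
#' finite-difference volume increase rate `(V(t2) - V(t1)) / (t2 - t1)`
#' over one sampling interval, averaged over *budded* cells only. Unbudded
#' cells are excluded so that shifts in cell-cycle repartition (e.g. stress
#' checkpoints) cannot masquerade as a change in metabolic activity.
#'
#' @param traces a [generateCellTraces()] result (or any data frame with
#'   `cell_id`, `t_min`, `volume_fL`, `budded`).
#' @param t time (min) at which to evaluate; snapped to the sample at or
#'   before `t`.
#' @return List with `mean` (fL/min), `sem`, `n` (budded cells used). When
#'   no budded cell exists at `t`, `mean` and `sem` are `NA` and
#'   `undefined` is `TRUE` (the estimate is undefined, not zero).
#' @export
estimateGrowthRate <- function(traces, t) {
  stopifnot(all(c("cell_id", "t_min", "volume_fL", "budded") %in%
                  names(traces)))
  tg <- sort(unique(traces$t_min))
  k <- findInterval(t, tg)
  if (k < 1 || k >= length(tg)) stop("t outside the sampled range")
  t1 <- tg[k]; t2 <- tg[k + 1]
  at1 <- traces[traces$t_min == t1, ]
  at2 <- traces[traces$t_min == t2, ]
  budded_ids <- at1$cell_id[at1$budded]
  use <- intersect(budded_ids, at2$cell_id)
  if (length(use) == 0)
    return(list(mean = NA_real_, sem = NA_real_, n = 0L, undefined = TRUE))
  dv <- (at2$volume_fL[match(use, at2$cell_id)] -
           at1$volume_fL[match(use, at1$cell_id)]) / (t2 - t1)
  list(mean = mean(dv),
       sem = if (length(dv) > 1) stats::sd(dv) / sqrt(length(dv)) else 0,
       n = length(use), undefined = FALSE)
}

#' Write cell traces as long-format CSV
#'
#' Columns: `cell_id`, `t_min`, `volume_fL`, `budded`, `fate`,
#' `parent_id`.
#'
#' @param traces a `cell_traces` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCellTraces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}
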