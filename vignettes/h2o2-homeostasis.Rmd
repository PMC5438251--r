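---
title: "Feedback models of H2O2 homeostasis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback models of H2O2 homeostasis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxadapt)
```

## The model

Budding yeast restores low internal hydrogen peroxide after an external
challenge through a transcriptional negative feedback: internal H2O2 (H)
activates expression of antioxidant enzymes — in practice the
peroxiredoxins Tsa1/Tsa2/Ahp1 — whose transcript (A_mRNA) and protein (A)
levels then scavenge H. With an external concentration I(t) the package
integrates

$$
\frac{dH}{dt} = \varepsilon + \alpha\,(I - H) - \beta A f(H), \qquad
\frac{dA_{mRNA}}{dt} = \gamma\,g(H) - \mu A_{mRNA}, \qquad
\frac{dA}{dt} = \gamma' A_{mRNA} - \mu' A,
$$

where $\varepsilon$ is basal internal production, $\alpha$ the membrane
transport rate, $\beta$ the scavenging rate constant, $\gamma,\gamma'$
transcription and translation rates, $\mu$ the transcript decay rate and
$\mu'$ the protein dilution rate set by growth. The two sensitivity
functions define four nested variants:

| variant | f(H) | g(H) | role |
|---|---|---|---|
| `integral` | 1 | H | perfectly adapting limit ($\mu' = 0$, $\varepsilon = 0$) |
| `linear` | 1 | H | reference model of limited accuracy |
| `transcription_saturating` | 1 | H/(H+K) | saturating transcriptional drive |
| `nonlinear` | H/(H+W) | H/(H+K) | H-limited scavenging; acquired tolerance |

The growth rate enters only through the constant $\mu'$: transient growth
slowdowns during stress are deliberately not fed back into the equations,
because they do not alter the internal peak dynamics that decide cell fate.

Two published calibrations are built in. `linearParams()` carries the
linear set ($\varepsilon=0$, $\alpha=1$, $\beta=5$, $\gamma'=0.01$,
$\mu'=\log 2/100$, all per minute) with either the slow transcript pairing
($\gamma=0.03$, $\mu=\log 2/40$; matches measured peroxiredoxin mRNA
stability) or the fast pairing ($\gamma=0.53$, $\mu=\log 2/2.5$); the two
pairings hold the absolute adaptation concentration fixed.
`nonlinearParams()` carries the nonlinear set ($\varepsilon=0.06$ mM/min,
$\beta=10$, $\gamma=0.1$, $\gamma'=0.005$ in per-mM-per-min units,
$K=W=0.01$ mM). The two tables use different units for $\beta,\gamma,
\gamma'$ (per minute vs per mM per minute) and are not dimensionally
reconcilable; we keep each table verbatim for its own variant and treat
A and A_mRNA as arbitrary model concentrations. No rescaling is guessed.

## Steady states and ramp asymptotics

For the linear family the equilibrium is
$H_{eq} = \mu\mu'(\varepsilon+\alpha I)/(\alpha\mu\mu' + \beta\gamma\gamma')$
(`steadyStateLinear()`), zero in the integral limit for any dose — which
is exactly why the integral architecture is rejected by steady-state
reporter data: the measured quasi-equilibrium signal grows with dose.
Under input ramps of rate $\delta$, integral feedback locks H onto the
plateau $\alpha\mu\delta/(\beta\gamma\gamma')$ and tolerates any amplitude
below the rate threshold
$\delta_{max} = H_{tox}\beta\gamma\gamma'/(\alpha\mu)$, while the linear
variant tracks its quasi-static equilibrium, growing at
$\mu\mu'\alpha\delta/(\alpha\mu\mu'+\beta\gamma\gamma')$ — the closed form
states the growth *rate*; the simulated value additionally carries a
constant feedback-delay offset, so agreement is asserted on the rate.

The saturating variants have closed forms built from
$Z = \gamma\gamma'\beta/(\mu\mu'\alpha)$ and
$\sigma = \alpha\mu\mu'KW/(\beta\gamma\gamma')$; where the printed source
formulas lost typographical structure, both composites were reconstructed
to be dimensionally and asymptotically consistent and validated against
the bracketed exact root over wide dose ranges (`steadyStateNonlinear()`
methods `"saturating"`, `"low_dose"`, `"high_dose"` against `"exact"`).
Low-dose approximations report a validity flag once $H_{eq}$ exceeds a
tenth of the relevant saturation constant.

## Numerical choices

* Integration uses `deSolve::lsoda` (adaptive, stiffness-switching) with
  defaults rtol = 1e-8, atol = 1e-12 mM, restarted at every protocol
  segment boundary so steps are discontinuities, never smoothed ramps. The
  step limit in phase diagrams is the exact discontinuity, not a large
  finite rate, which avoids stiffness artifacts.
* Output grids add 0.05-min samples in the first 60 min after each
  boundary (transients peak on the $1/\alpha$ timescale); the trajectory
  peak is refined beyond the grid by local spline interpolation
  (`peakInternal()`). Halving rtol moves the 0.6 mM benchmark peak by well
  under 0.05%.
* The linear-family variants are signed linear systems; after strong steps
  H transiently undershoots zero (an underdamped oscillation intrinsic to
  those equations — scavenging does not shut off at H = 0 when f = 1). No
  clamping is applied, which is also what preserves the superposition
  property the tolerance analysis relies on. The nonlinear variant cannot
  leave the nonnegative orthant and is checked for it.
* Numeric steady states eliminate the transcript/protein chain and
  bracket the scalar balance on $[0, I+\varepsilon/\alpha]$, where a sign
  change is guaranteed; the nonlinear equilibrium used in fitting is a
  damped, bracket-confined Newton iteration started from the low-dose
  closed form (vectorised over doses).
* Initial conditions are always the pre-stress equilibrium at I = 0 (the
  zero state when $\varepsilon = 0$, the basal equilibrium otherwise):
  cells are adapted to stress-free medium before any protocol starts.

## Phase diagram, training, and acquired tolerance

`calibrateHtox()` defines the toxicity threshold as the simulated internal
peak of the 0.6 mM step — the experimentally determined stepwise
adaptation limit. `hmaxGrid()` maps the global peak over the (amplitude,
rate) plane with ramp-to-amplitude-then-hold stimuli held for five
protein-dilution time constants; `adaptationBoundary()` bisects the
$H_{max} = H_{tox}$ contour to 1e-3 mM over $(0, 4 I_{abs}]$ and flags an
open bound when the peak never crosses the threshold (as for integral
feedback below $\delta_{max}$). The boundary runs from the 0.6 mM step
limit to the absolute adaptation concentration
$I_{abs} = H_{tox}(1+\beta\gamma\gamma'/(\alpha\mu\mu'))$ with slow-ramp
asymptote $\delta = \mu'(I_{abs}-I)$, a more than tenfold extension of the
tolerated amplitude ("training"). The peak grid is nondecreasing — not
strictly increasing — in amplitude at fixed rate: at fast rates the early
ramp transient can set the global peak for several amplitudes at once.

Acquired tolerance is probed with sustained pretreatment at $I_0$ followed
by a challenge step (`pretreatmentPeak()`, `toleranceThreshold()`). The
quantity that discriminates the variants is the internal *burst* above the
pretreatment baseline: linear feedback leaves it exactly unchanged
(superposition), nonlinear scavenging shrinks it strictly with $I_0$,
because the pre-accumulated enzymes act with no transcriptional delay. The
absolute peak is not monotone in $I_0$ — the baseline itself rises — so
tests and analyses are phrased on the burst. Fate classification is binary
(adapted/arrested) on $H_{max}$ vs $H_{tox}$; the three experimental
phenotype classes live in the trace generator, not in the ODE model, which
carries no DNA-damage state.

## Dose-response fitting

`fitDoseResponse()` minimises
$\sum_j ((y_j - \hat y(I_j))/\sigma_j)^2$ with SEM columns as weights,
free parameters chosen from $\{\varepsilon, K, W, s, \text{offset}\}$,
positive parameters log-transformed, and at least eight log-spaced
multistarts polished by a second Nelder-Mead pass. The readout bridge is
proportional: a nuclear-localization-like readout follows $s\,H_{eq}$, an
expression-like readout $s\,A_{eq}$; offsets default to zero because
readouts are reported as increase over the pre-stress level. No confidence
intervals are derived (a `profileChi2()` diagnostic is provided).

The built-in recovery study generates antioxidant-readout data from the
nonlinear calibration on 20 doses (0 plus 19 log-spaced points up to
0.4 mM — dose-response designs in this assay family are geometric), with
noise 5% of the dynamic range, and refits $\varepsilon$ and $K$ with the
observable scale held at its generating value: synthetic data are in model
units, so the scale is known there. Freeing the scale as well makes $K$
nearly degenerate with it — internal H stays below K/8 across this dose
range, so saturation curvature is a second-order signal — and only the
order of magnitude of $K/W$ would be recoverable. Model discrimination,
by contrast, is run fully scale-free (nonlinear $\{\varepsilon,K,s\}$ vs
linear $\{\varepsilon,s\}$), mimicking arbitrary-unit data.

## Stress protocols and the physical ramp generator

Protocols are ordered non-overlapping segments (constant, linear ramp,
mixing-tank ramp) with discontinuities only at boundaries; a "ramp of rate
$\delta$ to amplitude I" rises from zero and then holds, and the step is
its $\delta=\infty$ member. The physical ramp device pumps stock at
concentration $C_0$ and rate $\mu_0$ into a stirred tank of volume
$V_1^0$ perfusing the chip at $\mu_1$; at matched flows the tank follows
$C_0(1-e^{-\delta t})$ with $\delta = \mu_0/V_1^0$ (the saturating sign of
the exponent is required for the linearisation $C_0\delta t$ to follow —
we implement it as such), and with unequal flows the mass-balance ODE is
integrated numerically rather than silently applying the closed form. The
0.785 slope correction reflects stressor degradation in the unchilled
tank and applies only to `corrected`-mode tank calculations — simulated
model inputs always use the nominal protocol. The linearisation error is
$\delta t/2$ only to leading order; the tests bound the remainder at
second order rather than quoting $\delta t/2$ as an upper bound.

## Synthetic single-cell traces

`generateCellTraces()` emulates segmented time-lapse volume traces at
3-min sampling: linear volume growth (growth rate is uncorrelated with
volume in these cells, so no exponential scaling), faster in the budded
phase, a volume drop at division, and one of three post-stress fates —
adapted (a 90-min growth pause, the order of the observed 45–100 min
adaptation timescale, then normal cycling), prolonged cycle arrest
(budded, growing, not dividing), permanent growth arrest (volume frozen).
Fate fractions default to all-adapted at dose 0 and to the measured
(22%, 36%, 42%) split at 0.5 mM; any other dose requires explicit
fractions — figure-only values are never guessed. The division drop is
scored at the unbudded-to-budded transition so that every budded-start
sampling interval carries exactly the budded-phase slope; this is what
lets `estimateGrowthRate()` — the budded-cells-only finite-difference
estimator — recover the generating slope to machine precision on
noiseless traces, and makes the estimate invariant to how many unbudded
cells are present. Volumes are carried directly; contour segmentation and
spherical-approximation geometry are out of scope.

What passing tests on these synthetic data do *not* show: real traces
have measurement noise, correlated cell-cycle structure, lineage effects
and dose-dependent fate gradation that the generator does not emulate;
the round-trip results validate the estimators and the pipeline plumbing,
not the biology.

## Problem sizes and limitations

The test suite and acceptance script use: dense steps to 5000 min for
equilibria; a 5x4 (+ step) phase grid on amplitudes 0.05–10 mM and rates
1e-4 to 0.1 mM/min; boundary bisections to 1e-3 mM (2e-4 mM for the
asymptote-slope check); 20-seed recovery studies with 20 doses; and
100-replicate model-discrimination runs. These sizes were chosen so each
check is statistically meaningful at the tolerance it asserts.

Known limitations: no stochastic (Langevin) dynamics, no explicit Yap1
shuttling kinetics (nuclear Yap1 is treated as a proxy for H), no H2O2
decay inside the microfluidic chip, no feedback of stress on growth rate,
no DNA-damage or death machinery, and no attempt to fit time-course
trajectories — the fitting surface is steady-state dose responses only.
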