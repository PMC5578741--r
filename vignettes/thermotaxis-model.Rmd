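---
title: "Modeling bidirectional thermotaxis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bidirectional thermotaxis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotax)
```

This vignette explains the model the package implements, the assumptions
behind it, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## The receptor-team model

Chemoreceptors in *E. coli* work as allosterically coupled teams. The
package takes the basic signaling unit to be a trimer of receptor dimers:
a two-state unit that is active with probability

$$A = \frac{1}{1 + e^{F}}, \qquad F = \sum_{i=1}^{3} f_i,$$

where $f_i$ (in units of $k_BT$) is the free-energy difference between the
active and inactive conformations of dimer $i$. Each dimer contributes

$$f_i = f_0([L]) + (T - T_0)\,f_1 - \left[g_0 + (T - T_0)\,g_1\right] m,$$

a first-order expansion in temperature about a reference $T_0$, linear in
the methylation level $m$ (0 to $m_\mathrm{tot} = 8$ methyl groups per
dimer). The ligand term is the standard two-state binding form
$f_0([L]) = f_0(0) + \log[(1 + [L]/K_\mathrm{off})/(1 + [L]/K_\mathrm{on})]$;
for an attractant $K_\mathrm{off} < K_\mathrm{on}$, so ligand raises $f_0$
and suppresses activity. (The rendered source of this formula is ambiguous
about the division; the package reads $[L]K_\mathrm{off}$ as
$[L]/K_\mathrm{off}$, the only reading consistent with attractants having
$K_\mathrm{off} < K_\mathrm{on}$.)

Tar and Tsr share all parameters except the ligand term: Tar responds to
aspartate/MeAsp, Tsr to serine. Teams mix the two types binomially —
`trimer_mixing(p_tar)` gives the four composition weights; `p_tar = 0.5`
reflects 1:1 expression.

Because the methylation coefficient $g(T) = g_0 + (T - T_0) g_1$ grows with
temperature, the temperature sensitivity of a dimer is proportional to
$f_1 - m\,g_1$: low-methylation receptors respond thermophilically
(activity falls on warming), high-methylation receptors cryophilically, and
$m^* = f_1/g_1$ is temperature-insensitive.

## Adaptation kinetics and the adapted state

Methylation adapts with saturating kinetics,

$$\frac{dm}{dt} = \gamma_R\,\frac{m_\mathrm{tot} - m}{m_\mathrm{tot} - m + N_0}\,(1 - A)
               - \gamma_B\,\frac{m}{m + N_0}\,A,$$

whose occupancy factors slow methylation (demethylation) as $m$ approaches
$m_\mathrm{tot}$ (0); $N_0$ sets how abruptly. The adapted state satisfies

$$\frac{m_\mathrm{tot} - m_{ss}}{m_\mathrm{tot} - m_{ss} + N_0}\,
  \frac{1 - A}{1 - A_0} =
  \frac{m_{ss}}{m_{ss} + N_0}\,\frac{A}{A_0}.$$

With $N_0 = 0$ this reduces to $A(m_{ss}) = A_0$: perfect adaptation. With
$N_0 > 0$, teams near methylation saturation cannot restore $A_0$ — the
imprecision that drives everything interesting below.

The absolute rate constants are not constrained by steady-state data; the
package defaults to $\gamma_B = 1$ and
$\gamma_R = A_0/(1 - A_0)$ (= 0.5 at the default $A_0 = 1/3$) so that the
$N_0 = 0$ fixed point reproduces $A_0$, with model time in arbitrary units.

Parameter defaults (`model_params()`): $A_0 = 1/3$ (a typical wild-type
adapted activity), $N_0 = 2$, $T_0 = 24$ °C (an arbitrary reference),
$f_1 = 1.2$, $g_0 = 0$, $g_1 = 0.2$, $m_\mathrm{tot} = 8$, stimulus step 3
°C, saturating-ligand offset $f_0^\mathrm{sat} = 15\,k_BT$. The $f$ and $g$
values place the accumulation temperature in the experimentally observed
range.

## Thermal-response curves and the inversion temperature

`thermal_response_curve()` adapts the four-trimer ensemble at each grid
temperature $T$ (default 24–39 °C in 3 °C steps) and evaluates

$$R(T) = \frac{\bar A(T + 3) - \bar A(T)}{\Delta \bar A}.$$

Two readings of $\bar A(T+3)$ are exposed because the defining formula does
not fix one:

* `mode = "transient"` (default): methylation frozen at its $T$-adapted
  value. This matches the experimental observable — the *initial* amplitude
  of a kinase-activity (FRET) response before adaptation catches up.
* `mode = "re_adapted"`: fully re-adapted at $T+3$. Under perfect
  adaptation this is identically zero, which is exactly the null it exists
  to demonstrate.

The normalization $\Delta\bar A$ mirrors the experimental one (response
normalized to saturating attractant at the lowest temperature): the
ensemble is adapted at the lowest grid temperature with no ligand, the
cognate receptor's $f_0$ is then set to $f_0^\mathrm{sat} = 15$ with
methylation frozen, and $\Delta\bar A$ is the resulting activity drop. The
receptor choice follows `sat_receptor` (default Tar; Tsr for a Tar-free
ensemble so the stimulus always engages a receptor that is present).

Sign convention: $R < 0$ — kinase activity falls on warming, the
attractant-like, *thermophilic* response; $R > 0$ — *cryophilic*.
`find_inversion_temperature()` returns the linear interpolation of the
first strict sign change, or `NA` when there is none.

Why the inversion needs imperfect adaptation: under perfect adaptation the
ensemble-mean methylation tracks temperature so that the mean of
$f_1 - m\,g_1$ keeps one sign, even though individual compositions differ —
their adaptive methylations compensate. With $N_0 > 0$ and one receptor
type ligand-saturated (Tar at $f_0 = 15$), Tar-containing teams sit near
$m = 8$ where methylation barely moves, Tsr-only teams adapt freely at low
$m$. At low temperature the Tsr teams dominate (thermophilic); as their
methylation approaches $f_1/g_1$ their response fades while the saturated
Tar teams' cryophilic response persists, and the ensemble response changes
sign. Removing the saturation ($N_0 = 0$) removes the inversion — the
package reproduces both behaviors, and its tests assert them.

### Numerical choices and degenerate inputs

* The adapted-state residual $h(m)$ has $h(0) \ge 0$ and
  $h(m_\mathrm{tot}) \le 0$, so a root is always bracketed; bisection runs
  to an interval of $10^{-12}$ (cap 200 iterations), exact ties resolving
  to the lower $m$. Roots match an independent $10^5$-point dense-scan
  oracle to better than $10^{-4}$ over 1,000 random parameter draws, and
  the ODE route (`integrate_methylation()`, via `deSolve`) converges to the
  same fixed points within $10^{-4}$.
* Team activities use `plogis(-F)`, which neither overflows nor returns
  `NaN` for large $|F|$; activities within $\sim 10^{-16}$ of 0 or 1 round
  to the boundary in double precision, which is unavoidable and harmless.
* At $T = T_0$ with $g_0 = 0$ the methylation coefficient vanishes and
  activity is independent of $m$. The saturating solver still has a unique
  interior root (the occupancy factors remain strictly monotone), so the
  default grid may start at $T_0$. The *unbounded* perfect-adaptation
  variant has no adapted state there; `solve_steady_state()` returns a
  flagged `NA` state with a warning, the response curve carries `NA` at
  that grid point, the normalization moves to the lowest grid temperature
  with a valid adapted state, and inversion detection skips `NA` pairs.
* The perfect-adaptation comparison defaults to *unbounded* methylation
  ($N_0 = 0$ with the $[0, m_\mathrm{tot}]$ box removed), because a clipped
  $N_0 = 0$ model still truncates adaptation at large $f_0$ and would
  reintroduce the very imprecision the null is meant to exclude. The
  clipped variant remains available (`unbounded_m = FALSE`).

## Trajectory analysis

The pipeline follows the assay order and each stage only removes or groups
records: particle filters → nearest-neighbour linking → motility filter →
path-length filter → histogram / TMC.

* **Particle filters.** Keep detections with area ≥ 5 px and eccentricity
  ≤ 0.95 (the stated cuts are strict, so the boundary values survive).
* **Linking.** Greedy per-frame assignment in ascending distance order
  within `link_max_px`. The linking radius is not stated by the assay
  description; the default 15 px is about three times the per-frame flow
  displacement (30 µm/s ÷ 12 fps ÷ 0.3 µm/px = 8.33 px).
* **Motility.** A track is motile when the population-SD ratio
  sd(Y)/sd(X) is *below* 18 (a ratio of exactly 18 is non-motile);
  sd(X) = 0 counts as infinite ratio.
* **Viability.** Path length is the cumulative step displacement in pixels
  (not point count, not net displacement — "path length" read as distance
  travelled); tracks under 10 px are dropped. Single-point tracks are
  non-viable by construction.
* **TMC.** $-2[(\overline{X} - X_\mathrm{min})/(X_\mathrm{max} -
  X_\mathrm{min}) - 0.5]$ over the pooled X of viable tracks: +1 when all
  cells pool at the left cutoff, −1 at the right. With cold water on the
  left wall and warm on the right, warm-side accumulation therefore reports
  a *negative* value under the formula as printed, while the measurement it
  summarizes assigns +1 to the warm side — presumably the imaging
  orientation flips X. The package implements the formula exactly as
  printed and exposes `warm_positive = TRUE` to negate it; it does not
  guess further. `x_min`/`x_max` default to the observed range of the
  pooled X — supplying the channel cutoffs explicitly is recommended for
  cross-run comparability.
* **Gradient.** `gradient_map()` + `position_to_temperature()` interpolate
  linearly between the wall temperatures, which is how the near-linear
  wall-to-wall gradient of the device is summarized.

## Growth metrics

`max_growth_rate()` fits ln OD against time by least squares in every
contiguous window (default 5 points) and returns the largest slope —
the maximal *specific* growth rate — and its window-centre time, ties
resolving to the earliest window. An OD floor of $10^{-4}$ guards the log;
blank subtraction is the caller's responsibility.

Two growth-delay definitions are in circulation and they are **not**
equivalent; both are provided and neither is silently privileged:
`growth_delay_halfmax()` (time from inoculation to half-maximal OD, the
default notion) and `time_to_max_rate()` (time until the maximal growth
rate is reached). `growth_delay_halfmax()` applies a 5-point moving average
before locating the log-interpolated crossing: with plate-reader noise the
*first* crossing of a noisy series is biased early, and the light smoothing
removes that bias at negligible cost in time resolution (`smooth = 1`
disables it). A curve that reaches half-maximum only at its final reading
has an undefined delay (`NA` with a warning).

## Synthetic data: what it emulates, and what it does not

The generators replace the wet-lab inputs with seeded, ground-truthed
equivalents; every generator is a pure function of its configuration and
seed.

* `sim_trajectories()` emulates the statistical structure of the
  microfluidic video after particle detection: cells advected down-channel
  at 8.33 px/frame (30 µm/s at 12 fps, 0.3 µm/px) in a 1667 px (500 µm)
  channel, with motile cells exploring the cross-channel axis and
  non-motile cells only jittering (SD 0.1 px). Motile X motion is
  run-and-tumble — a persistent ±4 px/frame velocity reversing with
  probability 0.1/frame — plus the configured drift bias and Gaussian step
  noise (SD 1 px). A purely diffusive X walk cannot simultaneously pass the
  sd(Y)/sd(X) < 18 motility classifier and keep per-frame steps inside any
  sensible linking radius given the fixed flow displacement; swimming cells
  are in any case ballistic on the frame timescale, so the persistent-run
  model is both necessary and more faithful. Cells enter staggered along
  the flow axis (jittered 80 px spacing): since all cells share the flow
  speed, down-channel separation persists and distinct cells stay outside
  the linking radius, giving exact track recovery at default settings.
  X reflects at the walls (cells remain observable, as in the imaged
  window). Defaults: 60 frames, 40 motile + 10 non-motile cells.
* `sim_spurious_particles()` produces exactly the records the particle
  filters must remove (area < 5 px or eccentricity > 0.95).
* `sim_growth_curve()` produces logistic OD curves with lag:
  `baseline + K/(1 + exp(-r (t - t0)))` plus Gaussian noise, clipped
  positive. Defaults emulate plate-reader growth in minimal medium:
  K = 0.5 OD, r = 0.8 h⁻¹, t0 = 12 h, baseline 0.002 OD (a 1:200
  inoculum), 15-minute reads over 24 h, noise SD 0.005 OD.

What the generators deliberately do **not** emulate: raw images and
segmentation (the pipeline starts from detection records), temperature
dependence of swimming speed (a direct motility effect the assay design
minimized), cell division and collisions within a track, merged detections
of overlapping cells, and non-logistic growth phenomenology (diauxie,
death phase). Passing the recovery tests therefore shows the analysis
chain is correct and unbiased on data with this statistical structure — it
does not validate robustness to segmentation artifacts or tracking through
dense crowds.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run the solver-vs-oracle comparison on
1,000 random parameter draws (10⁵-point scans), the ODE cross-check on 100
draws, the drift-free TMC null on 50 seeded replicates of 35 cells × 60
frames, and the growth-delay recovery on 100 seeded curves — sizes chosen
so the full suite completes in well under a minute of compute per module
while keeping Monte-Carlo standard errors far below the asserted bounds.

## Known limitations

* All receptor parameters except the ligand term are shared between Tar
  and Tsr; receptor-specific $f_1$, $g_1$ would change quantitative
  inversion temperatures (the interfaces accept per-receptor $f_0$ only).
* The model predicts response *sign* versus temperature, not absolute
  accumulation positions in a physical channel; no parameters are fitted
  to kinase-activity data.
* Greedy nearest-neighbour linking can swap identities when cells pass
  within the linking radius of one another; the generator's staggered entry
  avoids this regime rather than solving it (no Kalman or multi-hypothesis
  tracking).
* The two growth-delay definitions can disagree on strongly asymmetric
  curves; users comparing conditions should pick one and say which.
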