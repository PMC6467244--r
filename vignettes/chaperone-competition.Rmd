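---
title: "Chaperone competition and cell-cycle entry: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaperone competition and cell-cycle entry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Budding yeast commits to a new division cycle at Start, when the most
upstream G1 cyclin, Cln3, accumulates in the nucleus with the Cdk Cdc28 and
inactivates the Whi5 repressor. Cln3 is an obligate client of the Hsp70/Hsp40
chaperone system (Ssa1/Ydj1): it must be folded and released by chaperones
before it can act. The same chaperone pool also serves the folding of the
bulk of nascent protein, whose flux scales with growth rate. `chapcomp`
implements a kinetic model in which these two demands compete for a limiting
pool of Ydj1, so that *chaperone availability* becomes the signal that couples
growth rate to the critical size at Start.

Seven state variables, all in molecule counts: unfolded bulk protein
$Prot_U$, Ydj1-bound bulk protein $YP$, folded bulk protein $Prot_F$,
unfolded Cln3 $Cln3_U$, Ydj1-bound Cln3 $YC$, folded Cln3 $Cln3_F$, and free
Ydj1 $Ydj1_A$. Unfolded clients bind free Ydj1 with the second-order rate
$k_b$ (scaled by $1/Vol$ because states are counts), complexes release a
folded client at $k_r$, and every species is degraded at a first-order rate;
degradation of a complex returns the surviving partner to its pool.
Synthesis is zero order and scales with $Vol$. Folded bulk protein is
degraded at $\beta\,kd_{ProtU}$ with $\beta = 0.01$ (a 100-fold longer
half-life than unfolded protein). The protein synthesis density $S_{ProtU}$
doubles as the specific volume growth rate through the conversion factor
$\gamma = 1$.

Two observables connect the model to single-cell measurements:

* **Diffusion**: Ydj1 mobility is a weighted average over its pools,
  $D_{sim} = \frac{Ydj1_A}{Ydj1}D_{free} + \frac{YP+YC}{Ydj1}D_{bound}$,
  with calibrated limits $D_{free} = 30$ and $D_{bound} = 1\ \mu m^2/min$.
  It is a convex combination, so it can never leave $[1, 30]$.
* **Critical volume**: cells growing at rate $S_{Vol}$ bud at the volume
  where steady-state $Cln3_F$ reaches the threshold $Cln3F_{crit} = 25$
  molecules.

Volume is treated as a frozen pseudo-parameter: biochemistry relaxes much
faster than cells grow, so all Start predictions are quasi-static statements
about steady states, not first-passage times. This is also why the critical
volume is defined by a *steady-state* threshold crossing.

## Steady states

Two routes are implemented and cross-checked. The reference route integrates
the rate equations from the empty state to $10^7$ s and polishes the endpoint
with damped Newton iterations on the full 7-dimensional system
(`method = "integrate"`). The default route (`method = "exact"`) uses an
exact reduction: at steady state the complex and client balances express
$Prot_U$, $YP$, $Cln3_U$ and $YC$ in closed form given free Ydj1, and the
Ydj1 conservation law ($Ydj1$ total $= s_{Ydj1}Vol/kd_{Ydj1}$) becomes a
single monotone scalar equation in $Ydj1_A$ on a bounded interval, solved by
Brent's method and Newton-polished. Both routes satisfy
$\lVert f \rVert \le 10^{-9}\max(1, \lVert x \rVert)$ and agree to $10^{-6}$
relative in the tests; the reduction is about three orders of magnitude
faster, which is what makes ensemble MCMC and dense response grids practical
on one CPU.

Two structural facts are worth knowing. First, the steady state is linear in
volume at fixed synthesis densities (scaling all counts and the volume by
$\lambda$ maps solutions to solutions), so steady-state Cln3$_F$ grows
linearly with volume and the critical-volume equation has exactly one root
when it is bracketed. The critical-volume solver still follows the generic
bisection contract (relative tolerance $10^{-3}$, endpoint bracket checks
with explicit "threshold not reached" and "already past Start" errors), so
it remains correct for model variants that break the scaling. Second, for
the reference fitted parameter set the threshold becomes unreachable within
the controlled 10–100 fl volume range for growth rates above roughly 0.45
molec s$^{-1}$ fl$^{-1}$; observation tables are therefore generated over
growth rates 0.01–0.4, the span the single-cell data actually cover.

## Parameters and fitting

Table-driven constants: $kd_{Cln3U} = 6.93\times10^{-2}$,
$kd_{Cln3F} = 3.85\times10^{-2}$, $kd_{Ydj1} = 5.77\times10^{-3}$ s$^{-1}$
(fixed), and five free parameters with log-uniform fitted ranges:
$s_{Cln3}$, $s_{Ydj1}$, $kd_{ProtU}$, $k_b$, $k_r$. The reference vector
("set 3114" in the deposited model) is the minimal-loss member of the
posterior ensemble.

The combined objective sums squared residuals of two curves: experimental
budding volume versus growth rate against the model critical volume, and
experimental Ydj1 diffusion versus growth rate (at each cell's volume)
against $D_{sim}$ at steady state. The two observables live in different
units (fl versus $\mu m^2$/min), so by default every residual is normalized
by its uncertainty (or by the data mean of its observable kind when absent);
the `"raw"` mode reproduces plain squared sums. Point estimation runs
Levenberg–Marquardt (`minpack.lm`) over the free parameters in log10 space,
box-constrained to the fitted ranges. Two numerical choices matter here: the
critical-volume solver is run at a much tighter internal tolerance
($10^{-8}$) during fitting so finite-difference Jacobians see a smooth
surface, and parameter vectors for which Start is unreachable contribute a
large finite penalty residual ($10^6$) rather than an error, so optimizers
and samplers can cross infeasible pockets.

The posterior is explored with an affine-invariant ensemble sampler
(Goodman–Weare stretch move, the scheme popularized by *emcee*), implemented
in the package because no installed R library provides one. The likelihood is
$\exp(-(L_1+L_2)/2\sigma^2)$ with $\sigma = 1$ in normalized-residual space
(the likelihood temperature is not an identified quantity here and is
exposed in the configuration); priors are log-uniform on the fitted ranges.
The canonical protocol discards 3,000 draws as burn-in and retains 1,500 by
uniform thinning. The tests run a scaled-down protocol (32 walkers × 500
steps, 12 synthetic records) that finishes in a few minutes on one CPU;
at that scale the planted truth sits inside every marginal 90% credible
interval and the two client-complex pools covary positively across the
ensemble. Posterior marginals legitimately span orders of magnitude — the
model is sloppy in the usual systems-biology sense — so the tests assert
coverage and sign structure, never tightness.

One covariation deserves a caveat. Across ensembles fitted to *real* data,
free Ydj1 and unfolded protein have been observed to anticorrelate. For
posteriors conditioned on model-exact synthetic data this sign is not
structural: the diffusion records pin the free *fraction* of Ydj1 at each
growth rate, so across the posterior the absolute free-Ydj1 level tracks the
(weakly constrained) Ydj1 synthesis rate while the unfolded-protein level
tracks the binding parameters, and the two directions decouple — we measured
correlations between 0 and +0.3 across likelihood temperatures spanning
ensemble widths of one to four decades. The competition signature that *is*
structural, and that the tests assert, is the anticorrelation of unfolded
protein and free chaperone across growth rates: raising the synthesis load
monotonically depletes the free pool.

## Perturbations

**Cycloheximide** is modelled as a sustained fold-reduction (canonically 3,
4.5, 6, 9 or 12; the measured effect of the sublethal dose is 5.9-fold) of
all three synthesis densities from the pre-treatment steady state. The
equations then produce a fast relief phase — unfolded protein drains within
seconds, freeing Ydj1 well above its pre-treatment level — followed by a slow
decline to the reduced fixed point as total Ydj1 decays. Free Ydj1 therefore
overshoots, peaks and settles below its starting point. Folded Cln3, by
contrast, declines essentially monotonically under this protocol: its own
synthesis is cut at the same instant, and that direct loss outweighs the
chaperone relief at every time. The package simulates the protocol exactly
as stated and the tests assert these shapes as the equations produce them.

**Stress** transfers a fraction (20–80%) of the folded pools to the unfolded
pools at $t = 0$ (conserving totals) and, for heat stress, multiplies Ydj1
synthesis by 2.9 for the rest of the window; salt stress leaves parameters
untouched, so its long-time state provably returns to the pre-stress fixed
point. The flood of unfolded protein sequesters free Ydj1 within seconds;
mobility and folded Cln3 dip and then recover on the slower protein-turnover
time scale. A `transfer_cln3 = FALSE` switch restricts the transfer to bulk
protein for sensitivity analysis. The "independent" scenario — used to show
that only *competition* couples bulk-protein unfolding to Cln3 — folds Cln3
with a private duplicate Ydj1 pool (identical parameters, no bulk load);
trajectories are compared after normalizing each scenario to its own
pre-stress steady state. The construction of the independent scenario is a
design choice (a duplicated pool rather than removal of Cln3 from the shared
pool); it is documented as such, and the comparison asserted is only that the
competing-mode Cln3$_F$ trough is at least as deep as the independent-mode
trough.

**Time-scale fitting.** To compare stress simulations with mobility time
courses, a single dilation factor $\tau$ (model seconds per experimental
minute) maps experimental time onto model time; for each candidate unfolding
fraction, $\tau$ is fitted by least squares on log mobility (matching the
multiplicative error structure) with a coarse-grid scan before local
refinement, and the fraction with the smallest error wins. Identification
rests on trough depth, which the dilation cannot change. Because the model's
sequestration transient is fast relative to its recovery, the synthetic
mobility generator samples densely at early times; the simulation grids for
both generator and fitter are logarithmic in time for the same reason.

## Photokinetics estimators

**Nuclear/cytoplasmic concentration ratio.** Wide-field imaging mixes
nuclear and cytoplasmic fluorescence in the nuclear projected area. Modelling
that area as a cylinder through the cell height and the nucleus as a sphere
(radius ratio $R_r$, z-height correction $k$) gives the forward projection
$F_r = (\tfrac32 k + (N/C - 1)R_r)/(k + (N/C-1)R_r^3)$, whose exact inverse
is $N/C = 1 + k(F_r - \tfrac32)/(R_r - F_r R_r^3)$. The uniform-fluorophore
limit ($F_r = 3/2 \Rightarrow N/C = 1$ for any geometry) anchors the
formula, and the forward/inverse pair is property-tested over the realistic
geometry range. The geometry degenerates when $F_r = R_r^{-2}$, where the
estimator raises an error rather than returning an unstable value.

**FLIP exchange rates.** Nuclear fluorescence loss in photobleaching obeys
$dF_n/dt = K_i F_c - (K_e + K_b)F_n$, $dF_c/dt = K_e F_n - K_i F_c$ during
bleaching. The import estimator uses the classical plateau identity
$K_i = (F_n/F_c)_{ss}(K_e + K_b/2)$ with the GFP bleaching rate obtained
from the reference channel times the bleaching factor 1.94. For the export
rate, two plateau ratios are combined: the recovery plateau is exactly
$r_2 = K_i/K_e$, while the bleach plateau exactly satisfies
$K_e r_1^2 + (K_e + K_b - K_i)r_1 - K_i = 0$ (the dominant-eigenvector ratio
of the linear system). Eliminating $K_i$ gives the exact inversion
$K_e = K_b r_1 / ((r_2 - r_1)(1 + r_1))$, the package default; the classical
form $K_e = r_1 K_b / (2(r_2 - r_1))$ is its linearization at $r_1 \to 1$
and is kept as `method = "linear"`. The distinction matters: at realistic
rates ($K_i \approx K_e \approx 0.2$ s$^{-1}$, $K_b = 0.05$ s$^{-1}$) the
linearized form recovers a planted export rate only to ~6%, the exact form
to better than 0.1%. The default export rate applied to import estimates is
0.199 s$^{-1}$, assumed constant among G1 cells and overridable per cell.

**FCS.** Curves are fitted with the single-component anomalous-diffusion
autocorrelation
$g(\tau) = g_0 /((1 + (\tau/\tau_D)^\alpha)\sqrt{1 + (\tau/\tau_D)^\alpha/s^2})$
with the anomaly exponent fixed at $\alpha = 0.5$, structure parameter
$s = 5$, over the canonical $10\,\mu s$–$100\,ms$ window; the diffusion
coefficient is $D = w_0^2/(4\tau_D)$ with a configurable focal radius
($w_0 = 0.25\ \mu m$ default). The original analysis used external fitting
software whose exact functional form and focal calibration are not
recoverable, so only round-trip correctness (generator → fit) is asserted,
plus the acquisition-quality rules used upstream of the model fits: a curve is flagged when the
relative standard error of the diffusion time exceeds 50% or the fitted
intercept exceeds 1.01, and isolated time-lapse outliers are removed when
they differ from both neighbours by more than 50%.

**Mobility index**: inverse fluorescence half-life of an exponential fit to
a normalized unbleached-region trace; constant traces return 0, rising
traces warn and return 0.

## The synthetic-data generators

Every input the estimators and fitters consume can be generated with a seed:
per-cell growth observations (growth rates log-uniform over the observed
span, volumes uniform over 10–100 fl, observables from the generating truth
with unit-mean lognormal noise, default CV 10% — a convention, as per-cell
measurement errors are not tabulated), two-compartment FLIP traces (exact
matrix-exponential propagation of the linear system, with a matched
reference-channel bleach trace), FCS curves, and stress mobility series. All
generators are pure functions of (configuration, seed) and restore the
caller's RNG state. Noise-free outputs lie exactly on the corresponding
model manifolds, which the tests assert generator by generator.

What the generators deliberately do not emulate: cell-to-cell parameter
heterogeneity (every synthetic cell shares the truth parameters), temporal
autocorrelation of single-cell growth, segmentation error structure, or
photophysics beyond first-order bleaching. Passing tests therefore certify
the estimators and the inference machinery, not robustness to every artifact
of real microscopy data.

## Problem sizes and numerical choices

The test suite and the acceptance script size their computations for a
single CPU: steady-state grids of 20 × 20, response curves on 5–12 growth
rates, observation tables of 12–50 records, and the scaled-down MCMC
protocol above. Integration uses `lsoda` with the analytic state Jacobian
(relative tolerance $10^{-8}$); integrator undershoots above $-10^{-8}$ are
clipped to zero with a warning, larger negatives are treated as errors.
Random-number use is always locally seeded. SBML export writes Level 3
Version 2 with one reaction per elementary process and term-by-term MathML
kinetic laws (the same network as the deposited reference model); the
importer validates the species set and parameter list and the round trip is
checked at the steady state to $10^{-9}$. The package's R functions are the
primary interface; `inst/scripts/chapcomp.R` provides a thin command-line
wrapper over them.

## Known limitations

* The model has no volume growth dynamics: Start predictions are
  quasi-static threshold crossings, valid when biochemistry is much faster
  than growth.
* No stochastic (molecule-number) simulation; all counts are continuous.
* The likelihood temperature, walker count and thinning protocol of the
  original ensemble exploration are not published; defaults are documented
  and results at the test scale are labelled scaled-down.
* The independent-scenario construction and the FCS focal-volume calibration
  are package design choices where the original is silent; both are flagged
  above.
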