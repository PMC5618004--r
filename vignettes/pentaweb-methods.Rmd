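---
title: "Linking the predator chain to prokaryote growth limitation: models and methods"
author: "pentaweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking the predator chain to prokaryote growth limitation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentaweb)
```

## The scientific question

In cold-water pelagic systems, the heterotrophic prokaryote community can be
limited either by mineral nutrients (phosphate; the **MNL** state) or by
labile organic carbon (the **OCL** state).  Which state the community is in
decides whether it responds to an input of labile carbon such as glucose --
and, downstream, whether the viral community coupled to it responds.
`pentaweb` implements a steady-state theory in which the position of this
switch is set from the *top* of the microbial food web: the standing stock of
ciliates, itself controlled by copepod predation, fixes the prokaryote
biomass and growth rate that the system can sustain, and thereby its carbon
demand.

## The pentagon food web and its closed forms

The model food web has five compartments, all measured in phosphorus units
(nmol-P/L): free phosphate $P$, autotrophic flagellates $A$, heterotrophic
prokaryotes $B$, heterotrophic nanoflagellates $H$, and ciliates $C$, with
copepods acting on ciliates as an external loss.  All consumption is
proportional to food concentration (type-I, bilinear interactions).  Setting
growth equal to loss for $H$ and $A$ gives two closed forms:

$$B = \frac{\alpha_C}{Y_H\,\alpha_H}\,C, \qquad
  P = \frac{\alpha_C}{\alpha_A}\,C,$$

and phosphate-limited prokaryote growth $\mu = \alpha_B P$ becomes
$\mu = \alpha_B(\alpha_C/\alpha_A)\,C$.  Carbon demand is production over
yield, which is quadratic in ciliate biomass:

$$\mathrm{BCD}_P = \frac{\mu B}{Y_{BC}}
  = \underbrace{\frac{\alpha_B\,\alpha_C^2}{Y_{BC}\,Y_H\,\alpha_H\,\alpha_A}}_{k}\,C^2 .$$

Sustainable consumption cannot exceed the labile-DOC supply rate $\psi$, so

$$\mathrm{BCD} = \min(k\,C^2,\ \psi),$$

with the MNL$\to$OCL switch at $C^* = \sqrt{\psi/k}$.  `steadyState()`
evaluates all of these; `crossoverCiliateDensity()` returns $C^*$.  The tie
$kC^2 = \psi$ is classified OCL, so the regime label is right-continuous in
$C$.

Cell counts are bridged to biomass by the phosphorus content per ciliate,
$\sigma$, computed by `ciliatePContent()` from an equivalent spherical
diameter (default 20 µm), a volumetric carbon content (0.13 pg-C/µm³) and
Redfield C:P (106): $\sigma \approx 4.3\times10^{-4}$ nmol-P/cell.  The
temperature dependence of all rate parameters uses a single $Q_{10}$ (1.3);
since $k$ contains three rate constants in the numerator and two in the
denominator, its net temperature factor is $Q_{10}^{(T-T_{\mathrm{ref}})/10}$
to the first power, which is how `bcdCells()` applies it.

### Parameters, units, defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `alphaB` | prokaryote P affinity | 0.08 | L/nmol-P/h |
| `alphaA` | autotroph P affinity | 0.04 | L/nmol-P/h |
| `alphaH` | HNF clearance on prokaryotes | 0.0015 | L/nmol-P/h |
| `alphaC` | ciliate clearance on flagellates | 0.0005 | L/nmol-P/h |
| `yieldH` | HNF yield on prokaryotes | 0.3 | nmol-P/nmol-P |
| `yieldBC` | prokaryote yield on DOC | *configured* | nmol-P/nmol-C |
| `sigma` | P per ciliate cell | 0.00043 | nmol-P/cell |
| `q10`, `tRef` | temperature scaling | 1.3, 17 | --, °C |
| `psi` | labile-DOC supply | *configured* | nmol-C/L/h |

`yieldBC` and `psi` deliberately have **no default**: the steady-state theory
leaves them free, and `foodWebParameters()`/`readFoodWebParameters()` refuse
to run without them.  The shipped example configuration
(`inst/extdata/params_pentagon.yaml`) uses `yieldBC = 0.006` nmol-P/nmol-C --
a bacterial growth efficiency of ~0.3 over a molar biomass C:P of ~50 -- and
`psi = 4.63` nmol-C/L/h, chosen once so that $C^*$ (5 nmol-P/L, about 11.6
cells/mL) sits mid-range of the ciliate abundances the simulator produces.
Both are documented as illustrative choices, not measured constants.

```{r}
params <- readFoodWebParameters(
  system.file("extdata", "params_pentagon.yaml", package = "pentaweb"))
steadyState(c(0, 2, 5, 12.5), params)
```

## The dynamic counterpart

`simulateFoodWeb()` integrates a Lotka--Volterra reconstruction of the same
web (via `deSolve`), used to show that the closed forms are genuine
attractors and to emulate mesocosm enrichment experiments.  The published
theory fixes only the bilinear grazing structure; every closure term we had
to invent is isolated in one internal function (`pentagonRates()`) for
auditability:

* prokaryote growth is a Liebig minimum
  $\mu_B = \min(\alpha_B P,\ Y_{BC}\,\alpha_D D,\ \mu_{\max})$ over a labile
  DOC pool $D$ (nmol-C/L) cleared at rate `alphaD` (default 2e-4), with a
  maximum growth rate `muMax` (default 0.06/h, a cold-water doubling time of
  ~12 h) that only matters during nutrient-pulse transients;
* ciliate yield `yieldC` defaults to `yieldH`; copepods are a fixed specific
  loss on ciliates, or ciliates can be clamped outright
  (`clampCiliates = TRUE`) as the boundary condition for steady-state
  experiments;
* the fraction $(1-Y)$ of every grazing flux, and copepod harvest, are routed
  to an explicit sink pool `S`, so that total phosphorus is exactly
  conserved in a closed run -- a testable invariant rather than an implicit
  leak.

Dosing follows the enrichment protocol: daily impulses of phosphate
(`phosphateDose`, default 100 nmol-P/L/d) and glucose at a Redfield-C
multiple of it (`glucoseMultiplier` × 106 × dose), plus the continuous
supply $\psi$.  For steady-state work a `"continuous"` dosing mode spreads
the same daily amounts evenly; `equilibriumPhosphateSupply()` returns the
supply that sustains a clamped equilibrium.

Two initialisation details matter and are deliberate: under OCL the DOC pool
has a finite equilibrium ($\psi/(\alpha_D B)$) and `equilibriumState()` uses
it, but under MNL supply exceeds demand and DOC accumulates without bound,
so MNL states are initialised organic-C replete (carbon branch comfortably
above `muMax`).  This is what makes the simulated MNL tanks insensitive to
glucose while OCL tanks respond strongly -- the defining contrast of the
theory.

**Equilibration horizon.**  With the reference rates, $\mu^*$ is of order
0.002--0.01/h and the clamped predator--prey transient is a slowly damped
oscillation; trajectories reach the closed forms to better than $10^{-3}$
relative only after roughly 1--2 × 10⁴ h.  The equivalence tests therefore
integrate to $t = 48000$ h (2000 days), a package choice reflecting the
system's intrinsic timescales.

## Synthetic mesocosm experiments

`generateDesign()` reproduces the two standard enrichment layouts: eight
700-L tanks in two four-point glucose gradients (0, 0.5, 1, 3 × Redfield-C;
±Si) and nine 900-L tanks (five-point gradient on NH₄⁺, four-point on
NO₃⁻, all Si-replete), sampled daily over 12 days.
`simulateExperiment()` runs every tank under a clamped low- (0.4 $C^*$) or
high-ciliate (2.5 $C^*$) boundary condition -- the two states of the trophic
cascade -- converts biomass to flow-cytometry-style counts and adds
multiplicative lognormal observation noise (counts are positive and FCM
errors are multiplicative).  Virus counts are a *documented stand-in*: the
dynamic model has no lysis term, so virus group I tracks prokaryote counts
through a virus-to-prokaryote ratio rising linearly with ciliate abundance
from a baseline of 10, and groups II--IV are fixed fractions of group I.

`generateBandMatrices()` emulates gel fingerprints (DGGE-like host bands,
PFGE-like virus bands) with the scale of real gels (~30 host bands, ~20
virus bands, presence probability 0.5): treatment shifts the presence
probability of half the host bands; each virus band either mirrors a mapped
host band (probability `coupling`) or varies independently; bit-flip noise
is applied last; empty lanes are redrawn (at most 100 times, then an
error).  The Bernoulli/flip structure is an explicit modelling choice -- no
distributional description of fingerprint noise exists to copy.

What passing tests on these generators do *not* show: real gels have band
co-migration, intensity thresholds and alignment error; real virus dynamics
are lytic, not ratio-driven; and real tanks share water-mass history.  The
generators make the *pipeline* testable, not the biology.

## Fingerprint statistics

* **Jaccard distances** (`jaccardDistances()`): $1 - |i \cap j|/|i \cup j|$
  on presence sets; undefined for empty fingerprints, which are rejected.
* **NMDS** (`nmdsOrdination()`): Kruskal nonmetric MDS minimising stress-1,
  implemented as SMACOF majorisation alternated with monotone regression on
  dissimilarity ranks (pool-adjacent-violators; primary tie treatment).
  Defaults: $k = 2$ (fingerprint ordinations are conventionally planar), 20
  starts (first metric, rest random), stress tolerance $10^{-7}$, 500
  iterations.  Zero-dissimilarity duplicates are collapsed before embedding
  and share coordinates after it.  Runs are deterministic given `seed`.
* **Procrustes / protest** (`procrustesAnalysis()`, `protestTest()`):
  symmetric scaling (both configurations centred, unit total sum of
  squares); $m^2 = 1 - (\sum_i d_i)^2$ from the singular values of
  $X^\top Y$; correlation $\sqrt{1 - m^2}$; permutation p-values use the
  add-one convention $(1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$
  and so are never zero.
* **PERMANOVA** (`bandPermanova()`): one-factor distance-based pseudo-F from
  the standard partition of squared interpoint distances, label-shuffling
  p-value, default 99999 permutations.  Single-factor fits are used
  throughout (marginal analyses, matching the residual degrees of freedom
  reported for this kind of design).
* **Ensemble** (`nmdsProcrustesEnsemble()`): because one NMDS fit is a
  stochastic optimisation, the coupling evidence is stabilised by repeating
  {fresh NMDS of host, fresh NMDS of virus, protest} -- 1000 times in the
  reference procedure -- and reporting the median p, % of repetitions with
  p < 0.05, and median correlation.  The alternative reading (ordinations
  fitted once, only protest repeated) is exposed as
  `mode = "fixedOrdination"`.  Child seeds are derived deterministically
  from one root seed, and within a repetition the two NMDS fits share one
  random-start stream (common random numbers).  The latter matters on the
  rugged stress landscapes of small binary data sets, where near-tied local
  optima exist: with independently seeded fits, even two ordinations of the
  *same* matrix can disagree purely through optimiser luck, whereas under
  common random numbers identical inputs give identical ordinations
  (correlation exactly 1) and the coupling statistic isolates genuine
  differences between the matrices.  Null calibration under this scheme is
  verified empirically by the test suite.

One statistical caveat is built into the design of the calibration tests:
within one dataset the ensemble's repetitions share the data, so under zero
coupling the per-dataset `pctSignificant` is nearly degenerate (close to 0
or 100).  Nominal 5% behaviour appears -- and is tested -- as an *average
over independently generated datasets*.

## Numerical choices

* Stiff-capable `lsoda` integration; every loss term is proportional to its
  source pool, so the flow is positivity-preserving, and trajectories are
  clipped at tiny negative excursions (beyond $10^{-8}$ of the state scale
  the run is reported as a failure instead).
* The crossover tie goes to OCL; `fitBcdCurve()` optimises
  $(\log k, \log\psi)$ by Nelder--Mead from a data-driven start and flags
  $k$ or $\psi$ unidentifiable when the fitted crossover falls outside the
  observed abundance range.
* NMDS monotone regression orders ties by current configuration distance
  (primary treatment); the Guttman update is stopped rather than accepted
  if stress would increase.
* Procrustes correlations in two dimensions use the closed form
  $\sigma_1+\sigma_2 = \sqrt{\lVert M\rVert_F^2 + 2\,|\det M|}$ for speed in
  permutation loops.

## Known limitations

* The regime theory is a steady-state argument; the package's 12-day
  enrichment simulations show the transient contrast, and their virus
  series are a stand-in, not mechanistic lysis dynamics.
* No silicate/diatom compartment: the ±Si arms of the tank designs are
  carried as metadata only, so Si effects cannot emerge from the dynamics.
* `yieldBC`, `psi`, `alphaD`, `muMax` and the ciliate clamp levels are
  configuration, not estimates; conclusions that depend on their absolute
  values should be treated as illustrative.
* Fingerprint statistics assume aligned, binary band matrices; gel
  processing (band calling, internal-standard normalisation) is upstream of
  this package.
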