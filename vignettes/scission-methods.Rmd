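---
title: "Modeling hydroxyl-radical-induced polymer chain scission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hydroxyl-radical-induced polymer chain scission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scission)
```

## The problem

Water-soluble polymers such as polyethylene glycol (PEG) enter surface
waters in large quantities. Sunlit waters maintain a steady-state pool of
hydroxyl radicals (roughly $10^{-17}$ to $10^{-15}$ M) that attack the
polymer backbone and cleave chains into progressively shorter fragments.
Because microbial degradation of PEG is strongly size dependent, the extent
of radical-induced chain scission is the key quantity linking photochemistry
to biodegradability. This package models that scission process at three
levels — a closed-form kinetic model, a stochastic ensemble simulation, and
an estimator that infers the scission extent of a real sample from
chromatographic data.

## The closed-form model

A monomer unit reacts with the radical with second-order rate constant
$k_M$ (default $2.1 \times 10^9\ \mathrm{M^{-1}s^{-1}}$ for PEG). At
steady-state radical concentration $[\mathrm{OH}]_{SS}$ this gives a
pseudo-first-order rate $k_1 = k_M [\mathrm{OH}]_{SS}$. Assuming every
monomer unit of every chain is equally likely to react, the average number
of scissions per initial chain after time $t$ is

$$\bar{S}(t) = \left(1 - e^{-k_1 t}\right) \cdot
  \frac{\bar{M}_n(t_0)}{M_{\text{monomer}}},$$

the reacted monomer fraction times the initial average degree of
polymerization. Each scission conserves monomer mass and adds one chain, so
the number-average molecular weight decays hyperbolically:

$$\bar{M}_n(t) = \frac{\bar{M}_n(t_0)}{\bar{S}(t) + 1}.$$

`kinetics_profile()` tabulates both quantities; `time_for_scissions()`
inverts the first relation (defined only below the saturation extent
$\bar{M}_n(t_0)/M_{\text{monomer}}$, where the reacted fraction reaches 1).
Internally all times are SI seconds; the command-line interface accepts
`s`/`h`/`d` suffixes. For $k_1 t > 700$ the reacted fraction is evaluated
as exactly 1 to avoid `exp()` underflow.

A caution on narrative cross-checks: direct evaluation of the equations
above at $\bar{M}_n(t_0) = 12$ and $3$ kDa, $[\mathrm{OH}]_{SS} = 10^{-15}$
M and $t = 1$ d gives extents of roughly 45 and 11 — not the 4-to-20 range
sometimes quoted alongside such figures. The package implements the
equations as stated; tabulated outputs, not narrative summaries, are the
contract.

## The stochastic ensemble simulation

The closed-form model predicts averages only. To resolve the full molecular
weight distribution, an ensemble of $m$ chains is evolved one scission at a
time:

1. **Initialization.** Chain lengths follow a normal distribution with mean
   $\lambda$ and spread $\sigma$ (in monomer units), discretized by
   evaluating the density at integer lengths $n \ge 1$ and renormalizing.
   With $\sigma \approx 9$ the difference between point evaluation and bin
   integration is negligible. Counts are assigned by deterministic
   largest-remainder apportionment by default — floor each quota
   $p(n)\,m$, then hand out the remaining chains to the largest fractional
   remainders (ties to the shorter length) — so initialization is
   bit-reproducible; multinomial sampling is available for realism studies.
2. **Selection.** A chain is picked with probability proportional to its
   length-specific rate constant
   $$k(n) = \begin{cases} 0.8\,k_M\,n & n \le 30 \\
   0.8\,k_M\,30\,(n/30)^{0.57} & n > 30,\end{cases}$$
   which is linear while the whole chain is exposed to the solvent and
   sublinear once coiling shields part of the backbone. The 0.8 prefactor,
   breakpoint 30 and exponent 0.57 are taken as given constants and exposed
   as `rate_model()` fields.
3. **Scission.** A bond is chosen uniformly among the $n-1$ inter-monomer
   bonds ("random position along the backbone" is read as uniform over
   bonds, the minimal interpretation, which also makes the per-monomer
   reaction probability uniform along the chain). The chain is replaced by
   its two fragments.
4. **Termination.** After exactly $\mathrm{round}(\bar{S}_{\text{target}}
   \cdot m)$ events (round half up — no rounding convention is canonical,
   so the simplest one is used and the achieved extent is reported
   alongside the request).

Two bookkeeping identities hold *exactly*, for any seed and any rate model:
total monomer mass is conserved, and the final chain count is $m$ plus the
number of events. Together they force the simulated ensemble's
number-average MW to obey the closed-form decay
$\bar{M}_n(t_0)/(\bar{S}+1)$ identically — the Monte Carlo reproduces the
hyperbolic law by construction, and the test suite asserts this at several
extents.

### Design choices

* **State representation.** The engine works on the length histogram with
  per-class weights $m(n)\,k(n)$ rather than on individual chains. This is
  observably identical to tracking chains one by one (a brute-force
  enumeration oracle in the tests asserts the equality of the selection
  distributions) and handles 5000 chains through 40000 events in about a
  second. Individual-chain tracking with parent/child genealogy is used
  only when requested and only below a configurable ensemble size (default
  1000 chains), which covers the small illustrative networks.
* **Monomers are terminal.** Ethylene glycol (length 1) is the final end
  product of the cascade, yet a literal reading of $k(n)$ would assign it a
  nonzero rate. Chains below length 2 are therefore never selectable.
  At extents up to 8 on 145-mer ensembles the monomer pool is tiny, so the
  sensitivity of every reported quantity to this rule is negligible — but
  it is the only self-consistent reading.
* **Replicates.** Replicate $r$ runs with seed `base_seed + r`, so any
  replicate is reproducible in isolation. The 95% envelope is the
  2.5/97.5 percentile across replicates; with 50 replicates this is a
  coarse but honest band.
* **Checkpointing.** Extent grids (trajectories, fit libraries) reuse one
  simulation per replicate with snapshots at each grid value. Events are
  cumulative and the process is Markovian in the ensemble state, so
  checkpoints of one run are statistically equivalent to independent runs
  per grid point, at a fraction of the cost — and they make the fit's SSE
  profile smooth in the grid (common random numbers).
* **Binning.** Weight-percent histograms default to 44 Da bins (one repeat
  unit, so each chain length is its own bin); the width is a parameter
  since no canonical binning exists for the averaged distributions.

## From chromatograms to an experimental curve

The experimental observable is a chromatographic peak table from HPLC with
charged-aerosol detection (CAD) and parallel high-resolution MS. The CAD
response is proportional to analyte mass and independent of MW, so peak
integrals normalize directly to weight percent. Oligomer identities come
from the MS side: an ion at mass-to-charge $m/z$ with charge $z$ is
assigned the repeat-unit count

$$n = \mathrm{round}\!\left(\frac{z \cdot m/z - M_{\text{end}} - z \cdot
M_{\text{adduct}}}{M_{\text{repeat}}}\right),$$

with defaults $M_{\text{repeat}} = 46.05$ Da (the carbon-13-labeled
ethylene-oxide unit), $M_{\text{end}} = 18.01$ Da and $M_{\text{adduct}} =
1.007$ Da per charge. The adduct identity is not documented for the
reference data, so protonation is the default and the assignment reports
its residual — a wrong convention shifts residuals by whole Daltons and is
flagged immediately. Published oligomer labels (e.g. $n = 75$ at 3468 Da)
are not exactly $n \cdot 46.05 + 18.01$; the convention behind such labels
is unstated, which is precisely why the assignment exposes its own.

Chromatographic resolution limits the usable window to roughly 2000–6400
Da. Mass outside it appears only as two lumped integrals. `to_fit_input()`
turns a table into a cumulative wt% curve that starts at the low-MW lump
value and whose final resolved value plus the high-MW lump is 100. The
"below 2000 Da" threshold is applied strictly (`<`), and curves are
evaluated at arbitrary MW by right-continuous step interpolation, since
simulated masses are discrete multiples of 44 Da while experimental masses
are not.

## Estimating the scission extent

`fit_sic()` estimates the scission extent of a sample by grid search:
simulated replicate-averaged cumulative curves are computed over a grid of
extents (default 0 to 8 in steps of 0.1), evaluated at the experimental MW
points — plus the lump intercept at the low boundary and the high-MW
complement at the upper boundary, as two additional uniform-weight
residuals — and the extent minimizing the sum of squared residuals is
returned, ties going to the smaller extent. The published description of
this step ("partial least-squares residual fitting") is ambiguous; plain
least squares on cumulative-curve residuals over the grid is the only
construction consistent with fitting "in increments of 0.1", and is what
this package implements. No special weight is given to the low-MW
intercept, since none is documented.

Because the estimator's truth cannot be re-derived from published
chromatograms (the raw peak tables are not deposited), validation is by
parameter recovery: `generate_fixture_peak_table()` simulates a sample at a
known extent, censors it exactly like a real chromatogram, perturbs every
integral with multiplicative lognormal noise, and `recovery_report()` fits
the fixtures blind. The true extent lives only in a JSON sidecar, never in
the table. At the reference scale (5000 chains, 50 replicates), noise-free
fixtures at extents 1.2, 2.1 and 3.9 are recovered within the 0.1 grid
resolution, and 5% integral noise widens errors to at most about 0.2.

### What the generator does and does not emulate

The fixture generator reproduces the *data reduction* of a censored
oligomer chromatogram: mass-proportional integrals, the resolved window,
the two lumps, and integral-level noise. It does not emulate co-elution,
MW-dependent ionization, the $-2$ Da aldehyde or $+16$ Da hydroxylation
side products seen in real spectra, baseline drift, or integration error
correlated across neighboring peaks. A green recovery test therefore
establishes that the estimator inverts its own forward model under
realistic noise — not that the forward model captures every artifact of a
real instrument.

## Numerical notes and limitations

* Extent-zero curves are deterministic (the apportioned initial ensemble),
  so a sample identical to the initial distribution fits to extent 0 with
  zero residual.
* The grid estimator's resolution is the grid step; no uncertainty beyond
  the replicate envelope and grid spacing is quantified.
* The simulator has no explicit time axis: calendar time enters only
  through the closed-form kinetics, and the two layers are linked by the
  scission extent.
* Photomineralization (carbon loss) is not modeled; summed integrals are
  conserved by construction, matching the observation that radical
  treatment redistributes rather than removes polymer mass.
* The default generator parameters — 5000 chains, mean 6380 Da, spread 400
  Da, monomer 44 Da — are the reference experimental system; tests that
  need speed reduce the chain count and replicate number and say so, while
  the acceptance checks run at the reference scale.
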