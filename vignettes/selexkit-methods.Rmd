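---
title: "Models and methods behind selexkit"
author: "selexkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind selexkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexkit)
```

selexkit implements the analytical stack of a parallel-and-serial SELEX
campaign: tracking a motif-defined aptamer family through selection rounds
from sequencing reads, estimating pool and aptamer affinities from
gel-elution and ITC data, and calibrating a dye-displacement colorimetric
assay. This vignette explains the models, the conventions the package
commits to where the underlying experiments leave room, and what the
synthetic-data generators do and do not emulate.

## Pool enrichment from sequencing reads

The selection library is a 73-nt stem-loop: a 30-nt randomized loop flanked
by 8-nt stem halves and primer-binding regions. `trim_to_random_region()`
recovers the loop by exact substring matching of the two flanks (first
occurrence of the forward flank; the reverse flank must follow immediately
after the 30-base extraction). Reads failing either match, or yielding a
region of the wrong length, are discarded and counted in the trim report.

Conventions committed to here:

* **Exact flank matching by default.** No mismatch tolerance is assumed;
  a Hamming-distance option (`max_mismatch`, no indels) exists for noisier
  chemistry. Exactness makes the trimmer's behaviour fully predictable on
  generated fixtures.
* **No quality filtering, no reverse-complement rescue.** Reads are used
  as-is; the discard count in the report is the diagnostic surface.
* **Sequence identity is exact string equality.** The family concept used
  downstream is motif containment, not cluster membership, so no
  clustering or error-correction is layered on top.
* **All fractions are over trimmed reads.** Whether pool percentages
  should be quoted against raw or trimmed totals is ambiguous in
  gel-to-sequencer workflows; selexkit consistently uses trimmed reads as
  the denominator (the trim report preserves the raw total).

`count_pool()` collapses exact duplicates into unique sequences with
fractions and reads-per-million; ranked output sorts by reads descending
with lexicographic tie-breaks, so tables are bit-reproducible.
`family_fraction()` sums fractions of sequences containing the family
motif (sense strand, any offset). `combine_pools()` models physical
mixing: the combined fraction of a sequence is the weight-averaged
per-pool fraction, with equal weights for equimolar combination.
`pool_summary()` reports the 5th/50th/95th percentiles of the
per-unique-sequence fraction distribution using linear interpolation
between closest ranks (`stats::quantile` type 7); the convention is fixed
so that an independent sort-and-interpolate oracle reproduces it exactly.

## Gel-elution statistic and Langmuir affinity

The gel assay immobilizes the pool on beads, elutes with target, and
quantifies two bands: supernatant (target-eluted strands, concentration
$c_s$) and formamide-released remainder ($c_b$). The eluted percentage is

$$\theta = 100\,\frac{V_1 c_s}{V_2 c_s + V_3 c_b}$$

with default volumes $(V_1, V_2, V_3) = (62, 40, 80)\ \mu$L; $V_1$ already
discounts the bead volume, mirroring the assay's standard geometry, and
all three are configurable per observation. Because the volume model and
band quantification are measured independently, $\theta > 100\%$ is
arithmetically possible; the function warns rather than errors, and the
Langmuir fitter accepts fractions up to 1.6 accordingly.

`fit_langmuir()` fits $\theta(c) = \theta_{max}\, c/(K_D + c)$ by
nonlinear least squares with $\theta_{max}$ free, because an enriched pool
is a mixture in which only a subpopulation binds: forcing
$\theta_{max} = 1$ would bias $K_D$ upward. A `fix_theta_max` argument
covers the pure-aptamer case. $K_D$ is optimized on the log scale with
deterministic multi-start (0.1x, 1x, 10x the median positive
concentration); standard errors are asymptotic, with the delta method
mapping the log-scale error back to micromolar. Data with no spread across
concentrations are rejected as unidentifiable rather than fitted.

## ITC: single-site and racemic competitive models

### Equilibrium core

The one-site bound concentration is the smaller root of the mass-action
quadratic, evaluated in the cancellation-safe form
$2 S L / (b + \sqrt{b^2 - 4SL})$ with $S = N M_t$ and $b = S + L + K_D$.
For two ligands competing for one site class, the free-site concentration
$S_f$ satisfies the monotone site balance
$S_f + \sum_j S_f L_{j,t}/(K_{Dj} + S_f) = N M_t$, solved by safeguarded
bisection plus Newton polishing until the mass balances hold to $10^{-9}$
relative. Both solvers are verified in the test suite against brute-force
bisection and nested-bisection oracles that share no code with them.

### Heat model and dilution convention

A fixed-volume (overflow) calorimeter cell is assumed. Each injection of
volume $v_i$ dilutes all cell contents by $f_i = V_0/(V_0 + v_i)$ and the
injected titrant enters at $X_{syr} v_i/(V_0 + v_i)$. The heat of
injection $i$ is

$$q_i = V_0 \sum_j \Delta H_j \left([\mathrm{ML}_j]_i - f_i\,[\mathrm{ML}_j]_{i-1}\right) + b$$

in µJ (µM, µL, kJ/mol), where $b$ is a constant per-injection
dilution-heat offset. The $f_i$ factor reflects that complex expelled by
overflow released its heat when it formed: at saturation
$[\mathrm{ML}]_i = f_i [\mathrm{ML}]_{i-1}$ and tail heats vanish, and the
cumulative heat approaches $N M_{t,0} V_0 \Delta H$ when the sites
saturate before significant unbound aptamer has been expelled. The plain
concentration difference (without $f_i$) would instead predict nonzero
tail heats of the wrong sign after saturation. The instrument cell volume
defaults to $V_0 = 1400$ µL, the scale on which a 25 x 10 µL schedule is
a standard run; it is configurable in `itc_experiment()`.

### Fitting strategy

In both models the enthalpies and the baseline enter the heat linearly.
The fitters exploit this by variable projection: for any trial values of
the nonlinear parameters — $(N, K_D)$ for one site,
$(N, K_{D,-}, K_{D,+})$ for the racemic model — the linear parameters are
solved exactly by least squares, and only the nonlinear ones are optimized
(`nlminb` on log scales, relative tolerance $10^{-15}$). Multi-start is
deterministic: one-site starts span $K_D$ decades around the cell
concentration; the racemic fitter starts from a one-site pre-fit with its
$K_D$ split by $\pm 1.5$ decades (and two one-sided splits). Standard
errors come from the numeric Jacobian over the full parameter vector at
the optimum. Noiseless round trips recover parameters to $10^{-6}$
relative or better; identifiability guards reject flat isotherms, and the
racemic fitter warns when the two fitted affinities are within a factor
of five, where the decomposition becomes fragile.

The racemic model fixes the enantiomer fraction $\phi = 0.5$ (a racemate
by definition); fitting $\phi$ is deliberately not a default, since
$\phi$ trades off against the $\Delta H$ split. With $\phi = 0.5$ the two
components are exchangeable, so results are reported with
$K_{D,-} \le K_{D,+}$. An option drops the customary unreliable first
injection; the default keeps all injections because simulated data have
no first-injection artifact.

`correct_dilution()` offers two baseline estimators: the trailing mean of
the last $k$ injections (default $k = 3$; exactly idempotent), and a
geometric-tail fit $b + a r^i$ over the trailing half of the schedule,
which tolerates residual binding heat in the tail. Both record their
estimate and method on the returned isotherm.

## Dye-displacement assay

Aptamer-bound Cy7 monomer absorbs near 775 nm; target displaces the dye,
which dimerizes in solution and absorbs near 670 nm. Signal gain is
defined as the relative change of the ratio $R = A_{670}/A_{775}$ against
the no-target blank, $G = 100 (R - R_0)/R_0$ — the relative form is the
default because gain-versus-concentration curves are anchored at zero in
the blank; the absolute difference $R - R_0$ is available via
`relative = FALSE`. Blanks are per matrix (buffer, diluted urine or
saliva) and never shared across matrices. Cross-reactivity is a ligand's
gain as a percent of the reference target's gain, exactly 100% for the
reference by construction.

`fit_dye_affinity()` fits the exact ligand-depletion (quadratic) 1:1
isotherm to an aptamer-into-dye titration. At micromolar dye
concentrations comparable to $K_D$, the hyperbolic (no-depletion)
approximation is measurably biased — the test suite quantifies this — so
the quadratic form is the model, with the signal endpoints profiled out
linearly and $K_D$ optimized on the log scale. Fits whose $K_D$ standard
error exceeds 50% are flagged low-confidence, which is the expected
outcome when $K_D$ lies far above the titrated range.

`fit_calibration()` regresses gain on concentration inside the declared
linear range and operationalizes the limit of detection as the
concentration whose predicted gain reaches blank mean + 3 blank SD,
solved from the fitted line; on noiseless linear data this reduces
exactly to $3\sigma_{blank}/\mathrm{slope}$. When curvature or offset
pushes the fitted intercept above the blank criterion, the solved LOD
degenerates; the function then warns and falls back to the
blank-referenced closed form. An alternative rule — the lowest tested
concentration significantly above blank by a one-sided Welch test —
is available via `lod_rule = "lowest_tested"`. At least three blank
replicates are required, since the blank SD is the whole basis of the
criterion.

## Synthetic-data generators

The generators exist so that every pipeline stage is exercisable, with
known truth, from a seed:

* `make_pool()` draws read-category counts from a multinomial over
  (spiked families, uniform background), embeds each 30-mer in the design
  flanks, corrupts a stated fraction of reads by truncating the forward
  flank, and shuffles read order. The truth manifest records per-family
  drawn and surviving counts, so expected downstream statistics are exact.
* `make_round_series()` strings pools into an ordered round series with a
  prescribed family-fraction trajectory.
* `make_assay()` forward-simulates the gel, ITC and dye models through the
  package's own simulators, adding seeded Gaussian noise; its truth
  manifest carries the generating parameters.

Everything is deterministic under a fixed seed (byte-identical FASTQ).
The flank sequences are synthetic stand-ins, recorded in every manifest;
analyses of real reads take the lab's own design. Read qualities are
constant placeholders because the pipeline ignores them.

What the generators do **not** emulate — and hence what passing tests do
not certify about real data: sequencing error (including the
homopolymer-indel profile of semiconductor sequencing), PCR amplification
bias, selection dynamics between rounds (round fractions are prescribed,
not evolved), correlated background sequence composition, instrument
drift in ITC power traces (inputs are integrated heats), and spectral
overlap beyond the two-wavelength absorbance readout.

## Numerical choices and degenerate inputs

* Equilibrium solves: bisection/Newton to $10^{-9}$ relative mass
  balance; non-convergence is an error with diagnostics, never a silent
  approximation.
* All nonlinear fits use deterministic multi-start; seeds affect only
  noise generation, never optimizer paths.
* Degenerate inputs fail loudly: empty pools, flat isotherms, flat
  elution curves, flat dye responses, missing blanks, reference ligands
  with non-positive gain, duplicate ligand labels.
* Ranked tables break ties lexicographically; TSV output rounds to six
  significant digits and round-trips exactly (write-read-write is a fixed
  point).

## Problem sizes

The test suite and the acceptance script choose sizes that keep full runs
in the minutes range while leaving sampling error far below the assertion
bands: property tests use pools of $10^3$–$5\times10^4$ reads with 100
seeded replicates where distributional claims are made; the enrichment
trajectory check uses $5\times10^5$ reads per round (3 multinomial SD of
a 29% spike at that depth is 0.2 percentage points); the full-size
final-pool check uses the study's 1,575,678-read pool total. Noise
studies use 100–200 seeded replicates per scenario. The analysis drivers
under `analysis/` use $2\times10^5$ reads per round as a compromise for
interactive use.

## Known limitations

* The trimmer's first-occurrence flank matching can, with vanishing
  probability, match a spurious flank copy inside the random region.
* The competitive ITC model assumes one shared site class ($N$ common to
  both enantiomers) and a fixed titrant composition; supplementary
  parameterizations with per-component stoichiometries are out of scope.
* Elution observations above 100% are carried (with a warning) rather
  than truncated, so volume-model mismatch propagates visibly into fits.
* The dye model treats the two dye states as linearly mixing absorbance
  endpoints; no monomer/dimer spectral deconvolution is attempted.
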