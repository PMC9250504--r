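---
title: "Finding minimal EEG electrode subsets that retain source-localization accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding minimal EEG electrode subsets that retain source-localization accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegselect)
```

## The problem

High-density EEG (200+ electrodes) gives the most accurate estimates of
where in the brain a measured signal originates, but most practical systems
carry far fewer channels, and electrodes are conventionally placed for scalp
coverage rather than for the activity actually being monitored. `eegselect`
answers a concrete question: *for a given brain source (or set of sources),
which small subset of electrodes retains the localization accuracy of the
full high-density montage?*

The search is posed as a multi-objective optimization over binary channel
chromosomes. For `s` sources there are `s + 1` objectives, all minimized
jointly: the number of selected channels, and the localization error of each
source. An elitist genetic algorithm (NSGA-II: non-dominated sorting,
crowding distance, binary tournaments) proposes channel subsets; each
candidate is scored by zeroing the excluded channels of the measured EEG,
solving the inverse problem with the *full* lead-field operator, and
measuring how far the reconstructed activity peak lands from the known
source position. Exhausting all subsets of a 128-channel montage would take
about `2^128 - 1 ≈ 3.4e38` inverse solutions; the genetic search needs a few
tens of thousands.

## The model chain

**Forward model.** Scalp data follow the linear model `y = M x + ε`, with
`M` the d × n lead field mapping unit cortical source amplitudes to
electrode potentials. The package ships a deterministic analytic head model
(`build_spherical_leadfield()`): three concentric shells representing brain,
skull and scalp (default radii 80/86/92 mm, conductivities
0.33/0.0042/0.33 S/m), electrodes quasi-uniform on the scalp sphere by a
seeded golden-angle layout, and radially oriented sources on a 71 mm
cortical sphere. The potential of a radial dipole in this geometry has an
exact Legendre-series solution; per degree, the interior and shell
expansions are matched at both interfaces (continuity of potential and of
radial current) under a zero-current outer boundary, with per-shell scaled
bases so the matching systems stay well conditioned at high degree. The
series is truncated at order 100 by default; with the default geometry the
skull's low conductivity damps high degrees so strongly that the truncation
error is below ~1e-8 relative (the test suite compares against a 4× deeper
truncation, and against the homogeneous-sphere closed form when all three
conductivities are equal). Realistic head models converted to the
documented plain-text archive layout (`write_leadfield_archive()` /
`load_leadfield()`) can be dropped in; by convention a dense `high` grid is
used for forward simulation and a coarser `inverse` grid for
reconstruction, so the inverse solver never works on the grid that
generated the data.

**Ground-truth simulator.** Each trial contains six transient oscillatory
sources with Gaussian-windowed sinusoid time courses
`x(t) = exp(-((t - c)/σ)²/2) · sin(2π f t)`: an occipital 19 Hz source at
c = 0.5 s, a sensorimotor 10 Hz source at c = 1 s, a frontal 7 Hz source at
c = 1.5 s, and repeats of the same three locations/frequencies at 2, 2.5 and
3 s that act as structured interference. The window width σ = 0.12 s makes
adjacent sources overlap in time. Per trial, each region's source position
is drawn uniformly from a predefined set of 12 candidate vertices (6 per
hemisphere); on the spherical fixture these sets are the most posterior,
most superior and most anterior source vertices, respectively. Trials last
3.5 s at 200 Hz (700 samples). White Gaussian channel noise is added and
then rescaled so the realized SNR — the ratio of mean squared clean signal
to mean squared noise, pooled over all channels and samples — exactly equals
the configured target (0 dB by default, i.e. signal and noise with the same
power). Exact rescaling removes between-trial noise-level jitter, which
keeps paired subset-vs-baseline comparisons clean. The default dataset is
150 such trials (`generate_dataset()`).

What the simulator does *not* emulate: ongoing background EEG (pink noise,
alpha rhythm), spatially correlated noise, artifacts, or realistic cortical
geometry. Passing tests therefore demonstrate correctness of the machinery
and the qualitative behavior of the method, not clinical-grade error levels.

**Inverse solvers.** Two distributed linear solvers are built in, both
authored here and cross-checked in the tests against dense closed-form
evaluations:

* `wmne()` — depth-weighted minimum-norm estimation,
  `x̂ = W⁻¹Mᵀ(MW⁻¹Mᵀ + λI)⁻¹y` with `W = diag(‖m_i‖^(2·γ))` built from
  lead-field column norms. The depth exponent γ (default 1, range 0–2)
  compensates the bias of minimum-norm solutions toward superficial
  sources; γ = 0 recovers plain Tikhonov MNE.
* `sloreta()` — the minimum-norm estimate standardized by the square root
  of the resolution-derived variance `R = Mᵀ(MMᵀ + λI)⁻¹M`. For a single
  noiseless dipole the standardized power peaks exactly at the true vertex
  (a Cauchy–Schwarz consequence that holds for any λ ≥ 0), which the suite
  verifies exhaustively over the fixture source space.

Because the regularization strength used in comparable studies is typically
unreported, λ defaults to an SNR-based rule, `λ = trace(G)/(d·10^(SNR/10))`
with `G` the data-space Gram matrix of the solver and SNR defaulting to the
simulator's 0 dB; a fixed λ can be forced. Noise covariance is assumed
identity (matching the simulator's white noise), so no whitening is
applied. A reference choice is exposed: the default applies no re-referencing,
because candidate evaluation encodes discarded channels as all-zero rows
and an average-reference projection would re-inject a nonzero time series
into every excluded channel; set `reference = "average"` to restore the
common convention when solving ordinary (unweighted) epochs. Additional
solvers can be attached through `register_solver()` without touching the
pipeline.

**Metrics.** Localization error is the Euclidean distance (mm) between the
true source position and the position of the source with the highest
reconstructed power averaged over a time-of-interest (TOI). TOIs convert to
half-open sample windows `[round(start·fs), round(end·fs))`, so a boundary
instant shared by two windows is counted once, in the later window; power
ties break to the lowest vertex index. Waveform fidelity across montages is
measured by relative error and Pearson correlation between the peak-vertex
time courses, with no sign alignment applied. The accuracy index of a
subset is the percentage of trials whose subset error is *equal to or
lower* than the paired all-channel baseline error — exact `≤` on floating
millimetre values, ties counting as success.

## The optimization loop

`run_optimization()` wires the pieces together for one trial: NSGA-II
(population 100, 400 generations, crossover probability 0.9, mutation
probability 1/C by default) proposes chromosomes; `weight_eeg()` zeroes the
excluded rows; the precomputed inverse operator (built once per run — the
operator depends only on the lead field and solver, not on the chromosome)
reconstructs the sources; per-source TOI localization errors complete the
objective vector. Every evaluated candidate is logged with its generation;
duplicate chromosomes are served from a cache keyed on the decoded
bitstring but still logged, so a run of P × G generations always logs
exactly P·G offspring evaluations (the initial population is logged as
generation 0). From the complete log, `extract_pseudo_pareto()` keeps the
best candidate per channel count, ranked by the unweighted mean of the
per-source errors; ties break by earliest generation, then lexicographically
smallest bitstring. `summarize_dataset()` aggregates fronts across trials
into per-channel-count means, sample standard deviations (n − 1
denominator) and accuracy indices.

Design points that were genuinely open, and how they were settled:

* **Binary genes under real-coded operators.** Simulated binary crossover
  and polynomial mutation are real-coded operators; applying them to binary
  channel genes requires a representation choice. The default (`encoding =
  "real"`) maintains real gene proxies in [0, 1] and thresholds at 0.5 when
  decoding, reproducing the behavior of the widely used adapted real-coded
  NSGA-II solvers. A consequence worth knowing: with distribution index 20,
  polynomial mutation flips a bit only when the perturbation crosses the
  0.5 threshold — about once per 22 mutated genes on average (the suite
  checks this rate against its analytic value) — so exploration is driven
  mostly by crossover and needs the full evaluation budget. The alternative
  `encoding = "binary"` (uniform crossover + bit-flip mutation) explores
  small montages much faster at equal budget; the scaled-down test suites
  use it for the stochastic recovery and plateau checks, whose GA budgets
  (population 60–100, 100–200 generations) were sized so that repeated
  seeded runs reliably reach exhaustive-optimal fronts on an 8-channel
  instance.
* **Degenerate chromosome.** The all-zero chromosome would make the
  weighted EEG identically zero; it receives objectives `(0, 10⁶ mm, …)` so
  it never survives selection, keeping the operator pipeline uniform.
* **Montage constraints.** Restricting the search to a sub-montage (e.g. a
  60-electrode 10–10 subset of a 231-channel layout) clamps the excluded
  genes to zero rather than shrinking the matrices: the inverse operator
  always retains all channels of the head model, which avoids re-factorizing
  per candidate and avoids worsening the conditioning of the inverse
  problem.
* **Baseline in the front.** The all-channel baseline chromosome is always
  evaluated and logged as a generation-0 row, so the front is defined at
  the full channel count in every run and the baseline comparison uses
  exactly the same code path as any candidate.
* **Front scope.** The best-per-count extraction scans *all* generations
  (not only the final population); a final-population front can be obtained
  by filtering the log before extraction.

## What the scaled-down experiments show

The test suite replicates the method's qualitative signature at desk scale
(32-channel spherical montage, 150-vertex inversion grid, 20 single-source
0 dB trials, the problem sizes chosen to keep a full run in tens of
seconds): the per-channel-count front flattens from a handful of channels
onward, and over the 5–16 channel range its mean localization error does
not exceed the all-channel baseline's — the plateau that motivates using
optimized low-density subsets in the first place. On an 8-channel instance,
where all 255 subsets can be enumerated, seeded GA runs recover the
exhaustive-optimal front at every channel count in at least 19 of 20
seeds. At intermediate counts above the plateau's onset the exact-count
front can sit *above* the baseline when search effort concentrates on few
channels — the same effect reported for full-scale runs, where most
evaluated combinations lie in the first third of the channel range.

## Known limitations

* The spherical fixture's absolute error levels are not comparable to
  FEM/BEM head models; only behavioral patterns transfer.
* Lead-field archives are plain text; HDF5 containers of published models
  must be converted externally (the field-name mapping is documented in
  `load_leadfield()`).
* Bayesian sparse-prior solvers are not included; the dispatcher accepts
  registered plug-ins instead.
* Per-trial GA runs are independent and seeded; parallelism across trials
  is left to the caller (results do not depend on scheduling order).
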