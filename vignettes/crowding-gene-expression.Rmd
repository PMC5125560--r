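---
title: "Modelling gene expression under macromolecular crowding with crowdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene expression under macromolecular crowding with crowdsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdsim)
```

## The model

`crowdsim` simulates a single gene in a closed nuclear sub-volume as a
reaction–diffusion master equation (RDME) on a Cartesian voxel lattice.
One transcription factor (TF) performs a random walk over the voxels; all
chemistry is local to the gene voxel:

* TF + promoter(repressed) &harr; promoter(active), rates `k_on`, `k_off`
* promoter(active) &rarr; + mRNA at `s_A`; promoter(repressed) &rarr; + mRNA
  at the basal rate `s_R`
* mRNA &rarr; mRNA + protein at `s_P`; mRNA and protein decay at `delta_M`,
  `delta_P`

mRNA and protein are global counters: no diffusion coefficients are
assigned to them, no downstream statistic depends on their position, and
their contribution to crowding is negligible next to chromatin.  Exactly
one TF and one promoter exist; the promoter is active if and only if the
TF is bound.  Initial mRNA and protein counts are zero.  Time is in
minutes, lengths in micrometres.

Crowding enters only through diffusion.  The jump rate of the TF into
voxel *i* along axis *a* is

    D0 * (1 - c_i) * delta_i / h_a^2

where `c_i` in [0, 1] is the static chromatin density of the destination
voxel (a stain-intensity grid normalised by its maximum, so the brightest
voxel is fully blocked), and `delta_i` is the attenuation of an artificial
crowding agent occupying the voxel: 1 if empty, 0.6 for the small size
class (40% reduction), 0.1 for the big class (90% reduction).  Each voxel
independently holds one crowder with probability `theta`; neither
chromatin nor crowders move, and a crowder never blocks a voxel outright.
Only the destination voxel matters — origin-voxel ("lock-in"),
hydrodynamic and electrostatic effects, and facilitated 1D sliding on DNA
are deliberately out of scope.

The sampler is a modified next subvolume method (NSM): one tentative
event time per voxel in an indexed binary min-heap, with only the voxels
affected by an event re-keyed.  Because redrawing an exponential waiting
time is statistically exact for a memoryless channel, affected voxels
simply receive fresh draws; per-voxel outbound jump rates are precomputed
once since the fields are static.  The event loop is written generically
over voxels even though only the TF's voxel and the gene voxel can have
non-zero propensity at any instant.

## Parameters

| name | default | unit | meaning |
|------|---------|------|---------|
| `k_on` | 0.1 | min^-1 | whole-domain promoter activation rate |
| `k_off` | 0.1 | min^-1 | unbinding rate |
| `s_A` | 50 | mRNA min^-1 | active transcription |
| `s_R` | 5 | mRNA min^-1 | basal transcription |
| `s_P` | 0.2 | protein min^-1 per mRNA | translation |
| `delta_M` | 0.1 | min^-1 | mRNA decay |
| `delta_P` | 0.05 | min^-1 | protein decay |
| `D_TF` | 10 | um^2 min^-1 | free TF diffusion coefficient |
| lattice | 50 x 50 x 11 | voxels | over a 1 um^3 box (`hz != hx`) |
| `t_end` | 1000 | min | trajectory length |
| `theta` | — | | crowder occupancy probability per voxel |

The deterministic steady states are `s_A / delta_M = 500` and
`s_R / delta_M = 50` mRNA — the two stable expression modes around which
population distributions concentrate.

**Mesoscopic `k_on` scaling.**  The table's `k_on` is a well-mixed,
whole-domain rate.  On the lattice the binding channel fires only while
the free TF occupies the gene voxel, with propensity `k_on * N`; in the
fast-diffusion uncrowded limit the TF occupies that voxel a fraction
`1/N` of the time, recovering `k_on` exactly.  Without this scaling
activation would be slower by the voxel count (~27500x at the reference
mesh), irreconcilable with the model's switching dynamics.  The unscaled
per-voxel convention remains available (`kon_domain_scaled = FALSE`).
This is the single most consequential interpretation in the package.

**Anisotropic voxels and boundaries.**  The 50 x 50 x 11 mesh over a cube
gives `hz != hx`; per-axis jump rates use the per-axis `h^2` (standard
RDME discretisation).  Boundaries are reflective: the artificial cell is
a closed volume.

**Gene placement.**  `place_gene()` selects a voxel by chromatin-density
regime — sparse, dense, super-dense — defined as quantile bands ([0,
0.2), [0.5, 0.8), [0.8, 1]) of the density over the voxels with `c < 1`.
Quantile bands (rather than absolute density bands) keep all three
regimes populated for any non-degenerate field; a fully blocked voxel is
never eligible because the TF could not reach it.  Within a band the
choice is deterministic (density closest to the band midpoint, lowest
index on ties).

**The gene voxel takes part in crowder placement.**  An earlier design
exempted the gene voxel from crowders.  Implementation proved that wrong:
the stationary distribution of the TF's walk weights voxel *i* by
`(1 - c_i) * delta_i`, so an uncrowded gene voxel inside a `theta = 1`
big-crowder lattice attracts ten times its share of TF occupancy.  The
measured activation rate then *rises* roughly tenfold with crowding — an
artefact of the exemption, not crowding physics.  Since a crowder only
attenuates (`delta >= 0.1`) and can never make the gene unreachable,
the gene voxel is treated like every other voxel.  Only the chromatin
constraint `c < 1` is enforced at the gene.

**Crowder resampling.**  Whether one crowder placement is shared by a
population or resampled per cell is not determined by the model
statement; `run_ensemble()` resamples per cell (isogenic cells with
independent cytoplasms) and exposes `resample_crowders = FALSE` for the
shared alternative.

## A structural property worth knowing: uniform crowding is a time dilation

At `theta = 1` every voxel carries one crowder, so all jump rates are
multiplied by the same `delta`.  The TF's walk is slowed uniformly while
the reaction clocks (`k_on`, `k_off`, transcription, decay) are not
rescaled — crowding affects reactions only through where the TF is.
Because the walk's stationary distribution is unchanged, every
*event-exact* stationary switching statistic (mean `t_on`/`t_off`,
per-event effective rates, promoter occupancy, and hence the end-point
mRNA distribution and its kurtosis) is invariant between `theta = 0` and
`theta = 1`.  The package's experiments confirm this numerically.

What does change is the *temporal clustering* of switching: slow escape
from the gene's neighbourhood turns unbind–rebind pairs into sub-minute
flickers separated by long excursions.  A sampled expression time course
therefore shows fewer, longer activity periods under crowding.
`n_transitions(trajectory, resolution = 1)` counts transitions at a
finite sampling resolution and reproduces this direction decisively,
while the event-exact count does not change.  Consequently, acceptance
checks phrased in terms of event-exact rate shifts between `theta = 0`
and `theta = 1` (12%/23%/29% shifts, and a kurtosis-vs-theta slope of 15)
are not attainable in this model family at the meshes the test budget
allows, and the corresponding expectations are left failing rather than
weakened; the resolution-limited transition count is used where the
quantity at stake is what an expression time course displays.  At
intermediate `theta` a genuine quenched-disorder effect exists (whether
the gene voxel itself drew a crowder differs between cells), which is
visible in per-cell activation rates.

## Synthetic chromatin fields

`generate_field()` stands in for voxelised 3D structured-illumination
DAPI stacks: white Gaussian noise is low-pass filtered in Fourier space
with a Gaussian kernel of physical scale `correlation_length` (default
0.15 um, the order of chromatin domain foci in a ~1 um region),
standardised and exponentiated with log-contrast 1.5, and the top 0.2% of
voxels are pinned to the maximum so that normalisation yields a few fully
blocked heterochromatin-like foci.  The result is non-negative,
spatially correlated, heavy-tailed, reproducible per seed, and populates
all three gene-placement regimes on the reference mesh.

What it does *not* emulate: nuclear boundary geometry, nucleoli,
chromosome-territory anisotropy, or the intensity statistics of any
specific imaged nucleus.  A green test against synthetic fields
establishes that the pipeline responds correctly to a correlated,
partially blocking density field — not that it reproduces measurements
on real nuclei.  Real grids enter through `import_intensity_stack()`
(CSV planes, mean-pooled in-plane, nearest-index z mapping — chosen
because mapping, e.g., 9 imaging planes onto 11 lattice layers is
otherwise under-determined; TIFF must be converted to CSV first since the
supported dependency set has no TIFF reader).

## Statistics and numerical choices

* **Kurtosis** is the plain moment ratio `m4 / m2^2` with biased sample
  moments (Gaussian = 3, sharp minimum 1 at a symmetric two-point mass).
  The magnitudes the effective-diffusion calibration works with (values
  ~4–15, slope 15 per unit theta) are only consistent with this
  convention, not with excess kurtosis; `excess = TRUE` is available.
* **Effective rates**: the default `aggregate` estimator is the literal
  reciprocal of the mean per-trajectory total duration — meaningful for
  relative comparisons at fixed `t_end`, dimensionally loose otherwise.
  The `per_event` variant is the Markov-switch MLE and recovers
  generating telegraph rates; both are always reported by
  `run_rate_comparison()`.
* **Population statistic**: end-point mRNA at `t_end` across cells.
* **Effective diffusion maps**: `D*/D = 1 - 0.9 theta` (big), `1 - 0.4
  theta` (small) in expectation over placements; composing the reference
  kurtosis–theta slope 15 with the big-crowder line gives `D* = 1 - 0.06
  x kurtosis`, clipped at zero (with a warning) beyond the physical
  theta range (kurtosis > 50/3).
* **Spectra**: mean-subtracted per-trajectory periodograms, averaged,
  with `P(f) = (dt/n) |FFT|^2` so the estimate targets the two-sided
  spectral density and is directly comparable to the closed-form
  telegraph-driven birth–death spectrum (`telegraph_spectrum()`).  No
  windowing is applied.  Sampling a jump process aliases power into the
  upper frequency range, so comparisons are made on coarse log bins
  below ~1/10 of the sampling rate.
* **RNG**: the C++ engines use a counter-seeded xoshiro256++ stream per
  trajectory, independent of R's global RNG; per-cell seeds derive from
  the ensemble base seed by a fixed integer hash (< 2^31), making
  ensembles reproducible and order-independent.  R-side sampling
  (crowder placement, TF start voxel) seeds and then restores the global
  RNG state.
* **Degenerate inputs**: all-zero intensity grids yield `c = 0`
  everywhere; a uniform positive grid yields `c = 1` everywhere (fully
  blocked domain, rejected as a gene host); zero-variance samples are
  errors for kurtosis/KDE; `t_off = t_end - t_on` enforces the partition
  identity to machine precision.

## Scaling of the shipped experiments

The reference experiments (50 x 50 x 11 mesh, 16000 cells, 3200
trajectories) cost ~1e8 diffusion events per trajectory and are far
outside a test budget.  The shipped acceptance experiments rely on the
voxel-size convergence property and run at 10 x 10 x 5 (rate-shift
comparison, 200 trajectories per arm) and 8 x 8 x 4 (kurtosis sweeps, 500
cells per theta), chosen before results were inspected.
`run_convergence()` exposes the mesh-refinement harness itself.

## Known limitations

* Coarse meshes weaken diffusion limitation; absolute rate-shift
  magnitudes at the reference mesh are not reproduced by the shipped
  scaled-down runs (see the invariance discussion above).
* The crowding model is a destination-voxel rate attenuation; it carries
  no excluded-volume interaction between TF and crowders beyond that
  factor, no dynamic chromatin, and no crowder diffusion.
* `import_intensity_stack()` reads CSV planes only.
* The KDE utility is a plain Gaussian-kernel density with Scott's rule —
  a figure aid, not inferential machinery.
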