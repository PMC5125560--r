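# crowdsim

Spatial stochastic simulation of single-gene expression in a crowded
nuclear volume, for researchers studying how macromolecular crowding and
chromatin architecture shape transcriptional noise across a cell
population.

A transcription factor (TF) random-walks over a Cartesian voxel lattice
(default 50 × 50 × 11 voxels over a 1 µm³ box) searching for its gene.
Binding/unbinding switches the promoter between a repressed and an
active state, which transcribe mRNA at `s_R` = 5 and `s_A` = 50 min⁻¹;
mRNA decays at `δ_M` = 0.1 min⁻¹ and is translated at `s_P` = 0.2 min⁻¹
per transcript.  The two deterministic expression modes are
`s_R/δ_M` = 50 and `s_A/δ_M` = 500 mRNA.  Crowding attenuates the TF's
jump rate into voxel *i* along axis *a*:

    k(i, a) = D_TF · (1 − c_i) · δ_i / h_a²

with `c_i ∈ [0, 1]` the normalised chromatin (stain-intensity) density of
the destination voxel (the brightest voxel is fully blocked) and `δ_i`
the factor of an artificial crowding agent occupying it with probability
θ per voxel: 1 (empty), 0.6 (small crowder, 40 % reduction), 0.1 (big
crowder, 90 % reduction).  The sampler is a modified next subvolume
method (exact event-driven RDME sampling, C++ core, ~10⁷ events/s).

On top of the simulator the package provides the full analysis pipeline:
event-exact t_on/t_off switch statistics and effective rate constants
(k₊ ≈ ⟨t_off⟩⁻¹, k₋ ≈ ⟨t_on⟩⁻¹, and a per-event maximum-likelihood
variant), population mRNA kurtosis (`m₄/m₂²`) and kernel density curves,
the effective-diffusion maps `D*/D = 1 − 0.9 θ` (big crowders) and
`D* = 1 − 0.06 × kurtosis`, ensemble mRNA power spectra with a
closed-form telegraph-process oracle, two-sample Kolmogorov–Smirnov
comparisons with Bonferroni correction, a synthetic DAPI-like chromatin
field generator, a CSV intensity-stack importer, and a voxel-size
convergence harness.

## Worked example

```r
library(crowdsim)

lat <- build_lattice(c(10, 10, 5))            # demo mesh over 1 um^3
ch  <- normalize_chromatin(generate_field(lat, field_params(seed = 1)), lat)
g   <- place_gene(ch, "dense")                # gene in a dense chromatin area
r   <- default_parameters()

tr <- simulate_cell(lat, ch, empty_crowders(lat), r, g,
                    t_end = 1000, sample_dt = 1, seed = 42)
tr
#> <crowdsim_trajectory> t_end = 1000 min, 1001 samples, 95 promoter switches, 2.16e+06 events
#>   final state: M = 420, P = 1372, promoter active

st <- ton_toff(tr)
c(t_on = st$t_on_total, t_off = st$t_off_total)
#>     t_on    t_off
#> 463.7107 536.2893

ens <- run_ensemble(lat, ch, r, g, theta = 1, size_class = "big",
                    n_cells = 50, base_seed = 7, t_end = 1000,
                    sample_dt = 1000)
est <- estimate_rates(lapply(ens, ton_toff), "per_event")
c(est$k_plus, est$k_minus, est$K_eq)
#> [1] 0.1030 0.1000 1.0300

kurtosis(endpoint_M(ens))
#> [1] 2.132
```

The trajectory alternates between bursts toward the active mode (~500
mRNA) and troughs toward the basal mode (~50): over 1000 min this cell
spent 464 min active across 48 activation events.  In the crowded
ensemble (θ = 1, big crowders) the per-event estimator recovers
switching rates matching the reference `k_on = k_off = 0.1 min⁻¹`, and
the end-point mRNA kurtosis ≈ 2.1 reflects a broad two-mode population.

A command line mirrors the main experiments:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "crowdsim", package = "crowdsim"))')
Rscript "$CLI" population --config config.json --seed 1 --out runs/pop \
        --theta 0.6 --crowder big --n-cells 200
```

Subcommands: `trajectory`, `population`, `rates`, `dstar-map`,
`convergence`.  Every output directory stores the exact configuration
(digest-stamped) and reruns are byte-identical.

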