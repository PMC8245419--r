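# rhodevo

Structure-based clustering and photocycle kinetics for light-driven proton
pumps.

Microbial (type 1) rhodopsins are 7-transmembrane-helix proteins that use a
covalently bound retinal to pump protons across the membrane. Two
computational analyses recur in structural studies of these proteins, and
`rhodevo` implements both as tested, reusable R functions:

1. **Structure-based phylogenetic clustering with a per-residue
   conservation metric.** Deposited structures are compared pairwise by
   Cα RMSD after sequence-guided rigid superposition with iterative
   rejection of outlier residue pairs (default: 2 refinement cycles,
   1.5 Å cutoff). The symmetric RMSD matrix — or the matrix of Pearson
   correlations between its rows — is clustered hierarchically, and for
   each cluster a per-residue conservation profile is computed against a
   reference structure:

   `Cα_RMSD_i = sqrt( (1/n) Σ_j d_ij² )`,

   where `d_ij` is the distance from reference Cα *i* to the **nearest**
   Cα of superposed cluster member *j*. The profile can be painted into
   PDB B-factors for coloring in any molecular viewer.

2. **Global multiexponential analysis of flash-photolysis data.** A
   transient-absorption surface ΔA(λ, t) is fitted as
   `ΔA(λ,t) = Σ_i A_i(λ) exp(−t/τ_i) + A_∞(λ)` with lifetimes shared
   across wavelengths (variable projection: linear amplitudes at fixed
   lifetimes, nonlinear search over log-lifetimes, multi-start). The
   component count is incremented until the weighted residual SD stops
   improving. Under a sequential irreversible photocycle
   (K → L → M → N → O → ground), the state concentrations are a Bateman
   cascade, so the decay-associated amplitude spectra can be inverted
   into intermediate difference spectra; absolute spectra follow as
   `S_j = S_ground + ΔS_j / f`, with the cycling fraction *f* chosen as
   the smallest value keeping every spectrum non-negative (which is also
   where the residual ground-state band vanishes).

Supporting tools: Shrake–Rupley solvent-accessible surface area and
monomer–monomer interface area, geometric hydrogen-bond detection,
quasi-logarithmic compression of dense kinetic traces (~100 points per
time decade), first-derivative melting-point detection for thermal
unfolding (nano-DSF) curves, and a synthetic-data module that generates
structure families and photocycle surfaces with known ground truth.

## Worked example

Cluster a synthetic two-family set of 7-helix bundles and profile the
conservation within one cluster:

```r
library(rhodevo)

fam    <- make_structure_family(family_spec(seed = 1))   # 5 + 5 bundles
traces <- lapply(fam$models, extract_ca_trace)
m      <- pairwise_rmsd_matrix(traces, superposition_params(pairing = "index"))
round(unclass(m)[c(1, 2, 6, 7), c(1, 2, 6, 7)], 3)
#>       A1    A2    B1    B2
#> A1 0.000 0.729 0.944 0.879
#> A2 0.729 0.000 0.930 0.896
#> B1 0.944 0.930 0.000 0.751
#> B2 0.879 0.896 0.751 0.000
```

Within-family RMSDs (~0.73–0.75 Å, set by the 0.3 Å coordinate noise)
are smaller than between-family ones (~0.88–0.94 Å), and clustering the
row-correlation matrix recovers the two families exactly:

```r
cluster_structures(m, mode = "correlation", k = 2)
#> <structure_clusters> k = 2 (correlation distance, average linkage)
#>    label cluster is_reference
#>  1 A1          1 FALSE
#>  ...
#>  6 B1          2 FALSE
```

Fit a simulated five-intermediate photocycle (38 wavelengths × 801
log-spaced times, signal-to-noise 50):

```r
spec <- photocycle_spec(snr = 50, seed = 1)
sim  <- simulate_photocycle_dataset(spec)
sel  <- select_component_count(sim$dataset, n_max = 6)
sel$sd_ladder
#>       n sd_weighted rel_improvement
#>   1     1     0.0477        NA
#>   2     2     0.0335         0.298
#>   3     3     0.0260         0.225
#>   4     4     0.0207         0.204
#>   5     5     0.00537        0.740
#>   6     6     0.00537        0.000681
sel$fit
#> <photocycle_fit> 5 components, weighted residual SD 0.00537
#>   lifetimes (s): 1.502e-06 2.992e-05 5.003e-04 8.060e-03 9.973e-02
```

The sixth component improves the residual SD by under 0.1 %, so five
components are selected; the recovered lifetimes match the simulated
1.5 µs / 30 µs / 500 µs / 8 ms / 100 ms chain to about 1 %. Reconstructing
the intermediate spectra recovers the simulated cycling fraction:

```r
gr  <- tibble::tibble(wavelength = spec$wavelengths,
                      absorbance = sim$truth$ground_spectrum)
rec <- reconstruct_intermediate_spectra(sel$fit, gr,
                                        state_names = c("K","L","M","N","O"))
rec
#> <intermediate_spectra> 5 states, cycling fraction f = 0.30
```

`tidy()`, `glance()` and `autoplot()` methods are provided for the fit
and spectra objects; `run_structure_pipeline()` and
`run_photocycle_pipeline()` drive either analysis end to end from a
config list or YAML file, writing CSV/newick/PDB reports.

To analyse deposited coordinate files, point `read_structure()` at local
PDB or mmCIF files and pass the extracted Cα traces through the same
functions.

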