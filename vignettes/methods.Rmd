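---
title: "Methods: structure-based clustering and photocycle analysis of proton-pumping rhodopsins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based clustering and photocycle analysis of proton-pumping rhodopsins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rhodevo` implements two analyses used when comparing light-driven proton
pumps across the domains of life: structure-based clustering with a
per-residue Cα conservation metric, and global multiexponential analysis of
flash-photolysis photocycle data. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## Rigid superposition with iterative outlier rejection

Two structures are compared on their Cα traces only: the conservation
metric is defined on Cα positions, and Cα-only comparison is insensitive to
side-chain rebuilding differences between depositions. Residues are paired
either by global sequence alignment (BLOSUM62, affine gap open 10 / extend
0.5, gapped columns dropped) or positionally (`pairing = "index"`, the
natural choice for equal-length synthetic families). The rigid fit is the
closed-form Kabsch solution — SVD of the 3×3 covariance with the
determinant correction, so the rotation is always proper (no reflections).

After the initial fit, residue pairs whose post-fit distance exceeds
`cutoff` (default 1.5 Å) are discarded and the fit repeated, for `cycles`
(default 2) rounds; the reported RMSD covers the retained pairs only. Two
points about this rule:

* The cutoff is interpreted as an **absolute distance in Å**. Iterative-trim
  aligners differ in whether the threshold is absolute or scaled by the
  current RMSD; the absolute form is the simplest defensible reading, and
  both `cycles` and `cutoff` are exposed so either behaviour regime can be
  explored. With `cutoff = Inf` the procedure reduces exactly to a single
  Kabsch fit, which is tested.
* Rejection makes the two directions of a comparison slightly asymmetric
  (aligning A onto B can retain a different pair set than B onto A). The
  RMSD matrix therefore averages the two directions, which restores the
  symmetry a distance matrix needs for linkage.

If a rejection round would leave fewer than 3 pairs, rejection stops and
the last valid fit is kept. Retained-pair RMSD is non-increasing over
rejection rounds (removing all pairs beyond a threshold can only lower the
RMS; refitting lowers it further), and this monotonicity is tested.

## Clustering and the Cα conservation profile

Hierarchical clustering (stats::hclust) can act on two distances:

* `mode = "rmsd"`: the RMSD matrix itself;
* `mode = "correlation"` (default): `1 − r_ij`, where `r_ij` is the Pearson
  correlation of rows *i* and *j* of the RMSD matrix with columns *i* and
  *j* excluded. Excluding those columns matters — otherwise each pair would
  correlate its own zero diagonal entries. The correlation form asks
  whether two structures *rank the rest of the set similarly*, which is
  robust to one structure being globally looser than another.

Both modes are first-class because either is a reasonable reading of
"clustering the RMSD correlation values"; on well-separated families they
agree (tested at adjusted Rand index 1.0 for both). Average linkage is the
default — no linkage is canonical for this problem, and average is the
least extreme choice; `complete` and `single` are available. Each cluster
gets a reference structure: user-designated when the user has a natural
anchor (the field's practice is to pick the best-studied member as
reference), otherwise the cluster medoid (smallest mean within-cluster
RMSD).

The conservation profile aligns every cluster member onto the reference
and, for each reference residue *i* and member *j*, measures the distance
`d_ij` from reference Cα_i to the **nearest** Cα of the transformed member
— nearest over the whole member trace, not the sequence-paired atom, so
insertions and register shifts are not over-penalized. Then

$$C\alpha\_RMSD_i = \sqrt{\tfrac1n \sum_j d_{ij}^2}.$$

The nearest-atom rule bounds the profile above by the paired-atom RMS
(tested), and makes the metric slightly biased *below* √3·σ under isotropic
per-atom noise of scale σ (at σ = 0.4 Å and 3.8 Å Cα spacing, the paired
atom is almost always the nearest, so the bias is a few percent; the
Monte-Carlo check asserts agreement with √3·σ within 10%). A numerical
detail: the vectorized nearest-neighbour search uses the expanded
`|a|² + |b|² − 2a·b` form, which loses ~1e−7 Å to cancellation, so the
distance of the located nearest atom is recomputed exactly — the
single-displaced-residue identity (profile equal to the displacement at
that residue, zero elsewhere) then holds to machine precision.

Profiles can be written into the B-factor column of a PDB file
(`write_structure(..., bfactor_map = )`) for the standard
colour-by-conservation rendering.

## Geometric annotations

**Hydrogen bonds.** Crystallographic models at ~2 Å lack hydrogens, so the
primary criterion is the donor–acceptor heavy-atom distance, default
2.4–3.5 Å, over a curated table of N/O donors and acceptors (backbone
amide N and carbonyl O plus standard side-chain groups; water can be
both). Where the hydrogen is inferable — backbone amides, H placed along
the bisector of N−CA and N−C(prev) — the D–H···A angle must exceed
`angle_min` (default 90°, permissive on purpose: the distance does the
work). Same-residue pairs are excluded as covalent context. Detection is
symmetric in selection order (both donor→acceptor directions are
enumerated).

**Surface areas.** Shrake–Rupley SASA with a deterministic golden-spiral
point set (default 960 points/atom, probe 1.4 Å, Bondi-style element
radii with a configurable fallback). Convergence is tested (doubling the
point count moves totals < 0.5%), and single-sphere and two-sphere
configurations are checked against the analytic sphere and spherical-cap
formulas. Exactly duplicated atoms are a degenerate input: a tie-break
buries the later copy so coincident spheres count once. Interface area is
the standard `(SASA(A) + SASA(B) − SASA(A∪B)) / 2`; both protomers must be
present in the input file (no symmetry-mate generation).

## Global multiexponential photocycle analysis

The model for a transient-absorption surface is

$$\Delta A(\lambda, t) = \sum_{i=1}^{n} A_i(\lambda)\, e^{-t/\tau_i} + A_\infty(\lambda),$$

with the lifetimes τ_i shared across wavelengths. Fitting uses **variable
projection**: at fixed lifetimes the amplitude spectra solve a linear
weighted least-squares problem (one QR solve for all wavelengths under
uniform weights; per-wavelength solves when weights vary), and only the
log-lifetimes are searched nonlinearly (`nlminb`, box-constrained to one
decade beyond the observed time span). Optimizing log τ makes the search
scale-free across the µs–100 ms range. Without user initials the search is
multi-started from shifted log-spaced lifetime grids (default 4 starts)
and the best start wins. Self-consistency is tested: re-solving the
amplitudes at the returned lifetimes reproduces the returned spectra to
1e−10.

**Component count.** Counts n = 1, 2, … are fitted until the weighted
residual SD improves by less than `improvement_threshold` (default 2%
relative — "stopped improving" needs an operational form, and the
threshold is exposed). Each fit is additionally warm-started from the
previous lifetimes with one extra component inserted into the largest
log-gap, which keeps the SD ladder monotone and roughly halves the cost.
Pure white noise selects n = 1 with near-zero amplitudes (the degenerate
guard is tested).

**Sequential scheme.** The photocycle is modelled as a unidirectional
chain (K → L → M → N → O → recovered ground state) with the fitted
lifetimes mapped onto the steps fastest-first. Concentrations follow the
Bateman closed form; when two rates are within 1e−6 relative the closed
form cancels catastrophically and a scaling-and-squaring matrix
exponential takes over (logged; verified against `t·e^{−t}` for equal
rates and against a stiff ODE integration for a 5-step chain).

**Intermediate spectra and the cycling fraction.** Because each
concentration c_j(t) is a known linear combination of the fitted
exponentials, inverting the (triangular) Bateman coefficient matrix turns
the amplitude spectra into `f·ΔS_j(λ)` — the difference spectra of the
intermediates relative to the final state, scaled by the fraction *f* of
molecules that entered the cycle. Absolute spectra are
`S_j = S_ground + ΔS_j/f`. The determination of *f* follows two physical
criteria: absolute spectra cannot be negative, and they should not retain
a residual ground-state band. These pull in opposite directions — as *f*
decreases, more of the ground band is subtracted until some spectrum dips
negative — so on a grid (0.01 … 1.00, step 0.01) the chosen *f* is the
**smallest non-negative-feasible value**: the point of maximal ground-band
removal without unphysical negativity. On noisy data "non-negative" must
mean "non-negative within noise": the feasibility tolerance is
`ε + 3·SE/f`, where ε = 1e−3 absorbance and SE is the standard error of
the difference spectra propagated from the fit's residual SD through the
exponential design and the Bateman inversion. Without the noise term,
spectral tails (where both state and ground absorbance are ~0) reject
every candidate and the search collapses to f = 1; with it, the noiseless
case reduces to the plain ε rule and the SNR-50 simulations recover
f = 0.30 exactly on the grid. When no candidate is feasible the best one
is returned with the violation magnitude and a warning.

**Quasi-log compression.** Dense oscilloscope traces are binned into
log-uniform time bins (default 100 per decade, the standard design for
multi-decade kinetics); each bin is replaced by its mean time and mean
signal, so per-bin means are preserved exactly and fully covered decades
carry 100 ± 1 points.

**Unfolding curves.** Melting temperatures are the peaks of the first
derivative of the fluorescence-ratio signal: moving-average smoothing
(default 11 points), central differences, then peak selection by
topographic prominence (≥ 25% of the derivative's spread), which rejects
both noise wiggles and the constant derivative of a linear ramp. The
unsmoothed boundary half-windows are excluded (edge artifacts), and each
peak is localized below the grid step by the vertex of a parabola fitted
to the derivative within ±4 °C — the same refinement instrument software
applies. Recovered midpoints land within one 0.25 °C grid step of the
construction value on both one- and two-transition curves.

## The synthetic-data generators

The generators define the conditions under which the pipeline is tested;
their defaults were chosen once, to emulate the study system:

* **Helical bundles**: ideal α-helix Cα geometry (1.5 Å rise, 100°/residue,
  2.27 Å helix radius — giving the canonical 3.8 Å Cα–Cα spacing), 7 helices
  × 25 residues on a 12 Å ring with alternating up/down orientation,
  poly-alanine backbone (N, CA, C, O) so H-bond and SASA code accept them.
* **Two-cluster families**: 5 + 5 members, within-cluster isotropic
  per-atom noise σ = 0.3 Å (typical coordinate uncertainty between
  independently solved homologues), between-template divergence 3 Å applied
  to the odd-numbered helices. The divergence is distributed — a radial
  shift of one third of the nominal displacement plus a tilt about the
  helix centre growing to the remainder at the helix ends — because
  homologous folds diverge gradually along helices; a block displacement of
  whole helices would simply be deleted by outlier rejection and,
  perversely, make between-family RMSDs *equal* to within-family ones.
  Members get a random rigid motion after noising, so alignment must
  genuinely undo it.
* **Photocycle surfaces**: five states (K, L, M, N, O) with Gaussian bands
  at 590/510/410/530/630 nm (FWHM 70–90 nm) against a 550 nm ground band —
  the canonical pattern of a proton-pump photocycle (red-shifted K, strongly
  blue-shifted M, red-shifted O); lifetimes 1.5 µs / 30 µs / 500 µs /
  8 ms / 100 ms spanning the µs-to-100 ms range of such cycles; cycling
  fraction 0.3 (a realistic single-flash conversion); 330–700 nm in 10 nm
  steps; 100 points per decade from 10 ns. Noise is specified either as an
  absolute σ or via `snr` (σ = max|ΔA|/SNR).
* **Unfolding curves**: logistic sigmoids (width 2.5 °C, step 0.1) on a
  15–98 °C ramp at 0.25 °C spacing with σ = 5e−4 noise — the smoothness of
  a modern scanning-fluorimetry ratio trace.

What passing these tests shows: the algorithms are internally correct —
the fitter recovers parameters it generated under the stated noise, the
clustering recovers a planted partition, the conservation metric matches
its analytic and Monte-Carlo values. What they do not show: performance on
real deposited structures (real divergence is not isotropic Gaussian noise;
loops, termini and crystal contacts behave differently from helix cores)
or on real flash-photolysis data, where back-reactions, spectral baselines,
scattering and cooling transients violate the clean sequential-irreversible
model. Applying the pipeline to deposited coordinate sets requires only
local files and the same function calls.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at sizes a laptop handles
in minutes: 10-member families of 175-residue traces (the full 90-pair
RMSD matrix takes a few seconds), photocycle surfaces of 38 × ~800 points
with component selection to n = 6 over 10 seeds (~1 minute), SASA on
fixtures of up to a few hundred atoms. All randomness flows from explicit
seeds; generators are bit-reproducible given the seed, and repeated
pipeline runs with the same config produce byte-identical reports.

## Known limitations

* Sequence-guided superposition only: no sequence-independent structural
  alignment, so the pairing degrades below ~25–30% sequence identity.
* The kinetic model is a single irreversible chain: no branching,
  back-reactions or pH-dependent equilibria; lifetimes are assigned to
  steps fastest-first by assumption.
* H-bond detection is geometric, not energetic, and side-chain donors are
  accepted on distance alone.
* SASA is O(n · neighbours) pure R; adequate for single structures,
  not for trajectories.
* PDB output follows the fixed-column format; B-factors outside the field
  width are refused rather than truncated.
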