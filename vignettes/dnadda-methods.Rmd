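---
title: "Sequence-only A/B compartment prediction with dnadda: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-only A/B compartment prediction with dnadda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnadda)
```

## The problem

Interphase chromatin segregates into two large-scale spatial classes, the
A (open, active) and B (closed, inactive) compartments, classically read
out from a Hi-C contact map: one computes the Pearson correlation matrix
of the (normalized) contact map, takes its first principal components,
and the sign of the compartment-associated component labels each genomic
bin A or B. `dnadda` predicts this partition *from the genome sequence
alone*, with no chromatin assay as input: Hi-C (or any reference
compartment track) is used only to select one pair of integer parameters
on a small training region and to evaluate the result.

The working hypothesis is dynamical: treat the DNA sequence in each bin
as the trajectory of an unknown nonlinear dynamical system, and posit
that loci that are close in 3D space share dynamical properties of their
sequence. Agreement of two bins' dynamics is measured with a
delay-differential fit, and the resulting pairwise similarity matrix
plays the role of a contact map.

## The model

### DNA walk

Each bin's sequence is encoded by the hydrogen-bond (strong/weak) rule
as a one-dimensional walk: `x(1) = 0`, and for each position `t + 1` the
walker steps up by 1 for C or G (strongly bonded pair) and down by 1 for
A or T (weakly bonded pair). Ambiguous IUPAC codes contribute a zero
step; the first base of a bin never contributes a step (the step at `t`
is driven by the base at position `t + 1`). Note that this encoding is
strand-symmetric: complementation maps C↔G and A↔T within the same
class, so a bin and its reverse complement carry the same step
multiset — the walk reflects base-pair composition dynamics, not strand
identity.

### Delay-differential fit

For a series `x(t)` the package fits sparse models of the form

    xdot(t) = sum_k a_k * prod_n x(t - tau_n)^(m_{n,k})

where `xdot` is the centered numerical derivative and the `tau_n` are
integer shifts in genomic coordinates. The default model — and the one
swept during structure selection — is the symmetric quadratic form

    xdot = a1 x_tau1 + a2 x_tau2 + a3 x_tau1 x_tau2 .

The model is *not* trained: coefficients are the minimum-norm
least-squares solution of the over-determined system `xdot = M a`,
computed by SVD over the fit window (all positions where every delayed
value and the derivative exist). The classifying feature set is the
coefficients plus the least-square error
`rho = sqrt(mean((xdot - M a)^2))` over the fitted rows.

Two bins can be fitted individually (single trial, ST) or jointly by
row-stacking their systems (cross trial, CT). The dynamical-ergodicity
score of a bin pair compares the temporal average (mean ST error) to the
ensemble average (CT error):

    E_ij = | ((rho_si + rho_sj) / 2) / rho_cij  -  1 |

`E` is near zero when the two bins obey similar dynamics. Computing `E`
for all bin pairs of a chromosome yields the raw sequence-only map `D`.

### From ergodicity scores to a contact map

Low ergodicity score should mean high contact, so `D` is post-processed
in a fixed order: (1) linear flip `max + min − d` over unmasked entries
(highest score maps to lowest value, spacing preserved; the reciprocal
`1/d` was rejected because exact zeros occur on the diagonal); (2)
natural log of every non-zero entry, zeros left untouched; (3) min-max
rescale to `[0, 1]`; (4) propagation of any reference-map exclusion
mask. The zero-skip in step (2) is applied verbatim; because the flip
maps the former maximum to exactly 0, the skipped zeros can sit above
the log of entries smaller than 1, so end-to-end monotonicity holds
whenever the flipped non-zero values are ≥ 1 and is deliberately not
enforced beyond that — the rescale step never reorders values.

### Compartment calling

Calling is classical: Pearson correlation matrix of the map (rows as
profiles, missing values dropped pairwise; zero-variance rows masked),
PCA over bins with column centering, and for each of the first four
components: replacement of extreme outliers (beyond 3 scaled MADs,
constant 1.4826, replaced by the nearest non-outlier *value*) and
z-normalization. The compartment component is the one most correlated
(in absolute value) with a ChIP-seq peak-count profile of an
open-chromatin mark (e.g. H3K4me1); a negative correlation flips the
sign so that positive PC = A. For sequence-derived maps each candidate
is first smoothed with a centered window-5 moving average (shrinking at
the edges); that smoothed series, re-z-scored, is the reported track —
Hi-C mode differs only in skipping the smoothing. A purely cosmetic
display scaling maps A into `[0, 0.5]` and B into `[0.5, 1]`; all
quantitative work uses the signed PC.

### Structure selection

The only free parameters are the delays. An exhaustive sweep over all
unordered pairs `tau1 < tau2` in a range (default 1–50, i.e. C(50,2) =
1225 pairs; unordered because the default model is symmetric in its
delays) runs the full pipeline on a training region and scores each
pair by `|r|` between the predicted and the reference PC. Ties break to
the smallest `tau1`, then `tau2`. The selected pair is then applied to
held-out chromosomes.

### Evaluation

`track_metrics` reports Pearson `r` between PC tracks, and AUC
(midrank/Mann–Whitney), accuracy and F1 at threshold 0 with A as the
positive class. Saddle analysis divides a contact map by its
per-distance mean (observed/expected), orders bins by the PC (scaled to
`[-1, 1]` by its maximum absolute value), aggregates into 30
equal-count quantile groups, and quantifies compartment strength
`S = (AA + BB) / (AB + BA)` over the extreme PC quartiles (corner cells
aggregated by mean; sums are available and leave `S` unchanged for
balanced corners). A per-bin GC-fraction track serves as the natural
baseline predictor, with a paired Wilcoxon helper for per-chromosome
comparisons.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_size` | 100000 | nt | compartment resolution; fixtures use 10 kb for speed |
| `tau1, tau2` | selected by sweep | nt | the only structure parameters; integer shifts of the walk |
| `w` | 1 | nt | derivative half-width; 3-point centered stencil, exact to quadratics. The original implementation's stencil is unpublished, so it is exposed rather than guessed |
| `standardize` | `TRUE` | — | per-bin zero-mean/unit-variance before embedding; raw walks carry strong composition trends that would dominate the monomials. Prominent because it materially changes features |
| `min_occupancy` | 0.5 | fraction | bins with fewer A/C/G/T calls are treated as empty and masked; the source method only says "nonempty" bins, so a conservative occupancy rule is made explicit |
| `n_mads` | 3 | scaled MADs | outlier cut in PC filtering |
| smoothing window | 5 | bins | moving mean applied to sequence-derived PCs before correlation |
| low-coverage fraction | 0.10 | — | bins whose row sum is below this fraction of the *mean* unmasked row sum are masked; "fraction of total mass" is selectable because the verbal rule is ambiguous |
| saddle quantiles | 30 | groups | equal-count groups (ties by stable bin order), not equal value-width |

## Numerical choices

* Least squares: minimum-norm SVD solution; singular values below
  `1e-12 * sigma_max` are truncated. `rho` divides by the number of
  rows actually fitted, not the nominal bin length.
* The all-pairs matrix builder computes per-bin sufficient statistics
  (`M'M`, `M'xdot`, `xdot'xdot`) once and solves each CT system from
  their sums — algebraically identical to stacking, O(1) per pair after
  O(L) per bin, and pinned to the explicit SVD fits by tests at 1e-8.
  `tau1 = tau2` is excluded (collinear columns).
* Degenerate inputs: constant walks are masked out of the matrix (their
  standardization is undefined); an all-zero system returns zero
  coefficients and `rho = 0` flagged degenerate; `E` with a zero CT
  error and non-zero ST errors is undefined and masks the pair.
* PCA sign is fixed pre-orientation (largest-magnitude score entry
  positive) so reruns are bit-identical; `|r|` ties in PC selection go
  to the lowest index and are logged.
* All reductions are plain sequential sums; rerunning any stage on the
  same inputs is bit-reproducible.

## What the synthetic fixtures emulate — and what they do not

`fixture_spec` plants a two-class world: per-class base composition
(GC 0.60 vs 0.40 by default, optionally with persistence and a lag-τ*
periodic GC modulation that shows up as a walk-increment autocorrelation
peak), a plaid contact map (intra 2 / inter 0.5, optional power-law
distance decay and log-normal multiplicative noise), and class-biased
Poisson peak counts (3 vs 0.3 per bin). All draws derive from one seed;
generators restore the caller's RNG state.

These fixtures establish that the machinery is correct: that the
pipeline recovers a planted composition partition, that the caller
inverts a plaid, that saddle strength behaves. They do **not**
establish biological performance: real compartments differ from a clean
two-regime composition signal (GC differences between real A/B bins are
far smaller), real Hi-C has distance structure, translocations and
coverage artifacts the plaid model only sketches, and real peak calls
are not Poisson. A green fixture test is a statement about the code,
not about the genome; genome-scale validation requires external
reference data and is documented as an external workflow only.

## Design decisions taken where the method description was open

* Ambiguous bases step 0 and do not count as informative; bins under
  50% informative bases are masked.
* The trailing partial bin of each chromosome is masked (fits assume
  equal series length).
* "Inverted" is the linear flip, and the flip → log → rescale → mask
  order follows the description's paragraph order.
* Peak-to-bin assignment uses the peak midpoint (any-overlap counting
  is available); "falling into" is otherwise ambiguous for
  boundary-spanning peaks.
* Outlier filtering precedes smoothing, which precedes correlation, for
  sequence-derived PCs; the alternative order is not exposed because it
  only reorders two local, nearly commuting cleanups.
* The sweep scores `|r|`, not signed `r`; orientation is resolved
  afterwards by the ChIP profile. Manual PC override (`pc_index`)
  mirrors the occasional need to pick a different component on visual
  inspection, but is never chosen automatically.
* Saddle extreme quartiles are defined on scaled PC values (as the
  procedure is phrased), with group-index selection available.
* The cooler interchange format is written/read by a bundled
  Python/h5py helper implementing the cooler v3 schema, because no R
  HDF5 binding is assumed; HOMER-style and dense TSV text are native.

## Known limitations

* Runtime grows as O(n²) in bins per chromosome for the pair matrix;
  genome-scale runs at 100 kb resolution are minutes per chromosome,
  but finer resolutions need chunking that this package does not
  provide.
* Only two delay embeddings and up to cubic three-term models are
  enumerated; the large-scale model-form search over all enumerated
  structures is out of scope.
* The ergodicity score is tied to the scalar SW walk; alternative
  encodings (integer, 2D walks) are deliberately not implemented.
* Sub-compartments (more than two classes) are not called.
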