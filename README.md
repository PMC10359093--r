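# dnadda

Sequence-only prediction of A/B chromatin compartments by delay
differential analysis.

## What it does, and for whom

Genomes fold into two large-scale spatial classes — the A (open, active)
and B (closed, inactive) compartments — normally read out from a Hi-C
contact map via the sign of a principal component of its Pearson
correlation matrix. `dnadda` is for computational (epi)genomics
researchers who want that compartment track **from the FASTA alone**:
no chromatin assay is consumed at prediction time; a reference track is
needed only once, to pick two integer parameters on a small training
region, and for evaluation.

The method treats the sequence of each genomic bin as the trajectory of
a nonlinear dynamical system. Each bin is encoded as a 1D *DNA walk*
(`x(1) = 0`; step +1 for C/G, −1 for A/T — the hydrogen-bond rule) and
fitted with a sparse delay-differential model

```
ẋ(t) = a₁ x(t−τ₁) + a₂ x(t−τ₂) + a₃ x(t−τ₁) x(t−τ₂) + ρ
```

whose coefficients come from a minimum-norm SVD least-squares solve and
whose residual ρ is the model error. Fitting two bins individually
(single trial, errors ρ_si, ρ_sj) and jointly on the row-stacked system
(cross trial, ρ_c) gives the *dynamical ergodicity* score

```
E_ij = | ((ρ_si + ρ_sj)/2) / ρ_c − 1 | ,
```

near 0 when the bins share dynamics. `E` over all bin pairs, inverted,
log-transformed and rescaled to [0, 1], is a sequence-only contact map;
compartments are then called exactly as for Hi-C (Pearson matrix → PCA
→ MAD outlier filtering → ChIP-seq-guided component selection and
orientation, plus window-5 smoothing for the sequence-derived maps).
The delay pair (τ₁, τ₂) is chosen by an exhaustive sweep over all
unordered pairs in a range (C(50,2) = 1225 by default), scored by |r|
against a reference compartment track on a training region.

## Worked example

Everything below is synthetic and self-contained: the fixture plants
two base-composition regimes (GC 0.60 vs 0.40 in alternating 25-bin
blocks) over 100 bins of 10 kb, plus peak calls enriched in the A
blocks.

```r
library(dnadda)

spec <- fixture_spec(n_bins = 100, bin_size = 10000, block = 25, seed = 8)
sq   <- gen_sequences(spec)               # FASTA with planted regimes
bw   <- bin_walks(sq$seqs, sq$bins)       # one DNA walk per 10 kb bin
chip <- chip_profile(gen_peaks(spec), sq$bins)

D     <- build_dda_matrix(bw, default_model(5, 21))  # ergodicity matrix
map   <- postprocess_dda(D)               # contact map in [0, 1]
track <- call_compartments(map, chip, mode = "dda")
track
#> compartment_track: 100 bins (0 masked), PC1, |r|=0.781, A: 50, B: 50

track_metrics(track, ifelse(spec$labels == "A", 1, -1))
#> metric_report: r = 0.976, AUC = 1.000, ACC = 1.000, F1 = 1.000 (n = 100)

saddle(map, track)
#> saddle_result: S = 1.324 over 30 quantile groups
```

Reading the output: the caller selected PC1 with |r| = 0.78 against the
peak profile and split the bins 50/50. Against the planted labels the
signed PC correlates at r = 0.976 and classifies every bin correctly
(AUC = ACC = F1 = 1): on this clean two-regime world the sequence alone
fully recovers the partition. The saddle strength S = 1.32 > 1 says
that same-compartment bin pairs have elevated contact scores relative
to cross-compartment pairs in the predicted map itself.

Structure selection and evaluation against a reference track follow the
same pattern (`sweep_delays`, `apply_model`, `observed_expected`,
`gc_baseline_metrics`); `run_predict` orchestrates the whole pipeline
from a config list, and a CLI with subcommands
`walk | simulate | map | compartments | sweep | evaluate | saddle | report`
lives at `dnadda_cli()` (an Rscript entry point).

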