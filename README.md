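# surfcomp

Shape, electrostatic and hydropathy complementarity of protein surface
patches — and an interpretability toolkit that asks which of those signals
actually predicts core-interacting residue pairs.

## The problem

At the core of a protein–protein interface, interacting residue pairs show
a characteristic combination of complementarities: the molecular surfaces
mate geometrically, the electrostatic potentials of the two sides tend to
be anti-correlated, and the chemistry is biased toward
hydrophobic–hydrophobic contacts with charged residues at the rim.
`surfcomp` quantifies these three signals for residue pairs on
solvent-accessible surface point clouds, scores pairs with a compact
convolutional classifier, and then dissects the classifier's information
sources with mutual-information ranking, feature-subset ablation, PCA
explained variance, and residue-class-specific decision thresholds.

The core quantities, in the field's standard notation:

* **Interface**: surface points of one chain within 6 Å of the partner
  surface; core-interacting pairs have residue centroids < 3 Å apart and
  < 5 Å from the interface center.
* **Patch descriptors**: the surface points within R = 9 Å of a center
  point are re-oriented onto their least-squares plane, projected through
  a 45° cone onto a 25 × 25 disk image, and expanded in 2D Zernike
  polynomials up to order N = 20,
  `f(r, ψ) = Σ c_nm R_nm(r) e^{imψ}`. The 121 coefficient norms `|c_nm|`
  are rotation-invariant; the Euclidean distance between the descriptors
  of two oppositely oriented patches is the shape (Z_s) or electrostatic
  (Z_el) complementarity — smaller is more complementary.
* **Hydropathy complementarity**:
  `H_r = −a (H_A H_B)² + b (H_A H_B)` with a = 0.033, b = 0.363 — a
  parabola in the product of two residues' hydrophobicity indices with
  roots at 0 and 11 and vertex ≈ 1; values near zero mark complementary
  pairs.
* **Pair features**: a 3 × 10 matrix per pair — the three complementarities
  between residue A and residue B itself (neighbor 0) plus B's nine
  nearest residues within 10 Å.
* **Classifier**: conv(16) → conv(32) → dropout → dense(64) → sigmoid,
  trained with Adam on binary cross-entropy; universal decision threshold
  0.38.

Real surfaces and potentials are computed upstream (molecular-surface and
Poisson–Boltzmann programs); `read_point_cloud()` documents the columnar
format. A synthetic-complex generator with planted, known signal strengths
(`generator_config()`, `generate_dataset()`) replaces experimental data so
the full pipeline runs and is tested at desk scale; the methods vignette
(`vignettes/surface-complementarity.Rmd`) describes the model, the
generator, and every numerical choice.

## A worked example

```r
library(surfcomp)

cfg <- run_config(
  generator  = generator_config(n_complexes = 10, seed = 7),
  classifier = classifier_config(epochs = 60, patience = 10),
  ablation_repetitions = 3,
  seed = 7
)
res <- run_pipeline(cfg, out_dir = "runs/demo")
#> [surfcomp] generate: 10 complexes (seed 7)
#> [surfcomp] features: 240 pairs
#> [surfcomp] train: 168 train / 36 val / 36 test pairs
#> [surfcomp] analyze: MI / PCA / thresholds / ablation
#> [surfcomp] report: run manifest

glance(res$model)
#> # A tibble: 1 × 6
#>   n_parameters epochs_run best_epoch train_loss val_loss train_acc
#>          <dbl>      <int>      <int>      <dbl>    <dbl>     <dbl>
#> 1        66369         43         33      0.132    0.401     0.976

head(dplyr::arrange(res$mi, rank_true), 3)[, c("feature", "kind", "mi_true")]
#> # A tibble: 3 × 3
#>   feature kind  mi_true
#>   <chr>   <chr>   <dbl>
#> 1 s_0     shape   0.418
#> 2 s_1     shape   0.344
#> 3 s_2     shape   0.251
```

The run directory holds the generated clouds and pair table, the feature
CSV, the trained model (JSON weights, history, test predictions), and the
analysis reports (MI ranking, explained variance, class thresholds,
ablation accuracies, `summary.json`). `autoplot()` methods draw the
annular composition, MI ranking, scree curve, ablation box plot, per-class
F1 comparison and score distributions.

Interpretation: the MI ranking is led by shape complementarity with the
direct partner (`s_0`, 0.42 bits at this desk scale), hydropathy
neighbor-0 ranks above every electrostatic feature, and the trained
network separates core pairs from decoys with a test ROC AUC of 0.79 on
this small 10-complex demo (about 0.9 at the 50-complex reference scale),
recorded in `runs/demo/manifest/train.json` — the planted structure of the
generator (strong shape, weaker hydropathy, weakest electrostatics)
recovered from the data alone.

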