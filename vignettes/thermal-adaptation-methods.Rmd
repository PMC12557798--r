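---
title: "Methods: detecting thermal adaptation in ortholog sequences and predicting thermal limits"
author: "thermadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal adaptation detection and thermal limit prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermadapt)
```

# The problem

Orthologous enzymes from species adapted to different temperatures often
differ at a handful of sequence positions, and those differences shift
the balance between catalytic flexibility and structural stability.
`thermadapt` implements one complete analysis of this phenomenon for an
LDH-A-like ortholog family: find the alignment columns whose variants
track habitat temperature, characterize how the cold and warm variant
pools differ structurally and dynamically, and ask how much of a species'
thermal tolerance can be predicted from the variants it carries at the
few key sites.

Because the real inputs of such a study (hundreds of genomes, predicted
structures, molecular-dynamics trajectories, curated occurrence
databases) are not distributable, the package ships a seeded generator
that emulates each of them with known planted truth. Every stage is
therefore testable as a parameter-recovery experiment.

# TRSS detection

## Model

For a substitution site with variants $v_1, \dots, v_k$ (each carried by
$n_j \ge 2$ species after singleton filtering), the association of
variant $v_j$ with temperature is modelled one-vs-rest:

$$\mathrm{logit}\, P(\text{species carries } v_j) = \beta_0 + \beta_1
\bar T_s,$$

with $\bar T_s$ the species' mean habitat temperature in °C. The
*p*-value is a likelihood-ratio test against the intercept-only model.
The LRT was chosen over the Wald test because it remains usable near
separation; when the fitted probabilities degenerate to 0/1 (complete or
quasi-complete separation) the reported slope and *p* come from a
Jeffreys-penalized (Firth) fit and the record is flagged. A constant
response is degenerate by convention: $p = 1$, no slope.

The omnibus criterion compares mean habitat temperature across the
variant groups. The parametric path (one-way ANOVA, LSD pairwise t-tests
on the pooled residual variance) is used only when every group passes
Shapiro–Wilk normality at $\alpha = 0.05$ (groups of $n < 3$ or zero
variance fail the screen) and Levene's test finds no variance
heterogeneity at $\alpha = 0.05$; otherwise the Kruskal–Wallis test with
Dunn's pairwise z-tests (tie-corrected variance) is used. The selection
rule is automated because both families of tests are legitimate here and
the data decide which assumptions hold; the chosen method is recorded
per site. Pairwise *p*-values on both paths receive a Bonferroni
adjustment (family = number of pairs) and are summarized as a compact
letter display via the insert-and-absorb algorithm, so that two variants
share a letter exactly when their adjusted pairwise $p \ge 0.05$.

A site is a TRSS iff (1) it retains $\ge 2$ variants with $n \ge 2$,
(2) some variant's regression $p < 10^{-4}$, and (3) the omnibus
$p < 10^{-4}$. We read criterion (3) as the omnibus *p*-value; the
pairwise letters are still computed because the cold/warm typing needs
them. Typing is pole-based: a variant sharing a letter with the
coldest-mean group but none with the warmest is cold-adapted, and
conversely; a variant bridging both poles stays untyped, which keeps the
cold and warm sets disjoint by construction.

## Decisions on open points

* **Gaps.** A gap is not a variant. Columns varying only by
  gap-vs-residue are reported separately, and species with a gap at a
  column are excluded *per column*, not globally — excluding a whole
  clade (e.g. the notothenioid-style deletion carriers) from all sites
  because of one deletion would discard informative cold-adapted species
  everywhere else.
* **No cross-site multiplicity correction.** The two $10^{-4}$
  thresholds are fixed design constants; no additional adjustment across
  sites or variants is applied. The null-calibration tests quantify the
  resulting family-wise behavior instead ($\le$ 1 false TRSS per 500
  neutral sites empirically).
* **One-vs-rest rather than multinomial** regression per variant: it
  matches the per-variant *p*-value criterion and is well-defined for
  any number of variants.

# Thermal profiles

Occurrence records are mapped into a regular longitude/latitude grid
with depth layers. Containment is half-open ($[\mathrm{edge},
\mathrm{next})$) so each record belongs to exactly one cell; the depth
match takes the nearest layer at or above (shallower than) the record
depth, a conservative choice for benthic records over steep bathymetry.
The grid is consumed as a long-format TSV of cell centers (a pre-averaged
climatology is assumed), keeping the module free of binary formats and
downloads.

Per species, `mean_temp` and `sd_temp` (n−1 denominator) summarize the
records, and the thermal limits are percentiles: $T_{01}$ and $T_{99}$,
computed by linear interpolation between order statistics (R's type-7
quantile). The interpolation rule is fixed and documented so that limits
are reproducible bit for bit; tests verify agreement with an explicit
sorting-based oracle to $10^{-9}$.

# Structural feature contrasts

The four per-residue features — hydrogen-bond count, hydrogen-bond
distance (Å), SASA (Å²) and RSA — are consumed from tables; computing
them from coordinates (polar-contact detection, DSSP-style surface
integration) is the job of upstream structure tools and out of scope
here. RSA is derived as SASA divided by the residue's theoretical
maximum; the bundled table is Tien et al. (2013) and is a configurable
argument recorded with the output. Values above 1 are permitted but
flagged.

Each TRSS contributes one two-group contrast per feature (cold vs warm
carriers, one value per species), using the same
parametric/nonparametric switch as the site tests. With exactly two
groups the Bonferroni family is of size one, so the adjusted *p* equals
the raw *p*. One subtlety worth knowing: when the cold and warm variants
are different residues, *derived* RSA can differ between poles even if
SASA does not, because the denominators differ — that is a property of
RSA itself, not an artifact.

# Flexibility metrics

With $r_i$ an atom position and $r_{\mathrm{ref}}$ its reference,

$$\mathrm{RMSD} = \sqrt{\tfrac1N \sum_{i=1}^{N} \lVert r_i -
r_{\mathrm{ref}} \rVert^2}, \qquad
\mathrm{RMSF} = \sqrt{\tfrac1T \sum_{t=1}^{T} \lVert r_t - \bar r
\rVert^2}.$$

RMSD defaults to backbone atoms after optimal rigid-body superposition
(Kabsch), the convention of trajectory toolchains; `fit = FALSE` applies
the literal formula and both modes are tested (fitted RMSD can never
exceed unfitted). RMSF uses the time-average position within the
analysis window as reference and averages per-atom values into
per-residue values. ΔRMSD is the mean windowed (10–20 ns, the
equilibrated stage) RMSD at 30 °C minus at 10 °C, with replicate
trajectories averaged *before* the difference — the replicate-mean
reading of the contrast, chosen because the replicates are exchangeable
simulations of the same molecule. The ΔRMSD-vs-adaptation-temperature
relation is ordinary least squares with $R^2$ the squared Pearson
correlation. Units are nm and ns throughout.

# The thermal-limit predictor

Each species is a graph of the five key sites in sequence order
(173, 174, 190, 230, 233), node features standardized per feature with
training-split constants. Two design points deserve explanation:

* **Propagation operator.** The description "symmetric normalized
  Laplacian used to update the feature vectors" is implemented as the
  renormalized graph-convolution operator $\hat A = \tilde D^{-1/2}
  (A + I) \tilde D^{-1/2}$ — update semantics imply a propagation
  operator, and the verbatim Laplacian $I - D^{-1/2} A D^{-1/2}$ is kept
  available behind `type = "laplacian"`. For the 5-path,
  $\hat A_{11} = 1/2$, $\hat A_{12} = 1/\sqrt6$, $\hat A_{22} = 1/3$;
  entries are non-negative, the matrix is symmetric and its spectral
  radius is $\le 1$. A fully connected topology is available behind a
  flag.
* **Readout.** The fingerprint concatenates the node-mean pooled
  activations of *every* layer, input included (the neural-fingerprint
  readout), rather than pooling only the last layer. Mean pooling after
  $\hat A$-propagation reweights nodes, so a last-layer-only readout
  cannot represent even a linear function of the plain node mean; with
  the input block included, such functions are exactly representable and
  the recovery test (noise-free linear target in mean node features
  gives held-out $R^2 \ge 0.99$) passes by construction of the model
  class, not by luck.

The network (two hidden layers of width 16 by default — the widths are
unreported in this design space, so small-but-sufficient values were
fixed once and exposed as arguments) is trained end-to-end on the target
with a linear head by full-batch Adam, deterministic under its seed.
Fingerprints then join the per-site functional flags, encoded −1
(cold-adapted variant), +1 (warm-adapted), 0 (reference/other) — an
ordinal encoding of the variant's thermal type. The gradient-boosted
regressor grid-searches its six hyperparameters (learning rate, maximum
delta step, maximum depth, L2 regularization, boosting rounds, minimum
child weight) by 5-fold CV minimizing MSE on the 70 % training split,
refits on the full split, and is evaluated on the held-out 30 % with
$R^2 = 1 - SS_{res}/SS_{tot}$ about the test mean (a constant test-mean
prediction scores exactly 0). Upper (T99) and lower (T01) limits get
independent models, as the two limits are reported separately and need
not share structure. The network is trained end-to-end first and its
fingerprints then frozen for the booster (train-then-extract), matching
the order in which the two stages are naturally specified.

# The synthetic generator

The generator's defaults are the study conditions: 277 species with mean
habitat temperatures uniform on −1.6…29.5 °C; 500 records per species
(stable 1st/99th percentiles), record SD 2 °C — a realistic within-range
spread for marine occurrence records; 332-column alignments with
invariant catalytic residues (Arg106, Asp166, Arg169, His193); 10
planted sites whose warm-variant probability is
$\mathrm{logit}^{-1}(\beta_0 + 0.4\,\bar T)$ with the curve centered at
the midpoint of the range (the first five planted sites sit at the key
positions); 100 neutral columns with minor-variant frequency uniform on
0.05–0.5, independent of temperature; warm-carrier feature shifts of
+1 hydrogen bond, −0.2 Å bond distance, −20 Å² SASA with Gaussian noise
(0.5, 0.1, 5); an optional gap column at position 75 carried by the 29
coldest species. Planted cold/warm residue pairs default to pairs
observed to distinguish cold- and warm-adapted orthologs (I/L, I/M, I/V,
V/A, K/R, E/M) and are configurable. Effect sizes are chosen for
testability — the real magnitudes are unknown — and the spec of each
test states what recovery at these settings does and does not show.

Trajectories are a stationary AR(1) fluctuation (1 ns relaxation time)
of each atom about a fixed random reference. A pure random walk would
never equilibrate, contradicting the "stabilized stage" the 10–20 ns
window is meant to capture; the AR(1) process is the simplest stationary
motion whose windowed RMSD has a well-defined expectation. The 30 °C
stationary SD exceeds the 10 °C one by the amount that makes the
expected ΔRMSD equal `delta_rmsd_intercept + flexibility_slope * T̄`
(default 0.08 nm − 0.002 nm/°C · T̄, floored near zero), so warm-adapted
backbones are planted stiffer. Default 8 isoforms spanning the
temperature range, 5 replicates, 0.1 ns frames over 20 ns.

In `limit_mode = "linear_features"` the species limits are replaced by a
fixed linear function of the key-site features plus 2 °C Gaussian noise:
the four features are averaged over the five key sites, standardized,
and combined with weights (+1, −1, −1.5, −1) — more and shorter hydrogen
bonds and lower solvent exposure push limits up, the direction the
structural analysis plants — then scaled to a 6 °C signal SD. The same
weight at every site encodes that the stability physics is shared across
sites; it also makes the planted signal representable by a mean-pooling
readout, so model-recovery tests measure estimation quality rather than
representability luck. The default `"percentile"` mode instead uses the
genuine record percentiles.

What the generator does **not** emulate: phylogenetic covariance among
species (the association tests treat species as independent, as does the
analysis this package implements — a real cohort's shared ancestry would
inflate false positives), linkage between sites, realistic protein
physics in the trajectories, or spatial structure in the occurrence
records. Passing recovery tests therefore demonstrates correctness of
the statistical machinery under the stated model, not robustness to
phylogenetic confounding.

# Numerical choices and problem sizes

* glm IRLS tolerance is tightened to $10^{-12}$ so the MLE agrees with
  independent brute-force likelihood maximization to $10^{-6}$.
* All-tie degeneracies in the rank tests (Kruskal–Wallis statistic and
  Dunn variance both 0) are defined as $p = 1$.
* CV grid ties break toward the first (lowest-index) combination; folds
  are assigned by a seeded permutation; xgboost runs single-threaded for
  exact reproducibility.
* The pipeline manifest contains only deterministic content (seeds,
  thresholds, statuses, output MD5 hashes, headline stage results);
  stage timings go to the stderr log so that two runs under the same
  configuration produce byte-identical manifests.
* Test and acceptance runs use cohorts sized for repeated execution:
  the full 277-species cohort for recovery and model runs, 20 replicate
  cohorts of 500 neutral sites for null calibration, 200 replicate
  trajectory cohorts (8 isoforms × 5 replicates, 15-atom structures,
  1 ns frames) for the slope-sign rate, and a 100-species cohort for the
  double pipeline-determinism run.

# Known limitations

* No phylogenetic correction: significance is conditional on species
  independence.
* Structural features are consumed, not computed; garbage tables in,
  garbage contrasts out.
* The real-data headline numbers of the motivating study design (counts
  of detected sites, real MSE/R², the empirical ΔRMSD regression)
  require the original cohort's sequences, structures and trajectories
  and cannot be reproduced from synthetic data; the package's claims are
  the property-based ones its tests compute.
* The graph is tiny (5 nodes) by design; the model machinery is not
  intended for large graphs.
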