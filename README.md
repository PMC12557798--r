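# thermadapt

Marine fishes live at habitat temperatures spanning roughly −1.6 °C to
29.5 °C, and glycolytic enzymes such as lactate dehydrogenase-A (LDH-A)
show convergent amino-acid changes along that gradient. `thermadapt` is an
R package for analysts who want to link ortholog sequence variation to
habitat temperature and to species thermal limits: it detects **thermal
adaptation-related sequence sites (TRSS)** in an aligned ortholog family,
types their variants as cold- or warm-adapted, contrasts structural
features between the two variant pools, summarizes backbone-flexibility
trends from trajectories, and predicts species thermal limits from a
graph fingerprint of the key sites. A fully seeded synthetic-data
generator emulates every input, so the whole pipeline is testable with
parameter-recovery experiments on a laptop.

## The statistics at the core

**TRSS detection.** For every substitution site (an alignment column with
≥ 2 distinct non-gap residues; gaps are not variants), variants observed
in fewer than two species are discarded. A site is a TRSS when all three
criteria hold:

1. it retains ≥ 2 variants with carrier count *n* ≥ 2;
2. some variant's binomial (logistic) regression of carrier status on the
   species' mean habitat temperature,
   logit P(variant) = β₀ + β₁·T̄, has a likelihood-ratio *p* < 10⁻⁴
   (complete separation falls back to a Jeffreys-penalized fit);
3. the omnibus test of mean habitat temperature across variant groups has
   *p* < 10⁻⁴ — one-way ANOVA with LSD pairwise comparisons when every
   group passes Shapiro–Wilk normality and Levene's homogeneity screen at
   α = 0.05, otherwise Kruskal–Wallis with tie-corrected Dunn z-tests;
   pairwise *p*-values are Bonferroni-adjusted and rendered as a compact
   letter display.

Letter-separated variants on the cold pole (carriers with significantly
lower mean habitat temperature) are typed *cold-adapted*; the warm pole,
*warm-adapted*.

**Thermal profiles.** Per species, occurrence records are mapped through
a gridded climatology (half-open cell containment, nearest-at-or-shallower
depth layer); the thermal limits are the 1st and 99th percentiles of the
habitat-temperature records (T01, T99), computed by linear interpolation
between order statistics.

**Structure and flexibility.** Relative solvent accessibility is
RSA = SASA / MaxSASA(residue) (Tien et al. 2013 theoretical maxima).
Trajectory statistics follow
RMSD = √(1/N · Σᵢ‖rᵢ − r_ref‖²) (optionally after Kabsch superposition)
and RMSF = √(1/T · Σₜ‖rₜ − r̄‖²), and
ΔRMSD = mean windowed RMSD at 30 °C − at 10 °C over the 10–20 ns window,
regressed on species mean habitat temperature.

**Thermal-limit model.** Each species becomes a 5-node graph over the key
sites (173, 174, 190, 230, 233, sequence order) with 4 standardized node
features (H-bond count, H-bond distance, SASA, RSA). Node features are
propagated with the renormalized operator Â = D̃^{−1/2}(A+I)D̃^{−1/2} of
the path graph through ReLU layers, H_{l+1} = relu(Â H_l W_l + b_l); the
node-mean pooled activations of every layer are concatenated into a
fingerprint, trained end-to-end on the target with a linear head. The
fingerprints plus the per-site functional flags (−1 cold / +1 warm / 0)
feed a gradient-boosted regressor (xgboost) whose six hyperparameters are
grid-searched by 5-fold CV on the 70 % training split; MSE and
R² = 1 − SS_res/SS_tot are reported on the held-out 30 %.

## Worked example

```r
library(thermadapt)

cfg      <- sim_config(n_species = 150, n_planted_trss = 5,
                       n_neutral_sites = 30, seed = 42)
cohort   <- simulate_species(cfg)
aln      <- simulate_alignment(cfg, cohort$species)
profiles <- species_thermal_profiles(cohort$records)
sites    <- find_substitution_sites(aln$alignment)
print(sites)
#> Substitution sites: 35 polymorphic columns among 150 species; 0 columns contain gaps

trss <- detect_trss(sites, profiles, alpha = 1e-4)
print(trss)
#> TRSS detection: 5 of 35 tested substitution sites pass the three criteria
#>  site variants min_p_binomial    omnibus_p cold_variants warm_variants
#>   173      I/L   1.439756e-29 1.095847e-21             I             L
#>   174      I/M   9.069990e-31 2.878139e-22             I             M
#>   190      I/V   6.545333e-27 1.717621e-20             I             V
#>   230      A/V   3.285925e-30 2.708565e-22             V             A
#>   233      K/R   7.505354e-29 1.618667e-21             K             R
```

All five planted sites pass both *p* < 10⁻⁴ criteria and none of the 30
neutral columns do; the typed poles match the planted cold/warm residues
(e.g. at site 230 the cold pole is V and the warm pole A). Contrasting
the structural features between the poles recovers the planted
directions — warm variants with more hydrogen bonds, shorter bonds and
lower solvent exposure:

```r
features  <- simulate_structure_features(cfg, aln$alignment, aln$truth)
contrasts <- contrast_variant_features(features, trss)
summarize_direction_counts(contrasts)
#>      feature cold_higher warm_higher ns
#> 1    hbond_n           0           5  0
#> 2 hbond_dist           5           0  0
#> 3       sasa           5           0  0
#> 4        rsa           4           1  0
```

On a 277-species cohort whose thermal limits are a linear function of the
key-site features plus 2 °C noise, the two-stage predictor recovers most
of the plantable signal on the held-out split:

```r
cfg <- sim_config(limit_mode = "linear_features", seed = 42)
ds  <- simulate_thermal_dataset(cfg)
fit <- fit_thermal_limit_model(ds$features, ds$flags, ds$profiles, target = "t99")
print(fit)
#> Thermal-limit predictor (t99) over key sites 173, 174, 190, 230, 233
#>   graph network: hidden 16/16 -> fingerprint dim 36
#>   booster: eta=0.1 max_delta_step=0 max_depth=2 lambda=1 nrounds=100 min_child_weight=1
#> Held-out evaluation: n = 83, MSE = 4.555 degC^2, R2 = 0.882
```

The full pipeline (simulate → sites → profiles → detect-trss → features →
flex → model) runs via `run_pipeline(run_config(...))` or the thin CLI at
`inst/cli/thermadapt.R`, writing a deterministic JSON manifest of stage
statuses, output hashes and seeds.

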