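# aevbind

Structure-based prediction of protein–ligand binding affinity from **elements
and Cartesian coordinates alone**, in R.

`aevbind` is aimed at computational chemists and method developers who want a
fully inspectable, dependency-light implementation of a neural-network-potential
style scoring function:

- the binding site (every ligand atom plus each protein residue with at least
  one atom within `d` Å of the ligand, default `d = 3.5`) is encoded per atom
  with **atomic environment vectors** (AEVs) — Behler–Parrinello atom-centred
  symmetry functions that are invariant under translation, rotation, mirror
  symmetry and exchange of same-element atoms;
- one small feed-forward network per element maps each atom's AEV to an atomic
  contribution (in pK units), and the contributions **sum** to the predicted
  affinity, giving a free per-atom decomposition of the prediction;
- a **Δ-learning** mode trains the same machinery on residuals
  `pK_exp − pK(S)` of a classical docking score `S` (kcal/mol), converted by
  `pK = −S / (R T ln 10)` at `T = 295 K`, so the final score is
  `S_pK + Δ`;
- **consensus ensembles** (default 5 members) report the mean prediction and
  its spread as a per-prediction uncertainty;
- CASF-style **scoring / ranking / docking / screening power** metrics with
  percentile-bootstrap confidence intervals;
- analytic **coordinate gradients** (`∂pK/∂x`, checked against finite
  differences) for interpretability and experimental pose refinement;
- a seeded **synthetic-complex generator** with an AEV-linear ground truth, so
  the entire pipeline is testable on a laptop with no external data.

## The model

For atom *i* with neighbours *j, k*, distances `R_ij` and angle `θ_ijk` at
vertex *i*:

```
f_c(R)        = 0.5 (cos(π R / R_c) + 1)                      for R ≤ R_c, else 0
G_radial(i)   = Σ_{j∈α}   exp(−η_R (R_ij − R_s)²) f_c(R_ij)
G_angular(i)  = 2^(1−ζ) Σ_{j∈α,k∈β} (1 + cos(θ_ijk − θ_s))^ζ
                 exp(−η_A ((R_ij + R_ik)/2 − R_s)²) f_c(R_ij) f_c(R_ik)
```

One radial block per species and one angular block per unordered species pair
are concatenated into the AEV `G_i`. With 8 species, the 16-shift radial grid,
`θ_s ∈ {0, π}` and one angular shift, the AEV has
`8·16 + 36·2 = 200` entries. Each element's network (default 256-128-64-1,
ReLU, 25% dropout at training) yields the atomic contribution, and

```
pK = Σ_i  net_{species(i)}(G_i)
```

Training uses ADAM (lr 1e-4, β₁ = 0.9, β₂ = 0.999), batch size 64, MSE loss,
best-validation checkpointing.

## Worked example

```r
library(aevbind)

species <- c("C", "N", "O")
params  <- aev_params(species = species)
map     <- species_map(canonical_species = species)

# synthetic dataset with known ground truth
ds   <- make_dataset(synthetic_config(seed = 11, species_pool = species),
                     150, params, d = 3.5, map = map)
recs <- featurize_complexes(ds$complexes, params, d = 3.5, map = map)

spec <- network_spec(aev_length(params), length(species))
mod  <- train_model(recs[1:120], recs[121:150], spec, params,
                    train_config(max_epochs = 200, seed = 1))

pred <- predict_system(mod, ds$systems[[130]])
pred
#> predicted pK: 3.526  ( 13 atomic contributions )
# (ground truth for that system: 4.306 pK)

s <- scored_set(ds$labels$id[121:150], ds$labels$pk_exp[121:150],
                vapply(ds$systems[121:150], function(x) predict_system(mod, x)$pk, 0))
scoring_power(s)
#> $pearson_r
#> [1] 0.5916169
#> $rmse
#> [1] 1.769278
```

(Printed numbers from this exact script — a ~1-minute toy run on 120
training systems; held-out correlation keeps rising with training scale, and
the acceptance benchmark in `tests/testthat/test-acceptance.R` trains the
full 5-member consensus on 400 systems. See the methods vignette for the
sample-size limits of this synthetic benchmark.) The predicted pK equals the
sum of the per-atom contributions exactly; `attribute_prediction()`
additionally returns `∂pK/∂coordinates`, and `write_pdb_bfactors()` exports
either quantity in the B-factor column for visualization.

## Command line

```sh
Rscript inst/cli/aevbind.R make-fixtures --out fx --n 40 --seed 1
Rscript inst/cli/aevbind.R train    --manifest fx/manifest.csv --out mdl --ensemble 5
Rscript inst/cli/aevbind.R predict  --manifest fx/manifest.csv --model mdl --out pred.csv
Rscript inst/cli/aevbind.R evaluate scoring --pred pred.csv --out metrics.json
```

`delta-predict` and `train --mode delta` switch to the Δ-learning pipeline
(manifest column `baseline_score`, kcal/mol); `attribute` writes annotated
PDB/CSV files.

## Scope

Desk-scale by design: the published benchmark numbers (CASF-2013/2016 after
PDBbind-Refined training) require external datasets and long training runs and
are out of scope; see `vignettes/aevbind-methods.Rmd` for what the synthetic
benchmark does and does not establish.
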