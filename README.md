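# molgat

Scalar molecular-property regression from SMILES strings with a
deliberately tiny graph attention network and a *SMILES-positional*
readout, in R.

## The idea

Benchmark regression tasks in drug discovery — aqueous solubility
(log mol/L), hydration free energy (kcal/mol), lipophilicity (logD),
enzyme inhibition (pIC50) — are usually attacked with large pretrained
models. molgat takes the opposite route: a five-layer single-head graph
attention network (GAT) with tanh activations and widths
35 → 28 → 28 → 28 → 28 → 1, about 3.7K trainable parameters, made
competitive by two pieces of chemical inductive bias:

* **Expert-crafted global features.** Each heavy atom (node) carries 14
  atomic features plus 21 molecule-level descriptors broadcast to every
  node — 15 chemical (TPSA, molecular weight, H-bond donors/acceptors,
  rotatable bonds, ring/aromaticity, hybridization fraction, mean Pauling
  electronegativity, …) and 6 geometric, measured on a seeded 3D conformer
  (grid volume, the sorted coordinate extents *length ≥ width ≥ height*,
  the partial-charge dipole magnitude ‖Σᵢqᵢrᵢ‖, and the principal-axis
  orientation angle). Three atomic features use fixed affine scalings:
  mass `(A − 10.812)/116.092`, vdW radius `(R − 1.5)/0.6`, covalent radius
  `(R − 0.64)/0.76`.
* **No pooling (unless you want it).** The network predicts one value per
  node; graphs are built so node *i* is the *i*-th atom token of the raw
  SMILES string, and the molecular prediction is read from a single
  selected position — by default the **last SMILES atom**, an outer atom
  by construction of the notation. Ten readout strategies (first, second,
  penultimate, last, middle-mean, random node, random-5 mean, mean/max/min
  pooling) can be compared on one trained model, which doubles as an
  interpretability probe: where the prediction is good tells you which
  part of the molecule carries the property.

Training minimizes the MSE between readout and target with RMSprop
(full batch, early stopping on validation RMSE); all results are exactly
reproducible from seeds. Everything tabular is a tibble, so the API
composes with the pipe; `tidy()`, `glance()`, `autoplot()` work on fits
and reports.

## Worked example

No downloads needed: the synthetic-data module generates valid SMILES with
planted signal. Here the signal is *purely positional* — the same alcohols
written with the hydroxyl last (`CCCO`, target +2) or first (`OCCC`,
target −2) plus noise — so only a readout that looks at the right SMILES
position can recover it:

```r
library(molgat)

spec <- synthetic_spec(n_molecules = 200, grammar = "alcohol_flip",
                       target_mode = "terminal_atom", noise_sd = 0.1,
                       seed = 42)
data  <- generate_dataset(spec)
feats <- attr(data, "features")            # featurized 35-column graphs
parts <- split_dataset(feats, c(0.8, 0.1, 0.1), seed = 42)

fit <- train_model(parts$train, parts$val, model_config(seed = 42),
                   train_config(epochs = 300, early_stop_patience = 300,
                                seed = 42))
glance(fit)
#> # A tibble: 1 × 8
#>   layer_type n_layers hidden readout   n_parameters epochs_run best_epoch
#> 1 gat               5     28 last_node         3699        300        291

node_position_report(fit, parts$test, random_seed = 42)
#> # A tibble: 10 × 3
#>    strategy          rmse     n
#>  1 first_node       3.69     20
#>  2 second_node      3.62     20
#>  3 penultimate_node 0.703    20
#>  4 last_node        0.664    20
#>  5 middle_mean      2.08     17
#>  6 random_node      2.70     20
#>  7 random_mean_5    2.16     20
#>  8 mean_pool        1.99     20
#>  9 max_pool         2.99     20
#> 10 min_pool         2.26     20
```

The last-node readout recovers the planted ±2 signal (RMSE 0.66 against a
target SD of 2); the first-node readout, which sees the same molecule from
the wrong end, is no better than guessing (3.69). The `middle_mean` row
evaluates the 17 of 20 test molecules with ≥ 5 heavy atoms.

Benchmark CSVs load the same way via their column dialects
(`load_dataset("esol.csv", "esol")`, likewise `freesolv`,
`lipophilicity`, `bace`), then `featurize_graphs()` →
`split_dataset()`/`kfold_cv()` → `train_model()` →
`node_position_report()`/`ablation_run()`/`rf_baseline()`; fitted models
serialize to versioned JSON checkpoints (`save_model()`/`load_model()`).
With the
downloaded solubility benchmark, test RMSE ≤ 0.90 under the default
configuration is the documented sanity bar. A thin CLI over the same
functions lives at `inst/cli/molgat.R`
(`Rscript inst/cli/molgat.R train --data esol.csv --dialect esol ...`).

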