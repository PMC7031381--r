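# neopred

Tools for predicting the clinical benefit of checkpoint-blockade
immunotherapy from tumour exomes, for computational immuno-oncology.
Two forces are modelled in one stack:

* **Antigenic mutations** create neoantigens — mutant peptides presented
  by MHC class I (HLA-A/B) that make a tumour visible to T cells. More
  predicted neoantigens generally means better response.
* **Functional mutations** (called simultaneously damaging by SIFT and
  deleterious by PROVEAN) can disable immune-related genes, so some
  high-neoantigen tumours still resist therapy.

## What is inside

1. **Contact potentials** (`energy_matrix`): 20×20 amino-acid interaction
   preferences from native protein structures, via the quasi-chemical
   log-odds `e(a,b) = −ln( f(a,b) / (f(a)·f(b)) )` on contact frequencies
   (Cα–Cα ≤ 6.5 Å or any-atom ≤ 4.5 Å), plus permuted/null controls.
2. **Interaction maps** (`interaction_map`, `encode_batch`): a 9/10-mer
   peptide × 183-residue HLA matrix of pairwise energies — the CNN input.
3. **Binding CNN** (`train_binding_model`): two convolution layers (50/10
   kernels, 5×183 windows, stride 1, no pooling), fully connected ReLU
   layer, sigmoid output; objective
   `NLL + λ₁‖W‖₂² + λ₂‖H‖₁` under the max-norm constraint
   `‖W_neuron‖₂ ≤ λ₃`, minimized by seeded SGD with momentum. Binder
   labels use the conventional IC50 < 500 nM threshold.
4. **Neoantigen load** (`mutant_peptides`, `call_binders`,
   `neoantigen_load`, `assign_groups`): all mutant k-mers covering each
   missense site, scored against patient HLA alleles; resistance = load
   > 70 with no clinical benefit.
5. **Resistance forest** (`cv_rf`, `variable_importance`,
   `matched_control`): 1000-tree random forest (authored in C++ inside the
   package) on the >5%-frequency functional-mutation matrix, ten-repeat
   stratified 5-fold CV, vote-ratio scores, permutation importance with
   selection cutoff 3, feature-count-matched synonymous negative control,
   interactome expansion of hits.
6. **Immune regression** (`immune_score`, `evasion_labels`,
   `fit_regressions`): geometric-mean immune score, 70th/30th-percentile
   evasion labels, min-max parameter scaling, and simple / lasso /
   elastic-net / ridge regressions with cross-validated AUC and
   standardized-coefficient importance.
7. **Synthetic data** (`gen_binding_data`, `gen_cohort`,
   `gen_structure_fixture`): seeded generators with planted signal so the
   whole pipeline is testable offline.

## Worked example

```r
library(neopred)

# 1. contact potential from synthetic helix structures
structs <- lapply(1:8, function(i) gen_structure_fixture(60, "helix", seed = i))
E <- energy_matrix(count_contacts(structs, "calpha"))
#> <energy_matrix> variant=calpha, range [-0.061, 2.662]

# 2. planted-motif binding data and the CNN
pool  <- gen_hla_pool(1, "A", seed = 3)
hla   <- prepare_hla(pool$allele[1], pool$sequence[1])
motif <- motif_from_energy(E, hla, anchors = c(2, 9), n_preferred = 4)
dat   <- gen_binding_data(2000, motif, pool, seed = 11)
maps  <- encode_batch(dat$table$peptide, hla, E)
cfg   <- model_config(n_kernels1 = 20, n_kernels2 = 10, n_hidden = 16,
                      batch_size = 100, learning_rate = 3e-4,
                      momentum = 0.9, epochs = 20, seed = 5)
model <- train_binding_model(cfg, training_set(maps[1:1600, , ],
                                               dat$table$label[1:1600]))
#> <binding_model> key=(A,9) conv1 5x183 x20 -> conv2 5x20 x10 -> fc 16 -> sigmoid
evaluate_scores(predict(model, maps[1601:2000, , ]),
                dat$table$label[1601:2000])
#> <eval_report> AUC=0.9336 F1=0.8304 (threshold 0.50, 137+/263-)

# 3. resistance classification on a synthetic cohort
co <- gen_cohort(cohort_spec(seed = 42))           # 120 samples, 100 genes,
fm <- build_mutation_matrix(co$mutations,          # 5 planted genes, OR = 8
                            co$samples, "functional")
dim(fm$values)
#> [1] 120  95
cv <- cv_rf(fm, co$truth$resistant,
            forest_config(n_trees = 300, repeats = 2, seed = 7))
cv$mean_auc
#> [1] 0.888
vi <- variable_importance(fm, co$truth$resistant,
                          forest_config(n_trees = 500, seed = 7))
head(vi, 5)
#>   gene importance         raw
#> 1 G005  17.195741 0.041510414
#> 2 G001  13.288048 0.027972461
#> 3 G002  10.481208 0.021283367
#> 4 G003   6.876488 0.008821404
#> 5 G021   5.419693 0.002779821
```

The held-out AUC of 0.93 is the planted-motif recovery the acceptance
tests require (≥ 0.90); the top importance ranks are dominated by the
planted resistance genes G001–G005 (all five sit in the top 10, with
importance far above the selection cutoff of 3); and the 0.89 mean CV AUC
is what separates the functional-mutation model from its
synonymous-mutation negative control, which stays at chance (≈ 0.5).

## Command line

A thin dispatcher over the same functions:

```sh
Rscript inst/cli/neopred.R potentials --pdb-dir pdbs/ --mode calpha --out E.tsv
Rscript inst/cli/neopred.R train --data binding.tsv --hla-seqs hla.tsv \
        --energy E.tsv --locus A --length 9 --out model.json
Rscript inst/cli/neopred.R resist --mutations muts.tsv --labels labels.tsv \
        --trees 1000 --repeats 10 --folds 5 --seed 1 --out out/
Rscript inst/cli/neopred.R simulate cohort --n 120 --seed 1 --out sim/
```
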