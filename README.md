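# methtransfer

Completing extremely sparse whole-genome bisulfite sequencing (WGBS)
methylomes — the kind produced from oocytes and preimplantation embryos,
where profiled CpG coverage can fall below 0.1% of the genome — by
predicting the methylation state of every unprofiled CpG site and keeping
only confident calls.

The predictor is a multi-task neural network with three feature-learning
subnetworks and one classification head per methylome profile:

* a **Sequence** subnetwork: two convolution blocks (convolution → max
  pooling → batch normalization) and a fully connected layer over the
  one-hot DNA window centered on the target CpG (1,001 bp by default);
* a **Methylation** subnetwork: a bidirectional GRU over one vector per
  profile, each concatenating the levels of the 50 nearest observed CpG
  neighbors (25 per side) with their normalized distances;
* a **Joint** subnetwork fusing both representations through two fully
  connected layers with batch normalization;
* per-profile heads ending in a two-class softmax, so each profile is a
  task and all tasks share the feature extractors.

Two ideas drive accuracy on sparse data. First, training minimizes the
**Kullback–Leibler divergence** between the observed methylation level
*y* ∈ [0, 1] and the predicted methylated-probability *ŷ*,

  D_KL(y, ŷ) = y log(y/ŷ) + (1 − y) log((1 − y)/(1 − ŷ)),

instead of the logistic loss on binarized labels, so the graded
information in intermediate methylation levels is never thrown away
(for binary *y* the two losses coincide exactly). The multi-task
objective is Σ_j α_j Σ_i β_ij D_KL(y_ij, ŷ_ij) with per-task weights α_j
and per-CpG class-balance weights β_ij. Second, **transfer learning**:
subnetworks pretrained on dense "source" methylomes (somatic tissues,
sperm) are loaded into the model for sparse "target" profiles and either
frozen or fine-tuned; all 5 source and 15 target transfer settings
(`Seq`, `Met`, `Full1`–`Full3`; `SeqN` … `FullTA2`) are built in.

Everything the pipeline needs ships in the package: Bismark-coverage and
bedGraph call parsing, the cleaning rules (read depth ≥ 4 per strand,
exclusion of single-strand and hemi-methylated sites, pooled strand
counts), chromosome-based train/validation/test splits, Adam with
ℓ1/ℓ2 regularization, early stopping on minor-class F1,
learning-rate grid search, τ-thresholded imputation, genomic-feature
coverage summaries (300-bp bins, 1,001-bp promoters, CpG islands), and a
synthetic multi-profile methylome generator for fully reproducible
benchmarking. The network, its backpropagation, the GRU and batch-norm
cells are implemented in plain R matrix algebra and verified against
central-difference gradients in the test suite.

## Worked example

A complete run on a synthetic benchmark (three 70-kb chromosomes, three
dense source profiles at 35% CpG coverage, two sparse targets at 1%):

```r
library(methtransfer)

bm <- make_benchmark(sim_config(seed = 7))
profiles <- lapply(bm$calls, \(cl) clean_calls(cl, bm$gidx)$profile)

plan <- split_plan("1", "3", "2")    # train / validate / test chromosomes
net <- network_config(
  conv_block_1 = list(n_filters = 16, filter_len = 11, pool_len = 2),
  conv_block_2 = list(n_filters = 8, filter_len = 3, pool_len = 2),
  seq_fc_units = 24, gru_hidden_units = 24,
  joint_fc_units = c(32, 16), head_fc_units = 16)

src <- split_examples(
  build_examples(profiles[bm$roles == "source"], bm$gidx, "covered",
                 window_len = 61, k_per_side = 15, dist_scale = 3000),
  plan)

fit <- train_model(NULL, src,
                   train_config(learning_rate = 1e-2, l2_coeff = 1e-3,
                                max_epochs = 40, patience = 10, seed = 11),
                   loss_config("kl"), plan = resolve_transfer("FullN"),
                   network_config = net)
prob <- predict(fit$model, src$test)
evaluate_predictions(prob, src$test$labels, src$test$label_mask)
```

On this seed the evaluation prints, per source profile (task), a
minor-class F1 of 0.741, 0.810 and 0.778 (mean 0.776) with AUC-ROC
around 0.92 — the from-scratch full model learns both the planted
sequence motif and the neighbor-correlation structure. `glance(fit)` summarizes
the fit (best epoch, validation F1); `tidy(fit)` returns the per-epoch
history; `autoplot(fit)` plots it.

Imputing a sparse target with the trained model and a confidence
threshold τ = 0.8 keeps only predictions above 0.8 or below 0.2:

```r
tgt <- profiles[bm$roles == "target"]
imp <- impute_profile(fit_target, tgt, "tgt1", bm$gidx, tau = 0.8,
                      window_len = 61, k_per_side = 15, dist_scale = 3000)
attr(imp, "rate_before"); attr(imp, "rate_after")
```

which raises the genome-wide CpG coverage rate of the target from about
1% to over 13% at these desk-scale settings, and feeds directly into
`feature_coverage()`, `feature_methylation_matrix()` and
`profile_correlations()` for bin/promoter/CGI summaries.

A thin command-line front end (`inst/cli/methtransfer.R`) exposes
`simulate`, `clean`, `impute` and `summarize` subcommands over the same
functions.

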