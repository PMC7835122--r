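# conceptbench

Benchmarking few-shot learning of novel visual categories from features
taken at different depths of a trained visual hierarchy.

## The problem

Humans learn new visual categories from a handful of examples; standard
object-recognition networks need orders of magnitude more.  One proposed
explanation is *concept-level reuse*: once a hierarchy has mastered many
categories, a new category can be described compactly by its pattern of
similarity to the known ones — so a linear readout over the
category-tuned ("conceptual") layer should need far fewer examples than
a readout over generic mid-level shape features, even though the generic
features are richer.

`conceptbench` tests this claim end to end at desk scale, for
researchers in computational neuroscience and transfer learning who want
a controlled, seeded, minutes-not-weeks version of the experiment:

1. **Synthetic category world** — base and novel categories composed of
   shape parts from a shared dictionary (so novel categories overlap
   known ones), rendered with translation/scale/rotation jitter, clutter
   and pixel noise.
2. **Trained hierarchy** — a three-stage convolutional network (16/32/64
   channels) plus a concept layer with one unit per base category,
   trained by momentum SGD (lr 0.01, 4% stepped decay, momentum 0.9).
   Four taps expose features at increasing depth: `Generic3`,
   `Generic2` (pooled early/mid activations), `Generic1` (global average
   pool before the fully connected layer) and `Conceptual` (pre-softmax
   concept scores), plus the concatenated `Generic1+Conceptual` set.
3. **Few-shot protocol** — for every feature set × novel category ×
   training size n ∈ {2,4,8,16,32} × 20 splits: a balanced n/2-positive
   / n/2-negative training set, a one-vs-all elastic-net logistic
   classifier
   (α = 0.5, λ = 1/n, training-set-only standardisation, monotone
   proximal-gradient solver), and a balanced held-out test set.
4. **Scoring and statistics** — sensitivity d′ = Φ⁻¹(HR) − Φ⁻¹(FAR)
   per split (extreme rates clamped to 1/(2N)); category-level means;
   category-resampling bootstrap CIs; paired sign-flip permutation
   contrasts between feature sets.

## Worked example

```r
library(conceptbench)

cfg   <- world_config(seed = 7)          # 30 base + 10 novel categories
world <- build_world(cfg)
train <- generate_dataset(world, "base-train")   # 5,250 images
val   <- generate_dataset(world, "base-val")     #   750 images
novel <- generate_dataset(world, "novel")        # 2,000 images

hc    <- hierarchy_config(concept_width = 30, seed = 7)
model <- train_hierarchy(train, val, hc, verbose = TRUE)
#> epoch 20  loss 0.7227  top1 0.787  top5 0.951

taps  <- c("Conceptual", "Generic1", "Generic2", "Generic3")
fsets <- setNames(lapply(taps, extract_features,
                         model = model, dataset = novel), taps)
fsets[["Generic1+Conceptual"]] <-
  combine_feature_sets(fsets$Generic1, fsets$Conceptual)

res <- run_benchmark(fsets, protocol_config(master_seed = 7),
                     enet_config())
summarize_benchmark(res, n_boot = 500, seed = 1)
#> <benchmark_summary> grand means (d'):
#>    feature_set n_pos mean_dprime ci_lower ci_upper
#> 1   Conceptual     1       0.707    0.506    0.895
#> 2   Conceptual     2       1.595    1.450    1.788
#> 6     Generic1     1       0.406    0.295    0.538
#> 7     Generic1     2       1.335    1.151    1.495
#> 16    Generic2     1       0.296    0.186    0.423
#> 21    Generic3     1       0.197    0.147    0.245
#> ...

contrast_feature_sets(res, "Conceptual", "Generic1", n_pos = 1,
                      n_perm = NULL)      # exact sign-flip permutation
#>        set_a    set_b n_pos mean_difference p_value n_permutations
#> 1 Conceptual Generic1     1           0.301  0.0332           1024
```

With a single positive training example, conceptual features support
markedly better discrimination of novel categories (d′ 0.71) than the
generic pooled features from any depth (0.41 / 0.30 / 0.20, ordered by
depth), and the paired contrast against the closest control is
significant (exact p = 0.033; likewise p = 0.037 at two positives).
The advantage shrinks as training sets grow (+0.30 at one positive,
−0.13 at sixteen), where the generic features catch up — concept-level
reuse is specifically a few-example advantage.

`write_report(summarize_benchmark(res), contrasts, "report/")` writes
`summary.tsv`, `contrasts.tsv`, a per-category dot / cross-bar CI figure
and a JSON manifest.  A thin CLI over the same functions lives in
`inst/cli/conceptbench.R` (`generate`, `train`, `benchmark`, `report`).

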