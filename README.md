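# pathproxy

Cross-modal alignment of preoperative brain MRI and postoperative
whole-slide-image (WSI) pathology for 12-month overall-survival prediction
in glioblastoma — including the retrieval trick that makes the pathology
side usable for patients who only have imaging.

## The problem and the method

Histopathology carries strong prognostic signal but only exists after
surgery; preoperative models therefore usually use MRI alone. `pathproxy`
implements a contrastive solution:

1. **Alignment.** For paired patients, an imaging feature (3D CNN + global
   average pooling, or a precomputed vector) and a slide feature (a
   padding-aware multi-head-attention aggregator with a learnable CLS token
   over the variable-length patch-feature set) are projected by two-layer
   MLP heads into one d-dimensional space and L2-normalized. With
   `S_ij = (ê_img(i) · ê_path(j)) / τ`, training minimizes the symmetric
   InfoNCE loss

   `L = -1/(2N) Σ_i [ log softmax_row(S)_ii + log softmax_col(S)_ii ]`,

   with Adam, a cosine-annealed learning rate (3e-3 → 1e-6), weight decay
   1e-5, batch size 15, in-batch negatives, and τ = 0.07 (grid
   {0.01, 0.05, 0.07, 0.1, 0.2} selectable on validation Recall@1).
2. **Library and retrieval.** The frozen model embeds every paired patient
   into a library of `(id, ê_img, ê_path)` records. A new, imaging-only
   patient queries the library by cosine similarity; the best-matching
   pathology embedding (or the similarity-weighted, re-normalized mean of
   the top k) becomes a *proxy* pathology representation.
3. **Survival fusion.** The imaging feature concatenated with the proxy
   feeds a small feed-forward classifier of the binary 12-month
   overall-survival label (strictly greater than 12 months = class 1).

Retrieval quality is measured by Recall@1 / Recall@5 / mean reciprocal
rank against the analytic random baselines k/N and H_N/N; classification
by accuracy, AUROC (midrank statistic), sensitivity, specificity and F1.
WSI preprocessing operators (non-overlapping 256-px tiling, Otsu
background rejection, Macenko stain normalization, tumor-centroid volume
cropping) are included and oracle-tested.

Everything runs end-to-end on a synthetic paired cohort whose latent
patient state drives both modalities and whose survival is mediated by a
pathology-visible nonlinearity — see the methods vignette
(`vignettes/pathproxy-methods.Rmd`) for the model, the generator design
and its limitations.

## Worked example

```r
library(pathproxy)

cohort <- generateCohort(syntheticConfig(n_patients = 98, seed = 42,
                                         imaging_noise_sd = 0.3,
                                         patch_noise_sd = 0.05))
model <- trainAlignment(cohort[1:60],
                        config = trainConfig(epochs = 30, embed_dim = 16,
                                             hidden_img = 64,
                                             hidden_path = 128, seed = 7))
emb <- embedCohort(model, cohort[61:98])
retrievalReport(emb$img, emb$path, k_values = c(1, 5))
```

```
$recall_at
       k1        k5
0.7105263 1.0000000

$mrr
[1] 0.8109649

$N
[1] 38
```

Against 38 held-out patients, the trained model ranks the true pathology
match first for 71% of imaging queries (random level 1/38 ≈ 0.026) and in
the top five for all of them (random 5/38 ≈ 0.132); the mean reciprocal
rank 0.81 compares to the uniform-ranking level H₃₈/38 ≈ 0.111. A full pipeline run
— simulation, alignment, library, retrieval, three survival input modes
and the top-k ablation — is one call:

```r
res <- runPipeline(runConfig(seed = 1), out_dir = "out")
res$survival_metrics     # imaging / trained_proxy / random_proxy rows
res$ablation             # one row per k in {1, 3, 5, 10}
```

A thin CLI wrapper lives at `inst/cli/pathproxy`
(`pathproxy simulate|pipeline --config cfg.yaml --out dir --seed 1`).

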