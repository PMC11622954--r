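# brainseg

Desk-scale brain-tumor MRI analysis on 2-D slices, fully testable against
synthetic ground truth. The package is aimed at researchers who want a
reproducible, inspectable implementation of an intensity-clustering
segmentation stack and a wrapper feature selector — every stage runs on
simulated phantoms, so no imaging data or GPU is needed to exercise,
verify or extend it.

## What it implements

* **Phantom simulation** — multi-tissue elliptical brain slices with a
  skull ring, a randomly placed tumor blob, a smooth multiplicative bias
  field and Rician magnitude noise, plus class-structured feature tables
  with a known informative subset (`generate_phantom`,
  `generate_feature_table`).
* **Preprocessing** — skull stripping (Otsu + morphology), exact median
  filtering, and entropy-adaptive contrast-limited histogram equalization
  with PSNR/contrast reporting (`strip_skull`, `median_filter`, `acclahe`,
  `enhancement_metrics`).
* **LWIFCM clustering** — intuitionistic fuzzy c-means with a Yager
  non-membership `γ = (1 − u^α)^{1/α}`, hesitation `π = 1 − u − γ`, and a
  local spatial-information penalty
  `G_ij = Σ_{r∈N_j} (1 + d_jr)^{-1} (1 − u_ir)^m ‖x_r − v_i‖²`
  weighted by the local-to-average variance ratio
  `k_j = (σ_j² + ρ)/(σ̄² + ρ)`; objective
  `Ĵ = Σ u*ᵐ d² + Σ π e^{1−π} + Σ k_j G_ij` (`run_lwifcm`).
* **Chameleon swarm optimizer** — bound-constrained continuous minimizer
  with decaying exploration `ρ = δ e^{−αt/R}`, inertia
  `W = (1 − r/R)^{λ√(r/R)}` and acceleration `y = 2590(1 − 1/r)`
  (`csa_minimize`).
* **Swarm-seeded segmentation** — the swarm searches the initial centers
  and `(α, m)` of LWIFCM; labels are matched to ground truth by greedy
  maximum overlap and scored with Dice/IoU (`segment_image`,
  `match_labels`).
* **Binary chaotic transient-search feature selection** — sigmoid-binarized
  transient search with logistic-map chaos, elitist best, and the
  cross-validated fitness `Fit = w₁·Acc + w₂·(1 − n/N)` over a
  5-nearest-neighbour wrapper (`bctso_select`).
* **Architecture shape calculus** — layer-by-layer tensor-shape propagation
  and seeded random-weight forward passes for a channel-expansion residual
  attention network (CER/ACA/BIF/Res2Net blocks), including reciprocal
  Gaussian-density channel attention (`propagate_shapes`, `ercp_net_spec`,
  `extract_features`).
* **Evaluation** — accuracy/precision/recall/F-score from confusion counts
  (macro one-vs-rest for multi-class), MAE/MSE/RMSE, Dice/IoU, stratified
  k-fold splitting (`classification_metrics`, `error_stats`, `dice_iou`,
  `stratified_kfold`).

A thin command-line front end with `simulate | preprocess | segment |
select | shapes | evaluate` subcommands ships in `inst/cli/brainseg`.

## Worked example

Simulate a noisy phantom, preprocess it, and segment the tumor:

```r
library(brainseg)

ph <- generate_phantom(phantom_config(image_size = 128, rician_sigma = 0.05,
                                      bias_amplitude = 0.1, seed = 4))
pre <- median_filter(strip_skull(ph$image)$image, 3)
cfg <- segmentation_config(c = 4, pop_size = 8, iterations = 10, seed = 7,
                           lwifcm = lwifcm_config(max_iter = 50))
res <- segment_image(pre, cfg, truth = ph$labels)
round(res$centers, 3)
#> [1] 0.000 0.353 0.553 0.831
res$scores
#>   pred_label truth_label      dice       iou
#> 0          0           0 0.9734776 0.9483258
#> 1          1           1 0.8813995 0.7879485
#> 2          2           2 0.8963912 0.8122363
#> 3          3           3 0.9689655 0.9397993
```

The recovered centers sit on the true tissue intensities (0.35, 0.55) and
the tumor intensity (0.8); the tumor (truth label 3) is delineated with
Dice 0.97 despite 5% Rician noise and a 10% bias field. The fainter tissue
rows lose a thin boundary band to skull-strip erosion, which is expected.

Select informative features from a synthetic radiomics table:

```r
tab <- generate_feature_table(feature_table_config(seed = 11))
sel <- bctso_select(tab, tso_config(pop_size = 20, iterations = 100, seed = 101))
sum(sel$best_mask & tab$informative_mask)  # informative features recovered
#> [1] 4
```

Four of the five planted informative features are recovered at this seed
(the median over seeds recovers all five); the fifth is the cyclic
duplicate marker, whose marginal accuracy rarely outweighs the fitness
term that rewards smaller subsets.

## Scope

Everything is 2-D and synthetic by design: the package demonstrates and
tests the algorithms, not clinical performance. See the methods vignette
(`vignettes/brainseg-methods.Rmd`) for the models, parameter defaults,
design decisions at ambiguous points, and known limitations.
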