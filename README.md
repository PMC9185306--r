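# endodiag

Classical image-analysis pipeline for computer-aided diagnosis of lower
gastrointestinal endoscopy frames, for researchers who want a fully
classical, dependency-light baseline: enhancement, seeded lesion
segmentation, handcrafted feature fusion, shallow classifiers, and complete
confusion-matrix reporting — exercised end to end on synthetic endoscopy
phantoms with ground-truth masks, so nothing requires external data or
pretrained networks.

## The method

For a frame *f* (grayscale by channel averaging), the enhanced plane is

&nbsp;&nbsp;&nbsp;&nbsp;*O = mean₅ₓ₅(f) − ∇²f*

with a centre-excluded 5×5 box mean (each pixel replaced by the average of
its 24 neighbours) and the 4-connected Laplacian, both replicate-padded.

Lesions are segmented by a region-based active contour: with inside /
outside means *c₁*, *c₂* under a smoothed Heaviside *H<sub>ε</sub>*, the
level set evolves by

&nbsp;&nbsp;&nbsp;&nbsp;*φ ← φ + dt · spf(I) · (λ|∇φ| + ν)*,&nbsp;&nbsp;
*spf(I) = (I − (c₁+c₂)/2) / max|I − (c₁+c₂)/2|*

until the mask area changes by less than SV% between iterations; the
seed's connected component is returned and interior holes are filled
morphologically.

Each region of interest yields a fused handcrafted descriptor of
**203 (LBP) + 13 (GLCM/Haralick) + 16 (fuzzy colour histogram) = 232**
features; a pluggable embedding extractor can prepend a deep block
(**4096 + 232 = 4328** with the conventional width). Classification is a
single-hidden-layer network (30 ReLU units, softmax output, cross-entropy
with MSE logged, early stopping on validation loss) or a linear one-vs-one
SVM. Evaluation covers stratified 640/160/200-style splits, eightfold
training augmentation, one-vs-rest accuracy / precision / sensitivity /
specificity, ROC AUC by threshold sweep, and pixel-level mask scores
(accuracy, precision, recall, Dice).

## Worked example

```r
library(endodiag)

# 5-class phantom study: generate, enhance, extract 232 features,
# split 64/16/20 per class, train the network, score the test set
res <- phantom_experiment(n_per_class = 100, seed = 1)
res$accuracy
#> [1] 0.98
res$metrics
#> Per-class metrics (%):
#>               class accuracy precision sensitivity specificity
#>  dyed-lifted-polyps       99      95.2         100        98.8
#>        normal-cecum      100     100.0         100       100.0
#>      normal-pylorus      100     100.0         100       100.0
#>              polyps       99      95.2         100        98.8
#>  ulcerative-colitis       98     100.0          90       100.0
#> Macro: accuracy 99.2, precision 98.1, sensitivity 98.0, specificity 99.5
#> Overall accuracy: 98.0%
```

98% of the 100 held-out phantoms (20 per class) are classified correctly;
the only confusions are two ulcerative-colitis frames whose diffuse
reddening resembles other lesion classes.

Segmenting a single lesion:

```r
ph <- generate_phantom(phantom_spec("polyps", seed = 2))
g  <- average_filter(to_gray(ph$image))       # smoothed plane for the contour
m  <- fill_holes(segment_lesion(g, seed = round(ph$spec$center), radius = 5))
mask_scores(m, ph$mask)
#>  accuracy precision    recall      dice
#>      99.4     100.0      90.8      95.2
```

A thin command-line front end over the same functions ships in
`inst/scripts/endodiag-cli.R` (subcommands `enhance`, `segment`,
`features`, `train`, `predict`, `evaluate`, `simulate`).

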