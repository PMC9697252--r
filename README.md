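# hierfusion

Multi-perspective hierarchical deep-fusion learning for 3D
nodule-vs-non-nodule classification, in R.

Computer-aided detection of pulmonary nodules in CT has to tell small,
bright, roughly spherical lesions apart from confusable structures
(vessels, noise clumps) with as few false positives per scan as
possible. `hierfusion` implements a decision-level fusion scheme for
this problem: instead of one 3D network, a volume of interest (VOI) is
sliced along its three orthogonal perspectives — transverse (V1),
coronal (V2) and sagittal (V3) — and classified in three hierarchical
stages, each trained separately on the frozen outputs of the previous
one ("modular training"):

* **Slice modules MS_i** — one compact CNN per perspective
  (4 × [3×3 conv, ReLU, 2×2 max-pool] with 8/16/32/64 filters, FC-32,
  softmax; input 56×56, spatial trace 56 → 28 → 14 → 7 → 3) scoring each
  of the 6 selected slices with a nodule probability,
* **Perspective modules MP_i** — a one-hidden-layer feedforward
  classifier mapping the 6 slice scores of perspective i to one
  perspective score,
* **Volume module MV** — the same kind of classifier fusing the three
  perspective scores into the final nodule probability.

Variants swap the raw slices for feature images (Laplacian of
Gaussian, Gabor, bilateral, or the trilateral filter — a bilateral
filter with a second range kernel on differences of Laplacian
responses), and a top fusion level combines several such hierarchies by
training one more classifier over their volume scores.

The package is self-contained: a seeded phantom generator produces
CT-like scans with bright quasi-spherical nodules, distractor
structures (tubes, dim blobs, speckle) and multi-reader annotations
with center jitter, followed by reader consensus, conflict elimination,
30 mm VOI extraction resampled to 56³, equal-interval slice selection,
stratified 70/30 splitting, and level-wise evaluation (ACC, AUC, F1,
sensitivity, specificity, ROC curves, false positives per scan).

## A worked example

```r
library(hierfusion)

records <- phantomStackDataset(nScans = 30, objectsPerScan = 4,
                               separability = "easy", seed = 11)
split <- splitDataset(records, 0.7, seed = 3)
cfg <- mpfConfig(dcnn = dcnnConfig(epochs = 8, patience = 3))

model <- trainMpf(records[split$train], cfg, seed = 5)
levelReport(model, records[split$test])
```

```
EvaluationReport over 36 objects / 23 scans; fp/scan = 0 
        level perspective   acc   auc    f1  sens  spec
1       slice          V1 0.935 0.980 0.936 0.944 0.926
2       slice          V2 0.921 0.983 0.924 0.963 0.880
3       slice          V3 0.912 0.954 0.918 0.981 0.843
4 perspective          V1 0.944 0.969 0.944 0.944 0.944
5 perspective          V2 1.000 1.000 1.000 1.000 1.000
6 perspective          V3 0.972 1.000 0.973 1.000 0.944
7      volume         all 1.000 1.000 1.000 1.000 1.000
```

Reading the table: individual slices are classified at 0.91–0.94
accuracy; fusing the six slice scores of each perspective lifts every
view to 0.94–1.00; fusing the three perspective scores gives the final
volume-level decision (here every test object correct, zero false
positives across the 23 test scans). That slice → perspective → volume
improvement is the point of the hierarchical scheme.

A feature-image variant only changes the front end, e.g.
`trainMpf(..., featureSpec = filterSpec("trilateral"))`, and
`trainMfmpf(list(model1, model2, ...), trainRecords, cfg)` fuses
several trained hierarchies at a fourth level.

A thin CLI over the same functions is installed at
`inst/cli/hierfusion` (`simulate`, `extract`, `train`, `evaluate`).

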