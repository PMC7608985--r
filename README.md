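# cystquant

Quantification of cystic disease severity from histological images of
polycystic kidney and liver.

In polycystic kidney disease (PKD) and polycystic liver disease (PLD),
parenchyma is progressively replaced by fluid-filled cysts, and the
standard severity biomarker in translational studies on mouse models is
the **cystic index (CI)** — the percentage of a tissue section occupied by
cyst lumens — together with the cyst count and the cyst-size profile.
Most labs estimate CI by global thresholding in a general-purpose image
tool, which overestimates it badly because every bright structure
(vessel lumina, bile ducts, dilated tubules, tears) counts as cyst.
`cystquant` is a headless library and command-line tool for researchers
who need reproducible, supervisable cyst quantification from H&E-stained
sections.

## What it does

**Automatic cyst recognition.** Cyst lumens are nearly unstained, so they
are bright in the green channel of an H&E image. The recognizer runs six
steps on an RGB section image:

1. extract the green channel `IG`;
2. compute its global mean grey level `μG`;
3. threshold: `IB = IG > μG`;
4. refine `IB` by two-cluster k-means on the pixel intensities
   (Lloyd's algorithm, initial labels `IB`); the brighter cluster of
   `Ik` is the cyst-candidate foreground;
5. remove noise with a morphological opening (disk of 3 px for liver;
   `max(3, round(dmin))` px for kidney), giving `Io`;
6. extract one outer-border contour per 8-connected component
   (Suzuki–Abe border following) and keep regions whose
   equivalent-circle diameter `2·sqrt(A/π)` lies in `[dmin, dmax]`.

**Small-cyst texture classification.** Very small cysts are confusable
with renal tubules and bile ducts. Candidates are described by
rotation-invariant uniform local binary patterns at scales
`(R,P) ∈ {(1,8), (2,16), (3,24)}` (a 54-dimensional histogram
descriptor over the candidate's pixels) and classified by an RBF-kernel
SVM whose `C` and `γ` are grid-searched (`2^-5..2^15` and `2^-13..2^3`,
step 2 in the exponent) by 4-fold cross-validated Cohen kappa.

**Supervision with an audit trail.** Delete, draw, complete, split,
merge, remove-inner and add-smaller-cysts edits operate on the cyst set
and append to a replayable edit log with undo/redo. The log drives the
error accounting: a deletion of an automatic detection is a false
positive, a manual addition a false negative, a split one FP plus two
FN, a merge of k cysts k FP plus one FN, and so on. From the counts,

    Se = 100·TP/(TP+FN),   Sp = (1 − FP/NA)·100,   NA = TP+FP,  NS = TP+FN,

plus the percentage of cysts deleted (`PCD = 100·FP/NA`) and added
(`PCA = 100·FN/NS`).

**Quantification and I/O.** Cystic index (union of cyst regions over the
section area), cyst count, diameter profile (100-px bins with an
overflow tail), organ-specific severity classes (kidney: mild < 35%,
cystic 35–55%, severe > 55%; liver: 5%/15%), CSV export and a lossless
annotation-XML round trip of cysts plus edit log. A System Usability
Scale scorer for questionnaire studies is included.

**Synthetic histology with ground truth.** A seeded generator emulates
H&E appearance (bright smooth elliptical lumens on speckled darker
tissue, plus speckle-textured tubule/duct/vessel distractors) and
returns exact ground-truth masks, so the whole pipeline is testable
without slide images.

## Worked example

```r
library(cystquant)

spec <- fixture_spec(n_cysts = 12, seed = 11)         # synthetic kidney section
gen  <- generate_histology_image(spec)
rec  <- recognize_cysts(gen$image, organ = "kidney",
                        range = diameter_range(12, 100))
rec
#> <cyst_recognition: 12 cysts, mean grey level 151.77>
summary(rec$cyst_set)
#> Cysts: 12   Cystic index: 1.90%   Edits applied: 0
#> Equivalent diameters (px):
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   25.26   29.26   38.66   38.49   42.77   57.98
#> Origins: auto=12
cystic_index(gen$truth$cysts)    # ground-truth CI for comparison
#> [1] 1.907935
```

All 12 planted cysts are recovered and the pipeline's cystic index
(1.90%) is within 0.01 points of the ground truth. Supervision edits
feed the error accounting:

```r
s <- delete_cyst(rec$cyst_set, 1)       # reviewer rejects one detection
k <- counts_from_log(rec$cyst_set, s)
k
#> <eval_counts: TP 11, FP 1, FN 0 (NA 12, NS 11)>
sensitivity(k); specificity(k)
#> [1] 100
#> [1] 91.66667
```

The command-line front end wraps the same functions:

```sh
cystquant synth     --seed 4 --out-dir demo --n-cysts 8
cystquant recognize --image demo/image.png --organ kidney \
                    --dmin 12 --dmax 100 --out demo/auto.xml
cystquant quantify  --annotations demo/auto.xml --csv demo/quant.csv
# Image auto.xml (kidney, automated): CI 1.68% [mild_cystic], 8 cysts
```

## Documentation

The methods vignette (`vignettes/cystquant-methods.Rmd`) describes the
model assumptions, parameter choices, the synthetic generator's scope,
and known limitations.
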