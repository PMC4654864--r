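# fociQuant

Automated counting of nuclear foci — such as gammaH2AX foci marking DNA
double-strand breaks — in two-channel fluorescence microscopy images, for
radiation biologists and DNA-damage labs who need per-nucleus focus counts
from batches of images without manual, operator-biased counting.

## What it computes

From an RGB image (DNA stain in blue, foci antibody signal in green) or a
grayscale image pair, the package reports the **mean foci number per
nucleus** with its standard error (SEM), per image and per batch.

Nuclei are segmented by Huang's fuzzy-entropy threshold, hole filling,
median filtering, opening by reconstruction (disk radius r_n = 10), bay
closing (3x3 element, 3 iterations) and a distance-transform watershed
that separates touching nuclei. Foci are detected inside each nucleus by:

1. adaptive median filtering (impulse-noise removal),
2. white top-hat with a disk of radius r_f = 3 (background and
   illumination correction),
3. the **H-maxima transform** with height h set to Otsu's threshold of the
   top-hat image — HMAX_h(f) is the morphological reconstruction by
   dilation of f − h under f, suppressing every peak of prominence < h,
4. regional maxima extraction, and
5. a final screening keeping maxima plateaus whose mean top-hat intensity
   is at least T_e = 0.07.

A built-in simulator generates single-nucleus foci images with known
ground truth (focus templates of varying size, shape and pairing, plus
homogeneous and inhomogeneous noise), enabling two benchmark statistics:

- reliability: RelDiff1 = (N_auto − N_ref) / N_ref · 100 %
  against the simulated ground truth (positive = overestimation);
- robustness: RelDiff2 = |N_base − N_art| / N_base · 100 % after adding a
  circularly averaged (pillbox radius f = 1..6) neighbouring focal plane
  to emulate out-of-focus contamination.

## Worked example

```r
library(fociQuant)

# a dense simulated image with known ground truth
sim <- simulateFociImage(presetConfig("irradiated"), seed = 7)
sim
#> SimulatedFoci: 300 x 300 pixels, 66 ground-truth foci

res <- detectFoci(pixelMatrix(sim), fullFrameNucleus(dim(pixelMatrix(sim))))
res
#> FociCount: 56 foci in 1 nuclei
#>   mean foci/nucleus = 56.000 (SEM 0.000)

relDiff1(sum(fociPerNucleus(res)), trueFociCount(sim))
#> [1] -15.15152
```

56 of 66 true foci are found on this image: the deficit is dominated by
paired templates placed 3 px apart, which the pipeline intentionally
stress-tests (adjacent foci merge when their intensity dip is below the
H-maxima height). The blur-robustness protocol on a simulated
base/neighbour pair:

```r
nb <- simulateFociImage(presetConfig("irradiated"), seed = 8)
blurRobustness(pixelMatrix(sim), pixelMatrix(nb), radii = 1:6)
#>   f nBase nArt relDiff2
#> 1 1    56   98   75.000
#> 2 2    56   93   66.071
#> 3 3    56   68   21.429
#> 4 4    56   55    1.786
#> 5 5    56   56    0.000
#> 6 6    56   56    0.000
```

At small radii the (independent) neighbour image's foci are still sharp
enough to be counted; from f = 4 on, the contamination is fully
suppressed by the top-hat/H-maxima chain.

Real images go through the same interface:

```r
pair <- readChannelPair("field.tif")   # or runCount("images/", "out/")
out  <- countFoci(pair)
meanFoci(out$foci); semFoci(out$foci)
```

`runCount()` processes a directory into a CSV of per-nucleus counts with
per-image summaries plus overlay PNGs marking each detected focus with a
red frame. A command-line wrapper with `count`, `simulate`,
`benchmark-reldiff1` and `benchmark-blur` subcommands lives at
`inst/scripts/fociquant.R` (YAML config supported; flags override file values).

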