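# lamellaR

Automated measurement of lamellar thickness in polarized-light micrographs
of cortical bone.

Under crossed polarizers, bone lamellae appear as alternating bright and
dark bands; their thicknesses are a histomorphometric readout of bone
formation and are altered in collagen disorders such as osteogenesis
imperfecta. Manual measurement is slow and samples each lamella at one
point. lamellaR measures every lamella across the full width of an
operator-chosen region: the operator draws a yellow rectangle (RGB
255,255,0) around a regular stack of lamellae, marks its top corners with
red pixels (237,28,36) and bottom corners with green (34,177,76), and
counts the bright/dark bands; the pipeline then

1. detects the fiducials and rotates the image so the red pair is level
   (lamellae horizontal), nearest-neighbor resampling so marker colors
   survive;
2. crops strictly inside the yellow rectangle;
3. converts to grayscale, stretches contrast (1% saturation per tail), and
   marks each pixel bright iff its intensity strictly exceeds the mean of
   the 20 nearest pixels in its column; isolated wrong-color runs of ≤ 2 px
   inside a lamella are recolored;
4. run-length encodes each pixel column, rejects columns whose first-pixel
   color or lamella counts disagree with the operator's counts, and
   reports each lamella's mean run length over the retained columns,
   converted to micrometers (default calibration 0.3185 µm/px at 20x).

For lamella *i* with run length `L_ij` px in retained column *j*,

    T_i = pixel_length_um * mean_j(L_ij),   j over the ngSets retained of nSets columns.

Method agreement against manual measurements is supported by paired
percent differences (manual as reference) and the exact two-sided paired
sign test, `p = min(1, 2 * sum_{j<=k} C(n,j) / 2^n)`.

## Worked example

The study's micrographs are confidential, so the package ships a synthetic
generator that renders annotated band scenes with ground truth:

```r
library(lamellaR)
fx <- generate_fixture(fixture_spec())          # 4 bright + 3 dark bands
m  <- measure_lamellae(fx, n_bright = 4, n_dark = 3)
m
#> Lamellar thickness measurement
#>   columns: 120 retained of 120 (pixel length 0.3185 um)
#>   bright lamellae (um): 1.5925 1.9110 1.5925 2.2295
#>   dark lamellae (um):   1.2740 1.2740 1.2740
```

The fixture's bands are 5/4/6/4/5/4/7 px thick top to bottom; bright bands
of 5, 6, 5 and 7 px yield exactly 5 × 0.3185 = 1.5925 µm and so on — a
noiseless, unrotated fixture is recovered exactly, and all 120 columns
pass quality control (`ngSets = nSets`). On real images `ngSets < nSets`:
columns crossing osteocyte lacunae or clipped lamellae are rejected and
grayed out in the sixth diagnostic figure (`plot(m)`, or
`output_dir = ...` to write `stage_1..6` PNGs plus `results.csv/json`).

A command-line front end with subcommands `measure`, `count`,
`make-fixtures` and `agree` is installed at
`system.file("scripts", "lamellar_measure.R", package = "lamellaR")`.

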