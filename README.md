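# steatr

Feature-based quantification of macrovesicular steatosis (MaS) on
hematoxylin–eosin (H&E) stained liver histology images.

## The problem

Macrovesicular steatosis — hepatocellular fat stored as large droplets that
displace the nucleus — is a key determinant of donor-liver quality in
transplantation, graded as the percent of tissue area occupied by fat.
Visual grading of frozen sections is subjective: expert pathologists
routinely disagree by several percentage points, and that variability feeds
directly into organ-utilization decisions made under time pressure.

`steatr` implements a transparent, geometry-only alternative for
pathologists and image-analysis groups: lipid vacuoles appear as bright,
round, unstained holes in eosin-pink tissue, so they can be found by
stain-agnostic grayscale processing and separated from look-alike artifacts
(vessel lumina, tears, folds, coverslip glare) by interpretable region shape
descriptors — no training data, no GPU, every decision auditable.

## The method

For a slide image with scale `mpp` (microns per pixel):

1. **Tissue mask** — grayscale luminance, 5×5 mean filter, Otsu threshold
   (tissue is the darker class); stained specks < 2000 µm² removed; a
   100-pixel border band cropped away.
2. **Artifact suppression** — morphological closing bridges narrow tears;
   interior voids are filled, then voids larger than 1.5×10⁶ µm² or with
   convexity < 0.85 (folds, tears) are carved back out; low-saturation
   pixels at clipped brightness (coverslip glare) are removed. Unstained
   vacuole voids stay filled: vacuoles are tissue.
3. **Candidate detection** — dynamic threshold: a pixel is a candidate iff
   its gray value exceeds its 31×31 local mean by ≥ 5 gray levels, within
   the tissue mask (vacuoles are bright-on-dark).
4. **Classification** — each connected candidate region (holes filled) is
   kept iff, with `F` the pixel count, contour polygon area `A`, perimeter
   `L`, centroid distances `d_i` and second-moment axis ratio `Ra/Rb`:

   | descriptor | definition | accept when (defaults) |
   |---|---|---|
   | area | `F · mpp²` | 50–12 000 µm² |
   | roundness | `1 − σ_d / d̄` | ≥ 0.55 |
   | circularity | `A / (π · max dᵢ²)` | ≥ 0.45 |
   | compactness | `L² / (4πA)` | ≤ 2.0 |
   | convexity | `A / A_hull` | ≥ 0.80 |
   | anisometry | `Ra / Rb` | ≤ 2.5 |

5. **Quantification** — `steatosis_pct = 100 · Σ accepted area / tissue
   area`, plus the ordinal grade over the bins
   {0%, 1–5%, 6–10%, 11–15%, 16–20%, 21–30%, >30%}.

All thresholds live in a config (`pipeline_config()`, or YAML/JSON via
`read_config()`); tuning = edit, re-run. The package also ships the
validation statistics used to compare automated and human scores —
quadratically weighted Cohen's κ with Landis–Koch bands, Pearson/Spearman
correlations with CIs, RMSE, Bland–Altman limits of agreement, ±5-point
tolerance rates, range classification — and a seeded synthetic-slide
generator with exact ground-truth masks so the whole system is testable
without clinical data.

## Worked example

```r
library(steatr)

# render a synthetic slide: 1024x1024 px at 1 um/px, true fraction 10%
out <- generate_slide(synthetic_spec(fraction = 0.10, seed = 42))
out$truth$true_fraction
#> [1] 0.09725879

res <- run_pipeline(out$slide)
res
#> <steatosis_result> 9.64% (6-10%)
#>   tissue 2.307e+05 um^2, vacuoles 2.224e+04 um^2
#>   9 accepted / 6 rejected regions

glance(res)      # one-row summary
tidy(res)        # per-region descriptors with accepted/reason
autoplot(res)    # where the shape filters cut
```

The estimate (9.64%) recovers the generated truth (9.73%) to within a tenth
of a percentage point; the 6 rejected regions are the rendered vessels and
tear fragments, each carrying the first filter it failed.

From a shell, the same pipeline runs via the bundled CLI
(`inst/cli/steatr`): `quantify` one image, `batch` a folder, `simulate`
fixtures, `agree` on a ratings CSV. Machine-readable JSON/CSV goes to files;
every report embeds its manifest (inputs, effective config, version, seed).

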