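# lequant

Object-based quantification of neuronal fluorescence micrographs for
studying mTORC1 signalling: how much mTOR is recruited onto
LAMP1-positive late endosomes/lysosomes (LEs) in dendrites, and where
mTORC1 activity — read out as phospho-S6 (P-pS6) immunofluorescence — is
located across the somatodendritic compartment.

The package is aimed at labs quantifying multi-channel 2D epifluorescence
images (MAP2 / LAMP1 / mTOR / P-pS6 stains) and at anyone who wants a
fully testable reference implementation of this class of analysis: every
stage can be validated against a built-in synthetic neuron-image
generator with complete ground truth, so no microscope data are needed to
verify the pipeline.

## The measurements

**IN/OUT recruitment ratio.** LE puncta are segmented from the
background-subtracted LAMP1 channel (isodata threshold, 8-connected
components, objects kept only if their area is strictly above 25 px —
about 350 nm equivalent diameter at 65 nm/px). The **IN** mask is the
union of LE footprints; the **OUT** mask is a 4-px-wide ring whose exact
Euclidean distance *d* to the nearest LE pixel satisfies 6 < *d* ≤ 10,
i.e. a ring starting 6 px outside each object. Both masks are restricted
to the dendritic MAP2 mask (mean auto threshold, somata removed), then
transferred to the background-subtracted mTOR channel:

    ratio = mean(mTOR | IN) / mean(mTOR | OUT)

A ratio of 1 means no recruitment; larger values mean mTOR is enriched on
LEs relative to the surrounding dendritic cytoplasm.

**Compartmentalized P-pS6 activity.** The MAP2 mask is transferred to the
background-subtracted P-pS6 channel to measure whole-field neuronal mean
intensity; somata are segmented from the P-pS6 image itself
(threshold + watershed) and removed from the MAP2 mask to split the
signal into somatic and dendritic compartments (the two partition the
whole mask exactly). Per-soma means support a percentile-shift analysis —
the fraction of treated somata strictly above the 75th percentile of the
control distribution — and line profiles along dendrites support
exponential-decay fitting and prominence-based hot-spot detection.

**Statistics.** Two conditions: Welch t-test when both groups pass
Shapiro-Wilk normality, otherwise Mann-Whitney U (exact for small
tie-free samples). Three or more: one-way ANOVA + Tukey HSD when all
groups are normal and Bartlett's test accepts equal variances, otherwise
Kruskal-Wallis + Dunn's test with Bonferroni correction. Stars at
p < 0.05 / 0.01 / 0.001.

Background subtraction throughout is the rolling-ball method (diameter
50 px for P-pS6, 75 px for mTOR/LAMP1), implemented exactly as grayscale
opening with a ball-shaped structuring element in compiled code.

## Worked example

Simulate two conditions (ground-truth enrichment 1.0 vs 2.18 — the
latter mirroring a glycine-stimulated condition), run the full
recruitment pipeline, and compare:

```r
library(lequant)

dir <- tempfile(); dir.create(dir)
cfg <- run_config(seed = 42, output_dir = file.path(dir, "out"))
manifest <- simulate_fixtures(dir, n_images = 5,
  conditions = c(control = 1.0, glycine = 2.18),
  phys = photophysics_params(psf_sigma = 0), config = cfg)

res <- analyze_recruitment(dir, manifest, config = cfg)
res$summary
#>  condition mean_ratio      sem n
#>    control     0.9994 0.002308 5
#>    glycine     2.0768 0.001304 5
res$comparison
#> <group_comparison> welch-t: statistic = -406.4, p = 3.423e-15 ***
```

The recovered mean IN/OUT ratios track the generator's ground-truth
enrichment (1.0 and 2.18; the residual deficit at high enrichment comes
from threshold-edge pixels of segmented puncta), and the two conditions
separate decisively. `analyze_activity()` provides the corresponding
P-pS6 tables (per field, per soma, percentile shift). All CSV outputs
carry a header recording the package version, a hash of the analysis
parameters and the seed, and reruns are byte-identical.

A thin command-line wrapper with `simulate`, `recruitment` and
`activity` subcommands is included at `inst/cli/lequant.R`.

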