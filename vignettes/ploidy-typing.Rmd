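---
title: "Methods: intensity-based ploidy typing, inheritance inference and variant filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intensity-based ploidy typing, inheritance inference and variant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyscope)
```

## The measurement model

A nucleus's integrated DAPI fluorescence is proportional to its DNA content.
If the integrated (summed, background-subtracted) intensity of a diploid
nucleus is `I`, a tetraploid nucleus measures `2I` and an octoploid `4I`, up
to multiplicative measurement noise. Absolute intensities are meaningless
across slides and settings, so everything is expressed relative to an
internal diploid standard: the **median** integrated intensity of CD31⁺
endothelial nuclei, which are uniformly mononucleated and diploid in these
preparations. The median (not the mean) makes the standard robust to the
occasional mitotic or mis-segmented endothelial nucleus. Normalization uses
at least `min_reference = 10` endothelial nuclei and refuses to run with
fewer — a fallback standard would silently change the meaning of every
downstream call, so there is none.

On the normalized axis (diploid = 1), classes are fixed windows:

| class | window |
|---|---|
| 2n | [0.5, 1.5) |
| 4n | [1.5, 2.5) |
| 8n | (3, ∞) |
| unassigned | [0, 0.5) and [2.5, 3] |

Two numerical choices deserve comment. The window ends are taken
closed-left/open-right so that every value has exactly one class; the
boundary convention matters only on a measure-zero set but must be
deterministic. The (2.5, 3] interval belongs to no class in the window
convention this assay uses; such nuclei (and sub-0.5 debris) are counted as `unassigned` and
reported, never imputed or reassigned, because guessing a class there would
manufacture octoploid or tetraploid counts the data do not support.

## The composition calculus

Per animal and cell type, over viable cells with one or two detected nuclei:

* `mononuclear_pct` and `binuclear_pct` (they sum to 100; cells with ≥3
  detected nuclei are rare segmentation artefacts in suspensions, flagged
  and excluded rather than forced into either bin);
* within each nucleation subgroup, the nuclear class spectrum including the
  unassigned remainder (each spectrum sums to 100);
* the cell-class distribution `1×2n … 2×8n`, where a binuclear cell gets
  class `2×k` only if both nuclei are called `k`;
* the headline quantity, the mononuclear-diploid fraction
  `mononuclear_pct × mono %2n / 100`.

Subgroup spectra are reported separately from nucleation because nuclei are
not sampled in proportion to cell frequency (mononuclear nuclei are
deliberately over-sampled); `combine_subgroups()` performs the explicit
reweighting. Percentages are reported to one decimal, the precision at
which such measurements are conventionally given. One known arithmetic
quirk: the reference values for BALB/cJ hepatocytes, 43.7% mononuclear and
31.9% diploid mononuclear nuclei, multiply to 13.94%, yet the corresponding
diploid-hepatocyte level is conventionally given as 13.6% — evidently
computed from unrounded inputs. This package always computes from its own
inputs and does not attempt to match that figure.

A composition from fewer cells than the per-type minimum (300
cardiomyocytes, 200 hepatocytes, 400 marrow cells — standard counting
depth for these preparations) is still computed but carries `flagged = TRUE`.

Group contrasts use the unpaired two-tailed Student t-test with pooled
variance, the conventional test for two-group contrasts of per-animal
percentages at these sample sizes.
Degenerate inputs are handled explicitly rather than left to error: zero
pooled variance with equal means is t = 0, p = 1; with unequal means the
result is flagged `degenerate` with p at the smallest positive double (an
honest "arbitrarily significant under the model's assumptions, which are
violated").

## What the synthetic generator emulates — and what it does not

`population_spec()` fixes, per cell type: cell counts, a mono/binucleation
probability, and a nuclear-ploidy distribution per nucleation subgroup.
Binucleated cells draw **one** ploidy class shared by both nuclei: a
binucleated cell arises from a single interrupted mitosis, so its nuclei
have equal DNA content, which is also what makes the `2×k` cell classes
well-defined. Intensity is `reference × copies/2 × lognormal(1, cv)` with
`cv = 0.08` by default — an 8% coefficient of variation is typical of
integrated-intensity measurements on well-stained suspensions, and the
lognormal keeps intensities positive and exactly linear in copy number at
`cv = 0`. Viability is Bernoulli(0.9); only live cells are photographed and
counted, so the renderer draws viable cells only, while the table-level path
keeps the flag for explicit filtering.

`strain_population_spec()` presets the measured substrain parameters: 6.6% vs
14.3% mononuclear cardiomyocytes and 66.7% vs 37.6% diploid mononuclear
nuclei for BALB/cJ vs BALB/cByJ (hepatocytes: 43.7/42.6% and 31.9/26.8%).
Binuclear spectra have no single agreed reference values; the presets
use values chosen once so that 2×2n remains the most common polyploid class
in both strains with the BALB/cByJ spectrum shifted toward octoploidy, the
qualitative pattern these substrains show.

The renderer places cells on a jittered exclusive grid (no two marker masks
can overlap), draws each nucleus as a discrete Gaussian blob renormalized so
its pixel sum equals the true intensity exactly, adds a flat background and
optional additive Gaussian pixel noise, and emits a placement map linking
every blob to its ground-truth record. Defaults: 256 px frames, nuclear
radius 4 ± 0.4 px, PSF σ 1.5 px, background 100 au, noise σ 2 au, 40
cells/frame. What is deliberately **not** modeled: illumination gradients,
touching/clumped nuclei, photobleaching, staining variation between slides,
out-of-focus light, ≥3-nucleate cells. Passing end-to-end tests therefore
demonstrate that the measurement chain is unbiased and self-consistent under
clean acquisition — not that segmentation is robust to pathological real
micrographs, where the fixed-threshold/no-watershed design would need the
area-outlier flags it emits.

## Segmentation numerics

Comparability across animals requires one threshold for every frame of a
study, so the default policy computes Otsu's
threshold on the histogram pooled over all frames of a study; a fixed
absolute value can be supplied instead. Background is the median of
sub-threshold pixels per frame. Integrated intensity is summed over the
thresholded component grown by a 6 px measurement aperture: thresholding a
Gaussian blob discards its tails, and because the lost mass is proportional
to the threshold rather than to the nucleus's brightness, skipping the
aperture would bias dim (2n) nuclei downward relative to bright ones. Where
grown apertures of neighbouring nuclei would overlap, pixels go to the
nearer component (a Voronoi split via `EBImage::propagate`), so no nucleus
annexes a neighbour's tail and per-pixel mass is counted at most once.
Background overshoot can make an integrated intensity non-positive; such
records are flagged, never silently dropped.

## Inheritance inference

Phenotypes enter as categories (`low`/`high`/`intermediate`); the inference
itself is categorical, with the threshold between parental levels
applied upstream. The model space crosses linkage (X/autosomal) ×
high-allele origin (2) × dominance (2) × cell autonomy (2) × maternal effect
(2) × imprinted parent (3) = 96 models. Predictions are total and
deterministic; the one modeling commitment is that an X-linked heterozygous
female shows `intermediate` under a cell-autonomous model (X-inactivation
mosaicism averages the two alleles across the tissue) and the dominant
allele's level under a nonautonomous one. Mosaicism is *not* simulated as a
stochastic fraction — the verbal prediction being tested is itself
deterministic. Inference returns exactly the models matching every observed
cell, never guessing missing cells; an empty survivor set is a reported
outcome, and indeed a fully constant eight-cell pattern has no single-locus
explanation (some parental strain must carry the high allele). Two-locus and
epistatic models are out of scope: these cross designs cannot identify them.

## Backcross simulation

Meioses follow Haldane's model: crossover count Poisson with mean (length in
cM)/100, positions uniform, no interference — the standard neutral choice
when no map function is specified. The default map uses generic mouse-scale
lengths (autosomes 39–98 cM, X 80 cM), overridable via `genome_model()`. The
selected X marker defaults to 35 cM, the approximate map position of Gdi1
(74.3 Mb of a ~171 Mb X). Males are X-hemizygous: they inherit their single
X from their mother, and hemizygous segments count as homozygous for their
origin in the length-weighted genome fractions. Selection (daughters
heterozygous at the marker) resamples daughters up to `retry_cap = 1000`
before erroring — with an unlinked-enough marker the predicate succeeds with
probability ~1/2 per daughter, so the cap only fires on misconfiguration.
Closed-form anchor: without selection, expected heterozygosity after *g*
crosses to the recurrent parent is (1/2)^*g*, which the simulator must and
does track within Monte-Carlo error.

## Variant filtering

The candidate filter is a conjunction: no rsID, QUAL ≥ 70 (a call at
exactly 70 survives, since the removal rule is "QUAL < 70"), homozygous-alt,
chromosome in the whitelist ({X} by default), consequence in
{nonsynonymous, stop_gained, splice_donor, splice_acceptor}; then calls
shared with the comparator substrain or with more than
`max_shared_panel_strains` (default 0 — the strictest reading of "shared
with several other strains") panel strains are removed. Because the rules
commute, the survivor set is order-independent; only the removal waterfall
depends on the fixed rule order (rsID → quality → zygosity → chromosome →
consequence → comparator → panel). Genotypes accept `0/1`, `1/1`, phased
`|` forms, and bare hemizygous `1` (treated as homozygous-alt — the natural
reading for male X calls); records with missing genotypes are excluded and
counted as malformed. Multi-allelic records are split per alt allele before
filtering. Consequence annotations are consumed (INFO `CSQ`), never
computed: consequence prediction is a solved problem for dedicated tools
and re-implementing it would add nothing.

## Determinism and problem sizes

Every stochastic function takes a seed; one user seed feeds named
substreams per generator so stages can be regenerated independently, and
RNG state is saved and restored around package calls. The test suite
exercises: populations of 5,000–10,000 cells for distributional checks;
ten rendered animals of 1,000 cells each for the end-to-end recovery of the
strain parameters (each generating fraction recovered within three binomial
standard deviations, and the two-strain contrast detected at five
animals/group); 150–1,000 pedigree replicates for the backcross anchors; and
100 random variant panels for filter soundness. These sizes were chosen to
make the binomial/Monte-Carlo tolerances meaningful while keeping a full
run of the suite around three minutes on one core.
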