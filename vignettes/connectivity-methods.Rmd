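---
title: "Functional landscape connectivity for pollinator-mediated gene flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional landscape connectivity for pollinator-mediated gene flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenscape)
```

## The problem

Hummingbird-pollinated understory plants in fragmented tropical
landscapes depend on habitat-specialist, traplining hummingbirds to move
pollen between forest patches. How much pollen-mediated gene flow a
sampling site receives should therefore depend not only on how much
forest surrounds it (structural connectivity) but on how that forest is
arranged relative to the birds' movement behaviour — their daily
movement range, home-range length, and reluctance to cross open,
non-forested gaps (functional connectivity).

`pollenscape` implements a family of raster-based connectivity metrics
that encode these behaviours, the pollen-pool statistics used to
measure realised gene flow from maternal-plant/seed microsatellite
genotypes, and an AICc model-comparison layer that asks which metric
best explains each gene-flow response. A fully seeded synthetic
generator supplies landscapes, genotypes and pollination events with
known ground truth, so every stage of the pipeline — and the headline
model-ranking behaviour — is testable without any external data.

## The connectivity model

All metrics start from an incidence function model (IFM) redefined over
raster cells. For a sampling site on pixel $i$, connectivity is

$$S_i = \sum_{j \ne i} e^{-\alpha d_{ij}} \, A_j \, p_j$$

where the sum runs over trapliner-habitat pixels $j$ of the local
landscape, $d_{ij}$ is the centre-to-centre Euclidean distance,
$A_j$ is the pixel's habitat area (0.01 ha for 10 m cells) and $p_j$
is a patch-level gap-crossing term. Metrics are reported in hectares of
functionally connected habitat.

Three design factors generate the 12 local-scale metrics
(2 habitat definitions × 2 weightings × 3 gap modes):

* **Habitat definition.** *Narrow*: mature forest only. *Broad*: mature
  forest plus regenerating forest and narrow forest elements
  (fencerows, riparian strips). Arable land and pasture are never
  habitat.
* **Distance weighting.** Either every habitat pixel counts equally
  (the kernel term is set to 1) or pixels are discounted by
  $e^{-\alpha d_{ij}}$ with $\alpha = 1/282\ \mathrm{m^{-1}}$, the
  inverse mean home-range length of *Phaethornis guy*, the dominant
  traplining pollinator.
* **Gap-crossing mode.** *Unlimited*: $p_j = 1$ everywhere.
  *Threshold*: $p_j = 1$ exactly for patches whose edge-to-edge gap
  chain to the focal patch never exceeds 50 m (equivalently, whose
  25 m buffers overlap, directly or through stepping-stone patches),
  else 0. *Probabilistic*: $p_j = e^{-\lambda d_k}$, where $d_k$ is the
  patch's minimum summed gap distance to the focal patch and
  $\lambda = \log(2)/50\ \mathrm{m^{-1}}$ halves the crossing odds
  every 50 m of open gap — the midpoint of the radio-tracking estimate
  that a 50% reduction occurs between 46 and 63 m.

Three intra-patch metrics describe the focal patch alone (narrow
definition; the broad definition cannot delineate discrete patches
because narrow forest elements connect everything): total focal patch
area, focal patch area within the 1 km movement radius, and the
distance-weighted kernel sum over focal-patch pixels. These are
log-transformed (natural log); the local metrics are not, matching the
convention that only the intra-patch areas are log-scaled before
standardisation. Both conventions are flags on `metric_spec()`.

### Numerical and geometric choices

* The local landscape is the disk of 1 km radius (the maximum daily
  movement range of trapliners) around the component-wise median of the
  site's maternal-plant coordinates; habitat is clipped to that disk
  *before* patches and gaps are measured.
* Patch labelling uses 8-connectivity by default (a flying pollinator
  traverses diagonally adjacent forest pixels); 4-connectivity is
  available. Labels are assigned in row-major first-seen order, so
  results are reproducible bit for bit.
* Edge-to-edge gap distance on a raster is the minimum centre-to-centre
  pixel distance minus one cell width, floored at zero — within half a
  cell of the polygon edge distance and exactly reproducible. The
  minimum is found over patch *boundary* pixels only, which is exact
  (the nearest pixel of a patch to an external point always lies on its
  boundary) and keeps the computation linear in patch perimeter.
* $d_k$ is a shortest-path distance on the complete patch graph with
  gap distances as edge weights (habitat traversal costs nothing), so
  stepping stones shorten the effective open-gap distance.
* The sampling pixel $i$ is excluded from every sum, including the
  unweighted local area metrics (a 0.01 ha difference, but defined).
* The summed factor weight of a design-factor level is the sum of the
  Akaike weights of the models containing that level; within a factor
  the level sums partition 1.
* `NODATA` landcover is treated as non-habitat: conservative, since it
  can never create connectivity.

The choice of gap-crossing decay rate deserves one note: at three
decimals $\lambda = \log(2)/50 = 0.0139\ \mathrm{m^{-1}}$ (sometimes
quoted truncated as 0.013). The package always uses the exact value;
what is fixed by field data is the 50% reduction at 50 m, which
`gap_crossing_probability(50)` reproduces exactly.

## Gene-flow responses

* **Pollen haplotypes** are obtained by subtracting the maternal
  genotype from each seed genotype, locus by locus. The case analysis
  is exhaustive: one non-maternal seed allele resolves the paternal
  allele; a seed homozygous for a maternal allele resolves to that
  allele; mother and seed sharing the same heterozygote is ambiguous
  (either allele could be paternal); a seed sharing no allele with its
  mother is a hard error by default (it indicates family mislabelling
  or genotyping error) and can be downgraded to missing.
* **Pooling**: haplotypes are pooled per sampling site (merging
  sampling years); resolved alleles count 1 and each allele of an
  ambiguous pair counts 1/2 in the frequency tables. An alternative
  policy excludes ambiguous haplotypes entirely; both are exposed
  because downstream conventions differ between workflows.
* **Haplotype diversity** $h$ is Nei gene diversity averaged over loci:
  $h = \overline{1 - \sum_a p_a^2}$, the probability that the paternal
  alleles of two randomly drawn seeds differ. The small-sample factor
  $n/(n-1)$ is off by default and available as an option.
* **Pollinator community composition** is the proportion of captures
  that are high-mobility (traplining) species, shrunk by four
  pseudo-observations — two successes and two failures — so the
  estimate is strictly inside (0, 1) and tends to 1/2 as captures
  vanish.
* **Biparental inbreeding** ($t_m - t_s$) is never estimated here; it
  enters as a supplied column (its estimation requires a mixed-mating
  model fitted elsewhere) or is simulated.

## Model comparison

Each response is transformed (arcsine square root for the two
proportions-scale responses), standardised, and regressed on each
standardised metric in a simple OLS with intercept. Model sets are
ranked by AICc with $k = 3$ (intercept, slope, residual variance); the
log-likelihood is Gaussian at the maximum-likelihood variance RSS/$n$
with the full normal constant, so absolute AICc matches standard
implementations. Intra-patch (3 models) and local (12 models) sets are
ranked separately — the metrics are alternative explanations, and their
mutual correlations are too high for multi-predictor models to be
interpretable (the synthetic correlation study,
`metric_correlation_study()`, reproduces this confounding). Akaike
weights are $w_m = e^{-\Delta_m/2}/\sum_n e^{-\Delta_n/2}$; if the
original analysis used a different parameter count convention, all
$\Delta$, weights and rankings are unchanged.

## The synthetic generator

`synthetic_config()` fixes the study conditions; `simulate_study()`
produces a complete data bundle. The generator emulates:

* **Landscape** (3 × 3 km, 10 m cells): a pasture matrix with
  quasi-elliptical mature-forest patches added until a requested 20%
  mature cover is reached (log-normal major semi-axis, median 55 m
  with a narrow spread, so remnants are mostly around a hectare and
  larger blocks arise only where patches merge), regenerating forest
  seeded against mature edges to a further 8.5% cover (succession
  concentrates on cleared margins next to remnants), a few arable
  inclusions, and straight narrow forest elements. The 20%/8.5% covers
  mirror a heavily deforested premontane mosaic in which roughly a
  fifth of old-growth remains and regeneration has partially offset
  the loss. The many-similar-small-remnants geometry is typical of
  long-settled agricultural mosaics; it keeps the total habitat per
  1 km disk comparatively even between sites while gap structure — how
  that habitat is split and spaced — varies strongly, and it places
  most inter-patch gaps in the range where the gap-crossing kernel is
  informative (roughly 20–200 m). Real study regions also contain much
  larger contiguous blocks than this generator produces; metrics on
  such landscapes are equally valid, but the recovery experiments
  below are calibrated to this geometry.
* **Sampling design**: up to 30 sites in distinct mature patches
  (≥ 0.6 ha), five maternal plants per site within 100 m, ten seeds
  per mother, eleven microsatellite loci with twelve alleles per locus
  drawn from a symmetric Dirichlet — the panel sizes of a typical
  microsatellite study of this design.
* **Pollination**: discrete donor plants (0.25 flowering donors per
  habitat hectare, plus two guaranteed flowering neighbours per site —
  maternal plants were found at every site, so nearby conspecifics
  always exist; the sparse density keeps pollen pools in the regime
  where diversity still responds to donor accessibility rather than
  saturating). Each seed's father is drawn with probability
  $\propto e^{-\alpha d(\text{mother, donor})} \cdot e^{-\lambda d_k}$,
  i.e. the same kernel family the probabilistic metric assumes. Fathers
  are discrete individuals rather than pixels so that paternity is
  recoverable in tests.
* **Responses**: capture counts are Binomial with a logit-linear
  dependence on the site's true (generative) donor accessibility;
  biparental inbreeding is a noisy declining linear function of the
  same driver. These are phenomenological by construction — only their
  regression role is needed.

Every generator output is a pure function of the configuration and its
seed (sub-generators use fixed offsets from the config seed, so each is
independently reproducible).

### What passing tests do and do not show

The generator reproduces the statistical skeleton the analysis assumes:
Mendelian seed genotypes under a known siring kernel, patchy landcover,
noisy linear responses. It does not emulate spatial genetic structure
in the donor population, pollen carry-over and correlated paternity
within bracts, flowering phenology, clonality, genotyping error, or
historical landscape change. Recovery results on synthetic data
therefore demonstrate that the pipeline's inference machinery is
self-consistent — not that real gene flow must behave this way.

One property of the mechanism is worth knowing when interpreting the
recovery experiments: haplotype diversity is a concave, saturating
function of the effective number of fathers, so sites far into the
well-connected regime compress towards a ceiling, and a skewed
predictor on a concave response loses linear-fit comparisons even when
its *ordering* of sites is the best (its rank correlation with h is
consistently the highest). The default donor density and the even
small-remnant geometry keep most sites on the informative part of
that curve. Even so, which gap-crossing mode ranks first in a
*single* ~30-site landscape is noisy; ensembles of ~120 sites (four
landscapes pooled) recover the generative probabilistic mode as the
best-supported gap-crossing level in the clear majority of
replicates, and the simulated negative inbreeding effect in
essentially all of them.

## Problem sizes and costs

The default study is a 300 × 300 raster with ~30 sites; one full
simulate–measure–compare cycle takes a few seconds. The test suite
exercises exhaustive oracles only at small sizes where enumeration is
exact (graphs of ≤ 6 patches, rasters of ≤ 50 × 50), dominance
invariants over 100 independent 800 m landscapes, and the recovery
experiment over five 120-site ensembles.

## Known limitations

* Gap distances are raster approximations (exact only up to the
  half-cell floor convention); vector-polygon distances would differ by
  at most about half a cell.
* The local landscape is clipped before the patch graph is built, so
  habitat just outside the 1 km disk contributes neither area nor
  stepping stones; the alternative (clip after graph construction) is a
  documented sensitivity, not currently implemented.
* Whether the focal patch's own pixels should receive kernel weighting
  in unweighted gap-restricted variants is a convention; here the
  factorial is strict: weighting and gap mode act independently.
* No reprojection: all coordinates must share one projected metric CRS.
* Raster I/O is plain-text Esri ASCII grid; compressed or tiled formats
  are out of scope.
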