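---
title: "Methods: co-expression screening, pellet morphometry and titre statistics"
author: "morphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression screening, pellet morphometry and titre statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscreen)
```

## Scope

Filamentous fungi such as *Aspergillus niger* are industrial workhorses for
secreted proteins and organic acids. Product titres, organic-acid flux
through the TCA cycle, and the macroscopic growth form in submerged culture
(compact pellets versus dispersed mycelium) are intertwined, and genes that
are transcriptionally coupled to more than one of these processes are
promising engineering targets. `morphoscreen` implements the three
quantitative stages of such a study as reusable, testable components:

1. a **multi-query Spearman co-expression screen** over a large expression
   compendium, with hypergeometric GO-term over-representation of the
   resulting candidate list;
2. **quantitative macromorphology** of submerged cultures from binary
   images (structure labelling, Euclidean descriptors, pellet/dispersed
   classification, Morphology Number);
3. **fermentation titre statistics** (normalisation, dose-wise comparisons
   against a progenitor control, protein-versus-acid trend fits).

Because compendium-scale expression data, culture photographs and
shake-flask measurements are rarely redistributable, a fourth component
generates **seeded synthetic inputs** with known planted structure, so the
whole pipeline can be exercised and validated end to end.

## Co-expression screen

For genes $g_i, g_j$ with expression profiles across $m$ conditions, the
edge weight is the Spearman rank correlation $\rho_{ij}$, computed with
average (fractional) ranks for ties. An edge exists iff
$\rho_{ij} > c$ with cutoff $c = 0.5$ by default. Three conventions are
fixed deliberately:

* **strict inequality** at the cutoff — a pair at exactly $\rho = c$ is not
  an edge, so the contract is unambiguous even on constructed data (ties at
  the cutoff are measure-zero on real compendia);
* **signed correlation** — anti-correlated genes do not form edges; the
  screen looks for co-expression, not for any association;
* **no missing values** — matrices with `NA`s are rejected at load time
  rather than pairwise-deleted, because silent pairwise deletion makes the
  edge set depend on the missingness pattern and is hard to reproduce.

The screen takes $k$ query genes, computes each query's neighbour set, and
intersects them (queries themselves excluded). `build_network()` offers a
*screen mode* that evaluates only query-versus-all correlations: with $G$
genes this costs $O(kG)$ correlations instead of $O(G^2)$, and the
neighbourhoods it yields are identical to the full network's. At least 5
conditions are required; rank correlations over fewer columns are too
unstable to threshold meaningfully (the intended scale is hundreds of
arrays over ~155 conditions, where the null spread of $\rho$ is about
$1/\sqrt{m-1} \approx 0.08$, putting the 0.5 cutoff more than 6 standard
deviations into the tail).

## GO-term over-representation

For a candidate list of size $n$ drawn from a universe of $N$ annotated
genes, a term carried by $K$ universe genes and $k$ candidates is scored by
the upper-tail hypergeometric probability

$$ p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n), $$

the one-sided over-representation test that standard GO tools use
(equivalent to a one-sided Fisher exact test). Design choices:

* the **test family** is the set of terms with at least one candidate hit —
  this fixes the Benjamini–Hochberg family size deterministically and
  matches common GO-tool behaviour;
* **no ontology propagation**: annotations are flat gene–term pairs.
  Propagating hits up a GO graph would import an external ontology release
  into the result; with flat sets, results are a pure function of the
  annotation table supplied;
* the **universe is every annotated gene** in the table, standing in for
  "the genome";
* terms with adjusted $q \le$ threshold (default 0.05) form the reported
  set — the conventional reading of an FDR cutoff — while all tested terms
  are retained in the output for inspection.

BH adjustment is the step-up $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$,
clipped at 1. It is order-preserving but not idempotent; it is applied once
per enrichment call.

## Morphometry

Structures are **8-connected** foreground components of a strictly binary
image; 8-connectivity keeps one-pixel-wide diagonal hyphae in one piece.
For each structure:

* **area** $A$ = pixel count × (pixel size)²;
* **Feret diameters**: the convex hull is built on *pixel corners* (each
  pixel contributes its four corners); the maximum Feret diameter $F$ is
  the largest distance between hull vertices and the minimum Feret is the
  smallest caliper width, attained perpendicular to a hull edge. The corner
  convention means a 1-pixel-wide line has minimum Feret of one pixel, not
  zero, keeping the aspect ratio finite for hyphal fragments;
* **aspect ratio** $AR = F_{\max} / F_{\min}$ (the max/min-diameter
  quotient, not a fitted-ellipse ratio);
* **solidity** $S = A / A_{\mathrm{hull}}$, which cannot exceed 1 because
  every pixel square lies inside the corner hull;
* the **Morphology Number**

$$ MN = \frac{2 \sqrt{A}\, S}{\sqrt{\pi}\, F\, AR}, $$

a dimensionless index equal to 1 for a perfect circle and approaching 0 for
a one-dimensional line. It increases with solidity and decreases with
aspect ratio.

Classification is by area alone: structures of at least 500 µm² are
**pellets**, areas in [95, 500) µm² are **dispersed** mycelium, and smaller
objects are **excluded** (debris, single spores). Both boundaries are
closed on the left — exactly 500 is a pellet and exactly 95 is dispersed.
Per-culture summaries report the pelleted share of the *measured* fungal
area (pellets + dispersed; excluded structures enter neither numerator nor
denominator, and with nothing measured the fraction is `NA`, not 0), and
summarise MN over pellets only, matching how pellet MN distributions are
conventionally reported.

### Discretisation behaviour

The corner-hull convention carries a small, systematic resolution effect
worth knowing about: for a rasterised disc the hull's corners overhang the
ideal outline by up to half a pixel diagonal, which inflates $F$ (an error
that enters $MN$ twice, once directly and once through $AR$) and deflates
$S$ by roughly the perimeter-to-area ratio. A 100-µm disc sampled at
0.5 µm/pixel therefore measures $MN \approx 0.978$ rather than 1.0; the
value rises to ≈0.989 at 0.25 µm/pixel and ≈0.995 at 0.1 µm/pixel. The
bias is a property of any outline-based measurement at finite resolution
(interactive image-analysis tools that measure on pixel outlines show the
same offset); analyses comparing MN across conditions are unaffected as
long as the calibration is constant, but absolute MN values close to 1
should be interpreted with the pixel size in mind. No hole-filling or
smoothing is applied: inputs are assumed to be pre-thresholded masks, and
the pixel calibration (µm/pixel) must always be supplied explicitly.

## Fermentation statistics

Secreted protein is normalised to fungal dry weight (mg/g biomass) and each
organic acid to depleted glucose (g/g). A zero denominator yields an `NA`
sentinel with a warning — an undefined yield, never silently 0. Mutants are
compared to the progenitor control at each shared dose with a two-sided
**pooled-variance Student's t-test**; Student's rather than Welch's form is
a deliberate, documented choice (it is the named convention in this
experimental tradition), and its equal-variance assumption is a known
limitation. Zero pooled variance with equal means gives $t = 0, p = 1$ by
convention. No multiple-testing correction is applied across the strain ×
dose × variable grid — individual comparisons are reported as-is, with the
number of tests attached so a reader can adjust.

Trend fits between mean protein titre and mean acid titre per strain × dose
cell use ordinary least squares with a degree-1 or degree-2 polynomial;
$R^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$, with $R^2 \equiv 0$ when
$SS_{\mathrm{tot}} = 0$ (constant response). Because the models are nested,
the quadratic $R^2$ never falls below the linear one on the same data.
Means (not medians) feed the fits, matching the convention of plotting
average titres per condition.

## Synthetic data: what it emulates and what it does not

**Expression.** Each planted module has a latent standard-normal condition
profile $z$; a member gene's profile is
$\sqrt{r}\, z + \sqrt{1-r}\, \eta_g + \sigma \varepsilon$, plus a per-gene
baseline offset, where $r$ is the module's `latent_correlation`
(population Pearson correlation between members before measurement noise),
$\eta_g$ is per-gene variation and $\sigma$ = `noise_sd` is measurement
noise. With the default $r = 1$ and $\sigma = 0$, members are exact
monotone copies of the latent profile (pairwise Spearman 1), a useful
degenerate case for contract tests. Background genes are independent
noise. The benchmark defaults — 155 conditions, a 50-gene module at
$r = 0.9$ with $\sigma = 0.3$, 1000 background genes — mirror the scale of
a public microarray compendium covering ~155 cultivation conditions. The
generator deliberately omits probe-level artifacts, normalisation residue
and batch effects, and its conditions are exchangeable rather than
structured into cultivation series; recovering planted modules here shows
the screen's logic is correct, not that any particular real compendium is
clean enough for a 0.5 cutoff.

**Annotations.** Module members carry their planted GO terms plus random
background terms; background genes carry random terms only. With an empty
background-term pool, genes outside any module carry no annotation and thus
fall outside the enrichment universe.

**Images.** Pellets are rasterised ellipses (pixel-centre inclusion) with
an optional boundary-roughness modulation of the radius,
$1 + a\cos(6\theta + \phi)$, rescaled so the enclosed area is preserved;
fragments are compact or elongated pixel packs whose area matches the
request to within one pixel. Images are generated directly as binary
masks — no simulated illumination or grayscale — because the
quantification operates on thresholded structures anyway. Objects must keep
a two-pixel gap so labelling never merges them, and every object's true
area, axes and class are returned as a ground-truth table. Rendered areas
stay within 3% of the request for objects of at least 95 µm² at pixel
sizes up to 1 µm.

**Fermentation.** Each strain × dose cell has model means for protein, dry
weight, citric acid, oxaloacetate and depleted glucose; replicates multiply
the mean by lognormal noise with unit mean and a chosen coefficient of
variation (multiplicative noise keeps titres nonnegative; `noise_cv = 0`
reproduces the means exactly, and zero means stay exactly zero, mirroring
"not detected"). The bundled `default_effect_model()` encodes the
qualitative dose-response patterns of a titratable-promoter experiment —
a dose-flat control, a mutant with citric acid absent at low doxycycline
and elevated oxaloacetate, and two essential-gene mutants whose growth and
secretion collapse at 0.2 µg/ml Dox and recover at 2 µg/ml, on the dose
grid {0, 0.2, 2, 20} µg/ml with four replicate flasks — but its numeric
levels are invented and should not be read as measurements.

All generators take explicit integer seeds, restore the caller's RNG state,
and are bit-reproducible for identical arguments.

## Parameter summary

| parameter | default | unit | where |
|---|---|---|---|
| Spearman cutoff | 0.5 | – | `build_network`, `pipeline_config` |
| minimum conditions | 5 | columns | matrix validation |
| enrichment FDR threshold | 0.05 | – | `enrich` |
| dispersed lower bound | 95 | µm² | `classify_structure` |
| pellet lower bound | 500 | µm² | `classify_structure` |
| connectivity | 8-neighbour | – | `label_structures` |
| t-test alpha | 0.05 | – | `pairwise_t_test` |
| dox dose grid | 0, 0.2, 2, 20 | µg/ml | `dose_response_spec` |
| replicate flasks | 4 | – | `dose_response_spec` |
| titre noise CV | 0.1 | – | `dose_response_spec` |

## Validation strategy and problem sizes

The test suite checks every statistic against an independent oracle:
Spearman against the classical $1 - 6\sum d^2 / (n(n^2-1))$ formula on
tie-free vectors; the hypergeometric tail against exhaustive enumeration of
all draws for universes up to $N = 12$; BH against a hand step-up
computation; Feret extremes against a 3600-angle brute-force projection of
the corner cloud; the t statistic against the textbook pooled-variance
formula. Screen recovery is benchmarked over 10 seeds at the
compendium-scale defaults above (the six-query screen recovers ≥95% of
planted module members with ≤1% background contamination), enrichment
calibration over 200 null candidate draws from a 1000-gene universe, and
shape measurements over randomized 100-shape suites. These sizes keep the
complete suite under a minute while leaving each property's margin wide;
they are stated here so reruns are comparable.

## Known limitations

* The screen treats compendium columns generically as "conditions"; it
  does not model replicate structure or condition averaging.
* Flat GO sets: no ontology hierarchy, evidence codes or term semantics.
* Morphometry assumes pre-thresholded input; no illumination correction,
  thresholding or hole-filling is provided.
* Student's t with pooled variance, no correction across the comparison
  grid — both inherited conventions, documented above.
* Synthetic generators are idealizations for validation, not
  reconstructions of any real compendium, photograph set or fermentation
  campaign.
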