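---
title: "Methods: pollinator-vision color dispersion in co-flowering communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollinator-vision color dispersion in co-flowering communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromacomm)
```

## The question and the model

A local co-flowering community is a sample from a regional species pool.
If pollinator-mediated competition structures membership, co-occurring
species should be *more* distinct in the color space their visitors
perceive than a random sample of the pool (overdispersion); habitat
filtering, facilitation or floral mimicry predict the opposite
(clustering). `chromacomm` measures "distinctness" with the
receptor-noise-limited (RNL) model of color discrimination, compares each
community against richness-matched random assemblies, and asks whether the
strength of dispersion varies with habitat size and richness.

### Receptor-noise-limited color distances

For each photoreceptor class $i$ of a viewer, the quantum catch of a
stimulus with reflectance $R(\lambda)$ under illuminant $D(\lambda)$ is the
Riemann sum over the analysis grid

$$Q_i = \sum_\lambda S_i(\lambda)\,R(\lambda)\,D(\lambda)\,\Delta\lambda ,$$

with $S_i$ the receptor's spectral sensitivity. Receptors adapt to the
prevailing background (von Kries adaptation): $q_i = Q_i / Q_i^{\mathrm{bkg}}$,
so the background itself maps to $q = 1$ in every channel and any uniform
rescaling of the illuminant or of a single receptor's sensitivity curve
cancels exactly (both invariances are tested properties). Signals are
log-transduced, $f_i = \ln q_i$, the standard choice for the large
suprathreshold distances seen among flower colors.

Discrimination is limited by channel noise
$\omega_i = W \sqrt{\eta_{\mathrm{ref}} / \eta_i}$, where $W$ is the Weber
fraction of the reference channel and $\eta_i$ the relative receptor
abundances: rarer receptor classes are noisier. The chromatic distance
$\Delta S$ between two stimuli, in units of noise standard deviations, is
computed from the signal differences $\Delta f_i$ with the standard RNL
closed forms for 2, 3 and 4 receptor classes. All three closed forms are
equivalent to one geometric operation — scale $\Delta f$ by $1/\omega$,
project out the achromatic direction $(1/\omega_1,\dots,1/\omega_n)$, take
the Euclidean norm — and the test suite verifies this equivalence to
$10^{-10}$ over a thousand random cases. $\Delta S$ is therefore a true
metric on receptor signals and is invariant to adding any constant to all
$\Delta f_i$ (brightness).

Two template viewers ship with the package: a honeybee-like trichromat
(UV/B/G; $W = 0.05$; $\eta$ = 2.125 : 1 : 9.375) and a hoverfly-like
tetrachromat (R7p/R7y/R8p/R8y; $W = 0.05$; $\eta$ = 1 : 2.33 : 1 : 2.33).
The Weber fraction is anchored to the most abundant receptor class (G for
the bee; for the fly, where two classes tie at 2.33, R7y) — the
conventional RNL anchoring when the source does not name the anchored
channel; both the anchor and all parameters are configurable in
`visual_system()`. With these numbers the bee noise vector is
$\omega = (0.10502,\ 0.15309,\ 0.05000)$ and the fly's is
$(0.07632,\ 0.05,\ 0.07632,\ 0.05)$, each reproduced to five decimals by a
hand evaluation of the formula in the tests.

Chromaticity coordinates (`chromaticity()`) map relative stimulation
$e_i = q_i/\sum_j q_j$ into the Maxwell triangle (trichromats) or a regular
tetrahedron (tetrachromats). They are descriptive only; no acceptance
quantity depends on them.

### Spectra processing

Reflectance files are two-column wavelength/value tables; the dialect
declares percent (default, the spectrometer convention) versus fraction.
Negative readings — instrument noise around dark flowers — are clipped to
zero with a warning. All spectra are linearly interpolated onto a common
300–700 nm grid (1 nm default; the step is configurable and must divide
the span) with no extrapolation: a file that does not cover the grid is an
error naming the uncovered range. Within a species, replicate measurements
are averaged within each floral-unit component first, then components are
merged by their display-area weights (which must sum to 1); this
replicate-then-weight order matches how multi-colored floral units are
described per species. Both operations are pointwise linear, so
resampling and compositing commute (tested to $10^{-12}$), and a composite
is always bounded by the pointwise envelope of its parts.

### Null models and standardized effect sizes

For a community of richness $k$, the null distribution is built from
`n_iter` (default 10,000) uniform draws of $k$ species without replacement
from the regional pool; each draw's mean pairwise $\Delta S$ is recorded,
and $z = (\text{observed} - \text{null mean}) / \text{null SD}$. The 95%
interval reported per community is the 2.5/97.5 percentile range of the
null means. Degenerate cases are explicit: richness equal to the pool
size, or a constant distance matrix (a star phylogeny), gives SD = 0 and
$z = 0$ with a warning rather than NaN. Sampling is of species, not
individuals — no abundance weighting — matching a pool defined as a
species list.

The phylogenetic analysis feeds patristic distances (branch-length sums
between tips, from an ultrametric Newick tree) through the *same* engine,
so SES-MPD and the trait analysis are bit-for-bit comparable under a
shared seed; a test asserts exactly that. Non-ultrametric trees warn
rather than fail, since time calibration happens upstream of this package.

Guild-restricted scenarios intersect each community with the species
recorded as bee- (or fly-)visited; communities left with fewer than
`min_guild_members` (default 3) guild species are dropped with a message —
two species give a single pair, too little for a meaningful community
mean. By default the null for a guild scenario samples from the
guild-restricted pool, the conservative choice that matches what the
restricted viewer could actually encounter; `null_pool = "full"` switches
to the whole pool.

Reproducibility: every routine takes a seed, and per-seep substreams are
derived deterministically from the master seed
(`master + 104729·stream + 7919·i (mod 2^31)`), so per-seep results do not
depend on the order in which communities are analysed.

### Habitat index and inference

Transect surveys are point intercepts every 0.25 m along a center and an
edge line: richness is the count of distinct species contacted, density
the fraction of points touching any plant. Area is length × mean of the
width measurements. Because area (m²), density (fraction) and richness
(count) are incommensurate, the "seep index" is PC1 of their *correlation*
matrix — which also makes the scores invariant to affine rescaling of any
input, a tested property — oriented so that richness loads positively:
high index = larger, denser, richer seep.

The dispersion ANCOVA models
`mean_disparity ~ community_type * seep_index` on the $2k$ rows (observed
and null per seep). Partial (Type-III-style, sum-to-zero contrast) tests
are reported per term; with this balanced two-type design the interaction
test coincides with the sequential one, and its partial $F$ equals the
squared $t$ of the slope-difference contrast (asserted to $10^{-10}$).
Adjusted means per type are evaluated at the covariate mean with 95% CIs
from the residual mean square; per-type slopes carry $t$ tests on the
residual df. The overall model $F$ is on $(3,\ 2k-4)$ df. A noise-free
table generated from known coefficients is recovered exactly; when the
residual variance is literally zero the partial tests are reported as NA
rather than fabricated.

Residual spatial structure is screened with Moran's $I$ under
inverse-distance weights ($w_{ij} = 1/d_{ij}$, zero diagonal, not
row-standardised), expectation $-1/(n-1)$, two-sided normal-approximation
$p$ (a permutation $p$ is available). The ANCOVA has two rows per seep but
Moran's $I$ wants one value per location, so the package uses the per-seep
mean of internally studentized residuals — a deliberate, documented choice.

## The synthetic-data generator

`synth_config()` defaults encode the study conditions this package was
built around: a 55-species regional pool, 14 seeps, community richness
6–20, bees visiting more species than flies (85% vs 55% of the pool),
seeps 20–100 m long and 1–5 m wide with 20–80% plant cover, placed in a
~14 km square. A latent seep-size factor couples geometry, cover and
richness — larger seeps are denser and more species-rich — reproducing
the strong positive correlations that make one habitat axis (PC1)
a meaningful summary in the target system. Flower spectra are drawn from five archetypes
(UV-reflecting white, blue, yellow, UV-absorbing white, purple — smooth
sigmoid/Gaussian shapes on 300–700 nm) plus seeded smooth perturbations,
clipped to [0.001, 1] so every receptor catch stays positive; the foliage
background is a low curve with a green bump near 550 nm; the illuminant is
a 5800 K black-body photon spectrum, a smooth daylight stand-in.
Sensitivities come from the α band of the A1 visual-pigment template,
recentred so the realised peak sits exactly at $\lambda_{max}$ and
normalised to 1; the ultraviolet β band is deliberately omitted to keep
the curves unimodal. None of these synthetic shapes is asserted to equal
any measured curve — tests depend on structural properties (ranges,
determinism, archetype separation), never on specific synthetic values.

Metacommunity assembly implements three rules. *Random*: uniform subsets.
*Overdispersed*: greedy growth choosing the candidate maximising its
minimum distance to the current members. *Clustered*: greedy minimisation
of the mean distance. Both biased rules select through a softmax on
standardised candidate scores with temperature `strength`, so strength 0
reduces exactly to the random rule (verified distributionally by a KS
test). Transect records are generated so that `transect_summary()`
recovers each seep's realised richness exactly, and the tree is a seeded
pure-birth phylogeny, independent of color — which keeps trait and
phylogenetic structure decoupled, so a trait-overdispersed synthetic world
shows no phylogenetic signal, and lets the two analyses be validated
separately.

What the generator does *not* emulate: correlated measurement error
between spectrometers, within-species color variation across individuals,
spatially autocorrelated community composition, phylogenetically conserved
color (no archetype–clade mapping by default), or abundance structure.
Passing tests therefore demonstrate correctness of the machinery and
calibration of the statistics under these idealised conditions, not that
any field dataset will show a particular pattern.

## Calibration and recovery, as tested

Three end-to-end facts anchor confidence in the chain (all in the test
suite, at the sizes given):

* **Calibration.** When communities really are uniform draws from the pool
  (pool 55, 20 seeps, richness 6–20, 2,000-iteration nulls, 100
  replicates), the $z$-scores have mean ≈ 0, SD ≈ 1, and $|z| > 1.96$ in
  5% of cases within binomial error.
* **Recovery.** Overdispersed assembly at strength 5 yields mean $z > 0$
  with ≥ 80% of seeps positive; clustered assembly mirrors this.
* **Oracles.** Null grand means match exhaustive enumeration on pools ≤ 8
  within three Monte-Carlo standard errors; ANCOVA and Moran's $I$
  reproduce closed-form values.

Problem sizes in the routine test run are scaled for quick iteration
(hundreds to a few thousand null draws); `scripts/acceptance.R` runs the
full study-scale configuration (10,000 iterations, 55 × 14) in well under
a minute.

## Known limitations

* The RNL closed forms assume independent Gaussian channel noise and a
  single adapting background for all stimuli; no achromatic channel or
  behavioural threshold interpretation is offered.
* The null model is richness-constrained only — no fixed-fixed or
  abundance-weighted algorithms.
* Moran's $I$ uses one aggregate residual per seep; with only ~14
  locations the normal approximation is serviceable but the permutation
  option is the safer check at small $n$.
* The seep-index PCA needs at least three seeps and non-constant inputs;
  with three highly correlated variables PC1 typically explains most
  variance, but its share is data-dependent.

## Session

```{r}
sessionInfo()
```
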