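# chromacomm

Community assembly of flower color, seen through pollinator eyes.

Co-flowering plants interact through their shared pollinators: competition
for visits (or avoidance of heterospecific pollen transfer) should push
community members apart in the color space the visitors actually perceive
(overdispersion), while habitat filtering, facilitation or mimicry should
pull them together (clustering). `chromacomm` provides the full analysis
chain for testing these hypotheses on replicated local communities — built
for serpentine-seep co-flowering assemblages, but generic over any
metacommunity with reflectance spectra, membership tables, a phylogeny and
habitat surveys.

## What it computes

**Receptor-noise-limited (RNL) color modeling.** For receptor *i* with
spectral sensitivity *S<sub>i</sub>(λ)*, stimulus reflectance *R(λ)* and
illuminant *D(λ)*, the quantum catch is
*Q<sub>i</sub> = Σ<sub>λ</sub> S<sub>i</sub>(λ)R(λ)D(λ)Δλ*; von Kries
adaptation to the background *q<sub>i</sub> = Q<sub>i</sub>/Q<sub>i</sub><sup>bkg</sup>*
and log transduction *f<sub>i</sub> = ln q<sub>i</sub>* give the receptor
signals. Channel noise is *ω<sub>i</sub> = W√(η<sub>ref</sub>/η<sub>i</sub>)*
with Weber fraction *W* and relative abundances *η*. The chromatic
distance ΔS between two stimuli (in noise standard deviations) uses the
standard closed forms for di-, tri- and tetrachromats; supported viewers
are a honeybee-like trichromat (UV/B/G, *W* = 0.05, η = 2.125:1:9.375) and
a hoverfly-like tetrachromat (R7p/R7y/R8p/R8y, *W* = 0.05,
η = 1:2.33:1:2.33).

**Null-model dispersion.** Each observed community's mean pairwise ΔS is
compared against richness-matched random communities drawn uniformly
without replacement from the regional pool; the standardized effect size
*z* = (observed − null mean)/null SD flags overdispersion (*z* > 0) or
clustering (*z* < 0). The same engine applied to patristic distances from
an ultrametric tree gives SES-MPD, the phylogenetic analogue.

**Habitat and inference.** Transect point-intercept surveys yield richness
and plant density; seep area is length × mean width; the three metrics are
consolidated into a "seep index" (PC1 of their correlation matrix,
oriented so richness loads positively). An ANCOVA
`mean ΔS ~ community type × seep index` tests whether dispersion exists
and whether it changes along the habitat gradient, with Moran's *I*
(inverse-distance weights) screening residuals for spatial structure.

**Synthetic data.** A seeded generator produces every input the pipeline
reads — archetype-based flower spectra, template visual systems, foliage
background, daylight illuminant, metacommunities assembled under random /
overdispersed / clustered rules, transect records, seep geometry, and a
pure-birth phylogeny — so the whole chain is testable end to end.

## Worked example

```r
library(chromacomm)

cfg <- synth_config(seed = 101, n_pool = 30, n_seeps = 10,
                    richness_range = c(5, 12))
dir <- file.path(tempdir(), "demo")
synth_bundle(cfg, dir)                       # writes the input files
run <- run_pipeline(run_config(dir, n_iter = 2000, seed = 101))
print(run)
```

```
guild_restrict(bee): dropped 1 community with < 3 bee-visited species: seep02
chromacomm pipeline run
  pool: 30 species with spectra; 0 excluded
  seeps: 10; PC1 variance explained: 83.6%
  bee_all      mean z = +0.18; overall F(3,16) = 0.35; interaction p = 0.9053
  fly_all      mean z = +0.08; overall F(3,16) = 1.35; interaction p = 0.1686
  bee_visited  mean z = -0.22; overall F(3,14) = 0.27; interaction p = 0.9542
  fly_visited  mean z = -0.58; overall F(3,16) = 1.19; interaction p = 0.4969
  phylo (MPD)  mean z = +0.44; overall F(3,16) = 0.51
```

This bundle was assembled under the *random* rule, and the run says so:
per-seep *z*-scores hover around zero in all four scenarios (bee/fly
vision × all/guild-restricted pools), no community-type effect or
type-by-index interaction approaches significance, and the phylogeny shows
no structure either. One seep fell below the three-member minimum for the
bee-visited scenario and was dropped from that scenario only, with the
message naming it. Rebuilding the bundle with
`assembly = "overdispersed", strength = 5` drives the mean *z* strongly
positive. Per-seep detail lives in `run$scenarios$bee_all$per_seep`
(observed mean ΔS, null grand mean, null SD, 95% percentile CI, *z*), the
fitted ANCOVA in `...$ancova`, and Moran's *I* in `...$morans`.

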