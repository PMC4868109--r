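---
title: "Quality assessment of long-range interaction data by random sub-sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of long-range interaction data by random sub-sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A proximity-ligation library is a multiset of paired-end tags (PETs), each
marking one ligation product between two genomic anchors. `petqc` treats the
binned contact matrix of a library as a multinomial sample over 2-D windows
(bin pairs) and asks how stable each window's count is under uniform random
thinning of the library.

If a window holds `o` of the `N` filtered PETs and we draw `floor(d*N)` PETs
without replacement, the window's sub-sampled count is hypergeometric with
mean `o * floor(d*N) / N ≈ o*d`. The recovered percentage
`recPET = 100 * s/o` therefore has expectation `samd = 100*d`, and the
dispersion `∂PET = samd − recPET` has expectation 0 with a spread that
shrinks as `o` grows (relative sd roughly `sqrt((1−d)/(d*o))`). A deeply
sequenced library concentrates its windows at high `o`, so nearly all
windows keep `|∂PET|` inside a narrow band; a shallow library does not. The
global indicators condense this:

* `denQC.samd` — fraction of assessable windows with `|∂PET| ≤ t`
  (threshold `t = 10 %` by default), computed at d = 0.9, 0.7, 0.5;
* `simQC.90/50 = denQC.90 / denQC.50` (similarly 70/50) — 1 exactly when
  sub-sampling affects the same fraction of windows at every density, the
  signature of saturation;
* `QCscore_raw = (denQC.50/simQC.90/50) * (denQC.50/simQC.70/50)`, reported
  on a decibel-style scale `QCscore = 10*log10(QCscore_raw)`.

The key assumption is exchangeability of PETs under thinning — sub-sampling
models reduced sequencing depth of the *same* library. Systematic artefacts
(ligation bias, mapping bias) are invisible to this statistic: a biased but
deep library can score well. The score measures reproducibility of the
interaction map under depth reduction, not biological truth.

### Why 2-D windows

"Genomic windows" could mean 1-D intervals (anchor marginals) or 2-D bin
pairs. Every per-window display this method is meant to feed — dispersion
heatmaps over interaction maps — is 2-D, and a 1-D marginal cannot produce
them, so the window universe here is the set of intra-chromosomal bin pairs
with at least `min_window_count` original PETs. A 1-D marginal mode would be
a straightforward extension but is deliberately not implemented.

### Why the score is a log

`QCscore_raw` lives in (0, 1] for realistic inputs and spans orders of
magnitude between shallow and deep libraries; `10*log10` maps it to a
human-sized negative scale where saturation is 0 and each factor-of-10 loss
in the raw product costs 10 points. Both the raw and log values are always
reported so the convention is transparent.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `span_threshold_bp` | 10000 | bp | minimum intra-chromosomal span (strict `>`); removes the diagonal-dominating short-range mass. 25 kb is a common stricter choice. |
| `resolution_bp` | 5000 | bp | window size; 5 kb and 25 kb are run as independent analyses, never mixed. |
| `densities` | 0.9, 0.7, 0.5 | fraction | sub-sampling densities; the lowest one is the reference in simQC/QCscore. |
| `dispersion_threshold_pct` | 10 | % | half-width of the acceptance band on `∂PET`. |
| `min_window_count` | 1 | counts | window-universe floor; singleton windows quantize `recPET` to {0, 100}, so raising this focuses the score on informative windows. |
| `replicates` | 1 | — | independent sub-sampling replicates; used only to estimate the score's coefficient of variation. |

Boundary conventions: the span filter is strictly greater-than ("longer
than" the threshold); the dispersion band is non-strict and applied to
`|∂PET|`, because over-recovery is as much a deviation from proportionality
as under-recovery, and a symmetric closed band avoids knife-edge behaviour
at exactly the threshold. Band membership is evaluated with a `1e-9`
epsilon so that windows sitting exactly on the edge (e.g. `rec = 60` at
s50) do not flip on floating-point rounding of `100*s/o`.

Deduplication keys on coordinates *and* strands: two PETs with identical
anchor coordinates but different strand configuration are distinct ligation
products, and both supported input formats carry strands. `use_strands =
FALSE` relaxes the key to coordinates only for pipelines that have already
collapsed strand information.

## Sub-sampling and seeding

Subsets have exact size `floor(d*N)` (floor rather than round, for
determinism at half-integers), drawn uniformly without replacement. The
three densities are drawn independently — nothing forces s50 to nest inside
s90 — which keeps the per-density dispersion statistics independent and
costs nothing under the hypergeometric model.

Each draw's seed is derived from `(master_seed, density, replicate)` by
iterated Lehmer steps modulo 2^31−1 (exact in doubles), so a run is fully
reproducible from one integer, sub-streams for different densities and
replicates are decorrelated, and adding a replicate never perturbs earlier
draws. Draws restore the caller's RNG state.

Degenerate inputs fail loudly rather than silently: zero filtered PETs
raises a "nothing to score" condition carrying the library statistics;
an empty window universe raises its own condition; `denQC.50 = 0`
(pathologically sparse input) yields an "undefined score" condition with
the partial denQC values attached instead of a ±Inf score.

## The synthetic generator

`generate_pets()` samples intra-chromosomal bin pairs with probability
`p(i,j) ∝ ((j−i)*r)^(−α) * τ^[same TAD]` (defaults α = 1, τ = 5, two 2 Mb
chromosomes tiled by 300–600 kb domains — domain sizes and the decay
exponent in the range reported for mammalian interactomes), places anchors
uniformly inside the chosen bins, converts a Bernoulli(0.1) fraction into
uniform inter-chromosomal pairs and re-emits a Bernoulli(0.05) fraction as
clonal duplicates. Sampling bin pairs first and offsets second makes the
binned matrix of the generated data an exact multinomial draw from the
model weights, so conservation and goodness-of-fit oracles are exact. The
model's true bin-pair probabilities travel with the generated set for such
tests. Short-range mass is included on purpose so the 10 kb filter is
genuinely exercised.

What the generator does *not* emulate: restriction-fragment geometry,
dangling ends and self-circles, mappability and GC bias, distance-dependent
ligation efficiency, structural variation. Passing tests on synthetic data
therefore demonstrate the correctness and statistical behaviour of the
scoring machinery — unbiased recovery, hypergeometric dispersion, score
monotonicity in depth — not that any particular real library will score
well.

`generate_saturated_pets()` is the limiting fixture: a deterministic
library whose every occupied window holds the same large count with
all-distinct anchor pairs, used to verify the saturation fixed point
(denQC = 1 at every density, simQC = 1, QCscore = 0 exactly).

`depth_ladder()` mirrors a metafile calibration: one large generated
library is reduced to its filtered population, rungs of increasing
filtered-PET depth are drawn from it by seeded sub-sampling, and each rung
is scored. The QCscore increases monotonically with depth; with replicated
scoring the per-rung CV is reported.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
desk scale, chosen so the statistical claims are testable in seconds: the
reproducibility checks use ~100k and ~600k filtered PETs on a 2 Mb
chromosome at 5 kb windows (the deep case holds ~50k non-empty windows);
the exhaustive oracle enumerates all 924 half-density subsets of a 12-PET
toy; Monte-Carlo comparisons use 1,000–2,000 seeded draws and 3-standard-
error bands; the calibration ladder spans 20k–500k filtered PETs. These
sizes are the package's own study conditions, stated here so results are
interpretable, and they reproduce the qualitative pattern expected at
hundred-million-PET scale (CV below a few percent, score increasing with
depth).

## Known limitations

* Scores from different upstream mapping/filtering pipelines are not
  directly comparable; the method assumes its input is the final mapped PET
  set.
* Windows are unnormalized raw counts; matrix balancing (ICE/KR) is out of
  scope and would change the window universe.
* The dispersion statistic is blind to artefacts that survive thinning
  proportionally (clonal families collapse first, but composition bias does
  not).
* Very sparse libraries (mostly singleton windows) hit the quantization
  floor: denQC.50 can exceed denQC.70 and may legitimately be 0, in which
  case the score is reported as undefined rather than extrapolated.
* Config files for the CLI are YAML, not TOML.
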