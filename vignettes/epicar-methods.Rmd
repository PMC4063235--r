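---
title: "Methods: exceedance-probability cluster screening with a zero-inflated Poisson ICAR model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exceedance-probability cluster screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epicar)
```

## Scope and data model

`epicar` implements the first, statistical step of a disease-cluster
investigation around a putative point source: decide whether the spatial
distribution of an adverse outcome shows a credible local excess, and where.
The unit of analysis is a 1 km² pixel. Point records (one row per birth,
with planar or geographic coordinates and 0/1 outcome flags) are projected
to planar kilometres, rounded to the nearest integer-kilometre pixel
centre, and cut into a study window — by default 20 × 20 pixels (400 km²)
centred on the site.

Three projection modes are supported. `"utm"` implements the Transverse
Mercator series on the GRS80 ellipsoid (scale 0.9996, 500 km false
easting), the UTM NAD83 convention; no external projection library is
required and the forward/inverse pair round-trips to well under a metre.
`"equirect"` is the flat-earth approximation — a constant ≈111 km per
degree of latitude and a cosine-shrunk longitude (≈97 km per degree at
Houston's latitude) — which agrees with UTM to well under 1% over a 20 km
window at mid-latitudes, the scale that matters here. `"none"` accepts
pre-projected metres.

Two conventions are resolved explicitly because "round to the nearest
kilometre" does not determine them:

* **Half-kilometre ties** round half to even (base R `round()`):
  deterministic and platform-stable.
* **Window centring** with an even width places the site's pixel at 0-based
  index `width %/% 2` (just north-east of the exact centre). The chosen
  origin is carried in the window object, so downstream geometry never
  depends on the convention silently.

## The model

For pixel *i* with `n_i` births, case count `Y_i`, and expected count
`E_i = n_i · r` (where `r` is the *overall* study-wide rate, not a
window-local one — the window is being compared against the wider region):

$$Y_i \sim \text{Poisson}(g_i\,\mu_i), \qquad
  \log \mu_i = \log E_i + \alpha + S_i$$

`g_i` is the structural-zero mask: 1 if the pixel holds any births, else 0.
The two-group ("zero-inflated") formulation matters because empty pixels —
common in patchy settlement — would otherwise be read as evidence of low
risk; in truth their zero case count is forced. Because group membership is
determined by the data (`p_i ∈ {0, 1}`), the Bernoulli mixture degenerates
and is implemented exactly as a likelihood mask rather than a sampled
latent variable. Unoccupied pixels influence the posterior only through the
spatial graph.

The spatial field `S` has the intrinsic conditional autoregressive (ICAR)
pairwise-difference prior on the queen-adjacency graph (each interior pixel
has 8 neighbours, i.e. nine-pixel neighbourhoods):

$$p(S \mid \tau) \propto \tau^{(n-c)/2}
  \exp\!\Big(-\frac{\tau}{2}\sum_{i \sim j}(S_i - S_j)^2\Big)$$

with `n` pixels and `c` connected components (1 on a grid). The prior is
improper (invariant to a constant shift); identification is by sum-to-zero
recentring after every sweep, with the mean absorbed into `α` — the
standard treatment for intrinsic fields. `α` carries an improper flat
prior: with hundreds of occupied pixels the likelihood identifies it
sharply, and any proper vague normal would be numerically indistinguishable.

The smoothness parameter is reported as the neighbourhood standard
deviation `σ = 1/√τ`, with three conventional hierarchical priors:
`Gamma(0.5, 0.0005)` and `Gamma(0.01, 0.01)` on the precision `τ`, and
`Uniform(0, 100)` on `σ` (the package default — it does not pull the
posterior of `σ` toward zero, which matters when the object of interest is
a risk *gradient*). A `prior_fixed_sd()` option holds `σ` fixed for
validation against closed-form oracles.

## Posterior computation

The sampler (C++, single-threaded) is Metropolis-within-Gibbs:

* each `S_i`: Gaussian random-walk Metropolis, per-pixel proposal scales
  adapted in batches of 50 sweeps during burn-in toward acceptance 0.44 and
  frozen afterwards (so the stationary distribution is exact);
* `α`: random-walk Metropolis with the same adaptation;
* `τ` under gamma priors: conjugate Gibbs,
  `Gamma(a + (n-c)/2, b + ½Σ(S_i−S_j)²)`;
* `σ` under the uniform prior: random walk on `log σ` with the Jacobian
  term, proposals outside `(lo, hi)` rejected. A dispersed starting value
  outside the support is clamped to just inside it.

Default chain lengths mirror long production runs (5,000 burn-in sweeps,
then every 100th of 500,000 sweeps retained, two chains started from a
zero state and a dispersed state). All simulation studies and tests in this
package use a scaled-down profile — 1,000 burn-in, 20,000 sweeps thinned by
10, i.e. 2,000 retained draws per chain — which on a 400-pixel window runs
in about a second per chain. Per-chain RNG streams derive deterministically
from one master seed, so fits are bit-reproducible.

Numerical details worth knowing: `exp(S_i)` values are cached and refreshed
every 1,000 sweeps to cancel multiplicative drift; the field recentring
makes every stored draw sum to zero within 1e−8; a 1 × 1 window has an
empty graph, the field pins to zero and the model collapses to a Poisson
with offset — this degenerate case is exploited by the conjugate-oracle
test.

## Exceedance probabilities and cluster screening

For each pixel, `EP_i` is the fraction of retained draws with
`RR_i = exp(α + S_i) > 1` (strict: a draw at exactly 1 does not exceed),
and the summary risk is the posterior median of `RR_i`. Two readings of
"relative risk" are defensible — with the intercept (`μ_i/E_i`, the
observed-to-expected ratio) or without (the spatial component only); both
are implemented (`include_intercept`), with the former as default since it
matches the observed/expected definition of RR. EP is a rank statistic of
the per-draw RR, so any strictly monotone re-expression leaves it
unchanged.

Clusters are connected components (queen rule, matching the model's
neighbourhoods; rook available) of pixels with `EP > 0.99`, keeping
components of at least `min_size = 2` pixels — "multiple adjacent pixels"
operationalised; both knobs are arguments. Each cluster is annotated with
its centroid's distance and 8-point compass bearing from the site pixel.

One subtlety: with 2,000–4,000 retained draws, EP saturates at exactly 1
across several pixels once a signal is strong, so "the maximum-EP pixel" is
ill-defined by scan order. `peak_pixel()` therefore breaks EP ties by the
posterior-median RR — the most elevated of the tied pixels.

## The synthetic generator

Real birth-certificate registries are protected and cannot ship with the
package, so validation uses a generator that emulates the features the
pipeline must survive:

* **heterogeneous density** — a mixture of a uniform background and
  Gaussian settlement patches (default: 5 patches of SD 2 km holding 70% of
  births) over a 20 × 20 km region, producing empty pixels (structural
  zeros) at realistic rates;
* **a rare outcome** — baseline probability 0.014, the published
  county-wide very-low-birth-weight rate, with optional per-outcome
  multipliers (e.g. ×10 emulates the more common low-birth-weight outcome);
* **a smooth excess** — `RR(d) = 1 + (RR₀ − 1)·exp(−d/decay_range)` around
  the source (default `RR₀ = 3`, range 2 km), the simplest smooth
  distance-decay consistent with a continuous exposure gradient; risk
  multiplies the outcome probability with clipping at 1;
* **scale** — 200,000 births by default, matching the order of ~176 births
  per pixel per 12-year period implied by the published county totals.

What it does *not* emulate: geocoding error and incompleteness,
personal-level covariates (race, maternal age), multiple gestations, or
true ICAR-distributed fields (the decay surface is smoother than an ICAR
draw). Passing the recovery suites therefore demonstrates correctness of
the machinery and calibration under a plausible gradient — not performance
on any real registry.

## Validation strategy

The test suite checks every stage against an independent route:

* projection against geodesic distances (`geosphere`) and inverse
  round-trips; components against an `igraph` oracle; adjacency against
  brute-force enumeration;
* the sampler against (i) the conjugate Poisson–Gamma closed form in the
  degenerate single-pixel model, (ii) a dense-quadrature oracle on a 2 × 2
  window with fixed `σ` (posterior means matched within 3 Monte-Carlo
  standard errors), (iii) the closed-form Gamma conditional of the
  precision Gibbs step (Kolmogorov–Smirnov on fixed-field draws), and
  (iv) the exact constrained-Gaussian ICAR sampler `ricar()` plus the
  identity `E[Σ(S_i−S_j)²] = (n−c)/τ` when the likelihood is switched off;
* frequentist calibration: over 50 windows simulated from the model itself
  (`α* = 0`, `σ* = 0.3`, 200 births/pixel), 95% posterior intervals cover
  the truth in ≥ 90% of replicates; 20 null-scenario seeds yield almost no
  spurious clusters; 20 signal seeds localise the peak-EP pixel within 2 km
  of the source;
* prior insensitivity: the three hierarchical priors agree on the
  `EP > 0.99` status of ≥ 95% of pixels on a strong-signal window, and on
  null windows all three shrink the `σ` posterior — spatial homogeneity —
  relative to signal windows.

Convergence is summarised by the potential-scale-reduction statistic
`R-hat = √((W + B/n)/W)` computed across whole chains (exactly 1 for chains
that agree perfectly, always ≥ 1), with an optional split-half variant for
within-chain drift; 1.1 is the conventional flag threshold, reported rather
than enforced.

## Limitations

* The model contains a single spatial term; there is no unstructured
  heterogeneity component and no covariate adjustment — this is a
  *screening* tool, and a flagged cluster is grounds for investigation, not
  an attribution to the source.
* Distance-based (kriging-type) covariance is out of scope by design; the
  ICAR neighbourhood structure ties smoothing to the pixel graph, which is
  what makes 400-pixel windows computationally trivial.
* EP thresholds trade sensitivity for specificity; 0.99 with `min_size = 2`
  is deliberately conservative and both are user-settable.
* Pixel edges are arbitrary; the 1 km resolution mitigates but does not
  remove boundary effects, and records are deliberately coarsened to pixel
  centres (which also protects identities).
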