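# epicar

Geostatistical first-step screening of disease clusters around putative
toxic sources, on a square-kilometre pixel grid.

## The problem

When residents suspect that a contaminated site (for example a Superfund
site) elevates the risk of an adverse birth outcome nearby, the first step
of a cluster investigation is statistical: is there a credible local excess
of cases? Classical approaches compare rates across arbitrary boundaries
(census tracts, one side of a street vs the other), which mutes genuinely
continuous exposure gradients. `epicar` instead models risk as a smooth
surface over small pixels and reports, for every pixel, the *exceedance
probability* (EP) — the posterior probability that the pixel's relative
risk exceeds one — so that clusters of any shape emerge as groups of
adjacent high-EP pixels.

It is aimed at spatial epidemiologists and health-department analysts
working with geocoded point records (births, case registries) around known
point sources.

## The model

Each geocoded record is projected to planar kilometre coordinates (UTM, an
equirectangular approximation, or pre-projected input), rounded to the
nearest 1 km pixel centre, and windowed into a 20 x 20 pixel study window
centred on the site. For pixel *i* with `n_i` births, the case count `Y_i`
and expected count `E_i = n_i * r` (with `r` the overall study-wide outcome
rate) enter a zero-inflated Poisson model with an intrinsic conditional
autoregressive (ICAR) spatial prior:

```
Y_i ~ Poisson(group_i * mu_i)
log(mu_i) = log(E_i) + alpha + S_i
group_i   = 1 iff the pixel holds any births (structural zeros otherwise)
S ~ ICAR(tau), queen adjacency (nine-pixel neighbourhoods),
               sum-to-zero constrained;  sigma = 1/sqrt(tau)
```

Pixels without births are "structural zeros": their zero case count is
forced, not a Poisson outcome, and they inform the fit only through the
neighbourhood graph. The posterior is sampled by adaptive random-walk
Metropolis-within-Gibbs (written in C++); the per-pixel relative risk is
`RR_i = exp(alpha + S_i)` and `EP_i = Pr(RR_i > 1 | data)`. Clusters are
connected components of pixels with EP > 0.99 containing at least two
pixels. Because the protected birth-certificate data behind such studies
cannot be redistributed, the package ships a synthetic generator with a
known distance-decay risk surface (`RR(d) = 1 + (RR0 - 1) exp(-d/range)`)
so every stage is testable end to end.

## Worked example

```r
library(epicar)

## a synthetic study window: 200,000 births, 1.4% baseline outcome rate,
## relative risk 3 at the source decaying over 2 km
scn <- scenario(n_births = 200000, rr0 = 3, decay_range = 2, seed = 42)
pts <- simulate_dataset(scn)

win <- extract_window(bin_to_pixels(pts), scenario_site(scn))
win <- compute_expected(win, overall_rate(pts))
win
#> Study window: 20 x 20 pixels of 1 km around site ' source '
#>   origin (SW pixel centre): (0, 0) km; outcome: VLBW
#>   births: 190115 in 400 occupied pixels; cases: 2889
#>   expected cases: 2870.7

fit <- zip_icar(win, control = mcmc_control(burn_in = 1000,
                iterations = 20000, thin = 10, seed = 1))
summary(fit)
#> Posterior summary (4000 draws, prior: Uniform(0, 100) on the neighbourhood SD)
#>          mean     sd    2.5%  median  97.5%
#> alpha -0.0006 0.0253 -0.0511 -0.0003 0.0476
#> sigma  0.3737 0.0600  0.2645  0.3701 0.4982
#> R-hat: alpha 1.0004  sigma 1.0023
#> posterior-median RR range: [0.7449, 1.603]; pixels with EP > 0.99: 3

surf <- exceedance(fit)
clusters <- site_proximity(detect_clusters(surf), win)
cat(cluster_report(clusters), sep = "\n")
#> Cluster screen for 'source': EP > 0.99, queen adjacency, min size 2
#>   cluster 1: 3 pixels, max EP 1.000, 1.7 km NE of the site

write_esri_ascii(surf, "ep.asc", layer = "ep")  # GIS-ready raster
```

The intercept sits at zero (the window-wide risk matches the internal
standard), the neighbourhood SD `sigma ~ 0.37` indicates a real spatial
gradient, and the screen flags one three-pixel cluster straddling the
source — the simulated excess, recovered. Under a null scenario
(`rr0 = 1`) the same screen returns no clusters.

Sensitivity analyses (`run_prior_sensitivity`, `run_outcome_sensitivity`)
refit the model under the three conventional smoothness priors —
Gamma(0.5, 0.0005) and Gamma(0.01, 0.01) on the precision, Uniform(0, 100)
on the SD — or across outcome definitions, and report EP-surface
concordance and cluster-location agreement. `gelman_rubin()` provides the
potential-scale-reduction convergence check across chains.

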