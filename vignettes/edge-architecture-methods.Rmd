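---
title: "Edge effects on tree architecture and biomass: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge effects on tree architecture and biomass: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragarch)
```

## The scientific problem

Forest fragmentation exposes trees to hotter, drier, windier and brighter
conditions near the created margins. Beyond the well-documented mortality
of large trees, these edge conditions can reshape the *architecture* of
individual trees — how wood is distributed among trunk, branches and
crown — and thereby shift the *allometric* relationships used to convert
simple stem measurements into woody volume and aboveground biomass (AGB).
If edge trees of a given diameter hold systematically more or less wood
than interior trees, then biomass maps built from interior-calibrated
allometries are biased precisely where fragmentation impacts are
strongest.

`fragarch` implements the full analysis chain for this question:

1. architectural traits computed from cylinder-based quantitative
   structure models (QSMs) of single trees,
2. allometric models for woody volume with nested random intercepts,
3. an edge-extent scan that estimates how far edge effects on each trait
   penetrate into the forest,
4. a plot-census AGB pipeline that decomposes the edge biomass deficit
   into a forest-structure component and a tree-allometry component, and
5. a synthetic stand/census generator with recorded ground truth, used to
   validate every estimator by parameter recovery.

## QSMs and architectural traits

A QSM represents one tree as a rooted hierarchy of cylinders, each with a
start point, unit axis, length $L$, radius $r$, a parent reference and a
branch order (0 = trunk). All geometry is metric. Because cylinder
fitting overestimates the size of the finest branches, trees are trimmed
before trait computation: every non-trunk cylinder with diameter below 2
cm is removed *together with its whole subtree* — branches are detached
whole, so a thick cylinder below a thin parent goes too.

The traits, per tree after trimming:

* **Surface area per unit volume** (m² m⁻³), per compartment:
  $\sum 2\pi r L / \sum \pi r^2 L$. Lateral areas only — no end caps;
  this is the QSM-literature convention and any consistent choice cancels
  in comparisons. For a tree whose cylinders share radius $r$ the ratio
  is exactly $2/r$, a closed-form oracle used in the tests. High values ⇔
  thin elements.
* **Path fraction** (–): mean over tips of the cumulative axial length
  from base to tip, divided by the maximum such length. Measured along
  cylinder axes, not Euclidean distance. 1 for an unbranched stem.
* **Asymmetry** (m): horizontal distance between the woody-volume-weighted
  centroid of cylinder midpoints and the base. This is a stand-in
  definition — the exact published formula lives in supplementary
  material we do not reproduce, and reported asymmetry values on other
  scales (confidence intervals of 11–18 for tall trees) indicate a
  different, likely normalised, definition. The `method` argument exists
  so alternatives can be added; comparisons *within* this package are
  internally consistent.
* **Crown base height** (m): the lowest attachment at which a parent
  supports ≥ 2 children whose radii are each ≥ 0.5× the parent radius
  (a multi-stemming point); if no such co-dominant split exists, the
  lowest branch attachment. The 0.5 ratio is the `codominance_ratio`
  knob.
* **Relative crown depth** (m m⁻¹): $(H - \text{crown base})/H \in [0,1]$.
* **Relative crown width** (m cm⁻¹): maximum horizontal distance between
  any two crown-cylinder endpoints, divided by DBH in cm. Max spread was
  chosen over an enclosing-circle or mean-spread definition for its
  simplicity and an exact $O(n^2)$ test oracle (computed via convex
  hull).
* **DBH** (cm): diameter of the trunk cylinder whose along-stem interval
  contains 1.3 m of cumulative axial length. Measuring along the stem
  path (not vertical height) mirrors field practice on leaning stems; at
  co-dominant basal splits the trunk follows the largest-radius chain.
* **Establishment class**: trees taller than 20 m must predate
  fragmentation (survivors); the comparison is strict, so exactly 20 m
  classifies as `short_tree`.

Geometric contiguity between parent and child cylinders is *not*
enforced: fitted QSMs contain gaps, so topology is authoritative.

## Allometric models

Woody volume follows a power law in stem size. On the log scale, with
$X = \mathrm{DBH}^2 H$ or $X = \mathrm{DBH}$:

$$\ln V = \beta_0 + \beta_1 \ln X \,(+\, \beta_2 \ln X^2) + \mu_i + \varepsilon_i$$

fitted by REML (`nlme::lme`) with random intercepts $\mu_i$ for plot
nested in fragment nested in site. If the nested fit is unfittable the
deepest level is dropped with a warning, terminating in ordinary least
squares with zero random-effect variances — so degenerate designs (one
plot) degrade gracefully rather than failing.

Four published equation variants are hard-coded in
`predict_volume_published()` (interior/edge × with/without height). A
unit subtlety matters here: the printed coefficients reproduce the
published worked examples (7.7, 7.4, 0.12, 0.18, 8.14, 6.27 m³) only
with **DBH in metres**, although the surrounding text says cm. The
predictor therefore takes metres, and the census pipeline divides cm by
100. Exponentiation is plain — no Baskerville/Duan back-transformation
correction — because the worked examples match plain exponentiation to
within 1%.

Whether a quadratic term is warranted is decided by AIC. REML
likelihoods are not comparable across fixed-effect structures, so
`select_quadratic_by_aic()` compares maximum-likelihood fits and refits
the winner by REML; ties (ΔAIC below 1e-9) go to the linear model.

Trait–height relations use the nonlinear power form
$\text{trait} = \beta_0 H^{\beta_1} + \mu_i + \varepsilon_i$
(`nlme::nlme`), initialised from a log-log least-squares fit, with a
restart grid on $\beta_0$ and a random-structure fallback ending in
Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`, which
unlike Gauss–Newton `nls` converges on zero-residual data).

Model stability is assessed by `permutation_validation()`: 200 random
80/20 calibration/validation splits, stratified by plot so every plot
contributes to calibration (plain uniform splitting is available via
`stratify = FALSE`), recording coefficient draws and held-out RMSE of
$\ln V$. Every stochastic function takes an explicit seed; the package
default is 20191980.

## Edge-effect models and the extent scan

For a candidate extent $d$, trees are coded `edge` when their distance
to the margin is strictly below $d$, and the trait model

$$\text{trait} = \beta_0 + \beta_1\,\text{edge} + \beta_2 H +
\beta_3\,\text{edge} \times H + \mu_i + \varepsilon_i$$

is fitted by REML with the same nested intercepts. The extent of the
edge effect on a trait is estimated by refitting over $d = 1, \dots,
100$ m and taking the $d$ maximising $|t|$ of the edge term
(`scan_edge_extent()`). Ties go to the smallest distance; thresholds
leaving fewer than 5 trees in either stratum (configurable floor) are
recorded as missing and excluded. Because the maximum of many $t$
statistics is selected, the chosen extent's $|t|$ overstates
significance under the null — the scan is an estimator of *where* the
effect is strongest, not a test of *whether* it exists; the package
documents this rather than interpreting the selected $t$ as a p-value.

For allometry, the interaction model is
$\ln V = \beta_0 + \gamma \ln X + \beta_1 (\text{edge} \times \ln X) +
\mu_i + \varepsilon_i$, and $\beta_1$'s $t$ is scanned. A "literal"
variant without the main slope $\gamma$ exists behind `literal = TRUE`:
the published equation sketch omits the main term, but a model with no
interior slope cannot reproduce the interior DBH-only law, so the
default includes it and the literal form is provided for comparison
only.

`variance_components()` normalises the four variances (site, fragment,
plot, residual) to proportions; in both the motivating field data and
the default generator, the within-plot (residual) share dominates.

## Census AGB and the decomposition

Census stems (DBH ≥ 10 cm, taxonomy to species where possible) are
converted to volume with the DBH-only equations — interior (eq3)
everywhere, or edge (eq4) for stems in plots closer than
`allometry_extent` (default 55 m) — and to biomass via wood density
(1 g cm⁻³ ≡ 1 Mg m⁻³). Density resolves at the finest available level:
species match, genus mean, family mean, then overall mean, with the
resolution level returned for audit. Because census plots are 1 ha,
stem-level distances are unavailable and the plot distance proxies for
all its stems; this is an acknowledged ambiguity of the design (the
alternative — applying the edge equation to every stem of every < 100 m
plot — corresponds to `allometry_extent = 100`).

The edge AGB deficit decomposes additively. With plot-mean AGB
$I$ (interior plots, interior allometry), $E_{\text{int}}$ (edge plots,
interior allometry) and $E_{\text{edge}}$ (edge plots, edge-allometry
rule):

* structure component $= I - E_{\text{int}}$ (stem sizes, density,
  composition),
* allometry component $= E_{\text{int}} - E_{\text{edge}}$ (the same
  stems re-predicted),
* total $= I - E_{\text{edge}}$, exactly the sum by construction.

Setting `allometry_extent = 0` disables the rule and forces the
allometry component to exactly zero — a useful null. Confidence
intervals for class means and the structure/total components come from
the mixed model `AGB ~ edge + (1 | site)`; the allometry component is a
within-plot paired difference, so its CI uses the paired standard
error.

## The synthetic generator

The generator is first-class, tested code: it defines the conditions
under which every estimator is validated.

`generate_stand()` emulates the statistical structure of the field
campaign: 2 sites, 4 fragments cycling sizes 1/10/100 ha whose maximum
interior distance is 50/100/500 m (so edge distances are continuous and
most trees sit within 100 m of a margin, as in edge-perpendicular
transect sampling), 12 plots, tree heights from a survivor/colonising
mixture (30% tall, log-normal around 26 m; 70% short, around 11 m), DBH
from a log-linear height–diameter relation, and woody volume from the
per-stratum published DBH-only laws (interior 2.80/1.97, edge
2.45/1.72) with residual sd 0.3 on $\ln V$ and nested random
intercepts (0.05/0.05/0.10). Trait values are linear in height with
additive edge shifts applied strictly inside `edge_extent_true`
(default 40 m). The default shifts mirror the direction and rough
magnitude of the reported short-tree edge contrasts (thicker branches,
higher asymmetry and path fraction, deeper and relatively narrower
crowns); `shift_scale` multiplies them all, with 0 the exact null and 3
the fixed convention for a "strong" shift in recovery simulations.

`generate_qsm_tree()` builds individual cylinder trees by a stochastic
recursive branching process. Archetypes inject the contrasts of
interest: `edge_short` gets 1.6× branch radii, an azimuth-biased crown
and a co-dominant basal split; `edge_tall` is shorter for its diameter
with shorter branch chains. This is a trait-contrast machine, not a
plant model: no phyllotaxis, no foliage, no mechanics.

`generate_census()` draws 44 one-hectare plots (28 edge, 16 interior,
4 sites), Poisson stem counts at 275 stems ha⁻¹, and DBH as 10 cm plus
an exponential excess with mean 16.3 cm — a reverse-J distribution
sized so that interior plots average ≈ 282 Mg ha⁻¹, the biomass level
typical of intact Central Amazonian forest. Edge plots default to a
7% density thinning (`edge_density_factor = 0.93`), so the default
census carries a structure deficit comparable, in relative terms, to
the one reported for these forests. The bundled wood-density fixture is
*synthetic*: 30 Amazonian taxa with plausible, invented densities
(`wood_density_synthetic.csv`), present so tests never download
anything.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: measurement and co-registration error,
occlusion-driven QSM bias, spatial autocorrelation beyond the nesting,
species identity and composition shifts, non-step edge gradients, and
correlated trait responses within trees.

## Numerical and design choices

* Strict `<` for edge coding everywhere; generator distances are
  continuous so grid thresholds never coincide with a tree's distance.
* Scan grid: integer metres 1–100; argmax ties → smallest distance;
  per-stratum floor 5 trees.
* $t$ and p-values from the `lme` t-table (containment degrees of
  freedom); this choice matters for borderline significance, not for
  the argmax of the scan.
* Mixed-model fallback chain: site/fragment/plot → site/fragment → site
  → OLS, each step warning; singular-fit errors are treated as
  unfittable.
* Cylinder CSV I/O writes doubles at 17 significant digits, so a
  write/read round trip is bit-exact.
* Problem sizes in the validation suites — 50 scan replicates of 300
  trees, 200 coverage replicates, 500 null simulations — were chosen to
  bound Monte-Carlo error near 1–3% on the reported rates.
* Coverage checks use marginal 95% CIs per coefficient. The joint event
  "both CIs cover" runs near 90% when estimates are correlated
  (here ≈ 0.75), which no correctly calibrated marginal intervals can
  lift to 95%; rates are therefore reported per coefficient. The
  coverage stand is generated with plot-level intercepts only: with just
  two sites, REML standard errors cannot fully propagate site-mean
  uncertainty (the few-groups problem), which would be a finding about
  the design, not the estimator.

## Known limitations

* The asymmetry and crown-width definitions are documented stand-ins;
  absolute values are not comparable to analyses using other
  definitions, though contrasts and extents are.
* The nonlinear trait–height fit can be sensitive to starting values on
  small, noisy strata; the restart/fallback chain makes it robust but
  the final fallback drops the random intercepts.
* No uncertainty propagation from QSM volume error into AGB; no spatial
  autocorrelation; no belowground or carbon conversion.
* Field-scale magnitudes (the ~282 Mg ha⁻¹ interior biomass, the 18.7
  vs 6.0 Mg ha⁻¹ component split, trait CIs, observed extents of
  10–76 m) depend on census and TLS data available only on request;
  this package validates the *methods* against synthetic ground truth
  and reproduces the published equations' worked examples exactly.
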