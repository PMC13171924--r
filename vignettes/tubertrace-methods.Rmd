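---
title: "Tracing vertical transfer of tuber microbiota: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing vertical transfer of tuber microbiota: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubertrace)
```

# The problem

Potato is propagated vegetatively: a seed tuber grows into a plant whose
daughter tubers seed the next season. Part of the tuber's bacterial community
travels with the plant (vertical transfer), part is recruited from the
environment, mostly from the soil adhering to the tuber surface (horizontal
acquisition). Quantifying the vertical fraction, how it differs between the
protected flesh and the soil-facing peel, and how *consistent* the abundance
of transferred taxa is across generations are the questions `tubertrace`
addresses. The unit of observation is an ASV-by-sample count table plus
sample metadata (generation, compartment, cultivar, field, replicate).

# Presence, classification, and flows

Presence is a pre-normalization concept: a taxon is *present* in a group of
samples when it has at least `min_count` reads in at least `min_prevalence`
samples, evaluated on raw counts. The default (1 read in 1 sample) is the
weakest rule; it is the only rule under which reported set sizes are plain
counts of detected ASVs, which is how printed community sizes are usually
meant. Raising the thresholds trades sensitivity for robustness to
cross-talk and index hopping, and presence sets are monotone in both
thresholds.

For generation $g$ with present set $A_g$ and seed set $A_0$, two
classifications are offered:

* **seed_baseline** — vertical at $g$ is $A_g \cap A_0$. This matches
  per-generation "vertical percentage" statements (vertical plus horizontal
  percentages sum to 100 by construction).
* **chain** — vertical at $g$ is $A_g \cap A_{g-1} \cap \dots \cap A_0$:
  a taxon must be observed in *every* prior generation. This is the right
  reading for "transferred across all generations" statements and is the
  default input for the heritability screen; chain-vertical sets are
  non-increasing across generations by construction.

Both are implemented because published analyses use both framings, and at
the first transition they coincide. Seed tubers predate the field trials, so
seed samples carry the explicit field level `"(none)"`; when a context names
a field, the seed baseline is taken from the field-missing seed group of the
same cultivar and compartment (one seed lot feeds all fields).

Stage-wise flows follow the retained set through the ordered generations:
each stage's entering set is the previous stage's retained set, and the
stage percentage is $|retained|/|entering| \times 100$. Percentages are kept
exact and also rounded half-away-from-zero to integers, the convention used
in printed flow diagrams. Empty generations yield `NA` percentages with a
warning rather than an error, since sparse groups are a fact of real
surveys.

# Normalization

Library sizes differ across samples, and rarefying discards reads, so the
package normalizes by **cumulative sum scaling**: sample $j$'s scaling
factor $s_j$ is the sum of its counts at or below the empirical quantile
$q$ of its *nonzero* counts. The quantile uses the nearest-rank convention
(the value at 1-based index $\lceil q\,m \rceil$ of the sorted $m$ nonzero
counts), which makes $s_j$ a deterministic, integer-friendly function of the
data and lets the implementation be checked against a brute-force oracle.
Normalized values are $x_{ij}/s_j \times R$ with $R$ the median scaling
factor (or a fixed 1000), keeping magnitudes comparable to counts.

The quantile level is a genuine free parameter: no single convention is
universal across CSS implementations, and results from other tools may
differ. The default is $q = 0.5$; `css_choose_quantile()` offers an
adaptive alternative that scans ascending levels and picks the smallest one
at which the median relative change of $s_j$ between successive levels
exceeds 0.1 (the point where cumulative sums start diverging across
samples). Downstream, the heritability screen consumes relative abundance
computed from CSS-normalized values by default (`css = FALSE` switches to
raw proportions); both are exposed because the choice is not fixed by any
convention we know of, and on per-sample proportions the two differ only
through the rescaling step.

# Transfer probability

Each context (compartment × cultivar × field) and transition (seed→daughter,
daughter→granddaughter) contributes one binomial observation: `trials` taxa
entering, `successes` retained. The model is a fixed-effects binomial GLM
with logit link. A random intercept for field would be the textbook choice
for the hierarchical design; with two fields and negligible field-level
variation the random effect is weakly identified, so the package instead
offers cluster-robust (sandwich) standard errors clustered on field — the
fixed-effects analogue — plus a quasi-binomial dispersion option in place of
an observation-level random effect. This keeps every estimator closed-form
and oracle-testable. Term tests are Wald χ² under sum-to-zero coding
(Type-III style, invariant to reference-level choice); marginal
probabilities are estimated marginal means on the response scale with
delta-method CIs computed on the logit scale, which respects the [0, 1]
bounds. Complete separation (a level with all successes or all failures) is
detected and reported with a pointer to `bias_reduced_fit()`, a Firth-type
penalized fit whose Jeffreys-prior score adjustment keeps coefficients
finite; on well-behaved data it agrees with maximum likelihood to $O(1/n)$.

# Broad-sense heritability

For each taxon within a cultivar–compartment context, transformed abundance
is modelled as a one-way random-effects layout,

$$y_{ijk} = \mu + G_i + \varepsilon_{ijk},\qquad
  G_i \sim N(0, V_G),\quad \varepsilon_{ijk} \sim N(0, V_E),$$

with generation as the only grouping factor (granddaughter replicates pool
over fields, because the model has a single random effect) and

$$H^2 = \frac{V_G}{V_G + V_E} \in [0, 1].$$

$H^2$ here measures how consistent a taxon's abundance is across
generations; it makes no claim about genetic inheritance. The transform is
$\log_{10}(x + 10^{-6})$ on relative abundance: the pseudocount maps absence
to $-6$, well below any observable abundance, and $H^2$ is invariant to the
affine location/scale this induces.

**Estimation.** Variance components are estimated by REML. The criterion is
profiled to the single ratio $\lambda = V_G/V_E$ and minimized by Brent
search on $[0, 10^6]$ (tolerance $10^{-10}$) after a log-scale pre-scan that
localizes the optimum; the boundary $V_G = 0$ is always compared. For
balanced layouts the REML solution has a closed form — it coincides with the
ANOVA method-of-moments estimator $V_G = (MSB - MSW)/n_0$, $V_E = MSW$ when
interior and truncates to $V_G = 0$ otherwise — and the package uses that
form directly to avoid optimizer round-off. The numeric path is
cross-checked in the tests against both an explicit sums-of-squares oracle
and `lme4`.

**Significance.** The null "no generation structure" is tested by $B$
independent uniform permutations of the generation-label vector (free, not
stratified — the labels are the only structure the null removes), with

$$p = \frac{1 + \#\{H^2_{perm} \ge H^2_{obs}\}}{1 + B}.$$

The $+1$ convention guarantees $p > 0$ and validity; ties count as extreme
(conservative), and a small numerical epsilon ($10^{-9}$) on the comparison
ensures that permutations which merely reorder the observed grouping are
counted as ties rather than lost to floating-point summation order. Within a
screen, p-values are Benjamini–Hochberg adjusted across taxa, and the
fraction of significant taxa is reported. Since label permutation preserves
group sizes, balanced layouts use the closed-form estimator inside the
permutation loop — exactly the REML value there — which keeps a
500-taxon × 999-permutation screen affordable.

**Estimator behaviour with 3 generations.** With only three levels of the
random factor the between-group mean square has 2 degrees of freedom, and
the sampling *median* of $\hat H^2$ sits below the generating value — around
0.20 when the true $H^2$ is 0.3 and around 0.75 when it is 0.8, at 10
replicates per generation. This is intrinsic to variance-ratio estimation
with so few groups (the $F_{2,27}$ numerator's median lies well below its
mean), not an implementation artifact; the permutation test is unaffected
because observed and permuted statistics share the bias. Users comparing
$H^2$ across studies should compare like layouts.

# Community statistics

Alpha diversity uses natural-log Shannon entropy; Pielou evenness is
$H/\ln(\text{richness})$, undefined (NA) for single-taxon samples. Diversity
is computed on raw counts by default — richness is count-based — with
normalized input accepted where wanted. Bray–Curtis dissimilarity is
computed on CSS-normalized values.

PERMANOVA follows the distance-based ANOVA construction: the dissimilarity
matrix is Gower-centered, term sums of squares are sequential (Type-I)
trace increments of cumulative projection matrices in model-formula order
(the dominant convention, and additive: term SS plus residual SS equals
total SS exactly), and significance comes from permuting samples. With an
integer $B$ the p-value is $(1+\#\text{extreme})/(1+B)$; passing an explicit
permutation matrix instead treats those rows as the complete null (useful
for exact enumeration on small designs, which the tests exploit on $N = 6$
two-group instances). The implementation is cross-checked against
`vegan::adonis2` for the F statistics and sums of squares; it is kept
in-package because the enumeration mode and p-value convention are part of
the contract. Dunn's post hoc test (pooled-rank z with tie correction) is
likewise implemented directly, as no installed package provides it.

# The synthetic data generator

`simulate_dataset()` emulates the processed data structure of a
multi-generation field survey, not raw sequencing: three ordered
generations, flesh/peel plus granddaughter tare soil, two cultivars, two
fields, ten replicate tubers per group. Per cultivar and compartment, a
seed community of known richness receives baseline log10 relative
abundances from a normal; each seed taxon is independently retained into
the next generation with a per-compartment probability, chained across
transitions; new horizontal taxa are injected per (generation, compartment,
field), with the tare-soil pool partially overlapping the peel pool; counts
are gamma–Poisson (negative binomial) draws given a gamma library size.

Default parameters are fixed once as a realistic scaled-down survey:
seed richness 100 (flesh) and 200 (peel); retention probabilities 0.20
(flesh) and 0.12 (peel), so that flesh retains more, the generational
vertical percentages land in the upper-teens/low-tens range, and horizontal
pools (150/300 daughter, 250/500 granddaughter per field, larger in peel)
dominate later generations; tare-soil pools of 400 per field with 30% peel
overlap; $V_G = 0.4$, $V_E = 0.1$ (true $H^2 = 0.8$ for non-null retained
taxa) with a 30% null fraction; mean library size 30,000 (gamma shape 8)
and NB size 5 for overdispersion. Two features matter for testing:

* **Generation offsets are drawn per (taxon, generation) and shared across
  fields and replicates**, so the heritability module's one-way model is
  *exactly* the generating model and parameter recovery is meaningful.
* **The detection guarantee** (count ≥ 1 in every sample of a group where a
  taxon is marked present; absent taxa are exactly zero) makes presence
  deterministic, so classification can be compared to the truth ledger
  taxon-by-taxon — tests demand 100% agreement. Disabling it
  (`detection_guarantee = FALSE`) restores stochastic detection for
  sensitivity studies.

What the generator does **not** emulate: taxonomic structure, phylogenetic
correlation among taxa, compositional competition between vertical and
horizontal fractions beyond renormalization, spatial field layout, or
sequencing artifacts (chimeras, contamination). Passing tests on synthetic
data therefore validate the *logic and estimators*, not robustness to those
real-data features.

# Numerical choices and degenerate inputs

* Percentages are rounded half-away-from-zero (matching how printed
  percentages are conventionally rounded); exact values are always kept.
* All-zero samples are hard errors for normalization and Shannon diversity,
  named per sample; empty groups map to empty presence sets; empty
  generations and empty entering sets yield `NA` percentages with warnings.
* `p = (1+\#extreme)/(1+B)` everywhere a permutation p-value is computed.
* GLM IRLS runs to a deviance tolerance of $10^{-12}$ (cap 100 iterations)
  so closed-form identities (pooled-proportion intercept, 2×2 Wald χ²)
  reproduce to many digits.
* Zero total variance in a heritability fit returns $V_G = V_E = 0$,
  $H^2 = 0$ with a warning rather than failing, since all-constant
  transformed abundances do occur for rare taxa.

# Problem sizes used in the validation suite

The test suite and the reproduction script exercise: the default simulated
survey (~6,500 taxa × 240 samples) for end-to-end classification; 500
simulated taxa for H² recovery (3 generations × 10 replicates each) and for
permutation-test calibration at $B = 199$; 500 simulated datasets
($N = 12$) for PERMANOVA null calibration at $B = 99$ plus exact
enumeration at $N = 6$; and 200 random 10×8 matrices for the CSS oracle.
These sizes give stable Monte Carlo estimates (binomial SE ≲ 0.01 on
rejection rates) while keeping a full run in the low minutes on one core.

# Known limitations

* True random-effects (GLMM) machinery is deliberately out of scope; the
  fixed-effects-plus-robust-errors reduction is documented above and is the
  package's contract.
* The H² point estimator's small-sample median bias with 3 groups (above).
* Chain-mode classification conditions on detection in every prior
  generation; with imperfect detection in real data this undercounts
  persistent taxa (a taxon missed in one generation is reclassified as
  horizontal later). The detection-rule thresholds are the available lever.
* CSS results depend on the quantile convention; cross-tool comparisons
  should fix the convention first.
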