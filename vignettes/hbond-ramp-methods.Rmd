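---
title: "Methods: position-dependent hydrogen bonding in ORFeomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: position-dependent hydrogen bonding in ORFeomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbramp)
```

## The quantity being profiled

Every codon pairs its three bases in double-stranded DNA with either two
hydrogen bonds (A:T) or three (G:C), so a codon carries between 6 and 9
bonds. Synonymous codons of one amino acid can differ in this count — for
leucine the span is 6 (TTA) to 8 (CTC/CTG), a 25% reduction available
without touching the protein. Codons with 6–7 bonds are called *cheap*,
those with 8–9 *expensive*. Because strand separation during transcription
must break these bonds, position-dependent preferences for cheap codons
near the 5' end of coding sequences are a candidate signature of selection
for efficient transcription (and, in organisms with co-transcriptional
translation, for coupling to the ribosome).

`hbramp` profiles the mean per-codon bond count of an ORFeome (all CDSs of
a genome) by codon position, models the resulting 5' ramp, and tests
whether the observed positional distribution of bonds could arise without
position-specific selection.

## Conventions: QC, start codon, coordinates

CDSs are retained when their length is divisible by 3 and they still have
at least `n_positions` codons (100 by default, 250 optionally) *after*
removal of the start codon; the start codon is removed before every
analysis. We interpret the length threshold post start-removal so that
every profile genuinely covers `n_positions` columns. Positions are always
labelled by their original 1-based codon index (start codon = 1), so the
first analyzed column is position 2. CDSs with an ambiguous base inside
the analyzed window are dropped for hydrogen-bond work (the count is
undefined there); for usage metrics (RSCU/CAI/tAI) codons containing N
instead take the neutral value 1. Trailing stop codons inside the window
are ordinary codons — no stop-specific filter exists.

## Positional profiles

A profile is the per-column mean of a per-codon valuation over the
left-aligned codon matrix, with a 95% percentile bootstrap interval
(default 1,000 resamples). Whole CDS rows are resampled, not cells, so
within-CDS correlation survives resampling; the percentile form was chosen
because only "nonparametric bootstrap" is inherent to the definition, not
an interval type. All stochastic steps take an explicit seed and restore
the RNG state afterwards.

## The ramp model

The positional mean of hydrogen bonds is fitted with three candidates:
uniform $y = A$, linear $y = Bx + C$, and the bounded exponential

$$y(x) = \frac{A\,C\,e^{Bx}}{A + C\,(e^{Bx} - 1)},$$

where $A$ is the carrying capacity (bonds/codon), $B$ the rate per codon
position, and $C$ the initial content. Positions are re-indexed so the
first analyzed position (original position 2) is $x = 0$, which makes $C$
exactly the bond content at the first codon after the start. For $Bx > 0$
the curve is evaluated as $AC / (Ae^{-Bx} + C(1 - e^{-Bx}))$ so large
exponents cannot overflow.

Fitting is weighted least squares; weights default to the inverse
bootstrap variance of the positional means (uniform weights are available
by flag). The nonlinear fit starts from a logistic-style self-start
($A_0$ = maximum mean, $C_0$ = first mean, $B_0$ from a log-linearisation
of the early positions) and runs a Levenberg–Marquardt optimiser (at most
1,000 iterations, parameter tolerance $10^{-10}$). Parameter p-values are
Wald tests from the asymptotic covariance. When the nonlinear fit fails,
fallback parameters are reported instead: initial content = minimum
positional mean, carrying capacity = trimmed mean of the positional means
after dropping 10 positions from each end of a 100-position profile
(proportionally otherwise).

### Model selection and the "success" flag

`select_model()` returns the AIC minimiser and flags AIC/BIC
disagreement. A ramp is *declared* — the `success` flag — only when the
bounded exponential converged, is best under **both** AIC and BIC, and
its rate parameter is significant (Wald $p < 0.001$ by default). The
joint rule matters: with a 100-point profile, AIC alone lets the
3-parameter curve beat the 1-parameter constant on pure noise with
probability $P(\chi^2_2 > 4) \approx 0.14$, so AIC-only selection would
"detect" ramps in flat data at an unacceptable rate, while BIC's
$\ln(100) \approx 4.6$ penalty brings the false-detection rate to the
percent level. The `success` flag is this package's operational
definition of a successfully modelled ramp and is labelled as such in
reports.

## Selection test against a synonymous-shuffling null

The null model shuffles synonymous codons within each full-length CDS:
for each amino acid independently, the multiset of its codons is permuted
over that amino acid's positions. Translation and the per-CDS codon
multiset are invariant; stop codons and single-codon families never move.
Shuffling full-length CDSs (not just the analyzed window) lets synonyms
enter and leave the window from downstream positions; a window-only mode
exists for sensitivity checks. From `n_sims` shuffled ORFeomes (200 by
default) the per-position total bond count yields a null mean $E$ and
standard deviation $\sigma$.

Per position the observed total $O$ gives $z^2 = ((O - E)/\sigma)^2$,
summing to a $\chi^2$-type statistic, and the hanging chi-gram
$(O - E)/E$, whose sign points toward fewer ($-$) or more ($+$) bonds
than the null expects. A $(O - E)/\sqrt{E}$ variant sits behind a flag
because the flattened rendering of the printed formula is ambiguous; the
literal $E$ denominator is the default. Positions with $\sigma = 0$
(nothing can move there) contribute $z^2 = 0$ and are flagged. The $z^2$
profile is min–max normalised per ORFeome; the chi-gram is centered and
scaled. $O$, $E$ are per-position *sums* over CDSs — means would rescale
$z^2$ only if $\sigma$ were rescaled accordingly, so sums are used
throughout.

## Codon-usage metrics

RSCU is a codon's count divided by the mean count of its synonym family,
computed from the whole input ORFeome (an optional reference set can be
supplied); CAI weights divide RSCU by the family maximum. tAI weights
follow the canonical gene-copy-number recursion over Watson–Crick and
wobble pairs with the selective-constraint vector
$s = (0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68, 0.89)$, configurable, and the
prokaryote/eukaryote switch `sking` controlling the bacterial ATA route.
The same $s$ vector is used for both kingdoms by default, matching the
source convention this package follows; it is a configuration value, not
a constant. Stop codons and ATG sit outside the canonical normalisation
set; mid-CDS methionines are assigned the natural extension
$\min(W_{ATG}/\max W, 1)$ so positional profiles cover every sense codon,
and stop codons fall back to the neutral value 1 in profiles.

The mRNA structure adapter parses per-position unpaired-probability
tables from an external local-folding tool (window parameters such as
L = W = u = 40). "The probability of a base being unpaired" admits two
readings under span output; the adapter exposes both — mean over all
reported spans containing the base (default) and mean over spans ending
at the base — and codon values are the mean of their three bases, with
structure probability $1 -$ unpaired.

## The synthetic-data generator

Generated CDSs start with ATG; at each subsequent position the amino acid
is drawn from the configured frequencies (uniform over the 20 by default)
and the codon within the family with probability
$\propto e^{\theta_x h}$, where $h$ is the codon's bond count and
$\theta_x$ is solved by bisection so the population mean equals the
target curve $\mu(x)$ — the bounded exponential with chosen $(A, B, C)$,
or a flat level for controls. Exponential tilting is the maximum-entropy
family matching a mean constraint: nothing beyond the positional mean is
imposed. Targets are clamped $10^{-6}$ inside the feasible interval
(population-weighted family minima to maxima; about $[6.90, 7.95]$
bonds/codon under uniform amino-acid frequencies) to keep the bisection
well-posed, and infeasible targets raise an error that reports the
interval.

Design choices worth noting: the tilt is applied over *all* generated
positions after the start codon rather than only the analysis window,
because a uniform-synonym tail would put a discontinuity in bond content
at the window edge that the ramp model does not describe; and generated
CDSs carry no terminal stop codon, so a 101-codon CDS is exactly a start
codon plus 100 analyzed positions. Defaults are 2,000 CDSs of 101 codons
with $(A, B, C) = (7.9, 0.3, 7.0)$ — a realistic bacterial-scale ORFeome
with a ramp of the size the method is meant to detect.

Operon emulation assigns consecutive CDSs to operons of given sizes and
can regenerate first-position CDSs with the target lowered by $\delta$
bonds/codon over the first 20 positions. Expression emulation draws
log-normal abundances with experiment-level noise and an optional
negative coupling between a CDS's 5' bond content and its abundance.

What the generator does *not* emulate — real amino-acid composition, GC
and codon-usage biases of specific taxa, length variation, UTR context,
genuine operon structure, or mutational processes — bounds what passing
tests show: they validate the pipeline's statistics and parameter
recovery under the stated generative model, not biological conclusions
about any organism.

## Strata and correlation analyses

Operon comparisons group CDSs by position within their operon (1, 2, 3)
and compare per-CDS mean bond content in 20-codon windows, the whole
window, and full CDS length, with two-sided unpaired Wilcoxon tests
(Benjamini–Yekutieli adjusted) and a joint Kruskal–Wallis test. Operon
delineation is an input contract (TSV), not a computation. Expression
strata intersect per-experiment rank cuts; the six preset (high, low)
percentage pairs are (5, 13), (10, 18), (15, 23), (20, 26), (25, 30),
(30, 35), chosen so the two strata hold comparable CDS numbers. Rank
ties break by stable CDS order for determinism. Group profiles are
LOESS-smoothed with span 0.75 (the smoother span is not dictated by the
method; 0.75 is the conventional default). Profile-to-profile association
uses Spearman's rank correlation (Pearson optionally), BY-adjusted, with
region-restricted variants over original positions such as 2–120, 2–60,
2–30.

## Problem sizes and statistical margins in the test-suite

The package's validation suite runs parameter recovery on 20 ORFeomes of
2,000 CDSs × 101 codons, model-selection controls at the same size, null
calibration on 20 ORFeomes of 500 CDSs with 200 shuffles each, and exact
enumeration on toy ORFeomes small enough to list every synonymous
arrangement. These sizes are the package's validation design. One margin
is worth stating analytically: at 2,000 CDSs the per-position standard
error of the mean is ≈ 0.02 bonds, which puts the best achievable
standard deviation of the rate estimate $\hat B$ (by the Cramér–Rao bound
for the weighted fit) near 0.008 — about 2.7% of $B = 0.3$. The rate is
thus recovered essentially at the information limit of a 100-position
profile; materially tighter recovery requires more CDSs or a longer
analyzed window, not a different estimator.

## Known limitations

Single-genome profiles only (no phylogenetic mapping of ramp parameters);
the RNA partition function itself is delegated to an external tool; the
standard genetic code is hard-wired (no mitochondrial or alternative
codes); codon-pair effects are out of scope; and the GAM-based smoothing
of some published figures is replaced by LOESS.
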