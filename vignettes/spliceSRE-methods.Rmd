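---
title: "Modeling and inferring splicing regulatory elements with spliceSRE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inferring splicing regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceSRE)
```

# The thermodynamic model

A cassette exon is spliced in when the spliceosome assembles around its
splice sites. `spliceSRE` collapses the multi-step assembly into a single
binding reaction with dimensionless weight $q_0 = K[S]$. A splicing
factor (SF) bound to its regulatory element contributes weight
$x_f = K_f[\mathrm{SF}_f]$ and couples to the spliceosome through a
cooperativity factor $c_f$; two SFs may couple to each other through
$c_{12}$. Summing Boltzmann weights over all binding states gives the
assembly probability $P_b$ (`spliceProbability()`); with one SF,

$$P_b = \frac{q_0(1 + c x)}{1 + x + q_0(1 + c x)}.$$

At steady state the inclusion/skipping expression ratio is
$N_1/N_2 = a\,P_b/(1-P_b)$, where $a$ absorbs synthesis and degradation
rates, and its logarithm decomposes exactly
(`decomposeLogRatio()`):

$$\ln\frac{N_1}{N_2} = \ln(a q_0) + \sum_f
  \underbrace{\ln\frac{1 + c_f x_f}{1 + x_f}}_{g_f(x_f)} +
  \gamma_{12},$$

with $\gamma_{12} = 0$ exactly when $c_{12} = 1$. The basal term
$\ln(a q_0)$ is exon-specific but tissue-invariant, so centering the
logit inclusion ratio by its cross-tissue average removes it:

$$y_{ij} = \mathrm{logit}(IR_{ij}) - \frac1T \sum_t
  \mathrm{logit}(IR_{it}).$$

Because SF concentrations (hence all $x_f$, $g_f$) are shared by the ASEs
of one tissue, $y$ is *linear* in binary hexamer-presence indicators and
their pairwise products — the model the inference framework fits.

## Effect signs

The fitted coefficient's sign alone does not say enhancer or silencer:
$\gamma_f(j) = g_f(x_{fj}) - \frac1T\sum_t g_f(x_{ft})$ can be negative
for an enhancer whose SF is *depleted* in tissue $j$. $g_f$ is strictly
increasing in $x$ iff $c_f > 1$ and strictly decreasing iff $c_f < 1$, so
when the SF's concentration in the target tissue lies strictly above
(below) every reference tissue, the coefficient's sign identifies
(inverts) the regulatory direction; otherwise `classifyEffect()` returns
`indeterminate`. This assumes the binding constant $K_f$ is
tissue-invariant, so that expression ordering determines occupancy-weight
ordering, and ties are treated as indeterminate.

# From annotation to the design matrix

`selectCassetteExons()` applies five criteria: an exon must be included
by at least one isoform and skipped by at least one; the outer flanking
splice sites must be identical in all isoforms; the exon's own boundaries
must be identical in all including isoforms; and both flanking introns
must reach a minimum length (default 400 nt, so the two 200-nt windows
taken from each intron never overlap). Isoforms that overlap the exon but
fit neither pattern disqualify it — the five regions are then defined
without ambiguity. Isoforms that end before reaching the exon are treated
as uninformative rather than disqualifying; the spliced-in/out status of
the exon in such transcripts is simply unobserved.

`extractRegions()` returns sense-strand RNA for UU/UD/EXON/DU/DD; exons
of 200 nt or more are represented by their first and last 100 nt. The
splice-site consensus windows (3 exonic + 6 intronic nt at each 5′ site;
14 intronic + 1 exonic nt at each 3′ site) are *masked* with `N` rather
than shifting region boundaries — masked positions simply contribute no
hexamer windows, and the two blocks of a capped exon are joined by five
`N`s so no window spans the junction. genePred input has no gene column;
gene assignment uses `name2` (extended genePred) when present, an
explicit `tx2gene` map, or strand-aware clustering of transcripts with
overlapping exons.

Features are presence indicators, not counts: the occupancy model is
driven by whether a site exists (occurrence counts are reported as
metadata in the results table). The same hexamer in two regions is two
features. Columns present in fewer than 1% of ASEs are dropped.

# The four-stage inference

1. **Screening.** Each column is tested by the simple regression
   $y = \beta_0 + \beta s + e$ (closed-form t-test, identical to `lm`),
   retained at $p < 0.05$. Pairs are formed only among retained columns
   and the product term is tested in the saturated two-way model; a pair
   additionally needs hypergeometric co-occurrence at $p < 0.05$ and a
   product present in at least 1% of ASEs. All screening tests are
   two-sided; the co-occurrence and overlap-enrichment tests are
   one-sided (enrichment).
2. **Lasso and adaptive Lasso.** `lassoPath()` solves
   $\min (2n)^{-1}\lVert y - \beta_0 - X\beta\rVert^2 +
   \lambda\lVert\beta\rVert_1$ by coordinate descent (glmnet) on a
   100-point log-spaced grid from the KKT bound $\lambda_{max}$ down to
   $10^{-4}\lambda_{max}$, with internal column standardization and
   coefficients reported on the original scale. The penalty is chosen by
   K-fold cross-validation on the mean squared prediction error
   (`cvSelectLambda()`; $\lambda^*$ at the strict minimum). Adaptive
   weights are $1/|\hat\beta_{lasso}|$ with exponent 1; first-stage zeros
   are excluded, and the weighted problem is solved as a plain Lasso on
   rescaled columns without re-standardization.
3. **Refitted cross-validation.** `rcvVariance()` estimates the residual
   variance by split halves: select on one half, refit by a restricted
   Lasso on the other, OLS the survivors there, swap roles, average over
   repeats. Two implementation choices matter and are deliberate. First,
   the internal penalty uses the *one-standard-error* rule: CV-minimum
   selection inside a half re-absorbs noise into the refit and biases the
   estimate downward by 10–40% in our simulations. Second, the marginal
   screen is *re-run inside the selection half*: screening performed once
   on the full data leaks every sample's noise into the candidate set, so
   even variables "selected on the other half" are informative about the
   refit half's noise; re-screening per half (at a strict level, 0.001,
   so that only variables with unambiguous half-sample signal enter)
   restores the independence the split-half argument needs and brings
   the estimate within a few percent of the realized noise variance.
4. **Final selection and FDR.** For every penalty on the adaptive path
   the selected set is OLS-refit and its residual variance recorded;
   `selectFinalLambda()` returns the model with the smallest refit
   variance still above $\hat\sigma^2_{RCV}$ — models below it are
   overfit relative to the honest noise level. When every model falls
   below, the model closest to $\hat\sigma^2_{RCV}$ (the most penalized)
   is chosen with a warning: falling back to the CV optimum in that
   situation would return precisely the model the RCV guard flagged as
   overfit. The chosen set is refit by OLS, two-sided t-tests feed
   Benjamini–Hochberg step-up at FDR 0.05 (the level is configurable),
   and $R^2 = 100(1 - RSS/TSS)$ of the FDR-passing refit is reported.

## Numerical choices and degenerate inputs

Natural logarithms throughout. Inclusion ratios are clipped to
$[\epsilon, 1-\epsilon]$, $\epsilon = 0.01$, before the logit (boundary
ratios usually reflect a low-abundance minor isoform); the reference
average includes the target tissue; ASEs quantified in fewer than two
tissues are dropped (the reference is undefined). Zero total isoform
expression drops the (ASE, tissue) pair; gene expression must exceed
3 RPKM *strictly*. Constant columns are untestable and dropped with a
reason; rank-deficient refits drop collinear columns deterministically,
first-kept in column order. Coordinate descent converges to $10^{-7}$ on
the coefficient scale; CV fold assignment is a seeded permutation, with
an n-fold fallback (and warning) when folds exceed n. The effective exon
length utility counts unique fully-contained read start positions,
$\max(l - r + 1 - m, 0)$.

# The synthetic benchmark

`benchmarkScenario()` fixes the validation conditions: 1200 ASEs, nine
tissues, ten planted SREs across the five regions and three planted
cooperative pairs, with logit-scale Gaussian noise calibrated so the true
model explains about 60% of the response variance in the target tissue —
comparable to what the model achieves on real inclusion profiles.
Sequences are i.i.d. nucleotides at configurable GC content;
`plantSequences()` inserts motifs at uniform positions of their region in
a Bernoulli-sampled carrier subset.

Design choices a user should know:

* **Unambiguous truth.** One base on each side of an insertion is masked
  and accidental background occurrences of planted motifs are scrubbed,
  so the realized feature column equals the sampled indicator exactly.
  Without the flank masking, every insertion creates shifted-variant
  windows whose columns correlate ~0.3–0.5 with the planted one; the
  Lasso splits its coefficient across the family and exact-match
  evaluation of recovery becomes ambiguous. The price is that the
  benchmark deliberately does *not* probe variant confusion — on real
  data a 7-mer SRE is expected to surface as two overlapping hexamers or
  a same-region pair (the results table flags such pairs).
* **SF activity profiles.** Each SF has occupancy weight 5 in four of the
  nine tissues and 0.1 elsewhere, so the centered effect is comparable in
  magnitude whether or not the target tissue is elevated (high in $k$ of
  $T$ tissues gives centered effects $\propto (T-k)/T$ and $-k/T$).
  Members of a cooperative pair share one profile — cooperating SFs must
  be co-expressed to act.
* **Pairs are antagonistic and built on the strongest SFs.** A product
  column is structurally collinear with its parents (here
  $\mathrm{cor} \approx 0.58$ at joint presence 0.10 and solo presence
  0.15), so a pair's *unique* signal is roughly a third of a main
  effect's at equal coefficient size. Mutually cooperative binding
  saturates the occupancy and yields weak tissue contrast; antagonistic
  coupling ($c_{pair} = 0.002$: the bound partner blocks the other SF's
  spliceosome coupling, as proposed for looping repressors) gives the
  strongest contrast. Pair members therefore carry cooperativity 5 (or
  1/5) against 3 (or 1/3) for unpaired SREs. These choices emulate the
  regime in which cooperative pairs are detectable at all; weaker pair
  configurations are silently absorbed by their parent columns under any
  L1 path.
* **Expression tables** carry one including and one excluding isoform per
  gene with totals log-uniform in [3, 300] RPKM and mild log-normal
  variation across tissues.

What passing the benchmark does and does not show: it validates the
inference machinery under the model's own assumptions (independent
binary features, additive occupancy terms, Gaussian logit noise). Real
data add positional effects, overlapping and degenerate motifs, correlated
features from sequence composition, and quantification error that is not
homoscedastic on the logit scale — recovery rates there will be lower.

## Problem sizes used in validation

The shipped checks run the benchmark at its stated conditions with
10-fold CV and 5–10 RCV repeats, the RCV calibration at $n = 200$,
$p = 500$ over 20 replicates of 12 split repeats each, and the
pure-noise null control at $n = 200$, $p = 500$ over 50–100 replicates;
these sizes keep a full validation run in the tens of minutes on one
core while leaving the acceptance margins comfortable.

# Known limitations

* Only hexamers are modeled; longer or degenerate motifs appear as
  overlapping hexamers or same-region pairs.
* At most two SFs interact per term; higher-order cooperativity is out of
  scope.
* OLS p-values after selection are optimistic; the RCV guard controls
  model size, but reported q-values should be read as ranking evidence,
  not calibrated error rates.
* The enhancer/silencer call needs the SF to be expressed strictly above
  or below all reference tissues; intermediate profiles are
  indeterminate.
* Isoform quantification is accepted as input; read alignment and
  isoform deconvolution are outside the package.
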