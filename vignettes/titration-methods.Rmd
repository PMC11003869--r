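---
title: "Models and methods behind titrADT"
author: "titrADT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind titrADT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`titrADT` turns a CITE-seq antibody titration experiment — the same cells
stained at a dilution series of antibody concentrations, with conditions
hashed by HTOs — into a per-antibody panel decision: keep at a chosen
working concentration, exclude, or recommend a fresh spike-in. This
vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the bundled synthetic data can establish.

## The synthetic binding model

`simulateTitration()` draws, for cell $i$ (relative depth $d_i$, cluster
$k$) and antibody $a$ at fold concentration $c$, a negative-binomial count
with mean

$$\mu_{ai} = d_i \left[ b_a\, c \; + \; s_a\, \mathbf{1}(k \in T_a)\,
\frac{c}{c + K_a} \right],$$

where $b_a$ is a nonspecific background rate (linear in antibody amount:
nonspecific binding scales with how much antibody is present), $s_a$ a
specific rate, $T_a$ the target clusters and $K_a$ the half-saturation
constant in fold units. Specific binding follows saturating occupancy:
dose-dependent antibodies have $K_a$ above the tested range (signal grows
across the series), saturating antibodies have $K_a$ far below it (every
tested dose sits on the plateau). Isotype controls and nonspecific
channels have $s_a = 0$ and share one background law, which is what makes
"indistinguishable from isotypes" the correct operational definition of
nonspecific staining.

Parameter defaults and why:

* `concentrations = c(0.25, 0.5, 1, 2, 4)` — the standard two-fold
  dilution series around a working concentration.
* `depth_lognormal_params = c(0, 0.3)` — per-cell relative depth is
  log-normal with $\sigma = 0.3$ (library-size CV ≈ 30%, typical for
  droplet data). This value also controls how unequal the two cells of a
  doublet are: with $\sigma = 0.3$ about 2% of doublet pairs exceed the
  2.7-fold HTO imbalance beyond which the 30% multi-hash rule cannot, even
  in principle, see them.
* `nb_dispersion = 0.4` — over-dispersion of ADT counts
  (variance $\mu + 0.4\mu^2$), in the range reported for tag counts.
* `background_rate = 0.5`, `specific_rate ∈ [50, 200]` — background one to
  two orders of magnitude below saturated specific signal, as for
  well-behaved antibodies; panels where background rivals signal would
  defeat titration entirely.
* `weak_rate_max = 1.2` with $K_a \in [1, 2]$ — derived, not free: a
  "weak" channel must stay under the default detection floor
  (`signal_min = 0.5` CLR units) at *every* tested concentration, which
  with the background model above requires
  $s\,c/(c+K) \lesssim 0.42\,(b c + 1)$, i.e. $s \lesssim 1.25$.
* `doublet_rate = 0.08`, `ambient_hto_fraction = 0.05` — typical 10x
  loading and ambient levels. Doublets sum two independently drawn cells'
  ADT and HTO profiles; the partner is forced onto a different hash, so
  every planted doublet is detectable in principle. The ambient pool is
  spread uniformly over hashes — the true ambient composition of HTO
  libraries is not identifiable from published data, so uniformity is a
  modelling convenience, not a claim.

One integer seed drives a top-level stream split deterministically per
modality (cells, ADT, HTO, QC covariates), so datasets are byte-identical
under a fixed seed and the caller's RNG state is never touched.

What the generator does **not** emulate: ambient ADT contamination,
cluster-correlated library sizes, batch effects within a titration,
RNA expression beyond three QC covariates, or the expert-curation layer
real panel design adds on top. Tests passing on synthetic data therefore
establish the *procedures* (thresholds applied exactly, estimators
unbiased, decisions reproducible), not performance on any real dataset.

## Demultiplexing and QC

HTO counts are CPTT-normalized per cell (counts per ten thousand); calls
use read fractions. The doublet rule fires first: more than 30% of
normalized reads off the top hash ⇒ doublet. Then a singlet needs more
than 40% on one hash; anything else (including zero-read cells) is
unassigned. Evaluating the doublet rule first resolves cells that satisfy
both descriptions (e.g. 45%/35%) conservatively as doublets; the
alternative reading of the multi-hash rule — second hash alone above 30% —
is available as `multi_mode = "second_hash"`. Ties on the top hash are
broken by lowest hash index and flagged. QC keeps a cell iff genes
detected > 500 AND RNA counts > 1000 AND mito% < 25, strict inequalities
exactly as printed.

## CLR and read load

ADT counts are normalized by the per-cell centered log-ratio with
pseudocount 1: $\mathrm{clr}(a,i) = \log(x_{ai}+1) - \overline{\log(x_{\cdot i}+1)}$.
Per-cell (across-antibody) centering is the CITE-seq convention and makes
rows of cells sum to zero exactly; depth effects cancel in the large-count
regime. Variational denoising is out of scope, but every downstream
function accepts an externally produced matrix in place of the built-in
CLR, so denoised values can be substituted. The read-load report flags
antibodies consuming more than 10% of total ADT reads — the sequencing-
economy rule that forces a concentration decrease regardless of signal.

## Marker ranking

Per concentration, a multiclass gradient-boosted tree classifier (xgboost,
exact greedy, single thread, seeded) predicts cluster labels from CLR
values; antibodies are scored by total gain and ranked descending, ties
broken by identifier, unused features scored 0. Hyperparameter defaults
(30 rounds, depth 3, eta 0.3) favour determinism and small-data stability.
`colsample = 0.5` makes each tree see half the features; without it the
booster is winner-take-all — a few strong markers absorb every split and
equally informative markers score zero, which destroys the rank ordering
the bottom-50% rule depends on. Class imbalance is handled by
inverse-frequency cell weights. One caveat discovered on synthetic data:
under CLR, isotype channels are not exactly information-free — a cluster
expressing many strong markers depresses every other channel's CLR, so
with small panels (tens of channels) isotypes can pick up real class
information through the compositional constraint. With realistic panel
sizes and cell numbers the effect is negligible and isotypes rank in the
bottom half throughout.

## The decision tree

For each antibody and concentration the dose-response profile records:

* **Dynamic range** $DR(a,c)$: best-cluster mean CLR minus the mean CLR of
  all isotype channels at that concentration, floored at 0. The isotype
  reference makes DR comparable across concentrations (background rises
  with dose for every channel). Note DR on the CLR scale typically rises
  then *falls* past saturation — signal is constant while background keeps
  growing — which is exactly why the flat/dose-dependent distinction uses
  rank correlation rather than end-point differences.
* **Background** $B(a,c)$: isotype-referenced mean CLR over non-best
  cluster cells — elevated $B$ at 1x is the "stains nonspecifically at
  higher concentrations" signature.
* **Specificity** $S(a,c)$: standardized two-sample Anderson-Darling
  statistic against the pooled isotype values; below 2 the staining
  pattern is statistically indistinguishable from isotype controls. The
  published workflow made this call by expert inspection of ridge plots;
  a rank-based two-sample statistic is the closest reproducible
  operationalization. Samples are capped at 4,000 values per group
  (seeded subsample) so the statistic's power — and hence the meaning of
  the threshold — does not drift with dataset size.
* **Positive fraction**: share of best-cluster cells above the isotype
  95th percentile; below `sparse_pos_min = 0.10` a SPARSE annotation is
  recorded (annotation only — the published sparse-signal judgement mixed
  statistical and literature evidence we cannot reproduce, so it never
  changes the action here).

Rules fire in order, each appending its code to the rationale: blacklist;
nonspecific + persistently bottom-ranked (excluding whitelisted markers);
weak → spike-in if whitelisted else exclude; dose-dependent → smallest
concentration retaining 75% of the maximal DR, after discarding
concentrations whose staining is isotype-like, with a one-step demotion if
the read-load flag fires there; saturating → 1x, or one step below when
$B(1\times) > \mathrm{signal\_min}/2$. Moves are restricted to the tested
grid — extrapolating beyond the tested series is not supported by the
data, so "considerably below optimal" maps to the spike-in recommendation
rather than an invented dose. A whitelisted antibody nonspecific at every
concentration yields an explicit CONFLICT exclusion, never a silent one.
The whitelist defaults to the seven canonical spike-in antibodies (CD34,
CD16, CD4, CD90, CD45, CD11b, CD127) and is fully user-overridable.
`buildPanel()` stores the profiles it decided from, and
`replayDecisions()` re-derives every action from them — a decision audit
that must reproduce exactly.

## Consistency statistics

`adKSample()` implements the rank-based k-sample Anderson-Darling
criterion with midrank tie handling and the combinatorial null variance
$\sigma_N^2$; the reported score is $T = (A^2 - (k-1))/\sigma_N$. The
statistic is invariant under common monotone transforms, its exhaustive
permutation distribution on tiny inputs centers exactly at $k-1$, and the
implementation matches an independent reference implementation to nine
decimals on fixed cases. Donor comparisons subsample each batch to 2,500
observations (2,450 for donor/technology combinations) without
replacement before testing, so scores are comparable across markers;
log10-transformed scores floor non-positive values at $10^{-2}$ and flag
them rather than dropping them. Asymptotic p-values are deliberately not
computed — the score is used as a dissimilarity, not a significance test,
and the final consistent/inconsistent cut is left to the user because the
published counts folded in expert curation. EMD uses 200 bins over the
pooled 0.1–99.9 percentile range by default (clipping outliers into edge
bins); for a translation it recovers the shift to bin resolution, and a
sorted-quantile coupling serves as the independent oracle in tests.
`rankAlign()` is a deliberately simple stand-in for heavier batch
correction: each batch is mapped through its empirical CDF onto pooled
reference quantiles, which is monotone within batch and removes
location/scale disagreement.

## Moderated t-test

For each feature the pooled two-group variance $s_g^2$ (on $d_g$ df) is
shrunk toward a prior $s_0^2$ with weight $d_0$:
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$. The prior is
estimated from the marginal distribution of $\log s_g^2$ by matching
digamma/trigamma moments, inverting the trigamma function by Newton
iteration; when the method-of-moments variance is non-positive the prior
df is infinite (complete shrinkage), and a plain moment-matching fallback
covers solver failure. $d_0 = 0$ recovers the ordinary pooled t exactly;
$d_0 = \infty$ pins every posterior variance at $s_0^2$. P-values use
$d_0 + d_g$ df and are BH-adjusted within cluster. Zero-variance,
equal-mean features yield $t = 0, p = 1$ by definition rather than an
error. The abundance filter requires, besides $q < 0.05$, at least a 10%
difference of min-max-scaled per-cluster means — scaling over the pooled
group means of the cluster, the closest reproducible reading of a
"percent of abundance scale" filter; the convention is configurable.
Cell-state frequencies are compared per sample with a plain equal-variance
Student's t-test, flagged at $P \le 0.05$, with zero-count states kept at
frequency 0.

## Pipeline and reproducibility

`runPipeline()` chains simulate → demux → QC → CLR/read-load → rank →
decide (optionally consistency and a differential demo contrast) with one
global seed overriding every stage seed. Each stage writes plain-text
outputs (MatrixMarket + TSV sidecars, TSV tables) and the manifest records
the config hash, seed, package version, per-stage row counts and output
MD5 checksums — two runs under one seed produce byte-identical manifests.
A stage failure aborts with the stage named after persisting the partial
manifest.

Problem sizes used in the shipped validation: demultiplexing accuracy is
measured on 20,000 hashed cells; QC on $10^5$ covariate rows; null
calibration of the Anderson-Darling statistic on 500 replicates of
$k = 4, n = 100$; prior recovery on 2,000 features at 50 + 50 samples with
null FDR over 200 replicates; panel recovery on a planted 132-antibody,
5 × 5,000-cell titration (100 specific, 20 nonspecific, 12 weak
whitelisted); ranking sanity on a 72-antibody panel at 1,500 cells per
concentration and 10 reseeded fits of a perfectly separating marker.

## Known limitations

* All thresholds are calibrated on synthetic data; agreement with any
  published, expert-curated panel on real data is not claimed.
* CLR compositional coupling gives nominally information-free channels a
  small amount of class information in small panels (see ranking above).
* The specificity statistic is extremely powerful at large n; any real
  difference from isotypes, however small, eventually exceeds the
  threshold. The subsample cap bounds this, but the threshold remains a
  policy choice, not an inference.
* The differential stage assumes roughly symmetric group sizes and
  within-cluster exchangeability; compositional transforms for frequency
  testing are intentionally not applied.
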