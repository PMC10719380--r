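---
title: "Models and design choices in spliceswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in spliceswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceswitch)
```

This vignette is the package's own account of its statistical machinery:
the PSI model and its assumptions, the differential-calling rule, the
composition, enrichment and switch statistics, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## The PSI model

An exon-centric splice event has two forms, inclusion and exclusion, and a
percent-spliced-in value $\psi$: the fraction of the gene's transcripts
using the inclusion form. A sequencing read informative for the event
supports one form or the other. Because the two forms expose different
numbers of informative read positions (their *effective lengths*
$L_{inc}$ and $L_{exc}$), a read drawn uniformly from informative
positions supports inclusion with probability

$$f(\psi) = \frac{\psi L_{inc}}{\psi L_{inc} + (1-\psi) L_{exc}},$$

and the observed counts are modelled as
$n_{inc} \sim \mathrm{Binomial}(n_{inc}+n_{exc},\, f(\psi))$. The model
assumes reads are independent given $\psi$, positions within a form are
exchangeable (no positional bias), and exactly two isoform forms per
event. Multi-isoform Dirichlet models and paired-end insert-length
modelling are out of scope. When effective lengths are unknown,
$L_{inc} = L_{exc} = 1$ applies no correction.

`estimate_psi()` places a uniform prior on $\psi$ — the reported quantity —
rather than on the read-class fraction $f$; the two differ whenever the
lengths differ. The posterior is computed by composite Simpson quadrature
on a uniform grid over $[0,1]$ (default 1001 nodes, forced odd). With
equal lengths the posterior is Beta($n_{inc}{+}1$, $n_{exc}{+}1$) exactly,
and the quadrature tracks that closed form to well below $10^{-6}$ in the
posterior mean, which the test suite asserts. The central 95% credible
interval is read off the trapezoid CDF of the grid posterior by linear
interpolation; it is accurate to a few times $10^{-4}$, which is ample for
an interval on a $[0,1]$ quantity estimated from tens of reads. With zero
reads the prior itself is returned (mean 0.5, interval [0.025, 0.975]).

## The Bayes factor and the calling rule

Differential splicing between conditions is scored by an exact
marginal-likelihood ratio computed on the same grid:
$m_1 = \int P(D_A|\psi)d\psi \cdot \int P(D_B|\psi)d\psi$ (independent
PSIs, uniform priors) against $m_0 = \int P(D_A|\psi)P(D_B|\psi)d\psi$
(shared PSI). This replaces the sampling-based Bayes factor that
isoform-mixture software computes for the same two-model comparison; a
deterministic quadrature is testable against closed forms and removes
Monte Carlo noise from the calling threshold. Numerical Bayes-factor
values from other implementations will differ in detail (different priors
and read models); it is the threshold behaviour — BF $\ge 20$ — that is
shared, and 20 is kept as the default. The ratio is symmetric in the
condition labels; $\Delta\Psi$ (defined throughout as condition B minus
condition A) changes sign under a swap.

`call_contrast()` implements the two-part rule: replicates are pooled
within each condition (element-wise count sums) and the pooled Bayes
factor carries the evidence weight; replicate-level information re-enters
only through direction consistency — every per-replicate $\Delta\Psi$
(posterior-mean difference, replicate $i$ of B against replicate $i$ of A)
must share the sign of the pooled $\Delta\Psi$. Choices made here, where
the procedure was open:

* **Pairing.** Replicates are paired by index (1 vs 1, 2 vs 2, ...), which
  matches a matched-culture design; mismatched replicate structures are an
  error rather than a guess.
* **Zero deltas.** A per-replicate $\Delta\Psi$ of exactly 0 fails the
  same-direction requirement (strict reading of the rule); a tolerance
  band `epsilon` is configurable and defaults to 0.
* **Testability floor.** An event with pooled depth below `min_info`
  (default 10 reads) in either condition is reported as untestable rather
  than called: with a handful of reads the Bayes factor is dominated by
  the prior and degenerate ratios can arise. Untestable events are
  excluded from the `n_tested` denominators used downstream.
* **No FDR layer.** The procedure is a hard Bayes-factor cutoff plus a
  consistency filter, not a multiple-testing-corrected frequentist
  procedure; no FDR correction is applied across events by design.

## Composition statistics

`composition_summary()` reports, per event category, tested/significant/
included/excluded counts, the direction ratio (orientation is always
explicit, because treatment summaries conventionally report
excluded/included while tumor-vs-normal summaries report the reciprocal),
and two tests:

* **Category proportion test** — is the category's significant rate
  different from the pooled rate of all remaining categories? Implemented
  as a two-sided two-proportion $z$-test with pooled variance; whether the
  comparison should be category-vs-own-total or category-vs-complement is
  ambiguous in common usage, and category-vs-complement is the implemented
  reading. Fisher's exact test substitutes whenever any cell of the 2x2
  table is below 5.
* **Inclusion imbalance test** — does the category's included/excluded
  split differ from 50:50? A 1-df $\chi^2$ test with Yates continuity
  correction for 20 or more events, the exact two-sided binomial test
  below that. The continuity correction is what keeps the two branches
  mutually consistent (within ~10% relative $p$ around the cutover);
  without it the $\chi^2$ branch overstates tail probabilities by ~20% at
  $n = 100$.

Both tests are Bonferroni-corrected with multiplier equal to the number of
categories actually tested (at most 7), capped at 1.

`psi_concordance()` is the validation regression used to compare PSI
measurements from two assays (e.g. RT-PCR against sequencing estimates):
ordinary least squares with $R^2$ the squared Pearson correlation, with a
zero-variance undefined marker.

## Enrichment and $\Delta\Psi$-distribution comparison

`hypergeometric_enrichment()` computes the exact upper-tail
hypergeometric probability of the overlap between differential genes and
a gene set. The **universe** is the genes with at least one testable event
in the contrast — the population actually eligible to be called — rather
than the whole genome; a whole-genome universe would inflate enrichment of
any set biased toward expressed, well-covered genes. Genes are
deduplicated: a gene counts once however many events it carries.

`ks_delta_psi()` compares the $\Delta\Psi$ values of substrate events
against non-substrate events with a two-sample Kolmogorov–Smirnov test,
at event granularity. The default compares $|\Delta\Psi|$ (effect
magnitude), since the magnitude question is usually the scientific one; a
`signed` mode is available because cumulative-fraction plots are sometimes
drawn on signed $\Delta\Psi$, and the mode used is recorded in every
result row. The p-value is exact when both groups have at most 25 values
and no ties (the `stats::ks.test()` rule), asymptotic otherwise.

## The switch analysis

`intersect_contrasts()` joins, by event id, the events significant in both
the treatment and the disease contrast, with disease $\Delta\Psi$ fixed in
the tumor-minus-normal orientation (the orientation is written into the
output header to prevent sign-convention bugs). The size of the shared set
is itself tested for excess over chance by reusing the hypergeometric test
at event granularity.

`classify_switch()` labels a shared event *switched toward the non-tumor
profile* when its treatment $\Delta\Psi$ sign is the negative of its
disease $\Delta\Psi$ sign, both nonzero — sign opposition only, matching a
quadrant colouring of the treatment-vs-disease $\Delta\Psi$ plane. No
requirement is imposed that the treatment restores the full non-tumor
magnitude; a stricter `restore` mode (magnitudes within a tolerance,
default 0.2) is available but off by default. Intersection is event-level,
not gene-level: a gene can host both a switched and a non-switched event.

`switch_summary()` reports the two headline percentages —
shared/treatment-significant and switched/shared — and accepts either
result tables or plain counts, so published tallies can be summarised
directly (2409/406/254 gives 16.9% and 62.6%).

## What the simulator emulates

The generator exists so that every downstream stage has known ground
truth. Its defaults are pinned to the study conditions the pipeline is
designed around:

* **Two contrasts, four conditions** (DMSO/apigenin; NBT/TNBC), three
  replicates per condition. The disease contrast in real cohorts has
  unequal patient numbers; the simulator uses matched replicates because
  the caller pairs replicates by index.
* **Differential fractions** 0.03 (treatment) and 0.0443 (disease),
  matching 2409/80501 and 3567/80501 at transcriptome scale.
* **Contrast linkage**: a treatment-differential event is also
  disease-differential with probability 0.17 (the observed shared
  fraction), far above independence; the rate for remaining events is
  adjusted to preserve the marginal disease fraction. Set
  `frac_disease_given_treatment = NULL` for independent contrasts.
* **Switch fraction** 0.63 of jointly differential events get opposed
  effect signs (254/406).
* **Effects**: $|\Delta\psi| \sim U(0.25, 0.45)$ with category-dependent
  sign bias — retained introns are predominantly excluded under treatment
  ($P(+) = 0.16$, mirroring a 327:64 exclusion excess) and predominantly
  included in tumors ($P(+) = 0.85$) — and category-dependent rate
  multipliers (RI doubled, ALE 1.5x, A3SS halved in the treatment
  contrast) reflecting which categories were preferentially affected.
* **Baseline PSI** is Beta(2,2)-shaped, rescaled away from 0 and 1 by half
  the maximum effect so every planted effect is representable; effects are
  applied symmetrically around the baseline ($\mp$ half the effect).
* **Substrates**: gene-level membership for hnRNPA2/MSI2/CELF1 at marginal
  rates 0.15/0.10/0.10, with membership odds multiplied by 4/3/3 for
  treatment-differential genes, and an extra $|\Delta\psi|$ shift of 0.1
  for hnRNPA2-substrate events only — so hypergeometric enrichment is
  recoverable for all three sets while the K–S magnitude test singles out
  hnRNPA2.
* **Coverage**: negative binomial, mean 100 reads per event and sample,
  dispersion 0.3 (variance $\mu + 0.3\mu^2$) — realistic overdispersion at
  desk-scale runtime; a Poisson option exists.

Each stage draws from its own RNG stream derived from one master seed
(`derive_seed()`), so stages are individually re-runnable and the whole
chain is byte-reproducible.

What the simulator does **not** emulate: reads as sequences (no FASTQ or
alignment), positional read models within isoforms, library-size or GC
biases, correlated events within a gene, annotation errors, and unequal
replicate numbers. Passing recovery tests therefore demonstrates that the
statistical machinery recovers structure *of the kind planted*; it does
not certify performance against real-data artefacts such as alignment
bias or annotation mismatch.

## Numerical choices and degenerate inputs

* Grid quadrature: 1001 Simpson nodes; log-likelihoods are normalised by
  their maximum before exponentiation, so extreme counts cannot overflow.
* Zero counts in both conditions: Bayes factor 1 by convention, flagged
  `uninformative`.
* Direction ratios: $x/0$ with $x>0$ reports `Inf`; $0/0$ reports `NaN`
  (undefined marker). Untestable statistics are `NA` throughout, never
  silently dropped rows.
* Ties in the K–S comparison fall back to the asymptotic p-value.
* Config hashing covers analysis parameters only (not the output
  directory), so identical configurations produce identical headers and
  therefore byte-identical outputs wherever they are written.

## Problem sizes used in the tests

The bundled checks run at desk scale, chosen so each property has adequate
statistical resolution: null calibration on 2,002 events (the called
fraction under no effect stays at or below 1%); effect recovery and
substrate enrichment on 3,920 events (~2,100 genes in the universe);
switch-fraction recovery on 6,300 events with both differential fractions
raised to 0.5 so that over 1,000 jointly called events exist, pinning the
recovered switch percentage within a few points of the planted 60%. The
transcriptome-scale tallies of real studies (tens of thousands of events)
are summarised through the same functions via their count interfaces.

## Known limitations

* Two-isoform events only; complex events must be decomposed upstream.
* The per-replicate consistency check uses posterior-mean point estimates,
  so a replicate with very low coverage can veto a call through a noisy
  sign; the `min_info` floor mitigates but does not remove this.
* The Bayes factor's absolute scale depends on the uniform-prior choice;
  thresholds tuned under other priors are not directly transferable.
* The category proportion test treats categories as independent strata;
  events of different categories within one gene are not modelled jointly.
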