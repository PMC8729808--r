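---
title: "Discovering and evaluating a complementary dual-marker methylation diagnostic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and evaluating a complementary dual-marker methylation diagnostic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmeth)
```

## The problem

A single methylation marker rarely detects every colorectal tumour: the
anchor gene *SDC2* is hypermethylated in most carcinomas, but a minority of
tumours — unevenly distributed across bowel subsites — carry an
unmethylated *SDC2* island and are missed. `dualmeth` implements the
two-stage strategy for closing that gap:

1. **Discovery.** From a probe-level beta-value matrix (Illumina 450k
   style), compute each sample's *island methylation level* — the mean
   beta over the probes of a CpG island. Select the carcinoma samples in
   which the anchor island is *hypomethylated* (level ≤ 0.2), then rank
   every other island by its *complement rate*: the percentage of those
   anchor-negative samples in which it is hypermethylated (level > 0.2).
   The top-ranked island (*TFPI2* in the motivating study) is the
   candidate complement, and a subsite-resolved rate table shows where it
   recovers missed cases.
2. **Evaluation.** A methylation-specific PCR (MSP) assay measures both
   markers plus the *ACTB* reference in clinical samples. A reaction is
   valid only if ACTB amplifies at Ct ≤ 36; a target is positive at
   Ct ≤ 38; the dual call is the OR of the two single calls. Performance
   is summarised as sensitivity/specificity at the fixed cutoffs, and as
   ROC curves over two indicators: the raw Ct (lower = more methylated
   template) and the relative methylation level
   ML = 2^−ΔΔCt^, ΔΔCt = (Ct~target~ − Ct~ACTB~)~sample~ −
   (Ct~target~ − Ct~ACTB~)~calibrator~, the calibrator being a fully
   methylated plasmid mix run on every plate.

## Threshold conventions

The beta threshold is 0.2 on both sides of the partition: a level equal
to 0.2 is *hypomethylated* (selected into the discovery subset) and
*negative* as a call; positivity requires a strictly greater level. The
two rules therefore partition samples exactly, which is unit-tested at
the boundary. On the MSP side the boundaries are inclusive where
amplification is the evidence: ACTB = 36.0 is still valid, target = 38.0
is still positive. NO_AMP (no crossing within the 45-cycle run) is a
distinct state: calls treat it as negative directly, and only the ROC
score builder maps it to Ct 45 so that scores are totally ordered. The
ML of a NO_AMP target is 0 — no detectable methylated template — rather
than a value computed from a pseudo-Ct. Invalid samples are excluded
from every performance denominator.

Rate tables round half-up, with decimals as a parameter (the published
tables print one decimal, displayed with a trailing zero). Missing
probe values are excluded from island means (a sample with every probe
missing gets a missing level, with a warning); the arrays' handling of
missing probes is not documented upstream, so exclusion-from-mean is
this package's choice.

## ROC details

AUC is rank concordance (tied scores count ½), with a 95% DeLong
confidence interval by default and a seeded 2000-resample bootstrap
behind a flag. The Youden-optimal cutoff maximises
J = sensitivity + specificity − 1 over the observed score values; at
ties in J the cutoff with the higher sensitivity wins, then the more
permissive threshold (higher Ct, lower ML). Tie-breaking is this
package's convention — with continuous scores ties are rare, but the
scan must be deterministic. How two markers reduce to one ROC score is
likewise a design choice here: the Ct score is the **minimum** target Ct
(consistent with the OR rule: a sample is dual-positive iff its min Ct
≤ 38, and the call/score consistency is property-tested), and the ML
score is the **maximum** ML.

The per-location dual-vs-single contrast is tested with Fisher's exact
test on the 2×2 detected/missed × marker-set table. Because the two
marker sets are evaluated on the *same* samples, an exact McNemar test
on the discordant pairs is reported alongside; under the OR rule one
discordant cell is structurally zero, so McNemar reduces to a binomial
tail on the dual-only detections. Fisher is the headline number for
comparability; McNemar is the paired-design supplement.

Rank tests (Mann–Whitney for group comparisons, Wilcoxon signed-rank
for paired ones) use exact small-sample p-values — including under
ties, via enumeration or a sign-flip convolution — and switch to the
tie-corrected normal approximation above 25 observations.

## What the synthetic cohorts emulate

Real cohorts for this assay are not publicly deposited, so the package
ships a generator whose defaults encode the study conditions, and all
statistical claims in the test-suite are made on these cohorts.

**Beta cohorts** (discovery): each sample draws a bowel location, then a
latent methylation state per gene, then i.i.d. probe betas from a
truncated normal on [0, 1] for the state's peak. Emission defaults are
the reported peak summaries: anchor unmethylated 0.067 (sd 0.018) and
methylated 0.492 (sd 0.178, the carcinoma-cohort dispersion); complement
unmethylated 0.161 (sd 0.078) and methylated 0.558 (sd 0.149). A
truncated normal is used rather than a Beta distribution because peaks
are reported as mean ± sd, which the truncated normal matches directly.
The anchor's methylated fraction in carcinoma is 1 − 50/391 (the
observed hypomethylated fraction); the complement is drawn
*conditionally*: given an anchor-negative carcinoma, it is methylated
with probability 0.88 — the observed tissue complement rate — which is
what creates the complementarity the screen must recover. Default
cohort sizes are 391 carcinomas and 45 normals; subsite weights reuse
the discovery subset's composition, the only subsite table the study
reports.

**Ct cohorts** (evaluation): the true ACTB Ct is drawn per group with
means 26 / 28 / 30 (sd 1.5) for carcinoma / adenoma / normal — stool
from cancer patients carries more exfoliated human cells, so *less*
cycles are needed — and the reported ACTB adds measurement noise
(sd 1). A methylated target amplifies at ACTB + ΔCt with ΔCt ~ N(6, 2)
(NO_AMP past 45 cycles); an unmethylated target is NO_AMP with
probability 0.97, matching the ~3% background positivity seen in normal
stool, else amplifies above the positivity cutoff. Anchor methylation
probabilities per subsite are the published single-detection
sensitivities (e.g. left colon 0.837, sigmoid 0.849, rectum 0.867 for
carcinoma); the complement's conditional probability among
anchor-negatives is 0.553 for carcinoma and 0.253 for adenoma — the
published recovery rates. Default sizes are 289 / 190 / 217. The
calibrator sits at ACTB 28 with ΔCt 2.

This architecture reproduces the study's stated mechanism for Ct-based
ROC outperforming ML-based ROC: the target Ct inherits the group
difference in template load (cases amplify earlier for *two* reasons),
while ΔΔCt cancels the load and inherits the ACTB measurement noise
instead. The acceptance suite verifies Ct-AUC ≥ ML-AUC in ≥ 90% of
replicates rather than asserting specific AUCs.

**What the generator does not emulate.** Probe betas are i.i.d. within
a sample given the state, so island means are *underdispersed* relative
to real arrays (no probe-level spatial correlation, no sample-level
methylation heterogeneity within a state); bisulfite-conversion error
and batch effects are absent; the fixed Ct cutoff censors a few percent
of late-amplifying methylated samples (ACTB + ΔCt > 38), so realised
sensitivities run one to a few points below the latent methylation
fractions, most visibly for adenoma. Passing tests therefore show that
the algorithms recover planted structure under the study's summary
statistics — not that the assay achieves those numbers on new clinical
material.

## Problem sizes used by the tests

The test-suite runs the discovery screen at 391 + 45 samples with the
planted complement among 50 decoy islands (50 replicates), and the MSP
evaluation at the full 289/190/217 stool design (50 replicates); oracle
equivalence is checked by exhaustive enumeration (all 2×2 tables with
N ≤ 40 for Fisher; concordant-pair counting and dense threshold grids
for 200 random ROC instances). These sizes were chosen to match the
study designs while keeping a full run in well under a minute per
property.

## Known limitations

* The screen ranks on the overall complement rate only; whether a
  per-subsite minimum should additionally be enforced is left to the
  user, who gets the per-subsite table.
* ML cutoffs reported by the ROC scan are this package's own
  Youden-optimal values; no published ML cutoffs exist to compare
  against.
* The normal-stratum complement rate computes to 2.88% from its own
  counts (6/208); the source table prints 2.89%, which no rounding of
  6/208 produces — the package reports the counts-derived value.
* Specificity denominators use valid samples only; whether published
  denominators did the same is inferred from their totals, not stated.
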