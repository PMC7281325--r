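---
title: "Methods: set-logic discovery of acquired-resistance phosphosite markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set-logic discovery of acquired-resistance phosphosite markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmark)
```

## The experimental design this package models

phosmark analyzes a SILAC phosphoproteomics time course comparing a
drug-resistant cell line against its parental, drug-sensitive line, each
measured untreated and under treatment, at three time points. Per time
point the design yields four biological contrasts, each quantified by one
heavy/light (H/L) ratio column:

* **A** — resistant vs parental, untreated (the baseline mix);
* **B** — treated resistant vs treated parental;
* **C** — treated vs untreated resistant;
* **D** — treated vs untreated parental.

The channel assignment is swapped between the two mixes: the resistant
line is heavy-labeled in the baseline mix and light-labeled in the treated
mix. Analysis must therefore resolve, per contrast, whether the heavy
channel carries the sample or the reference (`comparison_design()`), and
invert the raw H/L ratio to L/H where the light channel is the sample
(`orient_ratio()`). A correct implementation is invariant under a global
label swap; this is asserted on synthetic data where both channel
assignments of the same underlying measurements can be generated.

Oriented ratios are mapped to signed fold changes: a ratio `r >= 1`
becomes `+r` and `r < 1` becomes `-1/r`, so `+1` means "no change" and
up/down magnitudes are symmetric (`signed_fold_change()`). Only class-1
phosphosites — localization probability strictly greater than 0.75 — enter
the analysis (`filter_class1()`).

## The marker classification

A phosphosite is a resistance-marker candidate at a time point, in
direction `d` (up or down), when its four regulation calls (inclusive
threshold `|fc| >= cutoff`, default cutoff 1.5) satisfy the set rule

```
[(A) union (B)] intersect (C compatible) setminus (D in direction d)
```

operationalized in `classify_site_at_timepoint()` as:

1. A or B regulated in direction `d`, and neither regulated opposite to
   `d`. The prose conditions behind the union do not say what to do when A
   and B disagree in direction; we treat any disagreement as disqualifying
   because a direction-inconsistent "resistance" signal is not
   interpretable.
2. C unchanged, missing, or regulated in the same direction `d`. The set
   formula has no explicit term for the "same direction allowed" clause;
   we include it because a resistant line that continues to move a site
   further in the resistance direction under treatment does not contradict
   the marker interpretation, whereas an opposite C response does.
3. D not regulated in direction `d` (a shared treatment response is
   removed by the set difference). D regulated *opposite* to `d` marks
   de-novo loss of a sensitivity-relevant response; following the
   set-difference term literally we keep such sites as markers and carry
   the information as a per-time-point `de_novo` annotation rather than an
   exclusion.
4. Missing C or D calls never veto a classification: real tables retain
   marker sites despite unquantified time points, so missingness must not
   act as evidence. Missing A *and* B leave the time point
   `insufficient_data`.

The full 4^4 = 256-combination truth table of this rule is checked against
an independent enumeration written directly from the set formula, in both
the unit and the acceptance suites.

Across time points (`aggregate_over_time()`), the overlap level of a site
is the number of time points sharing the same non-none status; discordant
directions never combine. Markers are reported in two stringency tiers:
at least 2 of 3 concordant time points, and all 3 of 3 (the strict tier is
by construction nested in the relaxed one). Output ordering is
|consensus fold change| descending with the site key as tie-break, where
the consensus fold change is the mean signed A/B fold change over the
contributing time points — a reporting statistic only, chosen for
reproducible output rather than statistical optimality.

A note on cutoff monotonicity: raising the cutoff shrinks the sets of
regulated A/B calls and therefore the marker lists, but in principle it
can also *release* a site that a C or D call was vetoing at the lower
cutoff. On data where ancillary contrasts are either clearly regulated or
clearly flat relative to the swept range — as in the synthetic study
conditions — counts are non-increasing across the sweep, and the
acceptance suite asserts exactly that.

## Differential expression and the treatment-independent gene rule

The expression arm is a two-group comparison (resistant minus parental) in
each treatment arm on a log2 matrix with replicated arrays per condition.
`differential_expression()` fits a pooled-variance two-sample t statistic
per gene. This is a deliberate, documented stand-in for the moderated
statistics of dedicated microarray packages: the selection rule layered on
top, not the test itself, is the method of interest here.

With biological duplicates the plain pooled t has 2 degrees of freedom and
a two-sided p-value that cannot fall much below `1/t^2`, so
genome-scale FDR selection can never fire regardless of effect size —
precisely the problem moderated statistics solve. We therefore provide
variance shrinkage toward the median gene variance with `prior_df`
pseudo-observations,

```
s2* = (prior_df * median(s2) + df * s2) / (prior_df + df),
```

and evaluate the t statistic against `df + prior_df` degrees of freedom.
The default `prior_df = 4` behaves like a fixed-prior empirical-Bayes
moderation; `prior_df = 0` recovers the plain pooled t, whose null
p-values are exactly t-distributed — the property tests for null
uniformity and for the null false-positive fraction at `q < 0.05` run in
that mode, because the median-variance plug-in makes the shrunk statistic
only approximately calibrated.

Multiple testing uses Benjamini–Hochberg step-up (`bh_adjust()`, a
validated front-end to `stats::p.adjust`, property-tested against a
brute-force implementation of the step-up definition). A gene is selected
as *treatment-independent* (`select_resistance_genes()`) when it is
significant in **both** contrasts with the **same sign**, under strict
thresholds `q < 0.05` and linear fold change `> 2`. Strictness follows the
printed inequalities; "treatment-independent differential regulation" has
no formal published definition, and significant-same-direction-in-both-
contrasts is the operationalization used throughout this package.

Probe-level input is supported through `collapse_probes()` (per-gene
arithmetic mean of probe log2 values).

## Integration and enrichment

`build_network()` merges marker sites and selected genes into one
undirected graph keyed by gene symbol: phosphoprotein nodes carry the
per-time-point signed fold-change vector of contrast A with explicit gaps
for missing time points, mRNA nodes carry the mean signed fold change of
the two contrasts, and symbols present in both layers become `both` nodes.
Protein–protein edges come from a user-supplied file rather than a live
interaction database, for reproducibility without network access; edges
naming unknown symbols are dropped with a warning, and isolated nodes are
kept because unconnected markers are still results. Kinases are flagged
from a user-supplied list. GraphML and Cytoscape-JSON exports round-trip
all attributes (missing values serialize as absent/null and return as
`NA`).

`hypergeometric_enrichment()` tests over-representation of the selected
symbols in each gene set with the upper-tail hypergeometric probability
`P(X >= k)` and BH adjustment across terms. The default universe is the
set of measured symbols, not the whole proteome: with synthetic data the
measured universe is the only defensible reference, and for real data a
whole-proteome universe can be passed explicitly as the `universe`
argument. Terms with no member in the universe are skipped rather than
reported at `p = 1`.

## The synthetic-data generator

`generate_silac_dataset()` and `generate_expression_dataset()` define the
study conditions under which the pipeline's guarantees are tested:

| parameter | default | meaning |
|---|---|---|
| `effect_size` | 3.0 | planted |fold change| on the ratio scale |
| `noise_sd` | 0.05 | sd of log10 multiplicative ratio noise |
| `class1_fraction` | 0.74 | expected share of class-1 sites |
| `missing_rate` | 0.10 | per site-per-experiment missingness (MCAR) |
| `n_replicates_expr` | 2 | arrays per condition (biological duplicates) |
| `expr_noise_sd` | 0.2 | gaussian log2 noise on expression values |

Site categories are planted as resistance up/down (A and B shifted, C and
D flat), treatment-response-only (C and D shifted, A and B flat — these
must never appear as markers), de-novo reversal (a resistance shift plus
an opposite D response), and null. Ratio noise is multiplicative
log-normal because SILAC ratio error acts on the ratio scale;
missingness is completely at random because no mechanism is published for
the missing time points seen in real marker tables. Planted effects are
constant across time points by default; `fraction_two_timepoints`
restricts a share of planted sites to two of the three time points to
exercise the 2-of-3 versus 3-of-3 tiers. A single master seed drives
independent sub-streams for the site tables, the gene assignment and the
expression matrix, so enlarging the gene universe does not perturb site
measurements. Two named exemplars with synthetic symbols are planted by
default: a `YAP1L` Ser-109 dephosphorylation marker and a `TEAD2L` gene
with a 2.24-fold treatment-independent increase.

Recovery is scored by `truth_evaluation()` over the analysis universe,
i.e. the class-1 sites: sites the generator assigns a localization
probability at or below 0.75 are invisible to any downstream method by
construction. A classified site is predicted `de_novo_reversal` only when
its de-novo annotation is itself consistent across at least `min_overlap`
contributing time points, mirroring the overlap logic, so a single noisy
D call cannot relabel a planted resistance marker.

What the generator does **not** emulate: peptide-level evidence and
multiplicity structure shared across sites, intensity-dependent
(non-MCAR) missingness, correlated noise between experiments of one mix,
batch effects, and array probe-level artifacts. Perfect recovery on this
generator therefore demonstrates the correctness of the orientation,
transform, thresholding and set logic — not that real marker lists are
error-free.

## Problem sizes and numerical choices

The validation suite runs the end-to-end recovery check on 5,000 sites x
3 time points at `noise_sd = 0.05` with complete data (the recovery
guarantee is stated for complete quantifications; missingness behavior is
exercised separately), label-swap invariance on 2,000 sites with default
missingness, a cutoff sweep 1.2–2.0 on 3,000 sites, Benjamini–Hochberg
agreement with brute force on 1,000 random vectors, a 5,000-gene null
simulation, and exhaustive hypergeometric enumeration for every universe
size up to 30. Regulation boundaries are inclusive (`|fc| >= cutoff`),
the class-1 boundary is strict (`> 0.75`), and a ratio of exactly 1 maps
to `+1` (the sign of "no change" is arbitrary and never consulted
downstream). Generated TSVs round ratios to six decimals; all assertions
on regenerated data use tolerances wide enough for that rounding and no
wider.

## Limitations

* The set-logic classification is a thresholding rule, not an inferential
  procedure: it reports no error rates on the phospho side.
* The DE stand-in with fixed `prior_df` does not estimate the prior from
  the data; analyses requiring calibrated moderated inference should use a
  dedicated package and feed the resulting gene sets into the integration
  stage.
* Phosphosite multiplicity variants are treated as distinct sites
  throughout; no site-to-peptide collapsing rule is applied, so
  peptide-level counts are out of scope.
* Enrichment treats gene sets as fixed and independent; no term-redundancy
  reduction is performed.
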