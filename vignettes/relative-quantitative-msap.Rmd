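---
title: "Relative quantitative MSAP: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative quantitative MSAP: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapquant)
```

## The measurement and the model

MSAP profiles a genome with two isoschizomers cutting CCGG: *Hpa*II
cuts when the site is unmethylated or hemimethylated at the external
(5'-most) cytosine; *Msp*I cuts when the site is unmethylated or
methylated at the internal cytosines. A fragment scored in the
EcoRI/*Hpa*II and EcoRI/*Msp*I digests of a control sample and its
stressed counterpart gives a four-bit presence code per marker, in the
fixed order (control-HpaII, control-MspI, stressed-HpaII,
stressed-MspI).

The model admits six methylation states of the four site cytosines —
`U`, `HE`, `FE`, `HI`, `FI`, `FM` (see `msap_states()`). Mixed
external/internal partial patterns are excluded because they have not
been described for this site; hemimethylated states do not record which
strand carries the mark. These choices are encoded in a single constant
so that new enzyme-behaviour evidence can extend the state space
deliberately.

A code constrains the control site to the states consistent with its
first two bits and the stressed site to those consistent with its last
two (`consistent_states()`). Every consistent pair is one
*explanation*; comparing the two states position by position yields
exactly four events — DM, DNM, MSP or NMSP — with external positions
scored as CHG context and internal positions as CG
(`transition_events()`). Treating all explanations of a code as equally
probable, the code's weight vector is the **raw sum** of events over
its explanations (`code_weights()`, `msap_weights()`). Summation, not
averaging, is deliberate: the per-sample denominator
DM + DNM + MSP + NMSP then equals 4 × explanations × markers, and this
convention is what reproduces the published event tables for the
packaged triticale data exactly. Dividing each event total by the
denominator gives the relative characteristics (DM%, DNM%, MSP%,
NMSP%, M%, NM%, and the CG/CHG splits), which satisfy
NMSP% + MSP% + DM% + DNM% = 100 and M% + NM% = 100 identically.

### What the estimates mean — and their intrinsic baseline

Because ambiguous codes (such as `0101` or `0000`) include explanations
that contain change events, a sample can show DM% > 0 and DNM% > 0 even
when nothing changed. The characteristics are therefore *relative*
measures for comparing samples scored the same way, not absolute rates;
the equal-probability assumption underlying the weights is itself a
modelling assumption that external validation (e.g. bisulfite data)
could replace with empirical probabilities. The package documents this
baseline rather than hiding it: see the baseline-bias tests and
`recovery_report()`.

## Tunable parameters

* `include_absent` (`msap()`, `event_totals()`; default `TRUE`):
  whether markers scored `0000` (absent in all four digests) enter the
  quantification. Such markers are only identifiable with replicated
  stressed samples, but the model assigns them weights; both
  conventions are supported.
* Rounding (`format_characteristics()`, default 2 decimals, half away
  from zero): report formatting only. Group means and SDs
  (`group_summary()`: n−1 SD), distances and ANOVA always use
  unrounded values; averaging pre-rounded percentages does not
  reproduce correct group statistics.
* Clustering (`msap_cluster()`): squared Euclidean distance, Ward
  linkage via the Lance–Williams update (`stats::hclust`,
  `method = "ward.D"` on squared distances). Merge heights are the raw
  Ward criterion increments (no height scale is implied by the method
  itself). Automatic truncation cuts at the largest gap between
  successive merge heights; `k` can be forced. Ties in the minimal
  linkage distance are resolved deterministically by `hclust`'s
  ordering, so repeated runs are identical.
* ANOVA (`msap_anova()`): plain one-way fixed-effects decomposition
  per characteristic with variance explained = SS_between / SS_total.
  A stepwise "best model" selection over characteristics is *not*
  implemented: such a procedure is under-specified without its
  candidate set and selection rule, so published F statistics from one
  are not comparable and are deliberately not reproduced.

## The simulator

`simulate_msap()` emulates the data-generating situation the method is
designed for. Per marker and sample, a control state is drawn from
`state_probs`; stress flips each cytosine independently (methylated
positions demethylate with the context's `p_dm_*`, unmethylated gain
methylation with `p_dnm_*`); proposals that leave the six admissible
states are redrawn (rejection sampling), with the rejection rate
reported. Defaults: `n_markers = 440` and `n_samples = 10` match the
scale of a typical inbred-line experiment (~440 scoreable markers per
line); `state_probs` is uniform over the six states because no
empirical control-state frequencies are established for plant tissue —
it is a neutral, fully exposed choice; change rates
(`p_dm_cg = 0.05`, `p_dm_chg = 0.015`, `p_dnm_cg = 0.04`,
`p_dnm_chg = 0.005`) are of the order of the context percentages
observed in cereal stress studies, with CG > CHG and DM > DNM.

Two caveats define what simulation-based tests do and do not show.
First, rejection sampling conditions on admissibility, so realised
event rates are lower than the nominal flip probabilities (single-site
changes from some states, e.g. demethylating one internal cytosine of
`FM`, are inadmissible unless accompanied by other changes); recovery
is therefore asserted as *monotone association* between simulated rate
and estimated percentage, not unbiasedness — which is also the honest
claim given the model's equal-probability baseline. Second, the
simulator draws markers independently per sample and ignores AFLP
primer sampling, fragment-length effects, co-migration and scoring
error, so passing tests demonstrate internal consistency of the
model and pipeline, not robustness to gel artefacts.

Degenerate settings are handled explicitly: configurations whose every
outcome is inadmissible (e.g. `HE` with both `p_dm_chg = 1` and
`p_dnm_chg = 1`) error after a bounded number of redraw rounds instead
of looping; zero-change configurations return bit-identical control
and stressed tracks.

## Numerical and degenerate-input choices

* Explanations are listed in the canonical state order U, HE, FE, HI,
  FI, FM (control varying slowest), making enumeration and
  serialisation reproducible.
* A sample with no scoreable markers has denominator 0: totals warn,
  characteristics error ("no scoreable markers") rather than emitting
  NaN.
* Markers with a missing call in any of the four tracks are excluded
  sample-wise by `extract_codes()`, with the dropped count messaged
  and attached to the result; missing calls are never imputed.
* Matrix cells outside {0, 1, NA} and malformed code strings are parse
  errors naming the offending cell; duplicate marker/sample
  identifiers are rejected.
* Singleton groups receive a mean but an undefined (NA) standard
  deviation.

## Problem sizes used in the checks

The packaged triticale experiment (ten lines, ~438 markers each) is the
reference computation; it runs in well under a second. Simulation-based
checks use 5000 markers × 5 seeds × 3 rate settings for the
monotone-recovery claim and 2000 markers for quick property checks —
sizes at which the Monte-Carlo spread of the context percentages is a
small fraction of the effect being asserted, chosen once as adequate
for those claims.

## Known limitations

* The equal-probability weighting is an assumption, not an estimate;
  with genome-scale bisulfite data one could replace it by empirical
  state-transition probabilities (species-specific), which the
  single-constant design anticipates.
* Band intensities, partial digestion, co-migrating fragments and
  sequence mutations within the restriction site are outside the
  model; the method treats scored 0/1 calls as truth.
* The characteristics are aggregate (per sample), not locus-wise
  methylation calls.
* CHH-context methylation is invisible to this site model; only CG
  (internal) and CHG (external) positions of CCGG are scored.
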