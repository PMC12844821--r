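---
title: "Deriving generic foods from branded food composition data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving generic foods from branded food composition data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodagg)
library(dplyr)
```

## The problem

Branded food composition databases (BFCDs) hold label-declared nutrition for
individual packaged products — thousands of rows like *"sourdough wheat bread
loaf sliced"* or *"cow milk strained yogurt 2% fat with strawberry jam"*.
Nutritional epidemiology, national food composition tables and mHealth diet
trackers instead work with **generic foods**: aggregate items such as
*"Bread, wheat, white, sliced"* whose nutrient values are means over similar
branded products. foodagg implements a three-step framework for deriving such
generic foods, with a statistical guard that the aggregates it emits are
compositionally homogeneous enough to stand in for their members.

## The three steps

**Step 0 — quality control.** Label declarations contain errors. Before any
aggregation, each record passes a plausibility screen:

1. *Energy reconciliation.* Energy is reconstructed from the declared
   macronutrients with Atwater-type factors — protein and carbohydrate
   4 kcal/g, fat 9 kcal/g, fiber 2 kcal/g, polyols 2.4 kcal/g — and compared
   with the on-pack declaration. A relative difference strictly above 20%
   (relative to the declared value, the label quantity being audited)
   excludes the record.
2. *Ratio checks.* Saturated fat cannot exceed total fat, nor total sugars
   carbohydrate: SFA:TF or TS:CHO strictly above 1 excludes.
3. *Range checks.* Declarations outside physically possible ranges
   (a gram nutrient above 100 g/100 g, sodium above 40,000 mg/100 g, energy
   above 900 kcal/100 g — the energy density of pure fat) are improbable.

Checks whose inputs are unavailable are skipped, never failed; boundary cases
(difference exactly 20%, ratio exactly 1) are kept, since the rules are
strict inequalities. Nothing is ever corrected or imputed — exclusion only.
Carbohydrate is assumed to include polyols (the EU labeling convention), so
polyols are subtracted before the 4 kcal/g term and re-added at 2.4 kcal/g;
`qc_config(polyols_within_carbohydrate = FALSE)` toggles this for databases
following the US convention.

**Step 1 — name-based grouping.** Within each subgroup of the 4-level
LanguaL-style category hierarchy, product long names are parsed against a
per-category *descriptor vocabulary*: ordered dimensions (animal of origin,
processing, fat content, flavor, ...) each carrying ordered descriptor values
with regular-expression patterns. Matching runs on normalized text
(lower-cased, accent-folded — Greek and Latin diacritics removed —
punctuation collapsed); the first matching value in vocabulary order wins and
longer patterns are tried first within a value, so `"semi-skimmed"` resolves
to *2% fat* before the substring `"skimmed"` can claim *0% fat*. Records
partition by (category path, declaration basis, descriptor assignment);
the declaration basis (per 100 g vs per 100 mL) is part of the key because
mixing the two would average incommensurable quantities. Products whose
names indicate multipacks of different foods are set aside first — no single
generic food can represent them. The original protocol resolved ambiguous
names by discussion between researchers; this implementation replaces that
with a deterministic rule engine plus a conflict log listing every record
where several values of one dimension matched, the machine analogue of the
researchers' disagreement list.

**Steps 2–3 — homogeneity testing and refinement.** For each candidate
group, the mean, sample SD and coefficient of variation (CV = SD/mean) are
computed for energy, protein, total fat, SFA, carbohydrate, total sugars and
sodium over the group's *complete* members (those declaring all seven). A CV
strictly above 20% in any of them marks the group heterogeneous — a threshold
borrowed from inter-assay variability practice in analytical settings, and
admittedly arbitrary. Heterogeneous groups are then examined against
*secondary* descriptors mined from ingredient lists and on-pack claims
(sweetener type, fortification, consumption with or without the liquid
matrix). A candidate split is **accepted** when

* every subgroup keeps at least 2 members, and
* the member-weighted mean of the subgroups' worst (largest) CV is strictly
  below the parent's worst CV.

Among accepted candidates the largest improvement is applied (ties broken by
vocabulary order), and heterogeneous subgroups are refined recursively with
the remaining dimensions. When no candidate is accepted, the heterogeneity is
**inherent**: the group is kept intact and flagged. The acceptance rule is
the package's own operationalization — the framework's description asks for
descriptors that "reduce heterogeneity" without quantifying the reduction —
and was chosen conservatively: a split must help on the *worst* nutrient, not
merely on average, and may never strand singletons.

## Grades, emission rules and degenerate cases

CVs are graded into half-open bands `[0, 20%)`, `[20%, 40%)`, `[40%, ∞)`.
The left-closed choice keeps the grade bands consistent with the strict
`> 20%` heterogeneity trigger. Conventions for degenerate inputs:

* SD = 0 with mean 0 (every member declares zero): CV = 0, homogeneous —
  identical values are the definition of homogeneity.
* Mean 0 with SD > 0 cannot occur for nonnegative nutrients but is graded
  `undefined` for safety; fewer than two complete members also leaves the CV
  `undefined`. Undefined counts as heterogeneous wherever a decision is
  forced.
* Aggregated values are **emitted only for groups with ≥ 3 complete
  members**; two-product groups are grouped and counted in the yield table
  but carry no values forward — with n = 2 most derived values would be
  statistically meaningless.
* Refinement is likewise only attempted on groups with ≥ 3 complete members:
  below that the CV is undefined and "heterogeneity" would be an artifact of
  sample size, not of composition.
* Sodium is included in the trigger set (it is computed and graded throughout
  the framework's result surfaces); fiber and polyols are excluded — they
  feed the energy reconstruction and are reported as means, but labels
  declare them too sparsely to grade. Both choices are configurable
  (`agg_config(trigger_nutrients = ...)`).

## What the synthetic generator emulates

No real BFCD ships with this package, so `generate_db()` fabricates one with
planted, machine-checkable ground truth: category templates (yogurts, milks,
butters, margarines, breads, biscuits, canned and frozen vegetables) with
typical label means; descriptor-driven effects (fat-content values move total
fat, flavors move carbohydrate); within-group nutrient draws from a normal
truncated at zero **and at ±3.5 within-group SD** — label values do not stray
arbitrarily far from a product type's norm, and clean records must never trip
the improbable-value screen by construction; declared energy equal to the
Atwater-type reconstruction times multiplicative noise U(−0.12, 0.12),
comfortably inside the 20% tolerance even after rounding to whole kcal;
and planted structure on top:

* *QC violations* at configurable rates (defaults follow the published audit
  of a national BFCD: 747/4738 energy, 2/4738 SFA:TF, 1/4738 TS:CHO).
  Energy violations deflate the declaration by 30–45% so they can never
  double as improbable values; ratio violations multiply SFA or sugars past
  the denominator on records where the result stays in range. Each planted
  record carries exactly one violation, so truth-table comparisons are exact.
* *Latent splits*: a fraction of groups receives a binary secondary
  descriptor carried only in the ingredient text (e.g. `"sweeteners
  (stevia)"` vs `"sugar"`), shifting one nutrient's mean down by 3
  within-group SDs in the affected arm. Three SDs reflects the kind of
  formulation difference the framework targets (sugar-sweetened vs
  non-nutritively sweetened variants of one food); it makes the parent group
  reliably heterogeneous, which a 2-SD shift — mixture CV ≈ 19% at the
  default within-group CVs — would not.
* *Multipacks* ("... and crackers combo pack") at the published share
  (1332/3988), and optional hand-crafted boundary records sitting exactly on
  the QC cut-offs.
* SFA and total sugars are drawn as fractions of total fat and carbohydrate
  (fraction noise sized so the product reaches the configured CV target), so
  clean records can never violate the ratio rules, even after rounding —
  rounding is monotone, and the fractions are capped at 0.95.

Group sizes default to a distribution matching the published yield table
(53% single-product names, 16% two-product, 31% three-plus; mean ≈ 3).
Within-group CV targets (10–18% by nutrient) and per-nutrient missingness
(2–5% for the graded nutrients, 50% fiber, 95% polyols) are not published
and were chosen once as typical of label-declared data.

**What passing tests do and do not show.** The generator's names are built
from the same token inventory the vocabulary matches, so name parsing is
exact by construction; real product names are messier (abbreviations,
marketing copy, spelling variation), and the descriptor-recovery rates seen
here are an upper bound. Likewise the generator plants at most one latent
binary descriptor per group; real heterogeneity can be multi-causal,
continuous (reformulation over time), or reporting-driven (drained vs
as-sold values), which no vocabulary dimension may capture — exactly the
case the inherent-heterogeneity flag exists for.

## Numerical and design notes

* Sample SD (n−1 denominator): the standard inferential estimator for the
  small groups this framework deals in.
* Matching is deterministic: vocabulary order breaks value ties within a
  dimension (conflicts logged), vocabulary order breaks improvement ties
  between candidate dimensions, and group tables are sorted with a
  locale-independent comparator, so outputs are byte-identical across runs
  and platforms.
* Members a secondary dimension fails to match form their own bucket with
  value NA; the NA is recorded in the child's descriptor assignment (so
  assignments strictly grow along the refinement tree) but omitted from the
  generic name — the unmatched child keeps the parent's name, its matched
  siblings append their value.
* The refinement engine evaluates one dimension at a time, recursively. In
  principle a joint split on two dimensions could be acceptable when neither
  single split is; on groups small enough to check exhaustively (≤ 6 members,
  ≤ 2 secondary dimensions) the test suite verifies the greedy engine's
  inherent-heterogeneity calls against full subset enumeration.
* Problem sizes in the test suite and acceptance script (a few hundred
  planted groups, databases of ~700–2,200 records, one 500-member group for
  CV-target convergence) were chosen as the smallest sizes at which the
  statistical properties under test are stable.

## Limitations

* The vocabulary carries the language: there is no translation or stemming
  layer, and no embedding-based name similarity. A deployment writes its own
  YAML vocabulary per category, in its database's language(s).
* Salt vs sodium is standardized upstream: the package expects sodium in mg.
* kJ-only labels are out of scope; energy is kcal throughout.
* Statistically driven descriptor discovery (splitting on a latent mode
  without any on-pack token) is deliberately not attempted; the framework
  only formalizes evidence that is on the package.
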