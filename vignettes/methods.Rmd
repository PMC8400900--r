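---
title: "Methods: nutrient profile models, the exclusion cascade, and the synthetic market"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopwarn)
```

## The two models

A nutrient profile model is treated throughout as *data*: a table of rules
`(scope_key, nutrient, limit, comparator, gate, label)` plus two attributes
(scope type, NNS rule). The engine knows nothing about any particular model.

**SEARO.** Category-scoped: each of the 25 food categories carries its own
limits; beverages (codes 6A–6E) are evaluated per 100 ml, foods per 100 g,
always on the as-consumed basis. Rules are ungated. Additionally, a product
with an added non-nutritive sweetener meets the model's criteria regardless
of its panel (`nns_rule`). The shipped limits in
`inst/extdata/searo_thresholds.csv` are a **reconstruction** from the public
WHO regional NPM family: the authoritative per-category appendix is not
redistributable here, so the file documents itself as editable data and any
verbatim transcription can be dropped in without touching code. No test and
no acceptance quantity depends on a specific reconstructed limit: engine
correctness is established against an independent oracle on random panels,
and report arithmetic against published counts.

**CWO Phase 3.** Form-scoped: one rule set for all foods (per 100 g: sugars
10 g, saturated fat 4 g, sodium 400 mg, energy 275 kcal) and one for all
beverages (per 100 ml: 5 g / 3 g / 100 mg / 70 kcal), statutory 2019 values.
Every rule is gated on an added-ingredient flag; the calorie rule applies to
products with added sugar *or* added saturated fat, encoded as two rows
sharing the `energy` label. A label is earned at most once per product no
matter how many rules feed it, because published 0/1/2/3+ distributions
count warning labels, not rules.

### Boundary and gating conventions

* **Comparator.** The default is `greater_than` (strictly exceeds). The
  boundary convention is never defined in the policy literature with
  consistency, so it is table data, not engine code; `at_least` is accepted
  per rule.
* **Unknown gates.** An unknown added-ingredient flag closes a CWO gate by
  default (`gate_unknown = "skip"`). This matches the observed direction of
  the SEARO–CWO coverage gap: gating can only remove labels. A strict mode
  (`"evaluate"`) treats unknown as open for sensitivity analysis.
* **NNS counting.** Whether an NNS trigger contributes a warning label of
  its own or only forces "meets any criteria" is not resolved by published
  label-count tables. Default: it counts as one label (`nns_counts =
  "label"`), which keeps `meets_any ⇔ label_count ≥ 1`; the `"meets_any"`
  mode is available and `nns_triggered` is always reported separately.

## The exclusion cascade

Stages run in a fixed order and the first matching rule wins, so the ledger
partitions the input exactly — every record is either analyzable or counted
once in one bucket (`ledger_check()` enforces the identities):

1. duplicate barcodes (first occurrence in file order is kept; the source
   schema has no timestamps, so this is the deterministic choice);
2. missing information / nutrient errors (malformed numeric cells, negative
   amounts, saturated fat above total fat, added sugar above total sugar);
3. no category assignment; 4. variety packs; 5. baby food;
6. insufficient nutrients: a product is evaluable only if **every** nutrient
   referenced by any rule applicable to it, across **all** requested models,
   is present. Absent is never imputed as zero — in markets without
   mandatory nutrient declaration, absence is informative and imputation
   would silently inflate coverage;
7. missing preparation instructions: products labelled as sold that require
   reconstitution but carry no dilution factor. Sufficiency is checked
   before reconstitutability; a product failing both is counted under
   missing nutrients. The published flow counts are consistent with this
   order, which also keeps the ledger identity
   `assigned − (missing_nutrients + no_preparation) = analyzable`.

Reconstitution divides every amount by the dilution factor (water adds no
nutrients) and flips the basis; beverages move to the per-100 ml reference.
Units are normalised at read time — sodium mg (salt g × 1000 / 2.5), energy
kcal (kJ / 4.184) — so no downstream code ever converts twice.

## Reporting and rounding

Percentages are `100 × n / N` formatted under an explicit policy. The
default is round-half-up (R's `round()` is half-even, which survey tables do
not use). Several published cells in this literature are reproducible only
by truncation (e.g. 6,623/10,501 = 63.07 printed as 63.0, and 80/228 = 35.09
printed as 35.0), so `"truncate"` is available, and tests pin only cells
where the two policies agree. Empty denominators render `-`, never `0` or
`NaN`. One known prose-versus-table inconsistency is deliberately left
visible: recomputing the printed per-category coverage puts the largest
SEARO–CWO gap at processed nuts (94.9 − 52.1 = 42.8), not dairy beverages
(74.1 − 35.1 = 39.0); `compare_models()` reports the arithmetic.

## The synthetic market

`generate_products()` emulates the *structure* of a commercial new-product
extract, not any real joint nutrient distribution. What it states:

* **Category mix** proportional to the published per-category totals
  (31,519 assigned products); configurable.
* **Panels**: log-normal amounts (non-negative, right-skewed — the standard
  shape for composition data), location centred on each category's own
  limits, `sdlog = 0.8`, truncated at plausibility caps (100 g/100 g sugars
  and fats, 5 g/100 g sodium, 900 kcal). Saturated fat is a uniform fraction
  (0.2–0.9) of total fat and added sugar a sub-fraction of total sugar, so
  panel invariants hold by construction.
* **Ingredient flags** follow a logistic link in the amount relative to the
  category limit (`plogis(-1.5 + 2·rel)`), so gating and amounts are
  correlated as in real formulations — without this, the SEARO/CWO
  divergence tests would be vacuous. 15% of flags are `unknown`. NNS flags
  are rare (2% foods, 4% beverages), keeping the NNS floor below the lowest
  published category coverage (9%).
* **Exclusions** planted at the published rates: duplicates 6,113/41,255,
  label errors 1,339/35,142, no category 1,921/35,142, variety packs
  204/35,142, baby food 159/35,142.
* **Missingness**: one per-nutrient absence probability, solved at
  config-build time (`uniroot`) so the expected analyzable fraction of
  assigned products equals 10,501/31,519, given each category's required
  nutrient count and the preparation-instruction loss. Missingness is
  uniform across categories — real attrition is not (instant coffee reports
  more completely than composite foods), which is why an end-to-end total
  coverage on the *total* category mix lands near 72% while the published
  68.4% refers to the *evaluable* mix; analyses that target the published
  total use evaluable-mix weights.
* **Preparation**: any product is as-sold with probability 0.20 and then
  lacks instructions with probability 0.55, matching the published
  no-instruction loss (1,296 of 11,797 nutrient-sufficient products ≈ 11%).
  As-sold panels are the as-consumed panel scaled up by the dilution factor
  (4–12), so reconstitution recovers them exactly.

**Calibration.** `calibrate_to_table1()` adjusts one log-location shift per
category by monotone bisection so that the expected fraction meeting ≥1
SEARO criterion matches a target (default: the published per-category
coverage). Coverage is estimated on `m = 4000` panels with common random
numbers across the scan — a shift acts multiplicatively on amounts, so the
objective is deterministic and monotone in the shift and bisection
converges cleanly. Targets of 0 or 100 are unreachable with positive
log-normal scale and switch the category to degenerate modes: `"zero"`
(all amounts uniformly below half of every limit, flags off) and `"high"`
(all amounts 20%+ above some limit).

**Bias mode.** `biased_subsample()` samples without replacement with weights
`(1 + label_count)^w`. `w = 0` is simple random sampling (unbiased coverage
estimates); large `w` reproduces the industry-sample phenomenon where a
1,306-product selection drawn preferentially from multi-label products
reports ≥90% coverage out of a ~68% population.

### What a green test does and does not establish

Green engine tests establish that both rule engines implement their table
semantics exactly (oracle equivalence on 10,000 random panels, monotonicity,
gating dominance). Green cascade tests establish ledger conservation and
reproduction of the published flow arithmetic from planted counts. Green
calibration tests establish that the generator can be steered to stated
coverage targets. None of this establishes that the reconstructed SEARO
limits equal the authoritative ones, nor that real Indian nutrient panels
are log-normal with these parameters — those claims would need the original
appendix and raw data.

## Numerical choices

* Bisection: interval [−8, 8] on the shift, ~14 iterations to width 10⁻³.
* `uniroot` for missingness on (10⁻⁶, 1−10⁻⁶).
* Percent formatting: `floor(x·10^d + 0.5)/10^d` (half-up) or
  `trunc`-based truncation; comparisons in tests use exact equality on the
  formatted value.
* All randomness flows from one integer seed; RNG state is saved and
  restored around every seeded operation, so library calls never perturb a
  caller's stream.

## Known limitations

* The SEARO threshold file is a reconstruction (see above).
* Missingness and ingredient-flag models are independent across nutrients
  given the panel; real label completeness is category- and
  manufacturer-structured.
* Free-text preparation instructions are out of scope; the dilution factor
  is a numeric input field.
* Only the Phase 3 CWO is shipped; earlier phases and other NPMs
  (traffic-light, Nutri-Score, Health Star) would be new table files, not
  new code, but none is provided.
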