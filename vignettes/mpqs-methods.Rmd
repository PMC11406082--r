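---
title: "MPQS: model, parameters, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MPQS: model, parameters, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpqs)
```

# The model

The Meal Protein Quality Score (MPQS) rates one meal for one person. It asks:
of the ten essential amino acid (EAA) entities, which fraction of its
personalized per-meal requirement does the *worst-covered* one reach?

## Entities

The score is computed over ten entities, always in this canonical order:
histidine (HIS), isoleucine (ILE), leucine (LEU), lysine (LYS), methionine
(MET), cysteine (CYS), phenylalanine+tyrosine combined (PHE_TYR), threonine
(THR), tryptophan (TRP), valine (VAL). Phenylalanine and tyrosine are pooled
because tyrosine spares phenylalanine; composition inputs may supply them as
a single `phe_tyr` column. Cysteine is kept as its own entity (rather than
pooled with methionine) so that the methionine-to-cysteine top-up below can
be unidirectional.

## Intake

For each EAA $a$, the meal's digestibility-adjusted intake in mg is

$$
I_a \;=\; \sum_{\text{portions } f} \text{mass}_f \;\cdot\;
  \frac{\text{protein}_f}{100} \;\cdot\; \text{aa}_{f,a} \;\cdot\; d_f,
$$

with `mass_g` in grams, `protein_g_per_100g` from the food table,
`aa` values in mg per g protein, and $d_f$ the food's true ileal
digestibility expressed as a fraction (stored as `digestibility_pct` in
tables and converted on load). Digestibility is applied per food, before
summation, because foods in one meal digest differently; summation is done
at full floating-point precision.

## Requirement

The per-meal requirement for EAA $a$ is

$$
R_a = W \cdot t \cdot p_a,
$$

where $W$ is body weight in kg, $t$ is the per-meal protein target in g/kg,
and $p_a$ is the adult scoring pattern in mg per g protein.

| Parameter | Default | Units | Rationale |
| --- | --- | --- | --- |
| $t$ (`protein_target_g_per_kg`) | 0.3 | g protein / kg / meal | the per-meal dose shown to maximally stimulate muscle protein synthesis in adults, including older adults |
| $p$ (`reference_pattern()`) | HIS 15, ILE 30, LEU 59, LYS 45, MET 16, CYS 6, PHE_TYR 38, THR 23, TRP 6, VAL 39 | mg / g protein | the adult EAA scoring pattern used for protein-quality evaluation |
| daily target (`protein_target_g_per_kg_per_day`) | 1.2 | g / kg / day | a common higher-protein daily recommendation; `daily_requirements()` warns outside the plausible 0.4–2.5 band |

The pattern can be overridden from YAML or JSON with `load_pattern()`;
overrides merge over the default so partial files are valid.

## Methionine-to-cysteine top-up

Methionine can be transsulfurated to cysteine, but not the reverse. Before
taking the minimum, any methionine above its own requirement is credited to
cysteine:

$$
\text{CYS}' = \text{CYS} + \max(0,\; \text{MET} - R_\text{MET}),
\qquad \text{MET}' = \text{MET}.
$$

Methionine is reported unchanged and uncapped; only cysteine coverage
benefits. The top-up requires a positive methionine requirement and is
applied identically in single-meal and batch scoring.

## The score

$$
\text{MPQS} = 100 \cdot \min_a \frac{I'_a}{R_a}.
$$

Values above 100 are meaningful (surplus) and are preserved;
`mpqs_truncated` caps at 100 for analyses where 100 means "adequate, full
stop". A meal that entirely lacks any EAA scores exactly 0, because no
amount of the others can compensate for a missing indispensable amino acid —
this is why a collagen-only meal (zero tryptophan) scores 0 regardless of
its large protein mass.

# Cohort analyses

`score_records()` scores every meal of a multi-person, multi-day record set
in one vectorized pass (per-portion matrices aggregated with `rowsum()`),
and is property-tested to agree with `score_meal()` exactly. On top of the
per-meal table the package provides:

- `moment_summary()`: MPQS distribution per main meal moment (breakfast,
  lunch, dinner), with and without digestibility adjustment, plus the paired
  decrease due to digestibility.
- `limiting_frequency()`: among inadequate meals (MPQS < 100), how often
  each EAA is the limiting one, by meal moment or by plant-protein category.
- `person_summary()`: per-person medians, the share of adequate meals,
  protein and energy intake, and a split of descriptives by whether the
  person's median MPQS reaches 100.

Plant-protein categories partition meals by the plant share of meal protein:
[0, 27), [27, 65), [65, 100), and exactly 100 (fully plant-based). The last
category is an exact set, not an interval: the share is computed so that a
meal whose protein is entirely plant yields exactly 100 with no
floating-point leakage. Zero-protein meals cannot be categorized; they are
kept in the output with an `NA` category and their count is reported.

# The synthetic-data generator

The generator exists so the package can be exercised and demonstrated
without distributing proprietary food-composition data. It emulates the
*structure* of a dietary-record study, not any particular real dataset:

- **Food archetypes** with contrasting, nutritionally recognizable EAA
  signatures: cereals (lysine-poor), legumes (sulfur-amino-acid-poor),
  animal foods (complete, highly digestible), collagen-like foods (zero
  tryptophan), and starchy tubers (low protein). `check_archetype()`
  verifies each generated food qualitatively matches its archetype.
- **A cohort** (default 252 persons × 7 days, weights ~ N(75, 13) kg
  truncated to 45–120) whose meal-building rules reproduce familiar
  population patterns: smaller, cereal/dairy breakfasts; mixed lunches and
  dinners that usually include animal protein; occasional fully plant-based
  meals; optional snacks.

All randomness flows from a single integer seed through `with_seed()`, which
restores the caller's RNG state, so generation is reproducible and does not
perturb surrounding code. The generator does **not** model seasonality,
within-person correlation across days, under-reporting, recipe-level
nutrient retention, or real survey sampling weights — its outputs are
plausible, not survey-calibrated.

Default sizes (252 × 7, three foods per archetype) were chosen so a full
cohort run exercises every code path in well under a second while producing
enough meals (~5000) for stable descriptive statistics.

# Numerical conventions

- **Full precision internally, half-up at the edge.** All scores and
  coverages are computed and stored in full double precision. Only printed
  and published-style integer percentages use `round_half_up()` (0.5 always
  rounds away from zero), matching how nutrition tables are conventionally
  reported, rather than R's round-half-to-even.
- **Tie-breaking.** If several EAAs tie for the minimum, `limiting_eaa` is
  the first in canonical entity order and `limiting_ties` lists all of them.
- **Adequate meals.** When MPQS ≥ 100 the limiting EAA is reported as
  `"NONE"` — naming a "limiting" EAA for an adequate meal would be
  misleading.
- **Degenerate meals.** An empty meal (no portions, or zero total mass)
  scores 0 with `empty = TRUE`; its limiting EAA is the first entity by
  convention. Foods lacking amino-acid data contribute protein and energy
  but no EAAs, and the share of protein from such foods is reported as
  `pct_protein_without_aa_data` so users can judge the score's reliability.
- **Exactness of the vegan edge.** The plant-protein share short-circuits
  plant == total to exactly 100 before dividing, so the "exactly 100"
  category is robust to floating-point rounding.

# Interpretation choices

Some modeling questions have no single canonical answer; the package's
resolutions are:

- **Valine is scored.** All ten entities enter the minimum, including
  valine, even though it is rarely limiting in practice.
- **Snacks are excluded by default** from cohort analyses
  (`include_snacks = FALSE`), because the meal-moment comparisons concern
  the three main meals; the flag includes them as their own moment.
- **Before-breakfast intake** (e.g., early coffee with milk) is kept as its
  own moment by default; `merge_before_breakfast = TRUE` pools it into
  breakfast, which changes breakfast scores for affected persons.
- **Per-day scoring** (`score_day()`) pools a day's portions against a
  per-day requirement; it is not the sum or mean of per-meal scores, and the
  two deliberately answer different questions.

# Limitations

- Digestibility is a single per-food factor; true ileal amino-acid-specific
  digestibility coefficients, when available, would be more accurate.
- The requirement model is proportional to body weight only; it does not
  adjust for age, lean mass, pregnancy, or illness beyond what the user
  encodes in the target and pattern.
- MPQS is a screening/descriptive indicator: it identifies meals unlikely to
  support maximal muscle protein synthesis, it does not predict individual
  physiological outcomes.
- The synthetic generator supports method development and demonstration; its
  outputs must not be mistaken for real dietary surveillance data.
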