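# mpqs — Meal Protein Quality Score

`mpqs` is an R package for computing the **Meal Protein Quality Score
(MPQS)**, a per-meal indicator that combines protein *quantity* and protein
*quality* into a single number. Unlike per-day protein metrics, MPQS is
designed for the growing evidence that muscle protein synthesis responds to
the essential amino acid (EAA) content of individual meals, so that meal-level
adequacy matters for healthy ageing, sports nutrition, and the design of
plant-forward diets. The package is aimed at nutrition researchers working
with food-composition tables and multi-day dietary records.

## The score

For a meal eaten by a person of body weight $W$ (kg), each food portion
contributes, for each EAA $a$:

$$
I_a \;=\; \sum_{\text{foods } f} \text{mass}_f \cdot
          \frac{\text{protein}_f}{100} \cdot
          \text{aa}_{f,a} \cdot d_f
$$

where $\text{protein}_f$ is g protein per 100 g food, $\text{aa}_{f,a}$ is mg
of amino acid $a$ per g protein, and $d_f$ is the food's true ileal
digestibility (a fraction). The personalized per-meal requirement is

$$
R_a = W \cdot t \cdot p_a
$$

with $t = 0.3$ g protein/kg body weight per meal (the default per-meal
target) and $p_a$ the adult EAA scoring pattern in mg/g protein. Because
methionine can spare cysteine metabolically, any methionine intake in excess
of its own requirement is credited to cysteine before scoring (unidirectional
top-up; methionine itself is reported unchanged). The score is then

$$
\text{MPQS} = 100 \cdot \min_a \frac{I_a'}{R_a}
$$

over the ten EAA entities (histidine, isoleucine, leucine, lysine,
methionine, cysteine, phenylalanine+tyrosine combined, threonine,
tryptophan, valine). A meal completely lacking any EAA scores 0; scores
above 100 are possible and a truncated variant (`mpqs_truncated`) caps at
100, the threshold for a fully adequate meal.

## Worked example

Score the package's built-in three-ingredient example meal (one animal and
two plant ingredients) for a 70 kg adult:

```r
library(mpqs)

fx  <- table2_fixture()          # food table + recipe + person
req <- meal_requirements(70)     # per-meal EAA requirements, mg
score_meal(fx$meal, fx$table, req)
```

```
MPQS: 44  limiting EAA: MET
        adjusted_mg requirement_mg coverage_pct
HIS             263            315           83
ILE             488            630           77
LEU             803           1239           65
LYS             706            945           75
MET             148            336           44
CYS             128            126          102
PHE_TYR         825            798          103
THR             430            483           89
TRP             146            126          116
VAL             820            819          100
protein: 32.0 g (plant 8.0 g, animal 24.0 g), 390 kcal
```

The meal supplies 32 g of protein — more than the 21 g target — yet scores
only 44 because digestibility-adjusted methionine covers just 44% of its
requirement. That quantity/quality gap is exactly what MPQS is built to
expose.

## Main entry points

| Function | Purpose |
| --- | --- |
| `load_food_table()`, `load_records()`, `load_persons()` | Read composition tables (CSV/JSON), multi-day records, and person rosters |
| `meal_requirements()`, `daily_requirements()` | Personalized per-meal / per-day EAA requirements |
| `score_meal()`, `score_day()` | Score a single recipe or a pooled day |
| `score_records()` | Vectorized scoring of a whole cohort's records |
| `moment_summary()`, `limiting_frequency()`, `person_summary()` | Descriptive cohort analyses by meal moment, plant-protein category, and person |
| `generator_config()`, `make_food_table()`, `make_cohort()` | Seeded synthetic food tables and cohorts built from contrasting food archetypes |
| `mpqs_main()` / `exec/mpqs` | Command-line interface (`score-meal`, `score-day`, `cohort`, `make-fixtures`, `validate-table`) |

A command-line session looks like:

```sh
mpqs make-fixtures --out fixtures --seed 17
mpqs score-meal --table fixtures/example_foods.csv \
                --recipe fixtures/example_recipe.csv --reference-70kg
mpqs cohort --table fixtures/foods.csv --records fixtures/records.csv \
            --persons fixtures/persons.csv --out reports
```

## Documentation

Every exported function has roxygen documentation, and
`vignettes/mpqs-methods.Rmd` describes the model, its parameters and
defaults, the synthetic-data generator, and the numerical conventions
(rounding, tie-breaking, degenerate meals) in detail.

## License

MIT — see `LICENSE`.
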