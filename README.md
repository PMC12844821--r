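# foodagg

Derive **generic food items** from a **branded food composition database
(BFCD)**.

BFCDs record label-declared nutrition for individual packaged products as
sold at retail. Nutritional epidemiology, national food composition tables
and mHealth diet trackers need the opposite granularity: generic foods —
*"Yogurt, cow, strained, 0% fat, plain"* — whose nutrient values are means
over similar branded products. foodagg implements a three-step aggregation
framework for getting from one to the other, for data curators and nutrition
informaticians maintaining such databases.

## The method

1. **Quality control.** Energy is reconstructed from declared macronutrients
   with Atwater-type factors (protein, carbohydrate 4 kcal/g; fat 9 kcal/g;
   fiber 2 kcal/g; polyols 2.4 kcal/g) and records are excluded when
   |E<sub>declared</sub> − E<sub>calculated</sub>| / E<sub>declared</sub> > 0.20,
   when SFA:TF > 1 or TS:CHO > 1, or when a declaration is physically
   improbable. Exclusion only — declared values are never corrected.
2. **Name-based grouping.** Product long names are parsed against a
   per-category descriptor vocabulary (animal/plant of origin, processing,
   fat content, flavor, ...) inside a LanguaL-style 4-level category
   hierarchy; records partition by category path, declaration basis and
   descriptor assignment. Multipacks of different foods are set aside.
3. **Homogeneity refinement.** Per group, the coefficient of variation
   (CV = SD/mean, sample SD) of energy and each macronutrient is computed
   over members with complete data. CV > 20% in any of them marks the group
   heterogeneous; secondary descriptors mined from ingredient lists and
   claims (sweetener type, fortification, ...) are then tested as splits and
   applied while they reduce the worst CV without stranding singleton
   subgroups. When nothing on the package explains the spread, the
   heterogeneity is flagged **inherent**.

Aggregated values are emitted only for generic foods populated by ≥ 3
products with complete data; CVs are graded `<20%`, `20–40%`, `≥40%` for the
report surfaces (name yield per category, aggregation capacity, CV-grade
distributions per nutrient).

Because no real BFCD is bundled, the package includes a synthetic-data
generator (`generate_db()`) that fabricates databases in the same multi-file
layout with planted ground truth — known groups, latent secondary
descriptors, QC violations, multipacks, missingness — against which every
pipeline stage is validated.

## Worked example

The package ships a 34-product worked database across four categories
(`inst/extdata/worked_fixture/`):

```r
library(foodagg)
library(dplyr)

fx <- system.file("extdata", "worked_fixture", package = "foodagg")
records <- read_bfcd(
  file.path(fx, "description.csv"), file.path(fx, "nutrients.csv"),
  file.path(fx, "claims.csv"), file.path(fx, "ingredients.csv")
)
vocabulary <- load_vocabulary(file.path(fx, "vocab.yaml"))
res <- aggregate_pipeline(records, vocabulary)

res$groups |>
  select(generic_name, n, provenance, inherent_heterogeneity) |>
  arrange(desc(n)) |>
  print(n = 5)
#> # A tibble: 14 × 4
#>   generic_name                               n provenance inherent_heterogeneity
#>   <chr>                                  <int> <chr>      <lgl>
#> 1 Bread, multigrain, wholegrain, sliced      5 step1      FALSE
#> 2 Yogurt, cow, strained, 0% fat, plain       4 step1      FALSE
#> 3 Margarine, sunflower, spreadable, uns…     3 step1      FALSE
#> 4 Biscuits, wheat, plain                     3 step1      TRUE
#> 5 Milk, cow, pasteurized, full fat, cho…     3 step3_ref… FALSE
```

The 34 products collapse into 14 generic foods. One flavored-milk group was
heterogeneous (total-sugars CV 55%) and was split in step 3 on a sweetener
descriptor found in the ingredient lists (`provenance = "step3_refined"`);
the sugar-sweetened and stevia-sweetened halves are each homogeneous:

```r
res$profiles |>
  filter(nutrient %in% c("energy", "total_sugars"),
         generic_name == "Milk, cow, pasteurized, full fat, chocolate, with sweeteners")
#>   generic_name                      n_complete nutrient  mean    sd     cv grade
#> 1 Milk, cow, pasteurized, full fat…          3 energy    64.7 2.10  0.0325 lt20
#> 2 Milk, cow, pasteurized, full fat…          3 total_s…   4   0.200 0.0500 lt20
```

The biscuit group's sugar spread (CV 60%, members declaring 10–40 g/100 g)
matches no ingredient-list token, so it stays intact with
`inherent_heterogeneity = TRUE`. The report surfaces summarize the result:

```r
yield_table(res$groups)
#>   category                  n_products n_generic_names names_1 names_2 names_ge3
#> 1 Fat or fat product                 4               2       1       0         1
#> 2 Grain or grain product            11               4       1       1         2
#> 3 Milk, milk product or mi…         13               5       1       1         3
#> 4 Vegetable or vegetable p…          6               3       1       1         1
#> 5 Total                             34              14       4       3         7

cv_grade_distribution(res$profiles, digits = 1) |> filter(nutrient == "total_sugars")
#>   nutrient     grade          count   pct
#> 1 total_sugars lt20               6  85.7
#> 2 total_sugars between20and40     0   0
#> 3 total_sugars ge40               1  14.3
#> 4 total_sugars undefined          0   0
```

`names_1 + names_2 + names_ge3 = n_generic_names` per row; only the 7
generic foods with ≥ 3 complete members carry values (the `names_2` column is
counted but, per the framework, never populated). `run_all(input_dir,
vocab_path, out_dir)` — or the `inst/cli/foodagg` script — writes the derived
generic FCD, QC report, refinement log, report tables and a JSONL audit trail
in one call.

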