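# allergiscape

Community-level allergenicity analysis of vegetation surveys along
urbanisation and plant-invasion gradients.

Urban grasslands are a major, under-monitored source of pollen allergens:
grasses and forbs growing in road verges, parks and brownfields release
wind-borne allergenic pollen right where people live. `allergiscape` takes
the standard outputs of a vegetation survey — a species list with traits, a
plot-by-species per-cent-cover matrix, per-plot urbanisation covariates —
plus an allergen-molecule catalog, and quantifies how allergenic each plant
community is, how its allergen spectrum is composed, and how both change
from rural to urban sites and with the share of introduced (archaeophyte /
neophyte) species.

## The scoring model

Each species gets a **potential allergenic value**

```
PAV = allergenicity × pollination × phenology,      PAV ∈ [0, 36]
```

the product of three ordinal factors: an allergenicity score (0–4, from
allergen databases), a pollination-emission score (0 none, 1 biotic, 2
mixed, 3 wind) and a flowering-duration score (1, 2 or 3 for one, two, or
three-plus months in flower). A species is classified *allergenic* when it
has direct allergen-database evidence, is congeneric with such a species,
or is a grass (Poaceae); allergen molecules are extrapolated to the genus
level (tribe level for grasses) and grouped into protein families, the
biochemical units of cross-reactivity.

At the plot level the package computes, overall and per introduction
status: allergenic species richness, proportion and cumulative per-cent
cover; unweighted mean PAV and the cover-weighted community mean
CWM_PAV (the herbaceous-layer analogue of the iUGZA index); allergen
molecule and protein-family richness; month-by-month flowering profiles
with allergy-season bounds and peaks; and rarefaction curves of protein
families per status pool.

The statistical layer fits GLMs of every metric against urbanisation
(% impervious surfaces) and invasion (proportion of neophytes) with
field-standard families (Poisson counts, negative-binomial molecule
richness, quasi-binomial proportions, Gaussian cover/PAV), AICc model
selection with interactions, Nagelkerke pseudo-R² and likelihood-ratio
tests; distance-based redundancy analysis of Jaccard turnover in species,
molecules and families with seeded permutation tests; Moran's I residual
diagnostics; and bootstrap comparisons of flowering phenology between
status groups. A fully seeded synthetic-data generator reproduces the
statistical structure of a 56-plot dry-grassland survey with known ground
truth, so every stage can be calibration- and recovery-tested end to end.

## Worked example

```r
library(allergiscape)

study <- simulate_study(synthetic_config(), seed = 1)   # 56 plots x 216 species
ann   <- annotate_species(study$species, study$catalog)
sum(ann$is_allergenic)
#> [1] 75

res <- run_full_analysis(study, seed = 1)
subset(res$glm_table, subset == "all" & metric == "allergenic_cover")
#>   subset           metric      predictor model_family df   coef      se     r2       p
#> 7    all allergenic_cover impervious_pct     gaussian 54  0.194  0.0696 0.1258 0.00607
#> 8    all allergenic_cover  neophyte_prop     gaussian 54 70.262 30.6864 0.0885 0.02273
```

75 of the 216 generated species (34.7%) are allergenic. The first report
row says that cumulative allergenic cover rises by 0.194 cover-% per
percentage point of impervious surface (the generator injected a true
slope of 0.256; the Gaussian GLM recovers it within one standard error),
with Nagelkerke R² = 0.13 and a likelihood-ratio P = 0.006 against the
intercept-only model.

```r
res$dbrda[, c("level", "r2", "pseudo_f", "p")]
#>      level     r2 pseudo_f     p
#> 1  species 0.0545     1.53 0.007
#> 2 molecule 0.0521     1.46 0.084
#> 3   family 0.0669     1.90 0.040
```

Jaccard turnover in allergenic-species composition is significantly
structured by the two gradients (dbRDA r² = 0.054, permutation P = 0.007).

```r
subset(res$phenology_groups, variable == "duration")
#>          group   n mean lower upper letters variable
#> 7       native 149 2.42  2.24  2.58       a duration
#> 8 archaeophyte  37 3.32  2.92  3.76       b duration
#> 9     neophyte  30 2.60  2.27  2.97       a duration
```

Archaeophytes flower longest (3.3 months, 90% bootstrap CI 2.9–3.8) and
get their own significance letter; natives and neophytes are
indistinguishable.

Real surveys enter the same way: put `species.csv`, `catalog.csv`,
`direct_hits.csv`, `cover.csv` and `environment.csv` in a directory and
call `read_study()`; `write_report()` exports every result table as tidy
CSV.

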