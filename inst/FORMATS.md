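# File formats

Every stage boundary of the pipeline is a plain-text file, so any stage can
be run standalone. All CSVs are comma-separated with a header row.

## Inputs

### records.csv — injury records (one row per coded injury)

| column | type | notes |
|---|---|---|
| casualty_id | string/number | groups records into casualties |
| region_code | string | Barell body-region code or name (see `barell_regions()`); case/punctuation-insensitive |
| nature_code | string | nature-of-injury code or name (see `barell_natures()`) |
| ais | integer 1–6 | AIS severity of this injury |
| open_fracture_flag | logical | required (TRUE/FALSE) when nature is `fracture`; ignored otherwise |

### covariates.csv — casualty covariates (one row per casualty)

`casualty_id` plus one column per categorical covariate (e.g. `age_group`,
`sex`, `service_branch`, `combat_location`, `year_period`, `mechanism`,
`posture`). Values are category labels; `unknown` is an ordinary category.

### generator YAML (`write_generator_config()` / `read_generator_config()`)

Keys: `k`, `j`, `n`, `mixing_proportions` (length-k), `background_probability`,
`seed`, `items` (length-j cell ids), `template` (k rows of j probabilities),
`covariate_model` (per variable: `levels` plus per-level probability rows,
one entry per class).

## Outputs (`run_pipeline()` / `write_cohort()`)

* `indicators.csv` — `casualty_id` plus one 0/1 column per Barell cell id
  (`r<RR>c<CC>`, row-major order).
* `fit_statistics.csv` — one row per fitted K: `k`, `log_lik`,
  `n_parameters`, `bic`, `sabic`, `aic`, `caic`, `entropy`, `converged`.
  `fit_statistics.txt` is the same table formatted, smallest value per
  criterion starred, K = 1 entropy as `-`.
* `diagnostics.csv` — per assigned class: group size, mean posterior in
  every class, `diagonal`, `well_separated`, `empty`.
* `profiles.csv` — one row per profile-defining item: `class`,
  `prevalence`, `item` (cell id), `probability`, `nature_name`,
  `region_name`.
* `assignments.csv` — `casualty_id`, `.class` (hard assignment),
  `.posterior1..K`.
* `characteristics.csv` — long table: `variable`, `level`, `class`
  (`total`, `1`..`K`), `n`, `pct` (within-class, half-up to 1 decimal),
  `omnibus_p`, `marks` (Holm-significant pairwise superscripts, `a` =
  class 1). `characteristics.txt` is the formatted rendering.
* `pairwise_comparisons.csv` — `variable`, `level`, `class_a`, `class_b`,
  `prop_a`, `prop_b`, `p_raw`, `p_adj`, `significant`.
* `manifest.json` — package version, seed, configuration echo, selected
  K, inclusion/exclusion counts. Identical configuration + seed gives
  byte-identical artifacts.

## Acceptance output (`scripts/acceptance.R`)

JSON object mapping quantity names to `{"value": number, "n": size}`.
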