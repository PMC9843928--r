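# abilitysim

Monte-Carlo simulation of parallel-arm clinical trials in
neurodevelopmental disability, comparing two ways of scoring the same
standardized test as the trial endpoint:

* **person-ability scores** (growth scale values, GSV) — Rasch-derived,
  interval-scaled, designed to measure within-person change;
* **norm-referenced scores** (V-scale) — age-normed standard scores
  (population mean 15, SD 3, minimum 1), designed for diagnosis, which
  develop severe floor effects in highly impaired samples.

The package is aimed at trial statisticians and outcome-measure
researchers who need to quantify how much statistical power is lost (or
preserved) when a trial's endpoint is expressed on the norm-referenced
scale rather than the ability scale, as a function of the sample's age
range and impairment level.

## The simulated trial

For a scenario defined by an age range (3–6 or 12–16 years), an
impairment level (1–5 SD below the normative mean, i.e. target V-scale
12, 9, 6, 3, 1) and a subdomain:

1. The generative mean μ is anchored through the score tables: midpoint
   age → target V-scale band → mean raw score → GSV.
2. The generative SD is built from the standard error of measurement:
   per normative age band, σ = SEM/√(1−r); across the age bands spanned
   by the design, the mixture variance
   σ²(mix) = Σwσ² + (Σwμ² − (Σwμ)²) is used.
3. Baseline/endpoint GSV pairs are drawn from a bivariate normal with
   within-subject correlation ρ = 0.8; the treatment arm's endpoint mean
   is shifted by Δ = 0.8·σ (or 0 in the type-I-error condition).
   N = 24 (12 per arm): 66 participants give 90% power for d = 0.8 at
   α = .05 in a plain comparison, reduced by 1−ρ² for the
   baseline-adjusted analysis.
4. Ages are uniform on the month range; each record's GSVs are converted
   back through the tables (nearest tabulated GSV → median raw →
   age-banded V-scale) to yield the V-scale endpoint.
5. Each replication is analyzed by ANCOVA (endpoint ~ arm + baseline);
   power is the fraction of 5,000 replications (10,000 under the null)
   with two-sided p < .05.  Degenerate fits and complete floors (an
   entire arm at the scale minimum at both timepoints) count as failures
   to reject.

The real instrument's conversion tables are copyrighted, so
`generate_table_set()` builds structurally faithful synthetic tables
(11 subdomains, monotone raw→GSV maps from 10 up to 110–197, age-banded
V-scale bands, SEM/reliability per age band) whose developmental
geometry reproduces the qualitative floor behaviour; user-supplied CSV
tables are read by `load_table_set()`.  GSV power is invariant to the
table values (the ANCOVA is equivariant under affine rescaling), so the
ability-score results do not depend on the synthetic stand-in.

## Worked example

```r
library(abilitysim)
tables <- generate_table_set()           # synthetic score-conversion tables
design <- design_config()                # d = 0.8, alpha = .05, rho = 0.8

sc <- scenario(c(12, 16), 5, "Expressive")   # adolescents, 5 SD below mean
scenario_params(tables, sc, design)
#> <generative_params> mu=28.00 sigma=8.29 rho=0.80 delta=6.63

res <- run_scenario(sc, tables, design, n_reps = 5000, seed = 7)
res[c("power_gsv", "power_vscale", "floor_rate_vscale",
      "degenerate_rate_vscale")]
#>  power_gsv power_vscale floor_rate_vscale degenerate_rate_vscale
#>     0.8602       0.0054             0.741                 0.6752
```

The ability-score endpoint detects the 0.8-SD effect in 86% of trials;
the same trials scored on the norm-referenced scale almost never reject
(0.5%), because 74% of replications have an entire arm frozen at
V-scale 1 at both timepoints and the ANCOVA cannot even be fit in 68%.

A reduced full study (all feasible scenarios, both endpoints; use
`reps_effect = 5000, reps_null = 10000` for the full-size run):

```r
study <- run_study(study_config(reps_effect = 1000, reps_null = 2000, seed = 7))
study$summary[study$summary$effect == "large",
              c("age_min", "impairment_sd", "n_subdomains",
                "power_gsv_median", "power_vscale_median", "decrease_median")]
#>    age_min impairment_sd n_subdomains power_gsv_median power_vscale_median decrease_median
#> 1        3             1           11            0.865               0.740          0.1210
#> 2        3             2           10            0.849               0.728          0.1210
#> 3        3             3            5            0.855               0.770          0.0860
#> 4        3             4            4            0.857               0.733          0.1255
#> 5        3             5           11            0.861               0.552          0.3050
#> 6       12             1           11            0.856               0.788          0.0700
#> 7       12             2           11            0.852               0.803          0.0600
#> 8       12             3           11            0.860               0.791          0.0760
#> 9       12             4           11            0.864               0.763          0.1070
#> 10      12             5           11            0.865               0.219          0.6520
```

GSV power sits in a tight band around 85–86% in every condition (it is
scale-free by construction), while V-scale power degrades with
impairment and collapses in the most impaired adolescent condition.
Infeasible cells (a target V-scale band absent at the anchoring age) are
skipped and logged, mirroring how extreme-impairment scenarios can be
unattainable at some ages.  `run_study()` writes `scenario_results.csv`
and `condition_summary.csv` when given an `out_dir`, and accepts a YAML
configuration via `read_study_config()`.

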