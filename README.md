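# urbanhealth

Fuzzy inference assessment of urban environmental health risk from
multi-media monitoring data.

Urban health risk is driven jointly by air quality (PM2.5, NO2, PM10, O3),
water quality (heavy metals, dissolved oxygen, pH), soil quality (organic
matter, nitrogen/phosphorus) and noise. `urbanhealth` is for environmental
health analysts who have site-level monitoring tables for these ten
variables and want a single, explainable, comprehensive health risk index
per record, together with the statistical evidence for trusting it.

## What it computes

**Formula indices.** The graded air-quality sub-index by linear breakpoint
interpolation,

    IAQI = (I_high − I_low)/(C_high − C_low) · (C − C_low) + I_low,

the thermal comfort index
`TCI = (T − 14.3)/(1 + 0.0216·V·(T − 14.3)) + (1 − 0.01·|70.5 − RH|)`,
the contribution-weighted noise pollution index
`NPI = Σ pᵢdᵢ / Σ pᵢ`, and the dimensionless composite air-quality index
`I_sum = Σ_p C_p/S_p` against regulatory standards.

**Fuzzy risk assessment.** A hierarchical fuzzy inference system ("FIS
tree"): sigmoid input memberships `μ(x) = 1/(1 + exp(−c(x − a)/b))`,
Gaussian output memberships, weighted rule firing with product- or min-AND,
and weighted-average defuzzification
`Output = Σ wᵢ·Outputᵢ / Σ wᵢ` (zero-order Sugeno). Four per-medium systems
produce sub-scores on [0, 1]; a root system combines them into the
comprehensive health risk index. The shipped default tree is a documented
monotone rule grid — every function takes the tree as a parameter and trees
round-trip through YAML, so expert rule bases drop in.

**Evaluation protocol.** Bootstrap credibility intervals on the mean risk
(90 %/95 %), permutation significance tests of the IAQI/TCI/NPI
associations with the risk output, Pearson/Spearman correlation screening
of all factors, and applicability metrics (RMSE, R², mean absolute
residual) against an observed-risk reference.

**Synthetic cities.** A generator with three shipped archetypes anchored to
composite air-quality indices 3.92 / 3.04 / 2.3 and a planted latent risk
(logistic in standardized PM2.5 and noise), so the whole pipeline is
testable end to end without any external data.

## Worked example

```r
library(urbanhealth)

batch <- generate_city("B", n = 500, seed = 7)   # heavy-pollution archetype
tree  <- default_fis_tree()
a     <- assess_batch(batch$records, tree, noise = batch$noise)
print(a)
#> <risk_assessment: 500 record(s), mean risk 0.4440>
#>  site  timestamp   risk    air  water   soil  noise  iaqi    tci   npi i_sum
#>  B-S1 2022-01-01 0.5067 0.6111 0.4196 0.3608 0.5049 92.51  5.489 64.71 5.241
#>  B-S2 2022-01-01 0.3988 0.3642 0.2707 0.5314 0.4543 55.90  6.026 62.19 2.984
#>  ...
```

Each row carries the crisp risk index, the four per-medium sub-scores, and
the formula indices: the first record's air sub-score 0.61 and overall
sub-index 92.5 flag a poor-air day (composite index 5.24 ≈ "well above the
city's 3.92 average"), and the root combines that with moderate water, soil
and noise scores into a risk of 0.51.

```r
report <- evaluate_city(a, observed_risk = batch$latent_risk,
                        factors = batch$records[urbanhealth:::RECORD_VARIABLES],
                        seed = 42)
print(report)
#> == Evaluation report ==
#> -- credibility --
#> 90% credibility interval for mean risk: [0.4402, 0.4479] (point 0.4440, percentile, B=2000)
#> 95% credibility interval for mean risk: [0.4394, 0.4484] (point 0.4440, percentile, B=2000)
#> -- significance --
#>   iaqi  |r| = 0.313, p = 0.001 (holm 0.003)
#>   tci   |r| = 0.021, p = 0.643 (holm 0.643)
#>   npi   |r| = 0.747, p = 0.001 (holm 0.003)
#> -- correlation (|r| top 5) --
#>       factor     r   n flag
#>  noise_level 0.775 500
#>          npi 0.747 500
#>         pm10 0.428 500
#>         pm25 0.407 500
#>         iaqi 0.313 500
#> -- applicability --
#>   RMSE 0.1889 | R^2 0.2224 | mean |resid| 0.1565 (n = 500)

cor(a$risk, batch$latent_risk)
#> [1] 0.760138
```

The 95 % interval is wider than the 90 % (same resamples), the air and
noise indicators are significantly associated with the risk output at the
permutation floor while the thermal index is not (the generator plants no
thermal–risk association), and the tree recovers the planted latent risk at
r = 0.76. See the methods vignette (`vignettes/urbanhealth-methods.Rmd`)
for why the raw-scale R² understates that agreement.

A full run — synthesise, assess, evaluate, write stamped artifacts — is one
call:

```r
run_pipeline(list(profile = "B", n = 500, seed = 7, out_dir = "out"))
```

or from a shell via the thin CLI
(`system.file("cli", "urbanhealth", package = "urbanhealth")`) with
`synth`, `assess`, `evaluate` and `run` subcommands.

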