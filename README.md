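# concindex

Socioeconomic inequality in the utilisation of maternal health care —
measured, decomposed, and testable end-to-end on synthetic survey microdata.

## The problem

Coverage of critical maternal-care services — full antenatal care (full
ANC: 4+ visits, at least one tetanus injection, 100+ IFA tablets), skilled
birth attendance (SBA: institutional delivery or a skilled provider at
home), and postnatal care (PNC: a check-up within 48 hours of delivery) —
is typically far higher among wealthier women. Quantifying that gradient,
and attributing it to observable factors such as education, urban
residence, or media exposure, is the core task of health-equity analysis of
DHS/NFHS-style survey data. This package implements that analysis for
woman-level microdata with sampling weights: indicator recodes,
poor/non-poor gap tables, concentration indices and curves (nationally and
by state), and Wagstaff-type decompositions.

## The statistics

For outcome values *y<sub>i</sub>* with weighted mean *μ* and weighted
fractional ranks *R<sub>i</sub>* in the wealth distribution
(Lerman–Yitzhaki midpoints, so the weighted mean rank is exactly ½), the
concentration index is

> C = (2/μ) · cov<sub>w</sub>(y, R)

with C > 0 indicating pro-rich concentration. C equals twice the area
between the concentration curve (cumulative outcome share vs cumulative
population share, poorest → richest) and the diagonal; the package keeps
this twice-area computation as an independent oracle of the covariance
form.

Given a linear model y = α + Σ<sub>k</sub> β<sub>k</sub>x<sub>k</sub> + ε
on dummy-coded covariates, the index decomposes exactly as

> C = Σ<sub>k</sub> (β<sub>k</sub> x̄<sub>k</sub>/μ) · C<sub>k</sub> + GC<sub>ε</sub>/μ

where C<sub>k</sub> is the concentration index of regressor *k* (same ranks
and weights), β<sub>k</sub>x̄<sub>k</sub>/μ its elasticity, and
GC<sub>ε</sub> = 2·cov<sub>w</sub>(ε, R) the generalised concentration
index of the residual. With the linear probability model (the default) the
identity `explained + residual = total` holds to machine precision; a
weighted logit with finite-difference average marginal effects is available
as the alternative engine.

## Worked example

```r
library(concindex)

tab <- generate_population(scenario_preset("nfhs4_like", n = 20000), seed = 1)
weighted_proportion(tab$full_anc, tab$weight)   # 17.1 (% coverage)

concentration_index(tab$full_anc, scores = tab$wealth_score,
                    weights = tab$weight)
#> Concentration index
#>   C = 0.2470  (mu = 0.1712, n = 20000, ranking: continuous_score)
#>   interpretation: pro-rich (concentrated among the better-off)

fit <- ci_decomp(full_anc ~ ., data = tab)
fit
#> Wagstaff-type decomposition of the concentration index
#>   outcome: full_anc  (model: lpm , ranking: continuous_score )
#>          regressor   beta  mean     ci elasticity contribution percent
#>              urban  0.047 0.337  0.131      0.092        0.012   4.918
#>      edu_secondary  0.133 0.312  0.122      0.242        0.030  11.948
#>         edu_higher  0.238 0.108  0.278      0.150        0.042  16.935
#>          media_yes  0.092 0.701  0.057      0.377        0.021   8.683
#>   ...
#>   Explained CI +0.115   Residual +0.132   Total CI +0.247
```

Reading the table: 17.1% of women in this synthetic round used full ANC,
and utilisation is strongly pro-rich (C = 0.247). Higher and secondary
education carry the largest contributions (their holders are concentrated
among the wealthy — positive C<sub>k</sub> — and raise utilisation —
positive β), followed by media exposure and urban residence; the covariates
jointly explain 0.115 of the 0.247, the rest being the direct wealth
gradient left in the residual.

The full pipeline (gap table, state-wise indices, curves, decompositions,
metadata) runs from one config and writes tidy CSV/JSON:

```r
bundle <- run_analysis(run_config(scenario = "nfhs4_like", n = 20000, seed = 1))
write_tables(bundle, "report")
```

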