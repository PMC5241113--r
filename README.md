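# forestchron

Demographic dating of regeneration halts in tropical tree populations,
from forest-inventory diameter structures and radiocarbon chronologies.

## The problem

In central African moist forests, several light-demanding canopy timber
species (e.g. *Erythrophleum*, *Pericopsis*, *Terminalia*,
*Triplochiton*) show **unimodal** diameter distributions: many large
stems, almost no recruits. Read demographically, such a population is an
aging cohort whose recruitment stopped. The dating argument is simple
arithmetic on the modal cohort:

```
age at mode      = D* / MAI_d          (modal dbh over mean annual increment)
halt date (AD)   = reference year − age
```

e.g. a 72 cm mode growing at 0.44 cm/y from an AD 2000 inventory dates to
164 y, i.e. AD 1836. `forestchron` implements the full inference chain
behind this number and the independent human-activity chronology used to
interpret it:

* **inventory**: reading/validating stem tables (≥ 30 cm dbh), the
  13-class genus × diameter matrix, composition summaries;
* **structure**: correspondence analysis of the abundance matrix +
  average-linkage clustering of first-axis scores into reverse-J vs
  deviating genera, with a direct monotonicity heuristic as cross-check;
* **dmode**: maximum-likelihood left-truncated Weibull fits and modal
  diameter estimators (parametric, kernel, histogram);
* **growth**: MAI_d from repeated censuses; an eight-model growth-law
  suite (Mean, Linear, Power, Power mult, Gompertz, Verhulst, Canham,
  Lognormal) compared by BIC = n·ln(RSS/n) + p·ln(n);
* **chronology**: ages by quadrature of dD/dt = g(D) (or the mean-growth
  shortcut), calendar conversion, tree-ring validation;
* **radiocarbon**: calibration on a 1-year grid, HPD intervals, summed
  probability distributions (SPDs), outlier screening;
* **synthetic data**: a forward cohort simulator (recruitment epochs,
  annual Bernoulli mortality, growth laws with optional noise) so every
  stage is testable against a known history.

## Worked example

Simulate a light-demanding species whose recruitment ceased in 1850
(pulse 1300–1850 at 10,000 recruits/y, 2.5%/y mortality, census AD 2000,
mean growth 0.44 cm/y), monitor 367 stems for growth, and date the halt:

```r
library(forestchron)

law <- growth_law("mean", c(c = 0.44))
h <- recruitment_history(data.frame(start = 1300, end = 1850, rate = 10000),
                         mortality_rate = 0.025, census_year = 2000)
trees <- simulate_inventory(h, law, seed = 42)
nrow(trees)
#> [1] 9023

mon <- simulate_growth_observations(
  growth_law("mean", c(c = 0.44), noise_sd = 0.1),
  sample(trees$dbh_cm, 367), seed = 43)

date_regeneration_halt(trees, mai = mean(mon$mai_cm_yr))
#> Age estimate (mean_growth)
#>   mode dbh: 67.1 cm;  MAI_d: 0.444 cm/y
#>   age: 151.3 y (~151 y)
#>   calendar date: AD 1849 (reference AD 2000)
```

The kernel-mode pipeline recovers the 1850 halt to within a year here
(±10 y across seeds). The paper-style parametric route is also available:

```r
fit_weibull_truncated(trees$dbh_cm, 30)
#> Left-truncated Weibull fit (n = 9023 , truncation = 30 cm)
#>   shape k = 4.14, scale lambda = 89.75 cm
#>   mode = 83.95 cm;  log-likelihood = -39473.42
```

— note the Weibull mode sits in the bulk of this front-loaded
distribution, not at its peak; the methods vignette
(`vignettes/forest-chronology.Rmd`) explains when each estimator is
appropriate. And the headline arithmetic itself:

```r
age_at_mode(72, 0.44)
#> Age estimate (mean_growth)
#>   mode dbh: 72.0 cm;  MAI_d: 0.44 cm/y
#>   age: 163.6 y (~164 y)
#>   calendar date: AD 1836 (reference AD 2000)
```

Radiocarbon side:

```r
cv <- linear_calibration_curve(c(-100, 1200))
calibrate(200, 30, cv, lab_id = "DEMO-001")
#> Calibrated date DEMO-001: 200 +/- 30 BP
#>   68.2% HPD (cal BP): [170, 229]
#>   95.4% HPD (cal BP): [140, 259]
```

A thin CLI over the same functions ships in `inst/scripts/forestchron`
(subcommands `simulate`, `mode`, `age`, `c14`).

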