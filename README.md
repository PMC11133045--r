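# ccdrand

Randomization tests and power simulation for single-case **changing
criterion designs** (CCDs).

In a CCD, a performance criterion is stepped up (or down) across
successive intervention phases, and experimental control is demonstrated
by the behavior tracking the criterion. Because the intervention is never
withdrawn and only one treatment is in play, the usual
treatments-to-times randomization schemes of other single-case designs do
not apply. `ccdrand` implements the two randomization schemes that
preserve the stepwise character of the design, the associated exact
randomization tests, and a Monte Carlo engine for studying their type I
error rates and statistical power. It is aimed at behavioral researchers
analysing a single CCD series and at methodologists planning one.

## The test

Both procedures use the **mean absolute deviation** (MAD) of the `m`
intervention measurements from their phase criterion levels as the test
statistic:

```
MAD = (1/m) * sum_t | y_t - c(t) |
```

where `c(t)` is the criterion of the phase containing occasion `t`. A
small MAD means close criterion tracking. The one-sided p-value is the
proportion of assignments in the reference set whose MAD is at or below
the observed one. The baseline phase is excluded throughout: it has no
criterion the scores could be compared to.

The two reference sets:

* **Phase-change-moment (PCM) randomization** fixes the order of the
  criterion levels and randomizes the occasions at which the criterion
  changes. The admissible assignments are the compositions of `m` into
  `I` phase lengths between `k_min` and `k_max`; with a non-binding
  maximum their number is `choose(m - I*k_min + I - 1, I - 1)` (for
  example, 11,440 for `m = 37`, `I = 10`, `k_min = 3`). The package
  counts them by dynamic programming, enumerates them in lexicographic
  order, and samples them uniformly by sequential conditional sampling
  when the set is too large to enumerate.
* **Blocked-alternating-criterion (BAC) randomization** fixes the phase
  boundaries and randomizes the order of the two criterion levels within
  each consecutive block of two phases: `2^B` assignments for `B`
  blocks, always enumerated exactly. At least five blocks (ten phases)
  are needed for a p-value at or below .05.

## Worked example

The package ships a small synthetic series (`inst/extdata/synthetic_ccd.csv`)
with a 6-occasion baseline and ten 3-measurement criterion phases:

```r
library(ccdrand)
ser <- read_ccd(system.file("extdata", "synthetic_ccd.csv", package = "ccdrand"))
iv  <- strip_baseline(ser)
bac_test(iv)
#> BAC randomization test
#>   reference distribution: 32 statistics (systematic, all 32 randomizations)
#>   observed MAD: 3.5483
#>   p-value: 0.03125 (rounded: 0.03)
```

The observed criterion order gives the smallest MAD of all `2^5 = 32`
within-block orders, so `p = 1/32 = .03`: the criterion tracking is
unlikely under the null hypothesis of no criterion effect.

PCM on a simulated five-phase series of 30 measurements (3,876
admissible compositions):

```r
count_randomizations(pcm_design(m = 30, I = 5, k_min = 3))
#> [1] 3876

set.seed(11)
cond <- simulation_condition("PCM", I = 5, m = 30, lengths = "uniform",
                             variability = 0.10, phi = 0.3)
pcm_test(generate_effect_series(cond), k_min = 3)
#> PCM randomization test
#>   reference distribution: 3876 statistics (systematic, all 3876 randomizations)
#>   observed MAD: 1.6132
#>   p-value: 0.00257998 (rounded: 0.00)
```

Power and type I error for a grid of conditions:

```r
conds <- list(
  simulation_condition("BAC", I = 10, m = 30, variability = 0.10, phi = 0.3,
                       reversal = TRUE),
  simulation_condition("BAC", I = 10, m = 30, variability = 0.25, phi = 0,
                       effect = FALSE))
run_condition_grid(conds, seed = 1)
```

A thin command-line wrapper lives in `exec/ccd`
(`count`, `test-pcm`, `test-bac`, `simulate`, `summarize`,
`make-fixture`); run it without arguments for usage.

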