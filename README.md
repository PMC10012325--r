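# pipecap

Capacity-limited, pipelined-processing models for ongoing rapid motor
behavior, with steady-state rate extraction from behavioral event streams
and Bayesian ROPE/HDI analyses.

## The problem

In Object-Hit-family tasks (OH, OHA, TOH, TOHA) participants hit a stream
of objects whose creation rate and speed ramp up over a ~140 s trial until
everyone finishes overwhelmed. Performance is summarized by the
**steady-state rate (SSR)**: the average target-hit rate during the
overwhelmed phase. `pipecap` is for researchers who want to

* simulate two-module pipelined systems — modules process different items
  in parallel but every item passes through both, so throughput saturates
  at the slowest module's capacity (an information bottleneck);
* extract SSRs from timestamped creation/hit event streams; and
* compare SSRs across tasks with Bayesian estimation instead of null
  hypothesis tests.

## The models and statistics at the core

Three workload models map a module's initial capacity $c$ (Hz) and task
difficulty $d \in (0, 1]$ (1 = easiest) to a final capacity:

* additive workload: $c_{\text{final}} = \max(0,\, c - 1 + d)$
* multiplicative workload: $c_{\text{final}} = c \times d$
* flexible capacity: multiplicative, plus a shared 1 Hz pool allocated to
  the weaker module (fully if the capacity gap exceeds the pool, otherwise
  equalizing).

Simulated output at time $t$ is the pipelined minimum
$\max(0, \min(\text{input}(t), c_A^{\text{final}}, c_B^{\text{final}}))$
with input ramping as $0.5 + 0.025\,t + n/10$ Hz over update points. All
324 admissible systems (capacity grid $\{1.0, \dots, 3.5\}^2$ Hz filtered
by $|a - b| < a/3$) are swept across 100 task environments
($\{0.1, \dots, 1.0\}^2$); per-task regressions of SSR(task) on
SSR(baseline) separate the models: slopes near 1 (additive), slopes < 1
with intercepts near 0 (multiplicative), slopes < 1 with positive
intercepts — the regression crossing the unity line at a positive rate
(flexible).

SSR extraction smooths event rates with a Kolmogorov–Zurbenko filter (two
passes of a 5 s moving average), finds the overwhelmed phase from the
trailing windowed median minus MAD of the creation−hit rate difference
against a 0.1 Hz threshold, and averages the hit rate from there to the
creation-rate peak, with two refinement rules on the start frame.

Task comparisons use a normal difference model and a robust t regression
$\mathrm{SSR}_2 \sim t_\nu(\beta_0 + \beta_1\,\mathrm{SSR}_1, \sigma)$,
sampled by an adaptive Metropolis-within-Gibbs sampler (4 chains, with
Brooks–Gelman–Rubin, ESS, MCSE and autocorrelation diagnostics). Decisions
compare 95% highest-density intervals against regions of practical
equivalence: ±0.30 Hz for mean differences, (0.95, 1.05) for the slope,
(−0.12, 0.12) Hz for the intercept.

## Worked example

```r
library(pipecap)

# A synthetic paired-task cohort in the regime where the harder task costs
# skilled participants the most (slope < 1, positive intercept).
cohort <- generate_cohort(400, slope = 0.55, intercept = 0.16, seed = 7)
report <- run_cohort_experiment(cohort,
                                config = mcmc_config(chains = 4, warmup = 500,
                                                     draws = 5000, seed = 8))
print(report)
#> <cohort_report> n = 400
#>   mean difference: mode -0.628 Hz -> different
#>   quartile 1: mode -0.411 Hz -> different
#>   quartile 2: mode -0.566 Hz -> different
#>   quartile 3: mode -0.679 Hz -> different
#>   quartile 4: mode -0.837 Hz -> different
#>   regression: beta1 0.576 -> different; beta0 0.109 Hz -> undecided
```

Reading the output: the mean SSR drop between tasks (−0.628 Hz) is
practically different from zero (its 95% HDI lies outside the ±0.30 Hz
ROPE); the drop grows monotonically across baseline-performance quartiles
(−0.41 Hz for the weakest quarter to −0.84 Hz for the strongest), the
signature of multiplicative task demands; the regression slope 0.576 is
practically below 1; and the positive intercept 0.109 Hz is *undecided*
against its (−0.12, 0.12) Hz ROPE at this sample size — with this
generator more data pushes it to "different", the flexible-capacity
signature.

Single trials work the same way end to end:

```r
ev  <- generate_trial_events(1.5, "OH", seed = 1)  # 300 targets, 1.5 Hz bottleneck
res <- extract_ssr(ev)                             # recovers ~1.5 Hz
```

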