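# stepgls

Step detection for single-molecule real-time trajectories embedded in
**correlated (colored) noise**, by generalized least squares.

Single-molecule instruments such as high-resolution optical tweezers record
the motion of molecular motors — helicases, polymerases, cytoskeletal
motors — as a staircase of steps and dwells buried in noise. Most
step-finding algorithms assume that noise is Gaussian and white. In
kHz-bandwidth tweezers data it is not: the noise is autocorrelated over
several samples, and treating it as white either grossly inflates the step
count (slow noise excursions read as steps) or, after the pre-filtering
some methods require, destroys the short-lived transient steps that
single-molecule experiments exist to reveal.

`stepgls` fits the step regression

    y_t = beta_0 + sum_j beta_j I(t >= t_j) + eps_t,
    eps_t = a_1 eps_{t-1} + ... + a_p eps_{t-p} + w_t,   w_t ~ N(0, sigma^2)

directly on unfiltered data. The workflow:

1. **Candidates.** A quantile-contrast statistic eta in [0, 1] — the mean
   squared difference of the 0.25/0.5/0.75 quantiles between the two halves
   of a window, normalized by the squared window range — is scanned over a
   family of window sizes (half-widths 10–1000); above-threshold local
   peaks form the superset of plausible step locations.
2. **Noise.** The AR order p is identified from the partial
   autocorrelation function of the residuals (PACF of an AR(p) process
   cuts off after lag p); coefficients are Yule–Walker estimates.
3. **GLS.** The AR polynomial in the backshift operator,
   1 − a_1 B − ... − a_p B^p, filters the response and every design column
   (Cochrane–Orcutt), making the errors i.i.d.; the whitened system is
   fitted by least squares.
4. **Selection.** Backward elimination removes the step with the largest
   t-test p-value, refitting until none remain; the model with the lowest
   BIC along the path is returned. Noise estimation and elimination are
   iterated to a fixed point (feasible GLS).

The package also ships the benchmark apparatus: a trajectory simulator with
a canonical 33-step mock-unwinding fixture (2.5 kHz, AR(7) noise with
coefficients 0.222, 0.072, 0.035, 0.015, 0.016, 0.003, 0.013), and an
evaluation harness scoring detections against ground truth (false
positives, missed steps, signed location deviations, per-step detection
efficiency).

## Worked example

Simulate a 2.2 s, 2.5 kHz trace with three steps (+1, −1, +2 units) in
AR(7) noise of marginal sd 0.30, then detect:

```r
library(stepgls)

spec <- step_spec(dwell_times = c(0.6, 0.5, 0.4, 0.7),
                  step_sizes = c(1, -1, 2), sampling_rate = 2500)
sim <- render_trace(spec, noise = unwinding_noise(marginal_sd = 0.3), seed = 42)

fit <- detect_steps(sim$trace)
fit
#> GLS step fit: 3 steps, AR noise order 3
#>   loglik -1082.54 | AIC 2181.07 | BIC 2233.97 | sigma2 0.08681
#> # A tibble: 3 × 5
#>   step_index time_s   size     se t_p_value
#>        <int>  <dbl>  <dbl>  <dbl>     <dbl>
#> 1       1500  0.600  0.999 0.0173         0
#> 2       2749  1.10  -1.01  0.0191         0
#> 3       3749  1.50   2.03  0.0179         0
```

All three steps are found with sizes within one standard error of truth
(0-based sample indices; `time_s = step_index / 2500`). The AR order the
iterated fit settles on (3) reflects what is detectable at this trace
length — the higher-lag AR(7) coefficients are too small to resolve from
5,500 samples, and whitening the dominant lags is what matters. Scoring
against the ground truth:

```r
match_steps(sim$truth, fit)
#> Step match report: 3 matched, 0 false positives, 0 missed steps ("true negatives")
tidy(match_steps(sim$truth, fit))
#> # A tibble: 3 × 3
#>   true_index detected_index deviation_pct
#>        <int>          <int>         <dbl>
#> 1       1500           1500          0
#> 2       2750           2749         -0.08
#> 3       3750           3749         -0.1
```

Deviations are the signed location error as a percentage of the adjacent
true dwell: detections one sample early here, i.e. well under 1%. Order
identification on a long pure-noise trace recovers the generating model:

```r
fit_ar(simulate_ar(unwinding_noise(), 2e5, seed = 1))
#> AR noise model of order 7
#>   coefficients: 0.2234, 0.06729, 0.03111, 0.01576, 0.01468, 0.004166, 0.0136
#>   innovation sd: 0.2899
#>   marginal sd:   0.3005
```

`detect_steps(trace, assume_iid = TRUE)` runs the identical machinery while
ignoring the correlation — on correlated traces it detects roughly twice as
many steps, which is the cautionary tale the method exists to fix.
`autoplot(fit)` overlays the fitted staircase on the trace;
`replicate_study(n_reps, seed)` runs the full benchmark (fixture +
AR(7) noise + detection + scoring) and returns a per-replicate tibble.

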