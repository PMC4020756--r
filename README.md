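# icaref — stable one-unit ICA with a reference signal

`icaref` extracts a *single* independent component from a multichannel
recording, steered by a rough reference template, instead of blindly
unmixing everything and picking afterwards. The motivating problems are
biomedical: pulling the fetal ECG out of maternal abdominal leads (one
lead shows the fetal beat — use it as the reference), or isolating an
eye-blink artifact from EEG using the most contaminated channel.

## The method in brief

For whitened observations `z` and a normalized reference `r`, a single
output `y = w'z` (‖w‖ = 1) is scored by the negentropy approximation

    J(y) = ρ (E{G(y)} − E{G(ν)})²,   ν ~ N(0,1),

and constrained to the neighborhood of the reference through the
closeness measure `ε(y, r) = −E{y r}` and threshold `ξ`:
`ε(y, r) ≤ ξ`. The extractor minimizes the augmented Lagrangian

    f(w) = −J(y) + (1/2γ) [ max(0, μ + γ(ε − ξ))² − μ² ],

alternating a projected ascent of the inequality multiplier μ with a
damped Newton step of `w` along the unit sphere. Earlier one-unit ICA-R
rules can silently terminate at a "fake" component oscillating on the
constraint border, or blow up when the Newton curvature changes sign in
a mixed sub-/super-Gaussian mixture. This implementation adds the
stabilization machinery: it detects a *secondary rise* of μ (the
signature of border oscillation) and *persistent negative curvature*
(wrong attraction basin), restarts from Gram–Schmidt-orthogonal initial
vectors, and only accepts convergence at a feasible point where μ has
decayed to zero, the output is significantly non-Gaussian, and the
projected Hessian is positive definite. The legacy rules are included as
baselines (`extract_one_legacy`), and a benchmark harness tabulates
their misconvergence and negative-curvature fault counts against the
stabilized extractor.

On top of the extractor: reference deflation (`deflate_reference`) to
walk through the components present in a rough reference, direct channel
references (`channel_reference`), threshold widening
(`adaptive_threshold_extract`), and complete recovery of all
non-Gaussian components with a nonconvergence stopping rule
(`recover_all`) — which also counts the true sources when there are more
channels than sources, because Gaussian sensor noise is never accepted
as a component.

## Worked example

Four synthetic sources — uniform noise and a sinusoid (sub-Gaussian),
Laplace noise and a spike train (super-Gaussian) — are mixed into eight
channels with 20 dB Gaussian sensor noise. First, extract the component
dominating channel 1 using that channel itself as the reference:

```r
library(icaref)
fx  <- four_source_fixture(seed = 42, n_samples = 5000)
A   <- gen_mixing(8, 4, dominance = FALSE, seed = 43)
sd0 <- sqrt(mean(apply(A %*% fx$sources, 1, var))) / 10
obs <- mixture_fixture(fx$sources, A, noise_sd = sd0, seed = 44)

x  <- signal_matrix(obs$observations)
wh <- whiten_signals(center_signals(x))
set.seed(1)
res <- extract_one(wh$signals, channel_reference(x, 1),
                   icar_config(xi = -0.3, init = "center"))
print(res)
#> icar_extraction: converged after 33 iterations (0 restarts), closeness -0.8574 (xi = -0.3)
round(cor(res$source, t(fx$sources)), 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.033 0.015 0.995 0.006
```

The run converged in 33 iterations with no restarts; the closeness
−0.857 means the output correlates 0.86 with the reference channel, and
the correlation row shows it is source 3 (the sinusoid dominating that
channel), recovered at |corr| = 0.995 despite the sensor noise.

Recovering everything, with the summed channels as the initial
reference:

```r
set.seed(2)
rec <- recover_all(x)
print(rec)
#> icar_recovery: 5 components (stop: nonconvergence_reached)
#>   kurtosis: -1.189, 53.210, 3.049, -1.476, -0.093
#>   flagged as noise: 5
m <- match_components(rec$sources, fx$sources)
m$matches
#>    estimate truth correlation
#>           1     1  -0.9916310
#>           2     4  -0.9954222
#>           3     2   0.9965247
#>           4     3  -0.9954939
round(sapply(seq_len(nrow(m$matches)), function(i)
  snr_db(rec$sources[m$matches$estimate[i], ],
         fx$sources[m$matches$truth[i], ])), 1)
#> [1] 17.8 20.4 21.6 20.5
```

The loop extracted the four true sources — each matched to a distinct
truth at |corr| ≥ 0.99, recovered at 18–22 dB SNR against the noise-free
originals — plus one weakly structured residual whose excess kurtosis
(−0.09) falls far below the noise cutoff 0.7, so it is flagged as noise;
the next attempt failed to converge, which is the stopping signal that
nothing extractable is left. The kurtosis line identifies the sources:
−1.19 uniform, 53.2 spike train, 3.05 Laplace, −1.48 sinusoid.

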