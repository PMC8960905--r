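# rankdyn

Dynamics of ranking lists: measurement, simulation, theory and fitting.

## The problem

A ranking list is the top `N0` of a larger system of `N` elements,
ordered by score and observed at `T` time points — universities by ARWU
score, words by frequency, athletes by points, repositories by stars.
Across wildly different systems, the churn of such lists looks alike,
and a minimal model captures it with two mechanisms:

- **displacement** — with probability `τ` per micro-step (of duration
  `Δt = 1/N`), a random element jumps to a uniformly random rank,
  shifting the elements in between (a Lévy walk in rank space);
- **replacement** — with probability `ν`, a random element is replaced
  by a brand-new one at the same rank (a birth–death event).

The package implements, for this model and for longitudinal ranking
data in long-format TSV/CSV:

- empirical observables: rank flux `F_t`, turnover `o_t = N_t/N0`, mean
  turnover rate `ȯ = (o_{T−1} − o_0)/(T−1)`, per-rank change
  probability `C(R)`, displacement histograms `P(x, t)` with
  Savitzky–Golay smoothing;
- a fast compiled simulator (exact top-`N0` window, single-seed
  reproducibility) plus Monte-Carlo tracking of single elements;
- the closed-form theory: `P(x,t) = e^{−νt}(L_t + D_{x,t})` with Lévy
  term `L_t = (1 − e^{−τt})/N` and a Wright–Fisher-type degenerate
  diffusion kernel (`∂D/∂t = αx(1−x)∂²D/∂x²`, `α = τ/N`; Gaussian
  approximation and a conservative finite-difference backend);
- the aggregated laws `F = 1 − e^{−ν}[p + (1−p)e^{−τ}]` and
  `ȯ = ν(ν+τ)/(ν+pτ)` with `p = N0/N`, their numerical inversion to
  estimate `(τ, ν)` from data, rescaling `τ_r = τ/(p(1−p)ȯ)`,
  `ν_r = (ν − pȯ)/ȯ` onto the universal curve `τ_r·ν_r = 1`, regime
  weights `W_levy = e^{−ν}(1 − e^{−τ})`, `W_diff = e^{−ν}e^{−τ}`,
  `W_repl = 1 − e^{−ν}`, regime scans, subsampling analysis and a
  parametric-bootstrap test of distance to the curve;
- a command-line interface (`inst/exec/rankdyn`) covering simulate /
  measure / theory / fit / subsample / curve-test / convert / fixtures.

## Worked example

```r
library(rankdyn)

pp  <- model_params(n = 100, n0 = 80, tau = 0.1, nu = 0.2, t_obs = 50,
                    seed = 7)
tab <- simulate_rank_model(pp)
ft  <- flux_turnover(tab)
ft
#> flux/turnover summary (T = 50, N0 = 80)
#>   mean flux F        = 0.208929
#>   mean turnover rate = 0.201531 (o_{T-1} = 10.875)

fit <- fit_parameters(ft$mean_flux, ft$mean_turnover_rate, p = 0.8)
fit
#> rank_fit: tau = 0.340621, nu = 0.174899 (p = 0.8, F = 0.2089, o_dot = 0.2015)
#>   residual = 2.78e-17, converged, nested_bracket

regime_classify(fit$tau_hat, fit$nu_hat)$label
#> [1] "diffusion"
```

The measured flux (0.209) and turnover rate (0.202) sit close to the
closed forms at the true parameters (0.197 and 0.214); the residual
shows the inversion itself is exact, and the gap between `tau = 0.34`
and the true 0.1 is the documented approximation bias of the aggregated
equations at these rates — see the vignette's "Known biases" section.
The fitted weights put this system in the diffusion regime
(`W_diff ≈ 0.6`), i.e. most elements change rank by local score
fluctuations rather than long jumps or replacement.

From the shell:

```sh
rankdyn simulate --n 100 --n0 80 --tau 0.1 --nu 0.2 --t 50 --seed 7 -o s.tsv
rankdyn fit s.tsv          # JSON fit report to stdout
rankdyn subsample s.tsv --k 1,2,4,8 -o report.tsv
```

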