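# olfcs

Feedforward compressed sensing of sparse odor signals.

Natural odors are sparse: of the ~10^4 distinguishable mono-molecular
components, only a handful (`K`) are present in any one odor. The olfactory
system compresses this `N`-dimensional binary signal into the activity of
`M << N` glomeruli and then re-expands it onto third-order neurons (Kenyon
cells in insects, olfactory cortex in vertebrates) — a compressed-sensing
architecture, but a purely feedforward one, with no iterative optimization.
`olfcs` implements and analyzes the threshold codec that makes this work:

- **Encode (OR):** `x = H(A s0 - 1)` — a glomerulus fires if any connected
  component is present. `A` is an `M x N` random binary affinity matrix with
  connection probability `p`.
- **Decode (AND):** `s_hat = H(W' x - 1)`, with `W` the column-normalized
  `A` — a third-order neuron fires only if *all* its glomeruli fire.

At recovery threshold 1 nothing connected is ever missed; the only errors
are false positives, with per-component probability

    p_false = ([1 - p(1-p)^K]^M - (1-p)^M) / (1 - (1-p)^M)
            ~ [1 - p(1-p)^K]^M        (p not too small),

minimized at the **optimal connectivity** `p_m = 1/(K+1)`, independent of
`M`. From this follow the reconstruction SNR `K/((N-K) p_false)`, the
channel's mutual information, compression limits
(`alpha_SNR / alpha_min -> e ln 2 = 1.88`: the codec needs about twice the
information-theoretic minimum of measurements), the SNR bound for non-sparse
signals (`SNR < 4.4` at `K/N = 0.1`), and the minimal glomerulus count for
discrimination (roughly 200-300 at `p = 0.05`). The package pairs every
closed form with seeded Monte-Carlo verification, robustness experiments
(stuck-on, ablated, and silenced glomeruli; recovery-threshold sweeps), a
LASSO / pseudo-inverse baseline comparison, and the continuous extension
(min-operator decoding, effective-feedforward reduction of feedback
circuits, and a spiking LIF + short-term-depression demonstration of the
min operator).

For whom: computational neuroscientists studying olfactory coding or
expander-like sparse binary codes, and anyone wanting a reproducible
reference implementation of threshold-based compressed sensing.

## Worked example

```r
library(olfcs)

cfg <- model_config(N = 1000, M = 100, K = 5,
                    p = optimal_connectivity(5), seed = 42)
rec <- reconstruct(cfg)
glance(rec)
#> # A tibble: 1 × 6
#>   n_components k_true n_false_positives n_misses l1_error n_zero_degree
#>          <int>  <int>             <int>    <int>    <int>         <int>
#> 1         1000      5                 0        0        0             0
```

A 1000-component odor with 5 components present is pushed through 100
glomeruli at the optimal connectivity `1/6` and recovered perfectly — with
only a tenth as many measurement channels as signal dimensions. How lucky
was that? The theory says the per-component false-positive rate here is

```r
p_false_exact(cfg$p, K = 5, M = 100)
#> [1] 0.0009752339
```

so about one false component per reconstruction (`(N-K) * p_false ~ 1`,
SNR ~ 5.2), and simulation agrees to within its standard error:

```r
estimate_p_false(cfg, n_trials = 5000, seed = 7)
#> # A tibble: 1 × 4
#>      mean        se n_trials n_events
#>     <dbl>     <dbl>    <int>    <dbl>
#> 1 0.00100 0.0000209     5000  4975000
```

How close is this architecture to the information-theoretic limit?

```r
limits_table(10000, K_grid = c(5, 15, 50))
#> # A tibble: 3 × 7
#>       K      f m_min alpha_exact alpha_min alpha_snr ratio
#>   <dbl>  <dbl> <int>       <dbl>     <dbl>     <dbl> <dbl>
#> 1     5 0.0005    60      0.006    0.00620    0.0135  2.17
#> 2    15 0.0015   160      0.016    0.0162     0.0359  2.21
#> 3    50 0.005    451      0.0451   0.0454     0.103   2.27
```

`m_min` is the floor on the number of binary measurements; `ratio` is the
factor by which the codec's requirement (at reference SNR 10) exceeds the
asymptotic floor — about 2, trending to `e ln 2 = 1.88` as `f -> 0`.
Sweep results are tibbles with `autoplot()` methods; `reconstruct()` and
`lasso_reconstruct()` results have `tidy()`/`glance()` methods.

Command-line driving (sweeps, limits, LASSO comparison) is available via
`inst/cli/olfcs.R`; experiment configs are validated JSON
(`experiment_config()`, `run_experiment()`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch against the installed package — the optimal connectivity at `K = 1`
(cross-checked by grid minimization of the false-detection rate), the SNR
upper bound at relative sparsity 0.1, the minimal glomerulus counts for
discrimination at `p = 0.05` (both ends of the stated range), and the odor
sparsity implied by a 9% glomerular activation rate — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
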