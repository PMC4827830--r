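---
title: "Methods: the feedforward olfactory codec and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the feedforward olfactory codec and its analysis}
  %\VignetteEncoding{UTF-8}
---

## The model

An odor is a sparse binary vector `s0` of length `N`: entry `i` is 1 if
mono-molecular component `i` is present. Exactly `K` components are active
(`K << N` for natural odors), with the support uniform over K-subsets.
Olfactory receptor input converges onto `M << N` glomeruli through a random
binary affinity matrix `A` (`M x N`, i.i.d. Bernoulli(`p`) entries). The
package implements the two-stage threshold codec:

- **Encoding (OR).** `x = H(A s0 - theta_c)` with the step convention
  `H(0) = 1`. At `theta_c = 1` a glomerulus is active iff at least one of
  its connected components is present: a logical OR. `x` is the binary
  glomerular activity pattern.
- **Decoding (AND).** `s_hat = H(W' x - theta_r)`, where `W` is `A` with
  each nonzero column normalized to sum 1. `(W' x)_i` is then the *fraction*
  of component `i`'s glomeruli that are active, and `theta_r = 1` demands
  all of them: a logical AND over the connected glomeruli, implemented by
  third-order neurons (Kenyon cells / olfactory cortex).

Two structural consequences drive everything else. First, at
`theta_r = 1` no active component with at least one glomerular connection
can be missed (all its glomeruli are genuinely on), so the only error mode
is the *false positive*: an absent component whose glomeruli are all
activated by other components. Second, a component with no connection at
all (probability `(1-p)^M`) is invisible; such zero-degree components are
flagged, decoded as 0, and counted as misses when truly active. All
conditional statements in the theory are "given degree >= 1", and the
Monte-Carlo estimators condition their denominators the same way.

## Closed forms and conventions

The per-component false-detection probability is

    p_false = ([1 - p(1-p)^K]^M - (1-p)^M) / (1 - (1-p)^M),

exact for any `N` (rows of `A` are independent, so glomerular activations
are conditionally independent given the support). When `(1-p)^M` is
negligible *relative to the kept term* this reduces to
`p_false = [1 - p(1-p)^K]^M`. The validity condition matters: absolute
smallness of `(1-p)^M` is not enough (at `p = 0.14, K = 1, M = 50` the
neglected term is 5e-4 yet contributes a 48% relative error because the
kept term is comparably small); the property tests therefore condition on
`(1-p)^M < 5e-3 * p_false_approx`.

Minimizing `p_false` over `p` gives the optimal connectivity
`p_m = 1/(K+1)`, independent of `M` — the package's central prediction:
connectivity between glomeruli and third-order neurons reflects the odor
sparsity of the species' environment, and inverting the relation
(`infer_environment_sparsity()`) turns measured activation/connectivity
rates into sparsity estimates (0.5 -> K = 1, 0.09 -> K = 10,
0.05 -> K = 19).

Derived quantities: reconstruction SNR `K/((N-K) p_false)`; mutual
information of the channel (exact binomial sum over the number of false
detections, with `lchoose` log-coefficients; a leading-order form
`log2 C(N,K) - (N-K) p_false log2(K+1)` valid when `(N-K) p_false << 1`);
the information floor `M_min = ceiling(log2 C(N,K))`; the asymptotic
compression limit `alpha_min -> f log2(e/f)`; the compression the codec
needs at a target SNR, `alpha_SNR = e f (ln SNR + ln(1/f - 1))`; its
inversion at `alpha = 1`, the SNR bound `exp(1/(e f) - ln(1/f - 1))`
(4.4 at `f = 0.1`); and the minimal glomerulus count for discrimination
`M_low = ln(K/(N nu)) / ln(1 - p(1-p)^K)`.

**Logarithm convention.** Information quantities (`mutual_information_*`,
`min_bits`, `alpha_min_asymptotic`) are in bits (`log2`); the compression
algebra (`alpha_snr`, `snr_upper_bound`, `m_low`) uses natural logs. This
is required for consistency: the excess factor `alpha_SNR/alpha_min`
approaches `e ln 2 = 1.8842` only under this mixed convention. The limit
is confirmed numerically in the tests by evaluating at `SNR = e`, where
the slowly-vanishing `ln` terms cancel identically and the ratio equals
`e ln 2` to floating-point accuracy already at `f = 1e-6`; at any other
fixed reference SNR the tabulated ratio (`limits_table()`) converges only
logarithmically and is ~13% above the limit at `f = 1e-4`, which is why
the table test uses a 15% band.

**Numerical choices.** Powers of near-1 quantities are computed as
`exp(M * log1p(-z))` and differences via `expm1`, keeping the formulas
accurate to `M = 1e4` and beyond. Binomial coefficients never materialize
(log-gamma only). The exact mutual-information sum is evaluated in full up
to `N - K = 1e4`; beyond that the sum is restricted to a central binomial
range with tail mass below 1e-16 on each side — the summand's
`log2 C(K+n, K)` factor grows only logarithmically in `n`, so the
truncation error is far below the 1e-15-of-total target. The decoder
compares `(W' x)_i >= theta_r * (1 - 1e-12)` (relative tolerance) so exact
rational fractions `k/d` survive floating-point accumulation at the
`theta_r = 1` boundary.

## The simulated world

The Monte-Carlo module draws a *fresh* affinity matrix and a fresh odor
per trial (annealed averaging): the closed forms average over the `A`
ensemble, so this is the matching estimator. A quenched (fixed-`A`) mode
exists for the exhaustive small-instance oracle. False-positive rates are
estimated with the closed forms' conditioning (denominator = inactive
components with degree >= 1), and standard errors use a per-trial
ratio-estimator linearization rather than a pooled binomial SE — events
within a trial share `A` and `x` and are positively correlated, so the
binomial SE would be anti-conservative. Simulation checks run at 4 SE.

The defaults of the headline experiments are the stated conditions of the
analysis they verify: the false-detection sweep at `M = 500, K = 15`; the
agreement check at `N = 200, M = 50, K = 3, p = p_m = 0.25` with 2e4
trials; the threshold sweep at `N = 1e4, K = 15, M = 1000, p = p_m`; the
LASSO comparison at `N = 1000, M = 500, beta = 0.001` with 100 replicates.
Where a grid was not stated (the recovery-threshold grid, the sparsity
grid of the comparison) the declared defaults are `{1, 0.9, 0.75, 0.5}`
and `{2, 150}` (the two regimes whose ordering is the claim).

What a green simulation test establishes: that the implementation
reproduces its own ensemble's theory. The generator draws exactly the
idealized world the closed forms assume (i.i.d. Bernoulli connectivity,
uniform supports, binary signals); it does not emulate receptor noise,
correlated glomerular tuning, heterogeneous degrees, or concentration
dynamics, so agreement here says nothing about those features of real
olfactory data.

## Robustness experiments

Three corruption modes (`noise_spec()`): glomeruli stuck permanently
active, glomeruli ablated, and per-glomerulus false negatives. Stuck-on
corruption at `theta_r = 1` is *exactly* the model with the stuck rows
deleted, component-wise under shared randomness, for every component that
retains nonzero degree in the reduced circuit; the measure-`(1-p)^(M/2)`
complement (components whose every glomerulus is stuck) is trivially
active in the corrupted circuit and flagged unrecoverable in the reduced
one. The tests assert both halves of this identity rather than the looser
"same distribution" phrasing. Lowering `theta_r` below 1 buys tolerance to
false negatives (fewer misses) at the price of a higher false-detection
rate and lower SNR; the `threshold_sweep()` decodes every threshold from
the same trials, so the orderings are paired comparisons.

## Baselines

The conventional compressed-sensing decoder is the LASSO on the *linear*
measurement `x = A s0`: minimize `1/(2M) ||A s - x||^2 + beta ||s||_1`,
solved by cyclic coordinate descent with soft-thresholding (Rcpp inner
loop), one "iteration" = one full sweep over the `N` coordinates. Two
dialect decisions, both visible in the API:

- **Stopping rule.** Descent stops when the largest coordinate update in a
  sweep falls below `tol` times the largest coefficient — the rule of the
  standard coordinate-descent implementations. An objective-change rule
  was tried and rejected: the very sparse regime has a near-zero optimal
  objective, which turns a relative objective threshold into an absurdly
  tight absolute one and inverts the iteration-count trend the comparison
  is meant to exhibit.
- **Intercept.** `compare_architectures()` fits an unpenalized intercept
  (centering `A`'s columns and `x`), the default behaviour of the common
  Python implementation. Raw 0/1 columns share a large common direction;
  without centering, coordinate descent needs hundreds of sweeps and the
  comparison measures conditioning, not statistics. `lasso_reconstruct()`
  defaults to `intercept = FALSE`, honoring the bare objective.

The comparison draws, per replicate, one binary matrix at the per-K
optimal `p = 1/(K+1)` (the connectivity of the feedforward arm is not
fixed by the source analysis; optimal-p is the declared choice, recorded
in the output) and one odor, shared by both arms. Errors are
`||s_hat - s0||_1`, continuous for the LASSO (no binarization), which for
the binary codec equals false positives + misses. The expected picture:
the feedforward codec is essentially exact at `K = 2` while a
5-sweep-capped LASSO is far off; at `K = 150` the unrestricted LASSO wins
and works measurably harder (more sweeps). The `l2_reconstruct()`
pseudo-inverse is included as the minimum-norm straw man: exact fit,
no sparsity.

## Continuous extension and the spiking min-operator

With nonnegative real signals and affinities and a strictly increasing
glomerular activation `g`, encoding is `x = g(A s0)` and decoding replaces
AND with a minimum: `s_hat_i = min_j g^{-1}(x_j)/A_ji` over connected
glomeruli. Since `g^{-1}(x_j)` is the full linear drive, every ratio
upper-bounds `s0_i`: the decoder never underestimates, recovers exactly
whenever some glomerulus sees the component alone, and specializes (with
binary data, `g = id`, threshold at 1) to the binary AND decoder — the
tests assert that equivalence instance-by-instance. The caller supplies
`g_inv`; a bisection fallback handles monotone `g` without a closed-form
inverse. Noise magnitudes for this decoder depend on the signal and
affinity distributions and are available only by simulation here — no
closed form is provided.

Feedback circuits: adding an interneuron layer `z` with linear dynamics
`x' = -x + A s0 - B'z`, `z' = -z + B x` leaves a feedforward system with
effective affinity `(I + B'B)^{-1} A`. `effective_affinity()` does the
linear solve; `steady_state_dynamics()` integrates the dynamics
(forward Euler, stability guard `dt < 2/(1 + sigma_max(B)^2)`) and the
tests require agreement to 1e-8 across random circuits.

**Spiking min-operator.** The min can be approximated by a leaky
integrate-and-fire neuron whose inputs arrive through depressing synapses
(standard utilization/recovery model: release scales a resource by `U`,
recovery time constant `tau_rec`). Depression saturates the steady drive
of a high-rate channel at ~`w/tau_rec`, so the least active channel
carries the remaining rate information; the threshold sits just above the
saturated drive of `n - 1` channels, making a silent channel veto output
(the AND floor). Each input channel is delivered through `n_contacts = 48`
independent Poisson contacts: a single contact per channel makes
individual PSPs comparable to the threshold barrier, and no parameter
setting can then both silence the two-channel case and track the
three-channel case — biophysically this is the multi-contact (claw)
anatomy of the real connection. Parameters were tuned once by grid search
and frozen (`lif_stp_defaults`: `tau_m` 9.5 ms, `v_th` 1, `U` 0.25,
`tau_rec` 0.65 s, `tau_syn` 8 ms, `w` 0.005755, refractory 1 ms). The
frozen tolerance band, asserted as-is in the tests: equal input rates
`r` in {20, 40, 60} Hz give output within 25% of `r` (measured worst case
-22.7% at 60 Hz); inputs (10, 50, 80) Hz give ~26 Hz, closer to the
minimum than to the mean; a silent input gives < 2 Hz. The approximation
is genuinely coarse: it biases toward the minimum rather than computing
it, tracking degrades above ~60 Hz (saturation) and below ~15 Hz
(sub-threshold), and the band documents exactly that.

## Workbench

Experiments are driven by validated JSON configs (unknown fields are
errors), dispatch through `run_experiment()`, and write RFC-4180 CSV plus
a JSON sidecar carrying the config echo, an FNV-1a config hash, the seed
and the package version; identical config + seed reproduces byte-identical
CSV. Matrices serialize to Matrix Market coordinate format through the
Matrix package, normalized to `dgCMatrix` on read. Reproducibility flows
from one root seed through fixed child streams (stream 1: affinity,
stream 2: odor, stream 3: noise) via a Lehmer-hash `child_seed()`, so
enlarging one draw never perturbs another.

## Limitations

- The false-detection theory is marginal per component; weak dependence
  between output components (shared `x`) is quantified only by the
  exhaustive small-instance oracle, not analytically.
- Binary concentrations only in the analytic layer; the continuous
  extension has no closed-form error theory.
- The spiking demonstration is a tuned existence proof with a stated
  operating range, not a calibrated model of Kenyon-cell biophysics.
- `alpha_min` comparisons use the asymptotic form; at moderate `N` the
  exact `M_min/N` differs by a few percent (the tests show convergence).
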