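#' Exact false-detection rate of the binary codec
#'
#' Probability that an absent odor component is reported present by the
#' AND decoder at `theta_r = 1`, conditioned on the component having at least
#' one glomerular connection:
#' \deqn{p_{false} = \frac{[1 - p(1-p)^K]^M - (1-p)^M}{1 - (1-p)^M}.}
#' Evaluated in log space (`log1p`/`expm1`) so that powers of near-1
#' quantities remain accurate for `M` up to 1e4 and beyond.
#'
#' @param p Connectivity rate, strictly inside (0, 1); `p = 1` returns 1
#'   (all glomeruli always on), `p = 0` is undefined and errors.
#' @param K Odor sparsity, `K >= 1`.
#' @param M Number of glomeruli, `M >= 1`.
#' @return False-detection probability (vectorized over `p`).
#' @seealso [p_false_approx()], [optimal_connectivity()]
#' @export
#' @examples
#' p_false_exact(0.25, K = 3, M = 50)
p_false_exact <- function(p, K, M) {
  stopifnot(K >= 1, M >= 1)
  if (any(p <= 0 | p > 1)) {
    abort("p_false_exact requires 0 < p <= 1", class = "olfcs_invalid_probability")
  }
  lq <- log1p(-p)                      # log(1-p)
  l_num1 <- M * log1p(-p * exp(K * lq)) # log [1 - p(1-p)^K]^M
  num <- exp(l_num1) - exp(M * lq)
  den <- -expm1(M * lq)                 # 1 - (1-p)^M
  out <- num / den
  out[p == 1] <- 1
  out
}

#' Approximate false-detection rate
#'
#' The large-`M` approximation \eqn{p_{false} = [1 - p(1-p)^K]^M}, accurate
#' whenever `(1-p)^M` is negligible (connectivity not too sparse).
#'
#' @inheritParams p_false_exact
#' @return Approximate false-detection probability (vectorized over `p`).
#' @export
#' @examples
#' p_false_approx(1 / 16, K = 15, M = 500)
p_false_approx <- function(p, K, M) {
  stopifnot(K >= 1, M >= 1)
  if (any(p < 0 | p > 1)) {
    abort("p must lie in [0, 1]", class = "olfcs_invalid_probability")
  }
  exp(M * log1p(-p * exp(K * log1p(-p))))
}

#' Optimal connectivity rate
#'
#' The connectivity `p` that minimizes the false-detection rate:
#' `p_m = 1/(K+1)`. It is independent of the number of glomeruli `M` and
#' depends only on the sparsity of odors in the environment.
#'
#' @param K Odor sparsity, `K >= 1` (vectorized).
#' @return Optimal connection probability.
#' @export
#' @examples
#' optimal_connectivity(1) # 0.5
optimal_connectivity <- function(K) {
  if (any(K < 1)) abort("K must be >= 1", class = "olfcs_invalid_sparsity")
  1 / (K + 1)
}

#' Analytic reconstruction SNR
#'
#' `SNR = K / ((N - K) p_false)`: the number of true components over the
#' expected number of false detections. Returns `Inf` when `p_false = 0`.
#'
#' @param N Signal dimension.
#' @param K Odor sparsity, `K < N`.
#' @param p_false False-detection probability.
#' @return Signal-to-noise ratio.
#' @export
snr_analytic <- function(N, K, p_false) {
  if (any(K >= N)) abort("snr_analytic requires K < N", class = "olfcs_invalid_sparsity")
  stopifnot(all(p_false >= 0), all(p_false <= 1))
  ifelse(p_false == 0, Inf, K / ((N - K) * p_false))
}

log2choose <- function(n, k) lchoose(n, k) / log(2)

#' Mutual information of the sparse binary channel (exact binomial sum)
#'
#' With a uniform prior over K-subsets and false-detection probability
#' `p_false` (no misses), the mutual information between odor and
#' reconstruction is
#' \deqn{I = \log_2\binom{N}{K} - \sum_{n=0}^{N-K}\binom{N-K}{n}
#'   p_{false}^n (1-p_{false})^{N-K-n}\log_2\binom{K+n}{K}.}
#' Binomial coefficients are evaluated through `lchoose`, so there is no
#' overflow. For `N - K > 1e4` the sum is restricted to a central binomial
#' range whose excluded tail mass is below 1e-15 (the summand's log factor
#' grows only logarithmically, so the truncation error inherits that bound).
#'
#' @param N Signal dimension.
#' @param K Odor sparsity, `K < N`.
#' @param p_false False-detection probability in `[0, 1]`.
#' @return Mutual information in bits.
#' @export
#' @examples
#' mutual_information_exact(100, 5, 1e-4)
mutual_information_exact <- function(N, K, p_false) {
  if (K >= N) abort("requires K < N", class = "olfcs_invalid_sparsity")
  stopifnot(p_false >= 0, p_false <= 1)
  n_inactive <- N - K
  if (p_false == 0) return(log2choose(N, K))
  if (n_inactive <= 1e4) {
    nerr <- 0:n_inactive
  } else {
    lo <- qbinom(1e-16, n_inactive, p_false)
    hi <- qbinom(1e-16, n_inactive, p_false, lower.tail = FALSE)
    nerr <- max(0, lo - 5):min(n_inactive, hi + 5)
  }
  w <- dbinom(nerr, n_inactive, p_false)
  log2choose(N, K) - sum(w * log2choose(K + nerr, K))
}

#' Mutual information, leading-order approximation
#'
#' `I ~ log2 C(N,K) - (N-K) p_false log2(K+1)`, valid when
#' `(N-K) p_false << 1`. The value is returned as-is (it can go negative far
#' outside the regime); the attribute `in_regime` reports whether
#' `(N - K) * p_false < 0.01`.
#'
#' @inheritParams mutual_information_exact
#' @return Approximate mutual information in bits, with attribute `in_regime`.
#' @export
mutual_information_approx <- function(N, K, p_false) {
  if (K >= N) abort("requires K < N", class = "olfcs_invalid_sparsity")
  out <- log2choose(N, K) - (N - K) * p_false * log2(K + 1)
  attr(out, "in_regime") <- (N - K) * p_false < 1e-2
  out
}

#' Minimal number of bits to encode a K-sparse binary signal
#'
#' `M_min = ceiling(log2 C(N, K))`, the information-theoretic floor on the
#' number of binary measurements. Computed via log-gamma, so it does not
#' overflow for large `N`.
#'
#' @param N Signal dimension.
#' @param K Odor sparsity, `0 <= K <= N` (vectorized).
#' @return Integer bit count.
#' @export
#' @examples
#' min_bits(10, 2) # ceiling(log2(45)) = 6
min_bits <- function(N, K) {
  stopifnot(all(K >= 0), all(K <= N))
  as.integer(ceiling(log2choose(N, K) - 1e-9))
}

#' Asymptotic information-theoretic compression limit
#'
#' In the strong-compression limit (`f = K/N` small at fixed `f`), the minimal
#' compression ratio behaves as `alpha_min -> f log2(e / f)`.
#'
#' @param f Relative sparsity `K/N`, in (0, 1) (vectorized).
#' @return Compression ratio lower limit.
#' @export
alpha_min_asymptotic <- function(f) {
  stopifnot(all(f > 0), all(f < 1))
  f * log2(exp(1) / f)
}

#' Compression ratio required to reach a target SNR
#'
#' `alpha_SNR = e f ln(SNR) + e f ln(1/f - 1)` (natural logs): the number of
#' glomeruli per component that the codec at optimal connectivity needs to
#' achieve a given reconstruction SNR. Can exceed 1 when `f` is not small.
#'
#' @param f Relative sparsity in (0, 1) (vectorized).
#' @param snr Target signal-to-noise ratio, > 0.
#' @return Required compression ratio `M/N`.
#' @export
alpha_snr <- function(f, snr) {
  stopifnot(all(f > 0), all(f < 1), all(snr > 0))
  exp(1) * f * (log(snr) + log(1 / f - 1))
}

#' Upper bound on reconstruction SNR under compression
#'
#' Inverts [alpha_snr()] at `alpha = 1`:
#' `SNR < exp(1/(e f) - ln(1/f - 1))`. For `f = 0.1` the bound is 4.4, i.e. a
#' non-sparse signal cannot be both compressed and accurately reconstructed.
#'
#' @param f Relative sparsity in (0, 1) (vectorized).
#' @return SNR upper bound.
#' @export
#' @examples
#' snr_upper_bound(0.1)
snr_upper_bound <- function(f) {
  stopifnot(all(f > 0), all(f < 1))
  exp(1 / (exp(1) * f) - log(1 / f - 1))
}

#' Minimal number of glomeruli for odor discrimination
#'
#' If discrimination requires `SNR > nu`, the minimal number of glomeruli is
#' \deqn{M_{low} = \frac{\log(K / (N\nu))}{\log[1 - p(1-p)^K]}.}
#' The value is returned un-rounded; callers that need an integer count take
#' the ceiling.
#'
#' @param K Odor sparsity, `K >= 1`.
#' @param N_nu Product of signal dimension and the SNR threshold `nu`;
#'   must exceed `K`.
#' @param p Connectivity rate, strictly in (0, 1).
#' @return Real-valued minimal glomerulus count (vectorized over `K`/`N_nu`).
#' @export
#' @examples
#' m_low(K = 9, N_nu = 1e4, p = 0.05)
m_low <- function(K, N_nu, p) {
  stopifnot(all(K >= 1), all(N_nu > K))
  if (any(p <= 0 | p >= 1)) {
    abort("m_low requires 0 < p < 1", class = "olfcs_invalid_probability")
  }
  den <- log1p(-p * exp(K * log1p(-p)))
  if (any(den == 0)) abort("degenerate denominator in m_low")
  log(K / N_nu) / den
}

#' Infer environmental odor sparsity from an observed connectivity rate
#'
#' Inverts the optimal-connectivity relation `p_m = 1/(K+1)`: a measured
#' connectivity (or activation) rate `p` implies adaptation to odors of about
#' `K = 1/p - 1` components. E.g. the Drosophila glomerular activation rate of
#' 9% gives K = 10; the locust rate of 50% gives K = 1.
#'
#' @param p Observed connectivity rate, `0 < p <= 0.5`.
#' @return Integer sparsity estimate (rounded).
#' @export
#' @examples
#' infer_environment_sparsity(0.09)
infer_environment_sparsity <- function(p) {
  if (any(p <= 0 | p > 0.5)) {
    abort("p must lie in (0, 0.5]: larger rates imply K < 1",
          class = "olfcs_invalid_probability")
  }
  as.integer(round(1 / p - 1))
}
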