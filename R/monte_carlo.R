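#' Glomerular noise specification
#'
#' Describes the three corruption modes used in the robustness experiments:
#' glomeruli stuck permanently active (broad-ligand corruption), glomeruli
#' ablated (removed from the circuit), and false negatives (active glomeruli
#' silenced independently with a given probability). Stuck and ablated sets
#' are disjoint, so their fractions may not sum above 1.
#'
#' @param stuck_on_fraction Fraction of glomeruli forced active, in `[0, 1]`.
#' @param ablated_fraction Fraction of glomeruli removed, in `[0, 1]`.
#' @param false_negative_rate Per-active-glomerulus probability of a 1 -> 0
#'   flip, in `[0, 1]`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(stuck_on_fraction = 0, ablated_fraction = 0,
                       false_negative_rate = 0) {
  vals <- c(stuck_on_fraction, ablated_fraction, false_negative_rate)
  if (any(vals < 0 | vals > 1)) {
    abort("noise fractions must lie in [0, 1]", class = "olfcs_invalid_noise")
  }
  if (stuck_on_fraction + ablated_fraction > 1) {
    abort("stuck-on and ablated sets are disjoint: fractions may not sum above 1",
          class = "olfcs_invalid_noise")
  }
  structure(list(stuck_on_fraction = stuck_on_fraction,
                 ablated_fraction = ablated_fraction,
                 false_negative_rate = false_negative_rate),
            class = "noise_spec")
}

is_null_noise <- function(spec) {
  spec$stuck_on_fraction == 0 && spec$ablated_fraction == 0 &&
    spec$false_negative_rate == 0
}

#' Apply glomerular noise to a pattern and its affinity matrix
#'
#' Stuck-on glomeruli are forced to 1 in `x`; false negatives silence active,
#' non-stuck glomeruli independently; ablated glomeruli are removed outright
#' (their rows of `A` dropped and `x` shortened), after which the
#' reconstruction matrix must be rebuilt from the returned `A`.
#'
#' @param x Binary glomerular pattern.
#' @param A Affinity matrix the pattern came from.
#' @param spec A [noise_spec()].
#' @param seed Optional seed.
#' @return A list with the corrupted `x`, the (possibly row-reduced) `A`, and
#'   the index sets `stuck` and `ablated` (indices into the original rows).
#' @export
apply_noise <- function(x, A, spec, seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  check_dims(A, x = x)
  M <- length(x)
  with_seed_if(seed, {
    n_stuck <- round(spec$stuck_on_fraction * M)
    n_abl <- round(spec$ablated_fraction * M)
    perm <- if (n_stuck + n_abl > 0) sample.int(M, n_stuck + n_abl) else integer(0)
    stuck <- sort(perm[seq_len(n_stuck)])
    ablated <- sort(perm[n_stuck + seq_len(n_abl)])
    if (spec$false_negative_rate > 0) {
      flip_pool <- setdiff(which(x == 1L), stuck)
      flips <- flip_pool[runif(length(flip_pool)) < spec$false_negative_rate]
      x[flips] <- 0L
    }
    x[stuck] <- 1L
    if (n_abl > 0) {
      keep <- setdiff(seq_len(M), ablated)
      x <- x[keep]
      A <- A[keep, , drop = FALSE]
    }
    list(x = x, A = A, stuck = stuck, ablated = ablated)
  })
}

# Shared trial engine: fresh (or fixed) A and fresh s0 per trial, optional
# noise, decode at each theta_r in `thetas`. Returns per-theta accumulators.
mc_trials <- function(config, n_trials, thetas, noise = noise_spec(),
                      fixed_A = NULL, seed = NULL) {
  N <- config$N; M <- config$M; K <- config$K; p <- config$p
  nt <- length(thetas)
  fp_trial <- denom_trial <- miss_trial <- act_trial <-
    matrix(0, n_trials, nt) # per trial, per theta
  with_seed_if(seed, {
    for (t in seq_len(n_trials)) {
      A <- if (is.null(fixed_A)) sample_affinity(M, N, p) else fixed_A
      supp <- sample.int(N, K)
      x <- as.integer(as.vector(Matrix::rowSums(A[, supp, drop = FALSE])) >= config$theta_c)
      if (!is_null_noise(noise)) {
        nz <- apply_noise(x, A, noise)
        x <- nz$x; A <- nz$A
      }
      deg <- as.vector(Matrix::colSums(A))
      on <- which(x == 1L)
      cnt <- if (length(on)) as.vector(Matrix::colSums(A[on, , drop = FALSE])) else numeric(N)
      active <- logical(N); active[supp] <- TRUE
      rec_ok <- deg > 0
      for (h in seq_len(nt)) {
        s_hat <- rec_ok & (cnt >= thetas[h] * deg * (1 - 1e-12))
        fp_trial[t, h] <- sum(s_hat & !active)
        denom_trial[t, h] <- sum(rec_ok & !active)
        miss_trial[t, h] <- sum(!s_hat & active & rec_ok)
        act_trial[t, h] <- sum(active & rec_ok)
      }
    }
  })
  list(fp_trial = fp_trial, denom_trial = denom_trial,
       miss_trial = miss_trial, act_trial = act_trial)
}

# Ratio-estimator mean and standard error for per-trial (events, denominator)
# pairs. Events within a trial share the same circuit and glomerular pattern,
# so they are correlated: the SE comes from between-trial variation of the
# linearized ratio, not from a pooled binomial count.
ratio_estimate <- function(num, den) {
  n <- length(num)
  mu <- sum(num) / sum(den)
  if (n == 1) return(c(mean = mu, se = NA_real_))
  infl <- num - mu * den
  se <- sqrt(sum(infl^2) / (n - 1) / n) / mean(den)
  c(mean = mu, se = se)
}

#' Monte-Carlo estimate of the false-detection rate
#'
#' Per trial, a fresh affinity matrix and a fresh odor are drawn (annealed
#' averaging, matching the ensemble average of the analytic formula) and the
#' reconstruction at `config$theta_r` is scored. The estimate is the fraction
#' of false positives among inactive components with nonzero glomerular
#' degree — zero-degree components are excluded, matching the conditioning of
#' the closed form. The standard error is a ratio-estimator SE over trials
#' (false positives within a trial are correlated through the shared circuit
#' and glomerular pattern). A fixed affinity matrix can be supplied for
#' quenched (fixed-circuit) estimation.
#'
#' @param config An [model_config()].
#' @param n_trials Number of trials, >= 1.
#' @param seed Optional seed.
#' @param fixed_A Optional fixed affinity matrix (quenched mode).
#' @param noise Optional [noise_spec()].
#' @return A one-row tibble: `mean`, `se`, `n_trials`, `n_events`.
#' @export
#' @examples
#' cfg <- model_config(N = 200, M = 50, K = 3, p = 0.25)
#' estimate_p_false(cfg, n_trials = 200, seed = 1)
estimate_p_false <- function(config, n_trials, seed = NULL, fixed_A = NULL,
                             noise = noise_spec()) {
  stopifnot(n_trials >= 1)
  acc <- mc_trials(config, n_trials, thetas = config$theta_r, noise = noise,
                   fixed_A = fixed_A, seed = seed)
  est <- ratio_estimate(acc$fp_trial[, 1], acc$denom_trial[, 1])
  tibble(mean = est[["mean"]],
         se = est[["se"]],
         n_trials = as.integer(n_trials),
         n_events = sum(acc$denom_trial[, 1]))
}

#' Monte-Carlo estimate of the reconstruction SNR
#'
#' `SNR = K / <n_false_positives>`, with a delta-method standard error. When
#' no false positive is observed at all, the estimate is right-censored: the
#' returned `mean` is `Inf`, `censored` is `TRUE` and `lower_bound` carries
#' the scale `K * n_trials * (N - K)` implied by zero events.
#'
#' @inheritParams estimate_p_false
#' @return A one-row tibble: `mean`, `se`, `n_trials`, `censored`,
#'   `lower_bound`.
#' @export
estimate_snr <- function(config, n_trials, seed = NULL, fixed_A = NULL,
                         noise = noise_spec()) {
  stopifnot(n_trials >= 1)
  acc <- mc_trials(config, n_trials, thetas = config$theta_r, noise = noise,
                   fixed_A = fixed_A, seed = seed)
  nfp <- acc$fp_trial[, 1]
  m <- mean(nfp)
  K <- config$K
  if (m == 0) {
    return(tibble(mean = Inf, se = NA_real_, n_trials = as.integer(n_trials),
                  censored = TRUE,
                  lower_bound = K * n_trials * (config$N - K)))
  }
  se_m <- sd(nfp) / sqrt(n_trials)
  tibble(mean = K / m, se = K * se_m / m^2, n_trials = as.integer(n_trials),
         censored = FALSE, lower_bound = NA_real_)
}

#' Sweep the recovery threshold (accuracy-robustness trade-off)
#'
#' For each `theta_r` in the grid, estimates the false-detection rate, the
#' SNR, and the miss rate among recoverable active components, under a common
#' noise specification. All thresholds are decoded from the *same* trials
#' (shared randomness), so orderings across thresholds are paired. Lowering
#' `theta_r` trades accuracy (higher false-detection rate, lower SNR) for
#' robustness to recovery noise (lower miss rate under false negatives).
#'
#' @param config An [model_config()] (its own `theta_r` is ignored).
#' @param theta_r_grid Thresholds in `(0, 1]`.
#' @param n_trials Trials per sweep.
#' @param noise A [noise_spec()].
#' @param seed Optional seed.
#' @return A tibble of class `olf_sweep`, one row per threshold: `theta_r`,
#'   `p_false`, `p_false_se`, `snr`, `snr_censored`, `miss_rate`,
#'   `miss_rate_se`.
#' @export
threshold_sweep <- function(config, theta_r_grid, n_trials,
                            noise = noise_spec(), seed = NULL) {
  stopifnot(all(theta_r_grid > 0), all(theta_r_grid <= 1))
  acc <- mc_trials(config, n_trials, thetas = theta_r_grid, noise = noise,
                   seed = seed)
  pf <- vapply(seq_along(theta_r_grid), function(h)
    ratio_estimate(acc$fp_trial[, h], acc$denom_trial[, h]), numeric(2))
  mr <- vapply(seq_along(theta_r_grid), function(h)
    ratio_estimate(acc$miss_trial[, h], acc$act_trial[, h]), numeric(2))
  mean_fp <- colMeans(acc$fp_trial)
  out <- tibble(
    theta_r = theta_r_grid,
    p_false = pf["mean", ],
    p_false_se = pf["se", ],
    snr = ifelse(mean_fp == 0, Inf, config$K / mean_fp),
    snr_censored = mean_fp == 0,
    miss_rate = mr["mean", ],
    miss_rate_se = mr["se", ])
  new_sweep(out, experiment = "theta_sweep", config = config, seed = seed,
            n_trials = n_trials)
}

#' Sweep the number of glomeruli at optimal connectivity
#'
#' For each `M` in the grid, sets `p = 1/(K+1)` and estimates the SNR by
#' simulation, alongside the analytic value from the approximate
#' false-detection rate. On a log scale the analytic SNR is affine in `M`
#' (the false-detection rate is exponential in `M`).
#'
#' @param config An [model_config()] providing `N`, `K`, `theta_r`.
#' @param M_grid Glomerulus counts to test.
#' @param n_trials Trials per grid point.
#' @param seed Optional seed.
#' @return A tibble of class `olf_sweep`, one row per `M`: `M`, `p`,
#'   `snr_sim`, `snr_sim_se`, `snr_censored`, `snr_analytic`.
#' @export
m_sweep <- function(config, M_grid, n_trials, seed = NULL) {
  K <- config$K
  p_m <- optimal_connectivity(K)
  rows <- purrr::imap(M_grid, function(M, i) {
    cfg <- model_config(config$N, M, K, p_m, theta_r = config$theta_r)
    est <- estimate_snr(cfg, n_trials,
                        seed = if (!is.null(seed)) child_seed(seed, i) else NULL)
    tibble(M = M, p = p_m,
           snr_sim = est$mean, snr_sim_se = est$se, snr_censored = est$censored,
           snr_analytic = snr_analytic(config$N, K, p_false_approx(p_m, K, M)))
  })
  new_sweep(dplyr::bind_rows(rows), experiment = "m_sweep", config = config,
            seed = seed, n_trials = n_trials)
}
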