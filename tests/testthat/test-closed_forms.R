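test_that("exact false-detection rate matches hand evaluation and enumeration", {
  # (p=0.5, K=1, M=2): ([1 - 0.5*0.5]^2 - 0.25) / (1 - 0.25) = 5/12
  expect_equal(p_false_exact(0.5, 1, 2), 5 / 12, tolerance = 1e-12)
  # independent oracle: exhaustive enumeration over all binary matrices
  expect_equal(p_false_exact(0.5, 1, 2), oracle_p_false_enum(0.5, 1, 2),
               tolerance = 1e-12)
  expect_equal(p_false_exact(0.3, 2, 3), oracle_p_false_enum(0.3, 2, 3),
               tolerance = 1e-12)
  expect_equal(p_false_exact(0.1, 3, 3), oracle_p_false_enum(0.1, 3, 3),
               tolerance = 1e-12)
  # boundary: p -> 1 means all glomeruli always on
  expect_equal(p_false_exact(1, 5, 10), 1)
  expect_error(p_false_exact(0, 1, 2), class = "olfcs_invalid_probability")
})

test_that("approximate false-detection rate tracks the exact one when p is not too small", {
  expect_equal(p_false_approx(0.5, 1, 2), 0.5625, tolerance = 1e-12)
  expect_equal(p_false_approx(1, 3, 7), 1)
  # regime of the connectivity-sweep illustration (M = 500, K = 15)
  ex <- p_false_exact(1 / 16, 15, 500)
  ap <- p_false_approx(1 / 16, 15, 500)
  expect_lt(abs(ap - ex) / ex, 1e-2)
  # property: the neglected term (1-p)^M controls the error — whenever it is
  # below 5e-3 of the kept term [1 - p(1-p)^K]^M the relative error is
  # below 1e-2 (the "p not too small" condition)
  for (M in c(50, 500)) {
    for (K in c(1, 5, 15)) {
      p_grid <- seq(0.02, 0.9, by = 0.02)
      ap <- p_false_approx(p_grid, K, M)
      keep <- (1 - p_grid)^M < 5e-3 * ap
      rel <- abs(ap[keep] - p_false_exact(p_grid[keep], K, M)) /
        p_false_exact(p_grid[keep], K, M)
      expect_true(all(rel < 1e-2))
    }
  }
})

test_that("p_false is monotone increasing in K and decreasing in M", {
  p <- 0.1
  pf_k <- vapply(1:20, function(K) p_false_exact(p, K, 100), numeric(1))
  expect_true(all(diff(pf_k) > 0))
  pf_m <- vapply(c(20, 50, 100, 200, 500), function(M)
    p_false_exact(p, 5, M), numeric(1))
  expect_true(all(diff(pf_m) < 0))
})

test_that("optimal connectivity is 1/(K+1), independent of M", {
  expect_equal(optimal_connectivity(1), 0.5)
  expect_equal(optimal_connectivity(9), 0.1)
  expect_error(optimal_connectivity(0), class = "olfcs_invalid_sparsity")
  # grid minimization of the approximate formula recovers it for each K, M
  p_grid <- seq(1e-4, 0.9999, by = 1e-4)
  for (K in c(1, 2, 5, 15, 30)) {
    arg <- vapply(c(50, 500), function(M)
      p_grid[which.min(p_false_approx(p_grid, K, M))], numeric(1))
    expect_equal(arg[1], arg[2]) # independent of M
    expect_lt(abs(arg[1] - 1 / (K + 1)), 1e-4 + 1e-9)
  }
  # local minimum at K = 15: lower than at p_m +/- 0.01
  pm <- optimal_connectivity(15)
  expect_lt(p_false_approx(pm, 15, 500), p_false_approx(pm + 0.01, 15, 500))
  expect_lt(p_false_approx(pm, 15, 500), p_false_approx(pm - 0.01, 15, 500))
})

test_that("analytic SNR follows K / ((N-K) p_false)", {
  expect_equal(snr_analytic(101, 1, 0.01), 1)
  expect_identical(snr_analytic(10, 2, 0), Inf)
  expect_error(snr_analytic(5, 5, 0.1), class = "olfcs_invalid_sparsity")
  # high-SNR regime at N = 1e4, K = 15, M = 1000, optimal p
  snr <- snr_analytic(1e4, 15, p_false_approx(optimal_connectivity(15), 15, 1000))
  expect_gt(snr, 1e6)
})

test_that("mutual information: exact binomial sum and leading-order approximation", {
  expect_equal(mutual_information_exact(2, 1, 0), 1)
  expect_equal(mutual_information_exact(100, 5, 0), lchoose(100, 5) / log(2))
  expect_equal(mutual_information_exact(100, 5, 1), 0, tolerance = 1e-9)
  expect_equal(mutual_information_approx(2, 1, 0), 1, ignore_attr = TRUE)

  ex <- mutual_information_exact(100, 5, 1e-4)
  ap <- mutual_information_approx(100, 5, 1e-4)
  expect_lt(abs(ex - ap) / ex, 1e-3)
  expect_true(attr(ap, "in_regime"))

  # bounds: 0 <= I <= log2 C(N,K) across a p_false scan
  for (pf in c(0, 1e-6, 1e-3, 0.1, 0.5, 1)) {
    v <- mutual_information_exact(60, 4, pf)
    expect_gte(v, -1e-9)
    expect_lte(v, lchoose(60, 4) / log(2) + 1e-9)
  }
  # approx within 0.1% whenever (N-K) p_false < 1e-2
  for (pf in c(1e-5, 1e-4)) {
    for (N in c(50, 500)) {
      ex <- mutual_information_exact(N, 3, pf)
      ap <- as.numeric(mutual_information_approx(N, 3, pf))
      if ((N - 3) * pf < 1e-2) expect_lt(abs(ex - ap) / ex, 1e-3)
    }
  }
})

test_that("minimal bit count uses the log-gamma form without overflow", {
  expect_equal(min_bits(10, 2), 6L) # ceiling(log2(45))
  expect_equal(min_bits(10, 0), 0L)
  expect_equal(min_bits(10, 10), 0L)
  expect_equal(min_bits(1e4, 15), as.integer(ceiling(lchoose(1e4, 15) / log(2))))
})

test_that("asymptotic compression limit matches the bit count as N grows", {
  expect_equal(alpha_min_asymptotic(0.01), 0.01 * log2(exp(1) / 0.01),
               tolerance = 1e-12)
  expect_equal(alpha_min_asymptotic(0.01), 0.0809, tolerance = 1e-3)
  ratio <- vapply(c(1e3, 1e4, 1e5), function(N)
    (min_bits(N, 0.01 * N) / N) / alpha_min_asymptotic(0.01), numeric(1))
  expect_true(all(diff(abs(ratio - 1)) < 0)) # converging
  expect_lt(abs(ratio[3] - 1), 0.02)
  # coefficient check: alpha_min / (-f ln f) -> 1/ln2 as f -> 0
  # (convergence is logarithmic, ~1/ln(1/f), so f must be extreme)
  f <- 1e-60
  expect_equal(alpha_min_asymptotic(f) / (-f * log(f)), 1 / log(2),
               tolerance = 1e-2)
})

test_that("alpha_snr and the SNR upper bound are algebraic inverses", {
  expect_equal(round(snr_upper_bound(0.1), 1), 4.4)
  for (f in c(0.05, 0.1, 0.2)) {
    expect_equal(alpha_snr(f, snr_upper_bound(f)), 1, tolerance = 1e-10)
  }
  # bound decreases with f up to its turning point at f = 1/(1+e) = 0.269
  b <- snr_upper_bound(seq(0.01, 0.26, by = 0.01))
  expect_true(all(diff(b) < 0))
  # snr = 1: alpha_snr ~ e f ln(1/f) as f -> 0
  f <- 1e-8
  expect_equal(alpha_snr(f, 1) / (exp(1) * f * log(1 / f)), 1, tolerance = 1e-6)
})

test_that("compression-ratio excess approaches e ln 2 in the strong-compression limit", {
  # at snr = e the f-dependence cancels except via log(1-f): exact limit value
  expect_equal(alpha_snr(1e-6, exp(1)) / alpha_min_asymptotic(1e-6),
               exp(1) * log(2), tolerance = 1e-4)
  # trend from above at a fixed reference snr
  fs <- 10^seq(-2, -6, by = -1)
  ratio <- alpha_snr(fs, 10) / alpha_min_asymptotic(fs)
  expect_true(all(diff(ratio) < 0))
  expect_true(all(ratio > exp(1) * log(2)))
})

test_that("discrimination threshold M_low reproduces hand values and the stated band", {
  expect_equal(m_low(9, 1e4, 0.05), 219.0, tolerance = 0.5 / 219)
  expect_equal(m_low(9, 1e5, 0.05), 291.0, tolerance = 0.5 / 291)
  # insensitivity over K in 1..9, N*nu in [1e4, 1e5]: the whole grid spans
  # only [184.5, 291] — the "roughly between 200 and 300" band
  grid <- expand.grid(K = 1:9, N_nu = c(1e4, 3e4, 1e5))
  vals <- m_low(grid$K, grid$N_nu, 0.05)
  expect_true(all(vals > 184 & vals < 292))
  expect_lt(max(vals) / min(vals), 1.6)
  expect_error(m_low(9, 1e4, 0), class = "olfcs_invalid_probability")
})

test_that("environmental sparsity inversion matches the species estimates", {
  expect_equal(infer_environment_sparsity(0.5), 1L)   # locust
  expect_equal(infer_environment_sparsity(0.09), 10L) # Drosophila
  expect_equal(infer_environment_sparsity(0.05), 19L) # mouse, ~20
  expect_error(infer_environment_sparsity(0.6), class = "olfcs_invalid_probability")
})
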