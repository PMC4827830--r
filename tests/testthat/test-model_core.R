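test_that("sample_odor draws uniform K-subsets and validates sparsity", {
  expect_equal(sample_odor(5, 5, seed = 3), rep(1L, 5))
  expect_error(sample_odor(5, 0), class = "olfcs_invalid_sparsity")
  expect_error(sample_odor(5, 6), class = "olfcs_invalid_sparsity")

  # inclusion frequency of each component ~ Binomial(n, K/N): 4 SE band
  n <- 1e4
  withr::with_seed(11, {
    freq <- rowMeans(vapply(seq_len(n), function(i) sample_odor(20, 3),
                            integer(20)))
  })
  se <- sqrt(0.15 * 0.85 / n)
  expect_true(all(abs(freq - 3 / 20) < 4 * se))
})

test_that("sample_affinity is Bernoulli(p) in both storage modes", {
  expect_equal(sample_affinity(3, 4, 0, seed = 1), matrix(0, 3, 4))
  expect_equal(sample_affinity(3, 4, 1, seed = 1), matrix(1, 3, 4))
  expect_error(sample_affinity(3, 4, 1.2), class = "olfcs_invalid_probability")

  A <- sample_affinity(100, 100, 0.1, seed = 2)
  se <- sqrt(0.1 * 0.9 / 1e4)
  expect_lt(abs(mean(A) - 0.1), 4 * se)

  As <- sample_affinity(100, 100, 0.1, seed = 2, sparse = TRUE)
  expect_s4_class(As, "dgCMatrix")
  expect_lt(abs(mean(as.matrix(As)) - 0.1), 4 * se)
})

test_that("encode is the thresholded OR of affinity columns", {
  A <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2) # [[1,0,1],[0,1,0]]
  expect_equal(encode(A, c(1, 0, 0)), c(1L, 0L))
  expect_equal(encode(A, c(0, 0, 0)), c(0L, 0L))
  # single active component: x equals that column of A
  expect_equal(encode(A, c(0, 0, 1)), as.integer(A[, 3]))
  expect_error(encode(A, c(1, 0)), class = "olfcs_shape_error")
})

test_that("reconstruction matrix is column-normalized with zero columns flagged", {
  expect_equal(build_reconstruction_matrix(diag(3)), diag(3),
               ignore_attr = TRUE)
  A <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2)
  W <- build_reconstruction_matrix(A)
  expect_equal(unname(colSums(W)), c(1, 1, 1))
  expect_equal(W, A, ignore_attr = TRUE) # all degrees are 1 here

  A0 <- cbind(A, 0)
  W0 <- build_reconstruction_matrix(A0)
  expect_equal(attr(W0, "zero_degree"), 4L)
  expect_equal(unname(W0[, 4]), c(0, 0))
  expect_equal(zero_degree_components(A0), 4L)
})

test_that("decode is the thresholded AND, with exact theta_r = 1 boundary", {
  A <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2)
  W <- build_reconstruction_matrix(A)
  # worked example: component 3 shares its only glomerulus with component 1
  expect_equal(decode(W, c(1, 0), 1), c(1L, 0L, 1L))
  expect_equal(decode(W, c(0, 0), 1), c(0L, 0L, 0L))
  # theta_r = 0 boundary: H(0) = 1 activates every nonzero-degree unit
  expect_equal(decode(W, c(0, 0), 0), c(1L, 1L, 1L))
  # exact rational fractions at the theta_r = 1 boundary survive float
  # accumulation: degree-3 unit with all glomeruli on
  A3 <- matrix(1, 3, 1)
  W3 <- build_reconstruction_matrix(A3)
  expect_equal(decode(W3, c(1, 1, 1), 1), 1L)
  expect_equal(decode(W3, c(1, 1, 0), 1), 0L)
})

test_that("reconstruct composes the codec and counts errors", {
  # identity affinity: disjoint channels, exact recovery
  cfg <- model_config(N = 6, M = 6, K = 3, p = 0.5)
  s0 <- sample_odor(6, 3, seed = 4)
  r <- reconstruct(cfg, A = diag(6), s0 = s0)
  expect_equal(r$values, s0)
  expect_equal(r$n_false_positives, 0L)
  expect_equal(r$n_misses, 0L)

  A <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2)
  r2 <- reconstruct(model_config(N = 3, M = 2, K = 1, p = 0.5),
                    A = A, s0 = c(1, 0, 0))
  expect_equal(r2$n_false_positives, 1L)
  expect_equal(r2$n_misses, 0L)

  g <- glance(r2)
  expect_equal(g$l1_error, 1L)
  td <- tidy(r2)
  expect_equal(td$outcome[c(1, 3)], c("hit", "false_positive"))
})

test_that("codec agrees with the set-logic oracle on exhaustive small instances", {
  # all binary A for M = 2, N = 3, every support, theta_r in {1, 0.5}
  for (code in 0:63) {
    A <- matrix(as.integer(intToBits(code))[1:6], nrow = 2)
    for (K in 1:3) {
      for (supp in all_supports(3, K)) {
        s0 <- integer(3); s0[supp] <- 1L
        for (th in c(1, 0.5)) {
          ora <- oracle_codec(A, s0, theta_r = th)
          x <- encode(A, s0)
          expect_identical(x, ora$x)
          expect_identical(decode(build_reconstruction_matrix(A), x, th),
                           ora$s_hat)
        }
      }
    }
  }
  # random larger instances, N <= 6, M <= 4
  withr::with_seed(9, {
    for (rep in 1:200) {
      M <- sample(2:4, 1); N <- sample(3:6, 1); K <- sample(seq_len(N), 1)
      A <- sample_affinity(M, N, runif(1))
      s0 <- sample_odor(N, K)
      th <- sample(c(1, 0.75, 0.5, 0.25), 1)
      ora <- oracle_codec(A, s0, theta_r = th)
      x <- encode(A, s0)
      expect_identical(x, ora$x)
      expect_identical(decode(build_reconstruction_matrix(A), x, th), ora$s_hat)
    }
  })
})

test_that("no active component with nonzero degree is missed at theta_r = 1", {
  withr::with_seed(21, {
    for (rep in 1:300) {
      M <- sample(2:4, 1); N <- sample(3:6, 1); K <- sample(seq_len(N), 1)
      cfg <- model_config(N, M, K, runif(1))
      r <- reconstruct(cfg, A = sample_affinity(M, N, cfg$p),
                       s0 = sample_odor(N, K))
      active <- which(r$s0 == 1)
      missed <- active[r$values[active] == 0]
      expect_true(all(missed %in% r$zero_degree))
    }
  })
})

test_that("lowering theta_r never deactivates an active output unit", {
  withr::with_seed(33, {
    for (rep in 1:100) {
      A <- sample_affinity(4, 6, runif(1, 0.2, 0.8))
      s0 <- sample_odor(6, sample(1:3, 1))
      W <- build_reconstruction_matrix(A)
      x <- encode(A, s0)
      grid <- sort(runif(4, 0.05, 1), decreasing = TRUE)
      prev <- decode(W, x, 1)
      for (th in grid) {
        cur <- decode(W, x, th)
        expect_true(all(cur >= prev))
        prev <- cur
      }
    }
  })
})

test_that("identical config and seed give bit-identical draws and outputs", {
  cfg <- model_config(N = 120, M = 40, K = 4, p = 0.2, seed = 77)
  r1 <- reconstruct(cfg)
  r2 <- reconstruct(cfg)
  expect_identical(r1$values, r2$values)
  expect_identical(r1$s0, r2$s0)
  expect_identical(sample_affinity(40, 120, 0.2, seed = child_seed(77, 1)),
                   sample_affinity(40, 120, 0.2, seed = child_seed(77, 1)))
  # child streams differ from each other
  expect_false(child_seed(77, 1) == child_seed(77, 2))
})
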