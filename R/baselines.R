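#' LASSO reconstruction from a linear measurement
#'
#' Solves the penalized least-squares problem
#' \deqn{\min_{\hat s} \frac{1}{2M}\|A\hat s - x\|_2^2 + \beta\|\hat s\|_1}
#' by cyclic coordinate descent with soft-thresholding. One iteration is one
#' full sweep over all `N` coordinates; descent stops when the largest
#' coordinate update in a sweep falls below `tol` relative to the largest
#' coefficient (the stopping dialect of the standard coordinate-descent
#' LASSO solvers), or at `max_iter` sweeps. The linear,
#' unthresholded measurement `x = A s0` is the intended input — this is the
#' conventional compressed-sensing decoder the feedforward codec is compared
#' against. The continuous solution is *not* binarized; the reported error is
#' `||s_hat - s_true||_1`.
#'
#' @param A Measurement matrix (binary or real), M x N.
#' @param x_linear Real measurement vector of length M.
#' @param beta Penalty weight, > 0.
#' @param max_iter Maximum number of full sweeps, >= 1.
#' @param tol Relative coordinate-update stopping tolerance (default 1e-4;
#'   tighten for high-accuracy solutions).
#' @param s_true Optional ground truth for the `l1_error` field.
#' @param intercept If `TRUE`, profile out an unpenalized intercept by
#'   centering `A`'s columns and `x` before descent (the default behaviour
#'   of the common Python LASSO implementation, and dramatically better
#'   conditioned for 0/1 measurement matrices, whose columns share a large
#'   common component). The returned coefficients are unchanged in meaning;
#'   the fitted intercept is reported separately.
#' @return An object of class `lasso_fit`: `s_hat`, `l1_error` (or `NA`),
#'   `n_iterations`, `objective_trace` (one value per sweep, non-increasing).
#' @export
#' @examples
#' A <- diag(5)
#' fit <- lasso_reconstruct(A, x_linear = c(1, 0, 1, 0, 0), beta = 1e-6,
#'                          s_true = c(1, 0, 1, 0, 0))
#' glance(fit)
lasso_reconstruct <- function(A, x_linear, beta, max_iter = 1000L,
                              tol = 1e-4, s_true = NULL, intercept = FALSE) {
  if (max_iter < 1) abort("max_iter must be >= 1", class = "olfcs_invalid_iterations")
  stopifnot(beta > 0)
  A <- as.matrix(A)
  check_dims(A, x = x_linear)
  x <- as.numeric(x_linear)
  if (intercept) {
    col_mu <- colMeans(A)
    x_mu <- mean(x)
    A <- sweep(A, 2, col_mu)
    x <- x - x_mu
  }
  res <- lasso_cd_fit(A, x, beta, as.integer(max_iter), tol)
  structure(
    list(s_hat = res$s_hat,
         intercept = if (intercept) x_mu - sum(col_mu * res$s_hat) else 0,
         l1_error = if (is.null(s_true)) NA_real_ else sum(abs(res$s_hat - s_true)),
         n_iterations = res$n_iterations,
         objective_trace = res$objective_trace),
    class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> %d nonzero of %d, %d sweeps, final objective %.6g\n",
              sum(x$s_hat != 0), length(x$s_hat), x$n_iterations,
              tail(x$objective_trace, 1)))
  invisible(x)
}

#' @rdname lasso_reconstruct
#' @param x A `lasso_fit`.
#' @param ... Unused.
#' @export
tidy.lasso_fit <- function(x, ...) {
  tibble(component = seq_along(x$s_hat), estimate = x$s_hat)
}

#' @rdname lasso_reconstruct
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble(n_iterations = x$n_iterations,
         objective = tail(x$objective_trace, 1),
         n_nonzero = sum(x$s_hat != 0),
         l1_error = x$l1_error)
}

#' Minimum-norm least-squares (pseudo-inverse) reconstruction
#'
#' `s_hat = pinv(A) x`: the minimum-l2-norm solution of the linear system,
#' the l2 alternative to l1 minimization. For an underdetermined system it
#' fits the measurement exactly but spreads energy over all components, so it
#' does not recover a sparse signal.
#'
#' @param A Measurement matrix.
#' @param x_linear Real measurement vector.
#' @return Numeric vector of length N.
#' @export
l2_reconstruct <- function(A, x_linear) {
  A <- as.matrix(A)
  check_dims(A, x = x_linear)
  sv <- svd(A)
  pos <- sv$d > max(dim(A)) * .Machine$double.eps * max(sv$d)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  as.vector(sv$v %*% (dinv * crossprod(sv$u, x_linear)))
}

#' Compare the feedforward codec with LASSO across odor sparsity
#'
#' For each `K` in `K_grid` and each of `n_reps` replicates, draws a fresh
#' binary affinity matrix at the per-K optimal connectivity `p = 1/(K+1)` and
#' a fresh K-sparse odor. The feedforward arm encodes and decodes the binary
#' measurement (`theta_c = theta_r = 1`); the LASSO arm decodes the linear
#' measurement `x = A s0`, once unrestricted and (optionally) once with the
#' sweep count capped at `iter_cap` (a bounded response time). Errors are
#' mean `||s_hat - s0||_1`; for the binary codec this equals false positives
#' plus misses. The same matrix and odor are shared by both arms. The LASSO
#' arm fits an unpenalized intercept (`intercept = TRUE` in
#' [lasso_reconstruct()]), without which coordinate descent on a raw 0/1
#' matrix is too ill-conditioned to converge within a realistic sweep budget.
#'
#' @param N Signal dimension (default 1000).
#' @param M Number of measurements (default 500).
#' @param beta LASSO penalty (default 0.001).
#' @param K_grid Odor sparsities to test.
#' @param n_reps Replicates per K (default 100).
#' @param iter_cap Optional sweep cap for the capped LASSO arm (e.g. 5);
#'   `NULL` to skip that arm.
#' @param max_iter Sweep budget for the unrestricted arm.
#' @param seed Optional seed.
#' @return A tibble of class `olf_sweep`, one row per K: mean and standard
#'   error of the feedforward error, the LASSO error, the capped-LASSO error
#'   (if requested), and the mean LASSO iteration count.
#' @export
compare_architectures <- function(N = 1000, M = 500, beta = 0.001, K_grid,
                                  n_reps = 100, iter_cap = NULL,
                                  max_iter = 1000L, seed = NULL) {
  stopifnot(length(K_grid) >= 1, n_reps >= 1)
  rows <- purrr::imap(K_grid, function(K, ik) {
    p <- optimal_connectivity(K)
    ff <- la <- it <- cap <- numeric(n_reps)
    with_seed_if(if (!is.null(seed)) child_seed(seed, ik) else NULL, {
      for (r in seq_len(n_reps)) {
        A <- sample_affinity(M, N, p, sparse = FALSE)
        s0 <- sample_odor(N, K)
        rec <- reconstruct(model_config(N, M, K, p), A = A, s0 = s0)
        ff[r] <- rec$n_false_positives + rec$n_misses
        x_lin <- as.vector(A %*% s0)
        fit <- lasso_reconstruct(A, x_lin, beta, max_iter = max_iter,
                                 s_true = s0, intercept = TRUE)
        la[r] <- fit$l1_error
        it[r] <- fit$n_iterations
        if (!is.null(iter_cap)) {
          fitc <- lasso_reconstruct(A, x_lin, beta, max_iter = iter_cap,
                                    s_true = s0, intercept = TRUE)
          cap[r] <- fitc$l1_error
        }
      }
    })
    out <- tibble(K = K, p = p,
                  ff_error = mean(ff), ff_error_se = sd(ff) / sqrt(n_reps),
                  lasso_error = mean(la), lasso_error_se = sd(la) / sqrt(n_reps),
                  lasso_iterations = mean(it),
                  lasso_iterations_se = sd(it) / sqrt(n_reps))
    if (!is.null(iter_cap)) {
      out$lasso_capped_error <- mean(cap)
      out$lasso_capped_error_se <- sd(cap) / sqrt(n_reps)
    }
    out
  })
  new_sweep(dplyr::bind_rows(rows), experiment = "lasso_compare",
            config = list(N = N, M = M, beta = beta, n_reps = n_reps,
                          iter_cap = iter_cap),
            seed = seed, n_trials = n_reps)
}
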