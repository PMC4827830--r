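#' Model configuration for the binary feedforward codec
#'
#' Bundles the dimensions and thresholds of the olfactory codec: `N` odor
#' components, `M` glomeruli, odor sparsity `K` (number of components present
#' in an odor), glomerulus connection probability `p`, the compression
#' threshold `theta_c` (1 for the binary model, making encoding a logical OR)
#' and the recovery threshold `theta_r` in (0, 1] (1 makes decoding a logical
#' AND over the connected glomeruli).
#'
#' @param N Number of odor components (signal dimension).
#' @param M Number of glomeruli (measurement dimension).
#' @param K Odor sparsity, the number of active components; `1 <= K <= N`.
#' @param p Connection probability of the binary affinity matrix, in `[0, 1]`.
#' @param theta_c Compression threshold; the binary model uses 1.
#' @param theta_r Recovery threshold, a fraction of a unit's connected
#'   glomeruli, in `(0, 1]` (0 is accepted as the degenerate all-on boundary).
#' @param seed Optional integer root seed; child streams are derived with
#'   [child_seed()] (stream 1: affinity matrix, stream 2: odor).
#' @return An object of class `olf_config`.
#' @export
#' @examples
#' model_config(N = 100, M = 20, K = 3, p = 0.25, seed = 1)
model_config <- function(N, M, K, p, theta_c = 1, theta_r = 1, seed = NULL) {
  stopifnot(N >= 1, M >= 1)
  if (K < 1 || K > N) {
    abort(sprintf("invalid sparsity: K must satisfy 1 <= K <= N, got K = %s, N = %s", K, N),
          class = "olfcs_invalid_sparsity")
  }
  if (p < 0 || p > 1) {
    abort("invalid probability: p must lie in [0, 1]", class = "olfcs_invalid_probability")
  }
  if (theta_r < 0 || theta_r > 1) {
    abort("theta_r must lie in (0, 1]", class = "olfcs_invalid_threshold")
  }
  structure(
    list(N = as.integer(N), M = as.integer(M), K = as.integer(K), p = p,
         theta_c = theta_c, theta_r = theta_r,
         seed = if (!is.null(seed)) as.integer(seed) else NULL),
    class = "olf_config"
  )
}

#' @export
print.olf_config <- function(x, ...) {
  cat(sprintf(
    "<olf_config> N = %d, M = %d, K = %d, p = %.4g, theta_c = %g, theta_r = %g, seed = %s\n",
    x$N, x$M, x$K, x$p, x$theta_c, x$theta_r,
    if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' Sample a sparse binary odor signal
#'
#' Draws the support uniformly from all K-subsets of the N components, the
#' uniform prior over individual odor components assumed by the information
#' calculation.
#'
#' @param N Number of components.
#' @param K Number of active components, `1 <= K <= N`.
#' @param seed Optional seed.
#' @return An integer 0/1 vector of length `N` with exactly `K` ones.
#' @export
#' @examples
#' sample_odor(10, 3, seed = 1)
sample_odor <- function(N, K, seed = NULL) {
  if (K < 1 || K > N) {
    abort(sprintf("invalid sparsity: need 1 <= K <= N, got K = %s, N = %s", K, N),
          class = "olfcs_invalid_sparsity")
  }
  with_seed_if(seed, {
    s <- integer(N)
    s[sample.int(N, K)] <- 1L
    s
  })
}

#' Sample a random binary affinity matrix
#'
#' Each entry is independently 1 with probability `p`, the model's random
#' connectivity from odor components to glomeruli. Large matrices
#' (`M * N > 1e6`) are returned sparse (`dgCMatrix`); small ones dense.
#'
#' @param M Number of glomeruli (rows).
#' @param N Number of odor components (columns).
#' @param p Connection probability in `[0, 1]`.
#' @param seed Optional seed.
#' @param sparse Force sparse (`TRUE`) or dense (`FALSE`) storage;
#'   default chooses by size.
#' @return An `M x N` binary matrix (base matrix or `Matrix::dgCMatrix`).
#' @export
#' @examples
#' sample_affinity(4, 6, 0.3, seed = 1)
sample_affinity <- function(M, N, p, seed = NULL, sparse = NULL) {
  if (p < 0 || p > 1) {
    abort("invalid probability: p must lie in [0, 1]", class = "olfcs_invalid_probability")
  }
  if (is.null(sparse)) sparse <- (as.numeric(M) * N > 1e6)
  with_seed_if(seed, {
    if (!sparse) {
      matrix(as.numeric(rbinom(M * N, 1L, p)), nrow = M, ncol = N)
    } else {
      # nnz ~ Binomial(MN, p), positions uniform without replacement:
      # jointly equivalent to i.i.d. Bernoulli(p) entries
      nnz <- rbinom(1L, as.integer(min(M * as.numeric(N), .Machine$integer.max)), p)
      pos <- sample.int(M * N, nnz) - 1L
      Matrix::sparseMatrix(i = pos %% M + 1L, j = pos %/% M + 1L, x = 1,
                           dims = c(M, N))
    }
  })
}

check_dims <- function(A, s0 = NULL, x = NULL) {
  if (!is.null(s0) && ncol(A) != length(s0)) {
    abort(sprintf("shape error: A has %d columns but signal has length %d",
                  ncol(A), length(s0)), class = "olfcs_shape_error")
  }
  if (!is.null(x) && nrow(A) != length(x)) {
    abort(sprintf("shape error: A has %d rows but pattern has length %d",
                  nrow(A), length(x)), class = "olfcs_shape_error")
  }
  invisible(TRUE)
}

#' Encode an odor into a glomerular activation pattern
#'
#' Computes `x = H(A s0 - theta_c)` with the step convention `H(0) = 1`, i.e.
#' glomerulus k is active iff `(A s0)_k >= theta_c`. With `theta_c = 1` this
#' is the logical OR over the active components connected to the glomerulus.
#'
#' @param A Binary affinity matrix (M x N).
#' @param s0 Binary odor vector of length N.
#' @param theta_c Compression threshold (default 1).
#' @return Integer 0/1 vector of length M.
#' @export
encode <- function(A, s0, theta_c = 1) {
  check_dims(A, s0 = s0)
  as.integer(as.vector(A %*% s0) >= theta_c)
}

#' Build the column-normalized reconstruction matrix
#'
#' `W_ki = A_ki / sum_k A_ki`: each column of A with at least one connection
#' is normalized to sum to 1. Columns with no connection at all (glomerular
#' degree zero, probability `(1-p)^M` per component) are left all-zero and
#' recorded in the `"zero_degree"` attribute; such components can never be
#' recovered.
#'
#' @param A Binary affinity matrix.
#' @return A nonnegative matrix of the same shape and storage as `A`, with
#'   attribute `zero_degree` (integer indices of unrecoverable components).
#' @export
build_reconstruction_matrix <- function(A) {
  d <- as.vector(Matrix::colSums(A))
  inv <- ifelse(d > 0, 1 / d, 0)
  if (inherits(A, "Matrix")) {
    W <- A %*% Matrix::Diagonal(x = inv)
  } else {
    W <- A * rep(inv, each = nrow(A))
  }
  attr(W, "zero_degree") <- which(d == 0)
  W
}

#' Zero-degree (unrecoverable) components of an affinity matrix
#'
#' @param A Binary affinity matrix.
#' @return Integer indices of components with no glomerular connection.
#' @export
zero_degree_components <- function(A) which(as.vector(Matrix::colSums(A)) == 0)

#' Decode a glomerular pattern into third-order neuron activity
#'
#' Computes `s_hat = H(W' x - theta_r)` with `H(0) = 1`. Since the columns of
#' W sum to 1, `(W' x)_i` is the fraction of component i's connected glomeruli
#' that are active, and `theta_r = 1` is the logical AND. The comparison uses
#' a relative tolerance of 1e-12 so exact rational fractions k/d survive
#' floating-point accumulation at the `theta_r = 1` boundary. Zero-degree
#' components are always 0.
#'
#' @param W Reconstruction matrix from [build_reconstruction_matrix()].
#' @param x Binary glomerular pattern of length M.
#' @param theta_r Recovery threshold in `(0, 1]` (0 allowed as boundary).
#' @return Integer 0/1 vector of length N.
#' @export
decode <- function(W, x, theta_r = 1) {
  check_dims(W, x = x)
  if (theta_r < 0 || theta_r > 1) {
    abort("theta_r must lie in [0, 1]", class = "olfcs_invalid_threshold")
  }
  v <- as.vector(Matrix::crossprod(W, x))
  deg_pos <- as.vector(Matrix::colSums(W)) > 0
  as.integer(deg_pos & (v >= theta_r * (1 - 1e-12)))
}

#' Run the full encode/decode pipeline and account errors
#'
#' Composes [encode()], [build_reconstruction_matrix()] and [decode()] and
#' counts false positives (`s_hat = 1` where `s0 = 0`) and misses
#' (`s_hat = 0` where `s0 = 1`). An active component with glomerular degree
#' zero is unrecoverable and counts as a miss.
#'
#' @param config An [model_config()].
#' @param A Optional affinity matrix; sampled from `config` if missing.
#' @param s0 Optional odor signal; sampled from `config` if missing.
#' @return An object of class `odor_reconstruction`: a list with elements
#'   `values`, `s0`, `n_false_positives`, `n_misses`, `zero_degree`.
#' @export
#' @examples
#' cfg <- model_config(N = 50, M = 20, K = 2, p = 1 / 3, seed = 7)
#' r <- reconstruct(cfg)
#' glance(r)
reconstruct <- function(config, A = NULL, s0 = NULL) {
  stopifnot(inherits(config, "olf_config"))
  if (is.null(A)) {
    sd_A <- if (!is.null(config$seed)) child_seed(config$seed, 1) else NULL
    A <- sample_affinity(config$M, config$N, config$p, seed = sd_A)
  }
  if (is.null(s0)) {
    sd_s <- if (!is.null(config$seed)) child_seed(config$seed, 2) else NULL
    s0 <- sample_odor(config$N, config$K, seed = sd_s)
  }
  if (nrow(A) != config$M || ncol(A) != config$N || length(s0) != config$N) {
    abort("config inconsistent with A / s0 dimensions", class = "olfcs_shape_error")
  }
  x <- encode(A, s0, config$theta_c)
  W <- build_reconstruction_matrix(A)
  s_hat <- decode(W, x, config$theta_r)
  structure(
    list(values = s_hat, s0 = s0,
         n_false_positives = sum(s_hat == 1L & s0 == 0L),
         n_misses = sum(s_hat == 0L & s0 == 1L),
         zero_degree = attr(W, "zero_degree")),
    class = "odor_reconstruction"
  )
}

#' @export
print.odor_reconstruction <- function(x, ...) {
  cat(sprintf("<odor_reconstruction> N = %d, ||s_hat||_0 = %d, false positives = %d, misses = %d\n",
              length(x$values), sum(x$values), x$n_false_positives, x$n_misses))
  invisible(x)
}

#' @rdname reconstruct
#' @param x An `odor_reconstruction`.
#' @param ... Unused.
#' @export
tidy.odor_reconstruction <- function(x, ...) {
  tibble(component = seq_along(x$values),
         truth = as.integer(x$s0),
         estimate = as.integer(x$values),
         outcome = dplyr::case_when(
           x$s0 == 1L & x$values == 1L ~ "hit",
           x$s0 == 1L & x$values == 0L ~ "miss",
           x$s0 == 0L & x$values == 1L ~ "false_positive",
           TRUE ~ "correct_reject"))
}

#' @rdname reconstruct
#' @export
glance.odor_reconstruction <- function(x, ...) {
  tibble(n_components = length(x$values),
         k_true = sum(x$s0),
         n_false_positives = x$n_false_positives,
         n_misses = x$n_misses,
         l1_error = x$n_false_positives + x$n_misses,
         n_zero_degree = length(x$zero_degree))
}
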