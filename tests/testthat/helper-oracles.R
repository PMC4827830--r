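# Independent oracles used across the suite. These stay deliberately naive:
# explicit set logic, exhaustive enumeration, and a second (proximal
# gradient) LASSO solver, none of which share code with the package paths
# they check.

# Set-logic codec: active glomeruli are the union of the columns of the
# support; at threshold theta a unit fires iff at least theta * degree of its
# glomeruli are active (H(0)=1 convention => ">=").
oracle_codec <- function(A, s0, theta_c = 1, theta_r = 1) {
  A <- as.matrix(A)
  supp <- which(s0 == 1)
  counts_glom <- rowSums(A[, supp, drop = FALSE])
  x <- as.integer(counts_glom >= theta_c)
  s_hat <- integer(ncol(A))
  for (i in seq_len(ncol(A))) {
    gset <- which(A[, i] == 1)
    if (length(gset) > 0 && sum(x[gset]) >= theta_r * length(gset)) {
      s_hat[i] <- 1L
    }
  }
  list(x = x, s_hat = s_hat)
}

# Exact false-detection probability for one inactive component by exhaustive
# enumeration over every binary matrix of its column and the K active
# columns (M rows, K+1 columns => 2^(M*(K+1)) equally structured terms,
# weighted by the Bernoulli(p) measure), conditioned on the inactive
# component having nonzero degree.
oracle_p_false_enum <- function(p, K, M) {
  ncols <- K + 1
  nbits <- M * ncols
  num <- 0
  den <- 0
  for (code in 0:(2^nbits - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(nbits)]
    A <- matrix(bits, nrow = M, ncol = ncols)
    w <- prod(ifelse(A == 1, p, 1 - p))
    target <- ncols # the inactive component
    deg <- sum(A[, target])
    if (deg == 0) next
    x <- as.integer(rowSums(A[, seq_len(K), drop = FALSE]) >= 1)
    fires <- all(x[A[, target] == 1] == 1)
    den <- den + w
    num <- num + w * fires
  }
  num / den
}

# Proximal-gradient (ISTA) solver for 1/(2M)||x - As||^2 + beta ||s||_1,
# independent of the coordinate-descent path.
oracle_lasso_ista <- function(A, x, beta, max_iter = 20000, tol = 1e-12) {
  A <- as.matrix(A)
  M <- nrow(A)
  L <- (svd(A, nu = 0, nv = 0)$d[1])^2 / M
  s <- numeric(ncol(A))
  obj <- function(s) sum((x - A %*% s)^2) / (2 * M) + beta * sum(abs(s))
  o_prev <- obj(s)
  for (it in seq_len(max_iter)) {
    g <- crossprod(A, as.vector(A %*% s) - x) / M
    u <- s - g / L
    s <- sign(u) * pmax(abs(u) - beta / L, 0)
    o <- obj(s)
    if (abs(o_prev - o) < tol * max(o_prev, 1e-12)) break
    o_prev <- o
  }
  list(s_hat = as.vector(s), objective = obj(s))
}

# All K-subsets of 1:N as a list of supports (small N only).
all_supports <- function(N, K) {
  combn(N, K, simplify = FALSE)
}
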