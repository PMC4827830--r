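#' Continuous-valued generalization of the codec
#'
#' In the continuous extension the odor components and the affinity-matrix
#' entries may take any nonnegative value, and the glomerular output passes
#' through a strictly increasing activation `g`:
#' `x_j = g((A s0)_j)`. Decoding replaces the logical AND with a minimum:
#' `s_hat_i = min over {j : A_ji != 0} of g^{-1}(x_j) / A_ji`, which never
#' underestimates the true component and is exact whenever some glomerulus
#' sees component i uncorrupted.
#'
#' @param A Nonnegative real M x N affinity matrix.
#' @param s0 Nonnegative real signal of length N.
#' @param g Strictly increasing activation function (default identity).
#' @param g_inv Its inverse; if `NULL`, a monotone bisection fallback is used.
#' @return An object of class `continuous_model`.
#' @export
#' @examples
#' m <- continuous_model(matrix(c(1, 2), 2, 1), s0 = 3)
#' decode_min(m, encode_continuous(m))
continuous_model <- function(A, s0, g = identity, g_inv = identity) {
  A <- as.matrix(A)
  if (any(A < 0)) abort("A must be nonnegative", class = "olfcs_invalid_model")
  if (any(s0 < 0)) abort("s0 must be nonnegative", class = "olfcs_invalid_model")
  check_dims(A, s0 = s0)
  structure(list(A = A, s0 = as.numeric(s0), g = g, g_inv = g_inv),
            class = "continuous_model")
}

invert_monotone <- function(g, y, lower = 0, upper = 1) {
  vapply(y, function(yi) {
    up <- upper
    while (g(up) < yi && up < 1e12) up <- up * 2
    stats::uniroot(function(z) g(z) - yi, lower = lower, upper = up,
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Encode a continuous signal through the activation function
#'
#' @param model A [continuous_model()].
#' @return Real glomerular output vector `g(A s0)` of length M.
#' @export
encode_continuous <- function(model) {
  stopifnot(inherits(model, "continuous_model"))
  out <- model$g(as.vector(model$A %*% model$s0))
  if (any(!is.finite(out))) abort("activation g returned non-finite values",
                                  class = "olfcs_invalid_model")
  out
}

#' Min-operator decoder for the continuous model
#'
#' `s_hat_i = min_j { g^{-1}(x_j) / A_ji : A_ji != 0 }`. Since
#' `g^{-1}(x_j) = sum_k A_jk s0_k >= A_ji s0_i`, every ratio upper-bounds the
#' true value: the decoder never underestimates, and equals `s0_i` exactly
#' when some connected glomerulus receives no other active input. Components
#' with no connection at all are unrecoverable: output 0, flagged in the
#' `"unrecoverable"` attribute.
#'
#' @param model A [continuous_model()].
#' @param x Real glomerular vector (from [encode_continuous()]).
#' @return Numeric vector of length N with attribute `unrecoverable`.
#' @export
decode_min <- function(model, x) {
  stopifnot(inherits(model, "continuous_model"))
  A <- model$A
  check_dims(A, x = x)
  ginv_x <- if (!is.null(model$g_inv)) model$g_inv(x) else invert_monotone(model$g, x)
  N <- ncol(A)
  s_hat <- numeric(N)
  zero_deg <- integer(0)
  for (i in seq_len(N)) {
    j <- which(A[, i] != 0)
    if (length(j) == 0) {
      zero_deg <- c(zero_deg, i)
    } else {
      s_hat[i] <- min(ginv_x[j] / A[j, i])
    }
  }
  attr(s_hat, "unrecoverable") <- zero_deg
  s_hat
}

#' Effective feedforward affinity of a feedback circuit
#'
#' A glomerular layer with linear dynamics
#' `x' = -x + A s0 - B'z`, `z' = -z + B x` (excitatory feedforward,
#' inhibitory feedback through interneurons z) settles to
#' `x = (I + B'B)^{-1} A s0`: the circuit behaves like a pure feedforward
#' system with affinity `(I + B'B)^{-1} A`. Computed with a linear solve, no
#' explicit inverse; `I + B'B` is positive definite, so the solve always
#' succeeds.
#'
#' @param A Real M x N affinity matrix.
#' @param B Real interneuron coupling matrix with M columns (rows are
#'   interneurons).
#' @return The effective M x N affinity matrix.
#' @export
effective_affinity <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(B) != nrow(A)) {
    abort("B must have as many columns as A has rows", class = "olfcs_shape_error")
  }
  solve(diag(nrow(A)) + crossprod(B), A)
}

#' Integrate the feedback circuit to its steady state
#'
#' Forward-Euler integration of `x' = -x + A s0 - B'z`, `z' = -z + B x` until
#' the fixed-point residual drops below `tol`. The linear system is Hurwitz,
#' so it converges for any stable step; the step must satisfy
#' `dt < 2 / (1 + sigma_max(B)^2)`.
#'
#' @param A Real M x N affinity matrix.
#' @param B Interneuron coupling matrix.
#' @param s0 Signal vector of length N.
#' @param dt Integration step.
#' @param t_max Maximum integration time.
#' @param tol Residual norm declaring convergence.
#' @return Steady-state glomerular vector `x` of length M.
#' @export
steady_state_dynamics <- function(A, B, s0, dt = 0.05, t_max = 400, tol = 1e-10) {
  A <- as.matrix(A); B <- as.matrix(B)
  check_dims(A, s0 = s0)
  smax <- if (length(B) && any(B != 0)) max(svd(B)$d) else 0
  if (dt >= 2 / (1 + smax^2)) {
    abort(sprintf("dt = %g unstable: need dt < %g", dt, 2 / (1 + smax^2)),
          class = "olfcs_unstable_step")
  }
  drive <- as.vector(A %*% s0)
  x <- numeric(nrow(A)); z <- numeric(nrow(B))
  steps <- ceiling(t_max / dt)
  for (k in seq_len(steps)) {
    dx <- -x + drive - as.vector(crossprod(B, z))
    dz <- -z + as.vector(B %*% x)
    x <- x + dt * dx
    z <- z + dt * dz
    if (k %% 20 == 0 && sqrt(sum(dx^2) + sum(dz^2)) < tol) return(x)
  }
  res <- sqrt(sum((-x + drive - as.vector(crossprod(B, z)))^2))
  abort(sprintf("dynamics did not converge within t_max; residual %.3g", res),
        class = "olfcs_no_convergence")
}

#' Frozen parameters of the spiking min-operator demonstration
#'
#' Constants of the LIF + short-term-depression simulation, tuned once by
#' grid search so that the output rate approximates the minimum of the input
#' rates (see the methods vignette), then frozen.
#'
#' @format A named list: membrane time constant `tau_m` (s), threshold
#'   `v_th`, reset `v_reset`, refractory period `t_ref` (s), utilization `U`,
#'   depression recovery time constant `tau_rec` (s), synaptic time constant
#'   `tau_syn` (s), per-contact synaptic weight `w`, and the number of
#'   independent synaptic contacts per input channel `n_contacts` (the
#'   multi-claw connection from one glomerular channel).
#' @export
lif_stp_defaults <- list(
  tau_m = 0.0095, v_th = 1.0, v_reset = 0.0, t_ref = 0.001,
  U = 0.25, tau_rec = 0.65, tau_syn = 0.008, w = 0.005755, n_contacts = 48L
)

#' Configuration for the spiking min-operator simulation
#'
#' @param input_rates Presynaptic Poisson rates in Hz (one per synapse).
#' @param duration Simulated time in seconds; the rate is measured over the
#'   second half.
#' @param dt Time step in seconds; must resolve the fastest time constant
#'   (`dt <= 0.1 * min(tau_syn, tau_m)`).
#' @param params Synapse/neuron constants; defaults to [lif_stp_defaults].
#' @return An object of class `spiking_min_config`.
#' @export
spiking_min_config <- function(input_rates, duration = 20, dt = 2e-4,
                               params = lif_stp_defaults) {
  if (any(input_rates < 0)) abort("rates must be >= 0", class = "olfcs_invalid_model")
  stopifnot(dt > 0, duration > 10 * params$tau_rec)
  if (dt > 0.1 * min(params$tau_syn, params$tau_m)) {
    abort("dt too coarse: need dt <= 0.1 * min(tau_syn, tau_m)",
          class = "olfcs_invalid_dt")
  }
  structure(list(input_rates = as.numeric(input_rates), duration = duration,
                 dt = dt, params = params),
            class = "spiking_min_config")
}

#' Output rate of an LIF neuron with depressing synapses
#'
#' Simulates independent Poisson spike trains through
#' utilization/recovery-type depressing synapses into a leaky
#' integrate-and-fire neuron and returns the steady-state output rate
#' (measured over the second half of the run). With the frozen default
#' parameters the output approximates the *minimum* of the input rates — the
#' spiking implementation of the min-operator decoder: a silent input keeps
#' the neuron silent, and the depressed high-rate synapses contribute a
#' near-rate-invariant drive so the least active input limits the output.
#'
#' @param config A [spiking_min_config()].
#' @param seed Optional seed.
#' @return Output firing rate in Hz.
#' @export
#' @examples
#' \donttest{
#' lif_stp_output_rate(spiking_min_config(c(10, 50, 80)), seed = 1)
#' }
lif_stp_output_rate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "spiking_min_config"))
  p <- config$params
  with_seed_if(seed,
    lif_stp_sim(config$input_rates, p$tau_m, p$v_th, p$v_reset, p$t_ref,
                p$U, p$tau_rec, p$tau_syn, p$w, config$duration, config$dt,
                as.integer(p$n_contacts)))
}
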