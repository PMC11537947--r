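#' Sigmoidal output nonlinearity
#'
#' Maps the field's internal state to output activity,
#' `a_i = 1 / (1 + exp(-beta * u_i))`, elementwise.  Activity is bounded in
#' (0, 1) and strictly increasing in the internal state.
#'
#' @param u numeric vector of internal state values.
#' @param beta sigmoid steepness (> 0).
#' @return Numeric vector of activities, same length as `u`.
#' @export
#' @examples
#' sigmoid_activation(0, 0.09)            # 0.5
#' sigmoid_activation(-30, 0.09)          # ~0.063
sigmoid_activation <- function(u, beta) {
  stopifnot(beta > 0)
  if (any(!is.finite(u))) stop("non-finite internal state")
  1 / (1 + exp(-beta * u))
}

#' Toroidal distance between two field positions
#'
#' Distance on a circular (toroidal) feature space of the given period:
#' the shorter of the direct and the wrap-around separation.  Used both
#' for the lateral-interaction kernel and for the component-input kernels,
#' avoiding boundary effects at the field edges.
#'
#' @param x1,x2 positions (mm); vectorized.
#' @param period torus circumference (mm), e.g. 10 for a 100-node field at
#'   0.1 mm spacing.
#' @return Non-negative distances, at most `period / 2`.
#' @export
toroidal_distance <- function(x1, x2, period) {
  stopifnot(period > 0)
  d <- abs(x1 - x2) %% period
  pmin(d, period - d)
}

#' Lateral-interaction weight matrix
#'
#' Builds the N x N weight matrix coupling field nodes:
#' `G_ij = sf * exp(-(min(|i-j|, N-|i-j|) * dx)^2 / (2 sigma^2))`,
#' `W = (G - m) * dx` with `m = m_frac * max(G)`.  The Gaussian is
#' evaluated on the toroidal node-index distance scaled to mm, so `W` is
#' symmetric and circulant: positive (excitatory) for nearby nodes,
#' negative (inhibitory) for distant ones.  With the default constants the
#' diagonal is `(74.7 - 0.8 * 74.7) * 0.1 = 1.494` and the far field
#' approaches `-5.976`; the sign change falls at a node separation of
#' about 0.57 mm.
#'
#' @param constants a [model_constants()] object.
#' @return An `n_nodes` x `n_nodes` numeric matrix.
#' @export
build_interaction_matrix <- function(constants) {
  validate_constants(constants)
  n <- constants$n_nodes
  idx <- seq_len(n) - 1L
  # circulant: distances of every node from node 1, in index space with
  # period N, then scaled to mm
  d_idx <- pmin(idx, n - idx)
  d_mm <- d_idx * constants$dx_mm
  g_row <- constants$sf * exp(-d_mm^2 / (2 * constants$sigma_mm^2))
  m <- constants$m_frac * max(g_row)
  w_row <- (g_row - m) * constants$dx_mm
  # row j is row 0 rotated by j
  w <- matrix(0, n, n)
  for (j in seq_len(n)) {
    w[j, ] <- w_row[((idx - (j - 1L)) %% n) + 1L]
  }
  w
}

#' Initial field state at trial start
#'
#' Both the internal-state vector and (through the sigmoid) the output
#' activity are reset before every trial: `u = reset_value` (default -30,
#' a negative membrane-potential-like value) at every node, so trials are
#' independent of one another.
#'
#' @param constants a [model_constants()] object.
#' @return An object of class `field_state`: list with internal state `u`,
#'   activity `a`, and current time `t_ms`.
#' @export
field_state_init <- function(constants) {
  u <- rep(constants$reset_value, constants$n_nodes)
  structure(list(
    u = u,
    a = sigmoid_activation(u, constants$beta),
    t_ms = 0
  ), class = "field_state")
}

#' One-millisecond leaky-integrator update
#'
#' Advances the field state by one time step:
#' `u <- (1 - dt/tau) * u + (dt/tau) * (c_ext + W %*% a)`,
#' then recomputes `a = sigmoid(u)` and advances the clock.  The lateral
#' contribution `c_int = W %*% a` is always derived from the current
#' activity; activity itself is an instantaneous function of the internal
#' state, never integrated separately.
#'
#' @param state a `field_state` (see [field_state_init()]).
#' @param c_ext external drive vector (sum of the component inputs) at the
#'   current time, length `n_nodes`.
#' @param W lateral-interaction matrix from [build_interaction_matrix()].
#' @param constants a [model_constants()] object.
#' @return The updated `field_state`.
#' @export
integrate_step <- function(state, c_ext, W, constants) {
  n <- constants$n_nodes
  if (length(state$u) != n || length(c_ext) != n || !all(dim(W) == n)) {
    stop("vector/matrix length mismatch with n_nodes")
  }
  lambda <- constants$dt_ms / constants$tau_ms
  c_int <- as.numeric(W %*% state$a)
  u_new <- (1 - lambda) * state$u + lambda * (c_ext + c_int)
  structure(list(
    u = u_new,
    a = sigmoid_activation(u_new, constants$beta),
    t_ms = state$t_ms + constants$dt_ms
  ), class = "field_state")
}
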