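#' Fixed constants of the collicular field model
#'
#' Bundles every fixed parameter of the one-dimensional neural field that
#' emulates the intermediate superior colliculus: the discretization of the
#' collicular surface, the leaky-integrator dynamics, the sigmoidal output
#' nonlinearity, the lateral-interaction kernel, and the saccade-initiation
#' rule.  All arguments have the model's standard defaults and can be
#' overridden individually or loaded from a flat key-value configuration
#' file (see [read_config()]).
#'
#' The field spans `field_extent_mm` (default -5 to +5 mm of collicular
#' surface) with `n_nodes` nodes at spacing `dx_mm = 10 / n_nodes`; the
#' feature space is toroidal, so the two extremes are identified.  Internal
#' state evolves as a leaky integrator with time constant `tau_ms` on a
#' `dt_ms` grid; output activity is the sigmoid of the internal state with
#' steepness `beta`.  Lateral interactions use a Gaussian of width
#' `sigma_mm` scaled by `sf` and shifted down by `m_frac` of its maximum,
#' producing short-range excitation and long-range inhibition.  A saccade
#' is initiated when output activity at any non-central node (more than
#' `noncentral_radius_mm` from the foveal center) reaches `threshold`.
#'
#' @param n_nodes number of field nodes (N).
#' @param field_extent_mm length-2 numeric, field limits in mm.
#' @param dt_ms integration time step in ms.
#' @param tau_ms leaky-integrator time constant in ms.
#' @param beta sigmoid steepness.
#' @param sigma_mm width (s.d.) of the lateral-interaction Gaussian, mm.
#' @param sf scale factor of the lateral-interaction Gaussian.
#' @param m_frac inhibitory shift as a fraction of the Gaussian maximum;
#'   the shift applied is `m = m_frac * max(G)`.
#' @param threshold output-activity level that triggers saccade initiation.
#' @param reset_value initial internal state at trial start (negative,
#'   membrane-potential-like).
#' @param noncentral_radius_mm radius of the central (foveal) zone excluded
#'   from threshold detection, mm.
#' @param timeout_ms maximum simulated time after target onset, ms.
#' @param kernel_amp amplitude of the component-input spatial kernel.
#' @param kernel_gamma_mm s.d. of the component-input spatial kernel, mm.
#'
#' @return An object of class `model_constants`: a named list with the
#'   fields above plus the derived node spacing `dx_mm` and node positions
#'   `positions_mm`.
#' @export
#' @examples
#' mc <- model_constants()
#' mc$dx_mm          # 0.1 mm
#' range(mc$positions_mm)
model_constants <- function(n_nodes = 100L,
                            field_extent_mm = c(-5, 5),
                            dt_ms = 1,
                            tau_ms = 4,
                            beta = 0.09,
                            sigma_mm = 0.85,
                            sf = 74.7,
                            m_frac = 0.8,
                            threshold = 0.7,
                            reset_value = -30,
                            noncentral_radius_mm = 1.0,
                            timeout_ms = 500,
                            kernel_amp = 1.05,
                            kernel_gamma_mm = 0.6) {
  n_nodes <- as.integer(n_nodes)
  span <- diff(field_extent_mm)
  dx <- span / n_nodes
  mc <- structure(list(
    n_nodes = n_nodes,
    field_extent_mm = as.numeric(field_extent_mm),
    dx_mm = dx,
    dt_ms = dt_ms,
    tau_ms = tau_ms,
    beta = beta,
    sigma_mm = sigma_mm,
    sf = sf,
    m_frac = m_frac,
    threshold = threshold,
    reset_value = reset_value,
    noncentral_radius_mm = noncentral_radius_mm,
    timeout_ms = timeout_ms,
    kernel_amp = kernel_amp,
    kernel_gamma_mm = kernel_gamma_mm,
    # node i sits at the left extent plus (i-1) spacings; the right extent
    # is identified with the left one on the torus
    positions_mm = field_extent_mm[1] + (seq_len(n_nodes) - 1) * dx
  ), class = "model_constants")
  validate_constants(mc)
  mc
}

validate_constants <- function(mc) {
  stopifnot(
    inherits(mc, "model_constants"),
    mc$n_nodes >= 2,
    isTRUE(all.equal(mc$dx_mm * mc$n_nodes, diff(mc$field_extent_mm))),
    mc$threshold > 0, mc$threshold < 1,
    mc$tau_ms > mc$dt_ms,
    mc$reset_value < 0,
    mc$sigma_mm > 0,
    mc$sf > 0,
    mc$m_frac >= 0, mc$m_frac <= 1,
    mc$beta > 0,
    mc$timeout_ms > 0,
    mc$kernel_amp > 0,
    mc$kernel_gamma_mm > 0
  )
  invisible(mc)
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Collicular field model constants\n")
  cat(sprintf("  field: %d nodes over [%g, %g] mm (dx = %g mm, toroidal)\n",
              x$n_nodes, x$field_extent_mm[1], x$field_extent_mm[2], x$dx_mm))
  cat(sprintf("  dynamics: dt = %g ms, tau = %g ms, beta = %g\n",
              x$dt_ms, x$tau_ms, x$beta))
  cat(sprintf("  interaction: sigma = %g mm, sf = %g, m = %g * max(G)\n",
              x$sigma_mm, x$sf, x$m_frac))
  cat(sprintf("  saccade rule: activity >= %g at |x| > %g mm; reset u = %g\n",
              x$threshold, x$noncentral_radius_mm, x$reset_value))
  invisible(x)
}

#' Indices of non-central field nodes
#'
#' Nodes farther than `noncentral_radius_mm` from the field center are
#' eligible for saccade-initiation threshold detection; the central zone
#' represents the fovea and is excluded.
#'
#' @param constants a [model_constants()] object.
#' @return Integer vector of node indices.
#' @export
noncentral_nodes <- function(constants) {
  which(abs(constants$positions_mm) > constants$noncentral_radius_mm)
}
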