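#' Gap-task trial timeline
#'
#' Events of a gap-saccade trial: fixation onset at time 0, fixation point
#' offset (gap onset) after the fixation period, target onset after the
#' gap period.  The default periods are 200 ms each, with the target at
#' 6 degrees eccentricity mapped to +/- 2 mm on the collicular surface.
#'
#' @param target_position_mm signed field position of the target (mm);
#'   positive is rightward.
#' @param fixation_ms duration of the fixation period (ms).
#' @param gap_ms duration of the gap period (ms).
#' @param constants a [model_constants()] object (supplies the timeout).
#' @return An object of class `trial_timeline`.
#' @export
trial_timeline <- function(target_position_mm = 2,
                           fixation_ms = 200,
                           gap_ms = 200,
                           constants = model_constants()) {
  stopifnot(fixation_ms > 0, gap_ms > 0,
            abs(target_position_mm) <= max(abs(constants$field_extent_mm)))
  structure(list(
    fixation_onset_ms = 0,
    gap_onset_ms = fixation_ms,
    target_onset_ms = fixation_ms + gap_ms,
    target_position_mm = target_position_mm,
    timeout_ms = constants$timeout_ms
  ), class = "trial_timeline")
}

#' Spatial kernel of a component input
#'
#' Gaussian spatial profile centered at a field position, evaluated on the
#' toroidal feature space: `kappa_i = amp * exp(-d_i^2 / (2 gamma^2))`
#' with `d_i` the toroidal distance of node i from the center.  Defaults
#' `amp = 1.05`, `gamma = 0.6` mm.
#'
#' @param center_mm kernel center (mm).
#' @param constants a [model_constants()] object.
#' @return Numeric vector of length `n_nodes`, peaking at `amp` over the
#'   center node.
#' @export
spatial_kernel <- function(center_mm, constants) {
  period <- diff(constants$field_extent_mm)
  d <- toroidal_distance(constants$positions_mm, center_mm, period)
  constants$kernel_amp * exp(-d^2 / (2 * constants$kernel_gamma_mm^2))
}

# Canonical ids/names of the eight component inputs
INPUT_NAMES <- c("visual_transient", "automated_motor", "automated_fixation",
                 "voluntary_motor", "voluntary_fixation",
                 "voluntary_preparation", "inhibitory_gate",
                 "peripheral_inhibition")

# The per-ms update of an input is kappa * (RoR / 100) * dt: RoR percent
# converts to absolute drive units per millisecond, independent of the
# input's maximum strength (so a 1% rate takes 100 ms per drive unit and
# reaching a cap of 8 at 10% takes 80 ms).
ror_rate <- function(ror) ror / 100

#' Construct one component-input specification
#'
#' Internal constructor; see [make_trial_inputs()] for the semantics of
#' the eight inputs.
#'
#' @param input_id integer 1-8.
#' @param polarity +1 excitatory, -1 inhibitory.
#' @param profile one of `"ramp_decay"`, `"ramp_sustain"`,
#'   `"rise_hold_release"`, `"ramp_uncapped"`, `"gate_release"`,
#'   `"peripheral_release"`.
#' @param onset_ms absolute onset time (ms from fixation onset).
#' @param release_ms absolute time at which a releasing profile starts its
#'   decline (`NA` for profiles that do not release).
#' @param ror rate of response, percent of `maxval` per ms.
#' @param maxval maximum strength (drive units; `Inf` for the uncapped
#'   voluntary-motor input).
#' @param centers_mm one or two kernel centers (mm); ignored by the
#'   field-wide and peripheral profiles except where noted.
#' @return An object of class `input_spec`.
#' @keywords internal
input_spec <- function(input_id, polarity, profile, onset_ms,
                       release_ms = NA_real_, ror, maxval, centers_mm) {
  stopifnot(input_id %in% 1:8, polarity %in% c(-1, 1), ror >= 0,
            is.na(maxval) || maxval >= 0)
  structure(list(
    input_id = as.integer(input_id),
    name = INPUT_NAMES[input_id],
    polarity = polarity,
    profile = profile,
    onset_ms = onset_ms,
    release_ms = release_ms,
    ror = ror,
    maxval = maxval,
    centers_mm = centers_mm
  ), class = "input_spec")
}

# Scalar temporal profile of an input, vectorized over absolute times tvec.
# Returns magnitudes (non-negative); polarity is applied when the value
# field is assembled.
input_temporal <- function(spec, tvec) {
  s <- pmax(0, tvec - spec$onset_ms)
  M <- spec$maxval
  rate <- ror_rate(spec$ror)
  switch(spec$profile,
    ramp_decay = {
      # burst: rise to the cap, then decay at the same per-ms rate to a
      # sustained plateau at half the cap (transient riding on a
      # sustained visual response)
      pmax(pmin(rate * s, M, 2 * M - rate * s), M / 2 * (rate * s >= M / 2))
    },
    ramp_sustain = {
      pmin(rate * s, M)
    },
    rise_hold_release = {
      rel <- pmax(0, tvec - spec$release_ms)
      pmax(0, pmin(rate * s, M) - rate * rel)
    },
    ramp_uncapped = {
      rate * s
    },
    gate_release = ,
    peripheral_release = {
      # released amount since the release event, capped at full strength
      rel <- pmax(0, tvec - spec$release_ms)
      pmin(rate * rel, M)
    },
    stop("unknown profile: ", spec$profile)
  )
}

# Spatial structure of an input's drive.  For the separable profiles this
# is a single vector multiplied by the temporal scalar; the inhibitory
# gate and the peripheral inhibition combine a static inhibitory floor
# with a spatially windowed release, handled in input_value_matrix().
input_spatial <- function(spec, constants) {
  ks <- lapply(spec$centers_mm, spatial_kernel, constants = constants)
  Reduce(`+`, ks)
}

#' Drive contribution of one input over a time grid
#'
#' Evaluates a component input's signed value field at each requested
#' time, as an `n_nodes` x `length(tvec)` matrix.  Excitatory inputs are
#' elementwise non-negative, inhibitory inputs non-positive.
#'
#' @param spec an `input_spec`.
#' @param tvec absolute times (ms from fixation onset).
#' @param constants a [model_constants()] object.
#' @return Numeric matrix, nodes by times.
#' @export
input_value_matrix <- function(spec, tvec, constants) {
  v <- input_temporal(spec, tvec)
  M <- spec$maxval
  if (spec$profile == "gate_release") {
    # inhibition barrier at -maxval over the non-central motor map from
    # trial start, released toward 0 under a kernel-shaped window
    # (normalized to peak 1) centered on the target
    w <- input_spatial(spec, constants) / constants$kernel_amp
    mask <- as.numeric(abs(constants$positions_mm) >
                         constants$noncentral_radius_mm)
    out <- outer(-M * mask, rep(1, length(tvec))) + outer(mask * w, v)
    pmin(out, 0)
  } else if (spec$profile == "peripheral_release") {
    # inhibition over all non-central nodes, zero centrally; releases
    # uniformly at the input's rate
    mask <- as.numeric(abs(constants$positions_mm) >
                         constants$noncentral_radius_mm)
    outer(mask, pmin(v - M, 0))
  } else {
    spec$polarity * outer(input_spatial(spec, constants), v)
  }
}

#' Instantaneous state of one component input
#'
#' Evaluates an input at a single time point, returning its signed value
#' field together with a phase marker (`pre_onset`, `rising`, `saturated`,
#' `releasing` or `released`).  The inputs are deterministic functions of
#' time given their specification, so the state is computed directly
#' rather than integrated.
#'
#' @param spec an `input_spec`.
#' @param t absolute time (ms from fixation onset).
#' @param constants a [model_constants()] object.
#' @return An object of class `input_state`: list with `value` (length
#'   `n_nodes`), `phase`, `t_ms` and the originating `spec`.
#' @export
input_update <- function(spec, t, constants) {
  value <- as.numeric(input_value_matrix(spec, t, constants))
  phase <- input_phase(spec, t)
  structure(list(value = value, phase = phase, t_ms = t, spec = spec),
            class = "input_state")
}

input_phase <- function(spec, t) {
  M <- spec$maxval
  releasing_profiles <- c("rise_hold_release", "gate_release",
                          "peripheral_release", "ramp_decay")
  if (spec$profile %in% c("gate_release", "peripheral_release")) {
    if (is.na(spec$release_ms) || t < spec$release_ms) return("saturated")
    if (ror_rate(spec$ror) * (t - spec$release_ms) >= M) return("released")
    return("releasing")
  }
  if (t < spec$onset_ms) return("pre_onset")
  v <- input_temporal(spec, t)
  rising_peak <- if (spec$profile == "ramp_uncapped") Inf else M
  if (spec$profile %in% releasing_profiles &&
      !is.na(spec$release_ms) && t >= spec$release_ms) {
    return(if (v <= 0) "released" else "releasing")
  }
  if (spec$profile == "ramp_decay") {
    rate <- ror_rate(spec$ror)
    peak_t <- spec$onset_ms + M / rate
    if (t > peak_t) {
      # decaying toward the sustained plateau at half the cap
      return(if (v <= M / 2) "saturated" else "releasing")
    }
  }
  if (v >= rising_peak) "saturated" else "rising"
}

#' Assemble the external drive from input states
#'
#' The external contribution to the field is the elementwise sum of the
#' eight signed component-input value fields at a common time.
#'
#' @param states list of `input_state` objects at the same time.
#' @return Numeric drive vector.
#' @export
assemble_external_drive <- function(states) {
  if (length(states) == 0) stop("no input states supplied")
  ts <- vapply(states, function(s) s$t_ms, numeric(1))
  if (length(unique(ts)) != 1) stop("input states are at different times")
  Reduce(`+`, lapply(states, function(s) s$value))
}

#' Configure the eight component inputs for one trial
#'
#' Maps a sampled parameter assignment onto fully specified component
#' inputs on the gap-task timeline:
#'
#' 1. *Visual transient* — excitatory burst at the target, referenced to
#'    target onset; rises to its cap and decays at the same rate to a
#'    sustained plateau at half the cap.
#' 2. *Automated motor* — externally triggered motor command at the
#'    target, referenced to target onset; rises and sustains.
#' 3. *Automated fixation* — foveally centered; rises from its onset after
#'    fixation onset and releases from gap onset (the foveated stimulus
#'    disappears).
#' 4. *Voluntary motor* — internally triggered command at the target,
#'    uncapped ramp from the internal onset.
#' 5. *Voluntary fixation* — foveally centered hold from fixation onset,
#'    releasing from the internal onset (voluntary disengagement).
#' 6. *Voluntary preparation* — excitatory at both potential target
#'    locations, building through the gap; its rate is tied to its
#'    maximum strength so the cap is reached in 100 ms, at target onset.
#' 7. *Inhibitory gate* — inhibition barrier over the non-central motor
#'    map from trial start, selectively released under a target-centered
#'    window from the internal onset.
#' 8. *Peripheral inhibition* — inhibition over all non-central nodes,
#'    released field-wide from the internal onset.
#'
#' Inputs 4, 5, 7 and 8 share one jointly drawn internal onset delay,
#' referenced to target onset (the express/regular cut-off).
#'
#' @param assignment named numeric vector of sampled attribute values (see
#'   [sample_trial_parameters()]).
#' @param timeline a [trial_timeline()].
#' @param constants a [model_constants()] object.
#' @return List of 8 `input_spec` objects, one per component input.
#' @export
make_trial_inputs <- function(assignment, timeline, constants) {
  need <- c("vt_onset", "vt_ror", "vt_maxval", "am_onset", "am_ror",
            "am_maxval", "af_onset", "af_ror", "af_maxval", "vm_ror",
            "vf_onset", "vf_ror", "vf_maxval", "vp_maxval", "ig_ror",
            "ig_maxval", "pi_ror", "pi_maxval", "internal_onset")
  missing <- setdiff(need, names(assignment))
  if (length(missing) > 0) {
    stop("assignment missing attribute(s): ", paste(missing, collapse = ", "))
  }
  a <- as.list(assignment)
  tgt <- timeline$target_position_mm
  t_fix <- timeline$fixation_onset_ms
  t_gap <- timeline$gap_onset_ms
  t_tgt <- timeline$target_onset_ms
  t_int <- t_tgt + a$internal_onset
  list(
    input_spec(1L, +1, "ramp_decay", t_tgt + a$vt_onset,
               ror = a$vt_ror, maxval = a$vt_maxval, centers_mm = tgt),
    input_spec(2L, +1, "ramp_sustain", t_tgt + a$am_onset,
               ror = a$am_ror, maxval = a$am_maxval, centers_mm = tgt),
    input_spec(3L, +1, "rise_hold_release", t_fix + a$af_onset,
               release_ms = t_gap, ror = a$af_ror, maxval = a$af_maxval,
               centers_mm = 0),
    input_spec(4L, +1, "ramp_uncapped", t_int,
               ror = a$vm_ror, maxval = Inf, centers_mm = tgt),
    input_spec(5L, +1, "rise_hold_release", t_fix + a$vf_onset,
               release_ms = t_int, ror = a$vf_ror, maxval = a$vf_maxval,
               centers_mm = 0),
    # preparation builds through the gap toward both candidate locations;
    # its rate is tied to its maximum strength so the cap is reached in
    # 100 ms, i.e. exactly at target onset for a 200 ms gap minus the
    # 100 ms buildup window
    input_spec(6L, +1, "ramp_sustain", t_gap + 100,
               ror = a$vp_maxval, maxval = a$vp_maxval,
               centers_mm = c(tgt, -tgt)),
    input_spec(7L, -1, "gate_release", t_fix, release_ms = t_int,
               ror = a$ig_ror, maxval = a$ig_maxval, centers_mm = tgt),
    input_spec(8L, -1, "peripheral_release", t_fix, release_ms = t_int,
               ror = a$pi_ror, maxval = a$pi_maxval, centers_mm = tgt)
  )
}

#' External drive matrix for a whole trial
#'
#' Precomputes the summed external drive `c_ext` for every millisecond of
#' a trial, from fixation onset to `target_onset + timeout`, as an
#' `n_nodes` x T matrix (column k holds the drive at time k-1 ms).
#'
#' @param assignment named numeric parameter assignment.
#' @param timeline a [trial_timeline()].
#' @param constants a [model_constants()] object.
#' @return Numeric matrix of drives.
#' @export
trial_drive_matrix <- function(assignment, timeline, constants) {
  specs <- make_trial_inputs(assignment, timeline, constants)
  t_end <- timeline$target_onset_ms + timeline$timeout_ms
  tvec <- seq(0, t_end - 1, by = constants$dt_ms)
  Reduce(`+`, lapply(specs, input_value_matrix, tvec = tvec,
                     constants = constants))
}
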