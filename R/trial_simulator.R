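#' Run one deterministic trial of the field model
#'
#' Simulates a single gap-task trial: the field starts at the reset state
#' (`u = reset_value` everywhere), the eight component inputs configured
#' from the parameter assignment drive the field in 1-ms leaky-integrator
#' steps, and the trial ends at the first millisecond any non-central
#' node's output activity reaches the initiation threshold, or at
#' `target_onset + timeout_ms` with no saccade.  The SRT is the crossing
#' time minus target onset (negative for pre-target crossings).  All
#' stochasticity lives in the parameter sampling; given the assignment
#' and timeline the trial is fully deterministic.
#'
#' Ties across nodes at the first crossing millisecond are broken by
#' largest activity, then smallest node index.
#'
#' @param assignment named numeric parameter assignment (see
#'   [sample_trial_parameters()]).
#' @param timeline a [trial_timeline()].
#' @param constants a [model_constants()] object.
#' @param W optional precomputed [build_interaction_matrix()] (rebuilt if
#'   `NULL`); pass it when running many trials.
#' @return An object of class `trial_result`: list with `srt_ms` (integer
#'   or `NA`), `direction` (`"left"`, `"right"` or `"none"`),
#'   `crossing_node`, `crossing_time_ms`, `no_saccade`, and the
#'   `assignment`.
#' @export
run_trial <- function(assignment, timeline, constants = model_constants(),
                      W = NULL) {
  if (is.null(W)) W <- build_interaction_matrix(constants)
  drive <- trial_drive_matrix(assignment, timeline, constants)
  nc <- noncentral_nodes(constants)
  core <- simulate_field(drive, W, constants, nc)
  if (is.na(core$crossing_time_ms)) {
    res <- list(srt_ms = NA_integer_, direction = "none",
                crossing_node = NA_integer_,
                crossing_time_ms = NA_integer_,
                no_saccade = TRUE, assignment = assignment)
  } else {
    x <- constants$positions_mm[core$crossing_node]
    res <- list(
      srt_ms = as.integer(core$crossing_time_ms -
                            timeline$target_onset_ms),
      direction = if (x > 0) "right" else "left",
      crossing_node = core$crossing_node,
      crossing_time_ms = as.integer(core$crossing_time_ms),
      no_saccade = FALSE, assignment = assignment
    )
  }
  structure(res, class = "trial_result")
}

# Tight integration loop over a precomputed drive matrix.  Threshold is
# checked on the internal state (the sigmoid is monotone, so
# a >= threshold  <=>  u >= logit(threshold) / beta).
simulate_field <- function(drive, W, constants, nc) {
  n <- constants$n_nodes
  lambda <- constants$dt_ms / constants$tau_ms
  beta <- constants$beta
  u_thr <- log(constants$threshold / (1 - constants$threshold)) / beta
  u <- rep(constants$reset_value, n)
  a <- 1 / (1 + exp(-beta * u))
  n_steps <- ncol(drive)
  for (k in seq_len(n_steps)) {
    u <- (1 - lambda) * u + lambda * (drive[, k] + as.numeric(W %*% a))
    a <- 1 / (1 + exp(-beta * u))
    u_nc <- u[nc]
    if (any(u_nc >= u_thr)) {
      over <- nc[u_nc >= u_thr]
      node <- over[order(-u[over], over)][1]
      return(list(crossing_time_ms = k * constants$dt_ms,
                  crossing_node = node, u = u, a = a))
    }
  }
  list(crossing_time_ms = NA_integer_, crossing_node = NA_integer_,
       u = u, a = a)
}

#' Simulate a batch of randomly parameterized trials
#'
#' Draws `n_trials` independent parameter assignments from a species/step
#' grid (target side left/right with equal probability), simulates each
#' trial, and collects the SRT sample.  The no-saccade fraction is stored
#' in the sample's metadata.
#'
#' @param config a [step_config()] (e.g. from [builtin_step_configs()]).
#' @param n_trials number of trials.
#' @param seed integer RNG seed (the batch is reproducible given the seed
#'   and config).
#' @param constants a [model_constants()] object.
#' @return An object of classes `srt_sample`/`data.frame` with columns
#'   `trial`, `srt_ms`, `direction`, `crossing_node`, `no_saccade`, and
#'   attributes `species`, `step`, `seed`, `n_trials`,
#'   `no_saccade_fraction`.
#' @export
run_batch <- function(config, n_trials, seed = 1L,
                      constants = model_constants()) {
  stopifnot(inherits(config, "step_config"), n_trials >= 0)
  set.seed(seed)
  W <- build_interaction_matrix(constants)
  target_ecc <- 2  # mm; 6 deg eccentricity on the collicular map
  srt <- integer(n_trials)
  direction <- character(n_trials)
  node <- integer(n_trials)
  nosac <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    assignment <- sample_trial_parameters(config)
    side <- if (stats::runif(1) < 0.5) -1 else 1
    tl <- trial_timeline(target_position_mm = side * target_ecc,
                         constants = constants)
    tr <- run_trial(assignment, tl, constants, W = W)
    srt[i] <- if (tr$no_saccade) NA_integer_ else tr$srt_ms
    direction[i] <- tr$direction
    node[i] <- if (tr$no_saccade) NA_integer_ else tr$crossing_node
    nosac[i] <- tr$no_saccade
  }
  out <- data.frame(trial = seq_len(n_trials), srt_ms = srt,
                    direction = direction, crossing_node = node,
                    no_saccade = nosac, stringsAsFactors = FALSE)
  structure(out,
            class = c("srt_sample", "data.frame"),
            species = config$species, step = config$step,
            seed = seed, n_trials = n_trials,
            no_saccade_fraction = if (n_trials > 0) mean(nosac) else 0)
}

#' @export
print.srt_sample <- function(x, ...) {
  sp <- attr(x, "species"); st <- attr(x, "step")
  cat(sprintf("SRT sample: %d trials%s\n", nrow(x),
              if (!is.null(sp)) sprintf(" (%s, step %s, seed %s)",
                                        sp, st, attr(x, "seed")) else ""))
  ok <- x$srt_ms[!is.na(x$srt_ms)]
  if (length(ok) > 0) {
    cat(sprintf("  median SRT %g ms, range [%g, %g] ms, no-saccade %.2f%%\n",
                stats::median(ok), min(ok), max(ok),
                100 * mean(is.na(x$srt_ms))))
  }
  NextMethod()
}
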