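#' Attribute table of the parameter space
#'
#' Maps each variable attribute name to its component input and parameter
#' kind.  The `internal_onset` attribute is a joint group: one drawn value
#' is shared by the five internally driven inputs (4-8).
#'
#' @return Data frame with columns `attribute`, `input_id`, `kind`,
#'   `joint_group`.
#' @export
attribute_table <- function() {
  data.frame(
    attribute = c("vt_onset", "vt_ror", "vt_maxval",
                  "am_onset", "am_ror", "am_maxval",
                  "af_onset", "af_ror", "af_maxval",
                  "vm_ror",
                  "vf_onset", "vf_ror", "vf_maxval",
                  "vp_maxval",
                  "ig_ror", "ig_maxval",
                  "pi_ror", "pi_maxval",
                  "internal_onset"),
    input_id = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 5L, 5L, 5L,
                 6L, 7L, 7L, 8L, 8L, NA_integer_),
    kind = c("onset", "ror", "maxval", "onset", "ror", "maxval",
             "onset", "ror", "maxval", "ror", "onset", "ror", "maxval",
             "maxval", "ror", "maxval", "ror", "maxval", "onset"),
    joint_group = c(rep(NA_character_, 18), "internal_onset"),
    stringsAsFactors = FALSE
  )
}

#' Construct a species/step parameter grid
#'
#' A step configuration holds one ordered level set per attribute of the
#' trial-wise controlled variability (singleton sets are fixed
#' attributes).  The jointly varying internal onset delay appears once and
#' is mirrored to inputs 4-8 when trials are built.
#'
#' @param species `"marmoset"` or `"human"`.
#' @param step modification step (1-3 for marmoset, 1-2 for human).
#' @param levels named list of strictly increasing numeric level sets; the
#'   names must cover [attribute_table()].
#' @return An object of class `step_config`.
#' @export
step_config <- function(species, step, levels) {
  species <- match.arg(species, c("marmoset", "human"))
  need <- attribute_table()$attribute
  missing <- setdiff(need, names(levels))
  if (length(missing) > 0) {
    stop("levels missing attribute(s): ", paste(missing, collapse = ", "))
  }
  for (nm in need) {
    v <- levels[[nm]]
    if (length(v) == 0 || any(!is.finite(v))) {
      stop("empty or non-finite level set for ", nm)
    }
    if (is.unsorted(v, strictly = TRUE)) {
      stop("level set for ", nm, " must be strictly increasing")
    }
  }
  structure(list(species = species, step = as.integer(step),
                 levels = levels[need]),
            class = "step_config")
}

#' @export
print.step_config <- function(x, ...) {
  cat(sprintf("Parameter grid: %s, step %d (%s combinations)\n",
              x$species, x$step,
              format(enumerate_combination_count(x), big.mark = ",")))
  for (nm in names(x$levels)) {
    cat(sprintf("  %-15s %s\n", nm, paste(x$levels[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Size of a parameter grid
#'
#' Number of distinct parameter assignments: the product over attributes
#' of the number of levels, with each joint group counted once (the
#' internal onset is a single attribute shared by inputs 4-8).
#'
#' @param config a [step_config()].
#' @return The combination count as a double (exact for these grid sizes).
#' @export
#' @examples
#' enumerate_combination_count(builtin_step_configs("marmoset", 3))
#' # 3,779,136 = 3^10 * 4^3
enumerate_combination_count <- function(config) {
  stopifnot(inherits(config, "step_config"))
  prod(vapply(config$levels, length, integer(1)))
}

#' Draw one trial's parameter assignment
#'
#' Samples each attribute independently and uniformly from its level set
#' (one draw for the joint internal onset, mirrored to inputs 4-8 when
#' the trial is built).  Uses the current RNG state; seed outside for
#' reproducibility.
#'
#' @param config a [step_config()].
#' @return Named numeric vector with one value per attribute.
#' @export
sample_trial_parameters <- function(config) {
  stopifnot(inherits(config, "step_config"))
  vapply(config$levels, function(v) v[sample.int(length(v), 1L)], numeric(1))
}

#' Built-in species/step parameter grids
#'
#' Loads the packaged grid for a species and cumulative modification
#' step from its configuration file (`inst/extdata/configs/`).  Step 1
#' applies the species-specific internal onset delays to the originating
#' gap-task grid; step 2 adds the visual-response changes; step 3
#' (marmoset only) adds the variable-inhibition changes.  Each step
#' includes all previous steps' modifications.  The files are the
#' editable source of the level sets and can be copied and modified; use
#' [read_step_config()] to load a modified copy.
#'
#' @param species `"marmoset"` or `"human"`.
#' @param step 1-3 for marmoset, 1-2 for human.
#' @return A [step_config()].
#' @export
builtin_step_configs <- function(species, step) {
  species <- match.arg(species, c("marmoset", "human"))
  step <- as.integer(step)
  max_step <- if (species == "marmoset") 3L else 2L
  if (!(step %in% seq_len(max_step))) {
    stop("unknown step ", step, " for species ", species)
  }
  path <- system.file("extdata", "configs",
                      sprintf("%s_step%d.cfg", species, step),
                      package = "sacfield", mustWork = TRUE)
  read_step_config(path)
}

#' Read a parameter grid from a key-value configuration file
#'
#' @param path configuration file with `attribute = v1,v2,...` lines plus
#'   `species` and `step` entries (see the packaged files under
#'   `system.file("extdata", "configs", package = "sacfield")`).
#' @return A [step_config()].
#' @export
read_step_config <- function(path) {
  kv <- read_config(path)
  species <- kv$species
  step <- as.integer(kv$step)
  kv$species <- NULL
  kv$step <- NULL
  levels <- lapply(kv, as.numeric)
  step_config(species, step, levels)
}
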