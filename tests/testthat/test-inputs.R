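mc <- model_constants()
tl <- trial_timeline(2, constants = mc)

test_that("spatial kernel peaks at amp over the center and is symmetric", {
  k <- spatial_kernel(2, mc)
  ctr <- which.min(abs(mc$positions_mm - 2))
  expect_equal(k[ctr], 1.05)
  expect_equal(max(k), 1.05)
  # value at toroidal distance 0.6 mm (one kernel s.d.)
  expect_equal(k[ctr + 6], 1.05 * exp(-0.5), tolerance = 1e-6)
  expect_equal(1.05 * exp(-0.5), 0.6368, tolerance = 1e-3)
  # even function of distance around the center
  expect_equal(k[ctr + 1:5], k[ctr - 1:5])
})

test_that("inputs are zero before their onset and rise at kappa * ror/100 per ms", {
  asg <- base_assignment()
  specs <- make_trial_inputs(asg, tl, mc)
  # every input is zero well before fixation/gap/target events fire
  for (sp in specs[c(1, 2, 4, 6)]) {
    st <- input_update(sp, 5, mc)
    expect_equal(st$value, rep(0, mc$n_nodes))
    expect_equal(st$phase, "pre_onset")
  }
  # visual transient 5 ms after onset: 5 * 0.15 = 0.75 drive units,
  # scaled by the kernel amplitude at the center node
  vt <- specs[[1]]
  t5 <- tl$target_onset_ms + asg[["vt_onset"]] + 5
  st <- input_update(vt, t5, mc)
  ctr <- which.min(abs(mc$positions_mm - 2))
  expect_equal(st$value[ctr], 1.05 * 5 * 0.15)
  expect_equal(st$phase, "rising")
  # at the cap the center node carries kappa * maxval
  am <- specs[[2]]
  tcap <- tl$target_onset_ms + asg[["am_onset"]] + 100 / 0.08 + 5
  stc <- input_update(am, tcap, mc)
  expect_equal(stc$value[ctr], 1.05 * asg[["am_maxval"]])
  expect_equal(stc$phase, "saturated")
})

test_that("the visual transient decays to its half-cap plateau at the rise rate", {
  asg <- base_assignment(vt_ror = 20, vt_maxval = 8)
  vt <- make_trial_inputs(asg, tl, mc)[[1]]
  ctr <- which.min(abs(mc$positions_mm - 2))
  onset <- tl$target_onset_ms + asg[["vt_onset"]]
  rise <- 8 / 0.2                       # 40 ms to cap
  peak <- input_update(vt, onset + rise, mc)
  expect_equal(peak$value[ctr], 1.05 * 8)
  # decays at the same rate; plateau (half cap) reached after M/(2 rate)
  mid <- input_update(vt, onset + rise + 10, mc)
  expect_equal(mid$value[ctr], 1.05 * (8 - 0.2 * 10))
  late <- input_update(vt, onset + rise + 8 / (2 * 0.2) + 50, mc)
  expect_equal(late$value[ctr], 1.05 * 4)
  expect_equal(late$phase, "saturated")
})

test_that("value fields are polarity-consistent and the uncapped input is monotone", {
  asg <- base_assignment()
  specs <- make_trial_inputs(asg, tl, mc)
  tt <- seq(0, tl$target_onset_ms + tl$timeout_ms - 1, by = 7)
  for (sp in specs) {
    vals <- input_value_matrix(sp, tt, mc)
    if (sp$polarity > 0) expect_true(all(vals >= 0)) else
      expect_true(all(vals <= 0))
    if (is.finite(sp$maxval)) {
      # two-center kernels overlap by a vanishing toroidal tail (~1e-9)
      expect_true(all(abs(vals) <= mc$kernel_amp * sp$maxval + 1e-6))
    }
  }
  # voluntary motor never decreases until trial end
  vm <- input_value_matrix(specs[[4]], tt, mc)
  ctr <- which.min(abs(mc$positions_mm - 2))
  expect_true(all(diff(vm[ctr, ]) >= 0))
})

test_that("external drive assembly sums fields and cancels opposite inputs", {
  asg <- base_assignment()
  specs <- make_trial_inputs(asg, tl, mc)
  states <- lapply(specs, input_update, t = 450, constants = mc)
  drv <- assemble_external_drive(states)
  expect_equal(drv, Reduce(`+`, lapply(states, `[[`, "value")))
  # single excitatory input passes through unchanged
  expect_equal(assemble_external_drive(states[2]), states[[2]]$value)
  # equal-magnitude excitation and inhibition at one center cancel
  ex <- sacfield:::input_spec(2L, +1, "ramp_sustain", 0, ror = 10,
                              maxval = 4, centers_mm = 1)
  s1 <- input_update(ex, 200, mc)
  s2 <- s1; s2$value <- -s1$value
  expect_equal(assemble_external_drive(list(s1, s2)), rep(0, mc$n_nodes))
  expect_error(assemble_external_drive(list()), "no input states")
  s3 <- input_update(ex, 100, mc)
  expect_error(assemble_external_drive(list(s1, s3)), "different times")
})

test_that("internally driven inputs 4, 5, 7, 8 share the joint internal onset", {
  asg <- base_assignment(internal_onset = 125)
  specs <- make_trial_inputs(asg, tl, mc)
  t_int <- tl$target_onset_ms + 125
  expect_equal(specs[[4]]$onset_ms, t_int)
  expect_equal(specs[[5]]$release_ms, t_int)
  expect_equal(specs[[7]]$release_ms, t_int)
  expect_equal(specs[[8]]$release_ms, t_int)
  expect_error(make_trial_inputs(asg[-1], tl, mc), "missing attribute")
})

test_that("disabling the inhibitory inputs never lengthens the crossing time", {
  W <- build_interaction_matrix(mc)
  asg <- base_assignment()
  with_inh <- run_trial(asg, tl, mc, W = W)
  without <- run_trial(base_assignment(ig_maxval = 0, pi_maxval = 0),
                       tl, mc, W = W)
  expect_false(without$no_saccade)
  expect_lte(without$srt_ms, with_inh$srt_ms)
})

test_that("the drive matrix equals the summed per-millisecond input states", {
  asg <- base_assignment()
  drive <- trial_drive_matrix(asg, tl, mc)
  specs <- make_trial_inputs(asg, tl, mc)
  for (t in c(0, 150, 250, 399, 430, 520, 640)) {
    states <- lapply(specs, input_update, t = t, constants = mc)
    expect_equal(drive[, t + 1], assemble_external_drive(states))
  }
})
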