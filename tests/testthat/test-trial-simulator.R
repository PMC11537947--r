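mc <- model_constants()
tl <- trial_timeline(2, constants = mc)
W <- build_interaction_matrix(mc)

test_that("a trial with all excitatory drive disabled never saccades", {
  asg <- base_assignment(vt_maxval = 0, am_maxval = 0, af_maxval = 0,
                         vm_ror = 0, vf_maxval = 0, vp_maxval = 0)
  tr <- run_trial(asg, tl, mc, W = W)
  expect_true(tr$no_saccade)
  expect_equal(tr$direction, "none")
  expect_true(is.na(tr$srt_ms))
})

test_that("identical assignments give bitwise-identical trials", {
  asg <- base_assignment()
  t1 <- run_trial(asg, tl, mc, W = W)
  t2 <- run_trial(asg, tl, mc, W = W)
  expect_identical(t1, t2)
  expect_false(t1$no_saccade)
})

test_that("the simulator agrees with the independent reimplementation", {
  asg <- reference_assignment()
  tr <- run_trial(asg, tl, mc, W = W)
  ora <- oracle_trial(asg, target_mm = 2, timeout = mc$timeout_ms)
  expect_identical(tr$srt_ms, as.integer(ora$srt_ms))
  expect_identical(tr$crossing_node, ora$node)
  # and on a second, slow-inhibition assignment
  asg2 <- base_assignment(ig_ror = 1, pi_ror = 1, vm_ror = 1,
                          ig_maxval = 8, pi_maxval = 8, internal_onset = 125)
  tr2 <- run_trial(asg2, tl, mc, W = W)
  ora2 <- oracle_trial(asg2, target_mm = 2, timeout = mc$timeout_ms)
  expect_identical(tr2$srt_ms, as.integer(ora2$srt_ms))
})

test_that("mirroring the target yields the mirrored node and identical SRT", {
  asg <- base_assignment()
  right <- run_trial(asg, tl, mc, W = W)
  left <- run_trial(asg, trial_timeline(-2, constants = mc), mc, W = W)
  expect_equal(left$srt_ms, right$srt_ms)
  expect_equal(left$direction, "left")
  expect_equal(right$direction, "right")
  # positions are mirrored on the torus: x -> -x maps node i to the node
  # at the negated position
  expect_equal(mc$positions_mm[left$crossing_node],
               -mc$positions_mm[right$crossing_node])
})

test_that("visually driven crossings cannot precede the transient onset", {
  # voluntary motor disabled; crossing must come from the visual cascade
  asg <- base_assignment(vm_ror = 0, ig_maxval = 2, pi_maxval = 2,
                         vt_ror = 20, am_onset = 30, am_ror = 10,
                         am_maxval = 8, vp_maxval = 8)
  tr <- run_trial(asg, tl, mc, W = W)
  expect_false(tr$no_saccade)
  expect_gte(tr$srt_ms, asg[["vt_onset"]])
})

test_that("inhibitory-gate depth and transient rate act one-signed on SRT", {
  # ~20 single trials: gate/peripheral depth never shortens SRT, and in
  # the express regime a faster transient never lengthens it
  for (base in list(base_assignment(),
                    base_assignment(vt_ror = 20, am_onset = 30,
                                    am_ror = 10, am_maxval = 8,
                                    vm_ror = 20, vp_maxval = 8,
                                    ig_ror = 20, pi_ror = 20,
                                    vf_maxval = 2, internal_onset = 75))) {
    srt_ig <- vapply(c(2, 4, 6, 8), function(m) {
      run_trial(replace(base, "ig_maxval", m), tl, mc, W = W)$srt_ms
    }, numeric(1))
    expect_true(all(diff(srt_ig) >= 0))
    srt_pi <- vapply(c(2, 4, 6, 8), function(m) {
      run_trial(replace(base, "pi_maxval", m), tl, mc, W = W)$srt_ms
    }, numeric(1))
    expect_true(all(diff(srt_pi) >= 0))
  }
  express <- base_assignment(am_onset = 30, am_ror = 10, am_maxval = 8,
                             vm_ror = 20, vp_maxval = 8, ig_ror = 20,
                             pi_ror = 20, ig_maxval = 2, pi_maxval = 2,
                             vf_maxval = 2, internal_onset = 75)
  srt_vt <- vapply(c(5, 10, 15, 20), function(r) {
    run_trial(replace(express, "vt_ror", r), tl, mc, W = W)$srt_ms
  }, numeric(1))
  expect_true(all(diff(srt_vt) <= 0))
})

test_that("batches are empty-safe, reproducible and mostly saccade-producing", {
  cfg <- builtin_step_configs("marmoset", 2)
  b0 <- run_batch(cfg, 0, seed = 5)
  expect_equal(nrow(b0), 0)
  b1 <- run_batch(cfg, 40, seed = 5)
  b2 <- run_batch(cfg, 40, seed = 5)
  expect_identical(b1$srt_ms, b2$srt_ms)
  expect_identical(b1$direction, b2$direction)
  expect_lt(attr(b1, "no_saccade_fraction"), 0.05)
  expect_true(all(b1$direction %in% c("left", "right", "none")))
  # crossing nodes are non-central
  nodes <- b1$crossing_node[!is.na(b1$crossing_node)]
  expect_true(all(abs(mc$positions_mm[nodes]) > mc$noncentral_radius_mm))
})
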