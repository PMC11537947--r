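# Reference parameter assignment for the dual-implementation trial check:
# a mid-grid marmoset step-2 assignment, fixed so the simulated trial can
# be compared against an independent straight-line reimplementation of
# the field equations.
vt_onset = 20
vt_ror = 15
vt_maxval = 8
am_onset = 45
am_ror = 8
am_maxval = 6
af_onset = 45
af_ror = 10
af_maxval = 6
vm_ror = 10
vf_onset = 0
vf_ror = 10
vf_maxval = 6
vp_maxval = 6
ig_ror = 10
ig_maxval = 6
pi_ror = 10
pi_maxval = 6
internal_onset = 100
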