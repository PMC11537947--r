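# Human, modification step 1: the originating gap-task grid with the
# jointly varying internal onset delay (inputs 4-8) lowered to
# 100/115/130 ms.
species = human
step = 1
vt_onset = 50
vt_ror = 5,10,15
vt_maxval = 8
am_onset = 60
am_ror = 4,6,8
am_maxval = 4,6,8
af_onset = 60
af_ror = 10
af_maxval = 6
vm_ror = 5,10,15
vf_onset = 0
vf_ror = 10
vf_maxval = 4,6,8
vp_maxval = 4,6,8
ig_ror = 5,10,15
ig_maxval = 4,6,8
pi_ror = 5,10,15
pi_maxval = 4,6,8
internal_onset = 100,115,130
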