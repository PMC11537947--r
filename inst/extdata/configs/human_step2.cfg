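# Human, modification step 2 (cumulative over step 1): visual-transient
# RoR raised to 10/15/20% and automated motor / automated fixation onset
# delays varied over 60/75/90 ms, mirroring the marmoset treatment of
# inputs 1-2.
species = human
step = 2
vt_onset = 50
vt_ror = 10,15,20
vt_maxval = 8
am_onset = 60,75,90
am_ror = 4,6,8
am_maxval = 4,6,8
af_onset = 60,75,90
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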