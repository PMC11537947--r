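# Marmoset, modification step 3 (cumulative over steps 1-2): variable
# inhibition - minimum RoR of 1% for the inhibitory gate, peripheral
# inhibition and voluntary motor inputs (slow disengagement tail), and
# automated/voluntary fixation RoR set to 8%.
species = marmoset
step = 3
vt_onset = 20
vt_ror = 10,15,20
vt_maxval = 8
am_onset = 30,45,60
am_ror = 6,8,10
am_maxval = 4,6,8
af_onset = 30,45,60
af_ror = 8
af_maxval = 6
vm_ror = 1,10,20
vf_onset = 0
vf_ror = 8
vf_maxval = 2,4,6,8
vp_maxval = 4,6,8
ig_ror = 1,10,20
ig_maxval = 2,4,6,8
pi_ror = 1,10,20
pi_maxval = 2,4,6,8
internal_onset = 75,100,125
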