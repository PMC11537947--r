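# Marmoset, modification step 2 (cumulative over step 1): earlier and
# faster visual response (visual-transient onset 20 ms, RoR up to 20%;
# automated motor onset 30-60 ms, RoR 6-10%), weaker inhibition and
# fixation (weak MaxVal level 2 added for voluntary fixation, inhibitory
# gate and peripheral inhibition), faster disinhibition (gate/peripheral
# RoR up to 20%).
species = marmoset
step = 2
vt_onset = 20
vt_ror = 10,15,20
vt_maxval = 8
am_onset = 30,45,60
am_ror = 6,8,10
am_maxval = 4,6,8
af_onset = 30,45,60
af_ror = 10
af_maxval = 6
vm_ror = 5,10,15
vf_onset = 0
vf_ror = 10
vf_maxval = 2,4,6,8
vp_maxval = 4,6,8
ig_ror = 5,10,20
ig_maxval = 2,4,6,8
pi_ror = 5,10,20
pi_maxval = 2,4,6,8
internal_onset = 75,100,125
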