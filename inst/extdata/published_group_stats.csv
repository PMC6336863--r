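assay,label1,mean1,sem1,n1,label2,mean2,sem2,n2,printed_t
soma_area_um2,wt,257.7,16.2,39,het,216.2,11.19,33,2.031
total_outgrowth_um,wt,848.1,62.41,39,het,452.2,46.27,33,4.94
synaptic_puncta_per_50um,wt,11.16,0.4508,55,het,7.569,0.2818,51,6.643
social_approach_ratio,wt,1.457,0.060,20,het,1.575,0.175,20,0.6379
social_novelty_ratio,wt,1.573,0.130,20,het,1.021,0.078,20,3.643
social_preference_ratio,wt,1.599,0.149,20,het,1.187,0.108,20,2.24
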