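tissue,indicator,phantom_mean,phantom_sd,exponent
adipose,sf_triceps,15.4,4.47,1
adipose,sf_subscapular,17.2,5.07,1
adipose,sf_supraspinale,15.4,4.47,1
adipose,sf_abdominal,25.4,7.78,1
adipose,sf_front_thigh,27.0,8.33,1
adipose,sf_medial_calf,16.0,4.67,1
muscle,girth_arm_relaxed_corr,22.05195,2.33,1
muscle,girth_forearm,25.13,1.41,1
muscle,girth_chest_corr,82.45646,5.18,1
muscle,girth_thigh_corr,47.33770,4.23,1
muscle,girth_calf_corr,30.22345,2.30,1
bone,breadth_biacromial,38.04,1.92,1
bone,breadth_biiliocristal,28.84,1.75,1
bone,breadth_humerus,6.48,0.35,1
bone,breadth_femur,9.52,0.48,1
bone,breadth_wrist,5.21,0.28,1
residual,girth_waist,71.91,4.45,1
residual,girth_hip,94.67,5.58,1
skin,girth_head,56.00,1.44,1
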