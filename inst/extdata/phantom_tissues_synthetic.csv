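tissue,phantom_mass_kg,phantom_sd_kg
adipose,25.60,5.85
muscle,24.50,3.04
bone,10.49,1.57
residual,6.10,1.90
skin,3.30,0.30
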