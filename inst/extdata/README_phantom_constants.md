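# Phantom constants fixture (synthetic reconstruction)

Five-way tissue fractionation expresses every anthropometric indicator as a
z-score against a unisex "phantom" reference human (stature 170.18 cm), then
maps the mean tissue z-score back to a tissue mass and rescales it by the
cube of the stature ratio:

    z_i  = (x_i * (170.18 / height)^d_i - p_i) / s_i
    mass = (mean(z) * s_tissue + p_tissue) * (height / 170.18)^3

`phantom_indicators_synthetic.csv` lists, per tissue, the indicator
measurements with their phantom means/SDs and exponent d (all indicators here
are girths, breadths or skinfolds, so d = 1). Corrected girths subtract the
overlying skinfold: girth_cm - pi * skinfold_mm / 10.

`phantom_tissues_synthetic.csv` gives the phantom tissue masses and SDs.

**Provenance / "_synthetic" label.** The original tabulation of the method's
constants is not available in this environment. Indicator phantom means and
SDs follow the widely published phantom reference values; the tissue-mass
constants and the indicator-to-tissue assignment are a reconstruction that is
faithful to the method's structure (phantom identity and cubic scale laws
hold exactly) and produce tissue fractions in the ranges reported for lean
endurance athletes, but they are not a verified transcription of the original
source. Corrected-girth SDs reuse the uncorrected girth SDs (documented
approximation). Treat absolute tissue masses accordingly.

Both files are integrity-checked at load time with an md5 checksum embedded
in the package; a mismatch aborts rather than silently computing with edited
constants.
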