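# Template-generated (synthetic) receiver sensitivities
#
# receiver_sensitivities_template.csv: five cone sensitivity curves (uv, sw,
# mw, lw single cones and the dbl double cone) generated from A1 visual
# pigment templates at violet-sensitive-class peak wavelengths (432, 477,
# 537, 605, 565 nm). These are synthetic stand-ins, not measured curves;
# replace the file (same columns) to model a measured receiver via
# read_receiver_csv().
#
# illuminant_d65.csv: CIE standard illuminant D65 relative spectral power
# interpolated to the 300-700 nm working grid.
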