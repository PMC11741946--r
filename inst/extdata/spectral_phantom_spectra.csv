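wavelength_index,marker_mu_a,unknown_mu_a,background_mu_a
1,0.2,0.025,0.005
2,0.2,0.055,0.010
3,0.2,0.080,0.020
4,0.2,0.060,0.035
5,0.2,0.030,0.050
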