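# Molar extinction coefficients of oxy- (HbO) and deoxyhaemoglobin (HbR),
# units 1/(mM*cm), from the standard compiled haemoglobin absorption
# spectra (Gratzer/Cope compilation) as distributed with common fNIRS
# processing toolboxes; original values in 1/(M*cm) divided by 1000.
# Values between tabulated wavelengths are linearly interpolated; extend
# this table before using montage wavelengths outside 690-850 nm.
wavelength_nm	hbo_1_mM_cm	hbr_1_mM_cm
690	0.276	2.05196
760	1.4865865	3.843707
850	2.526391	1.798643
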