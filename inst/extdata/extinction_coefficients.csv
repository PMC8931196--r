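# Optical extinction coefficients used for spectral mixing and unmixing.
# Units: cm^-1 per arbitrary concentration unit.
# HbO2/HbR values are molar extinction coefficients from the standard
# Prahl/OMLC hemoglobin compilation scaled by 1e-3 (one concentration
# unit ~ 1 mmol/L heme), reproducing the isosbestic crossover: HbR
# dominates at 760 nm, HbO2 at 840/910 nm.
# Collagen and water are bundled effective spectra: their band shapes are
# qualitatively faithful (collagen dips near 840 nm and rises steeply
# toward its ~1030 nm band; water rises from 760 nm toward its ~970 nm
# peak), with values chosen so that the three-wavelength non-negative
# unmixing of the tissue compositions modelled here is well conditioned
# (see the methods vignette for the identifiability analysis). All
# package tests and simulations depend on this file only.
chromophore,wavelength_nm,epsilon
HbO2,760,0.586
HbO2,840,1.022
HbO2,910,1.204
HbR,760,1.549
HbR,840,0.693
HbR,910,0.732
collagen,760,0.025
collagen,840,0.020
collagen,910,0.105
water,760,0.020
water,840,0.055
water,910,0.065
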