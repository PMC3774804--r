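# Calibrated base rate constants (counts convention: first-order rates
# in 1/min, second-order in 1/molecule/min, one effective well-mixed box).
#
# In-vivo rate constants for these interactions are not measurable;
# these defaults were obtained with the calibration helper in
# tools/calibrate.R against the observed population kinetics:
# for M3 at Itk0 = 100, PIP3_0 = 370, PIP2_0 = 17000 the readout peaks
# near tau_p ~ 2 min with R ~ 2 and an amplitude of a few tens of
# molecules; the monomer feedback model yields intermediate asymmetry
# ratios and the no-feedback models much larger ones.

calibrated_base_rates <- function() {
  list(
    M1 = list(rates = c(k_on_low = 5e-3, k_off_low = 150, k_on_high = 0.1,
                        k_off_high = 1.5, k_cat = 4e-3), alpha = 2000),
    M2 = list(rates = c(k_on_low = 1e-2, k_off_low = 30, k_on_high = 0.1,
                        k_off_high = 0.15, k_cat = 2e-3), alpha = 2000),
    M3 = list(rates = c(k_on_low = 5e-3, k_off_low = 150, k_on_high = 0.1,
                        k_off_high = 1.5, k_cat = 2e-3), alpha = 2000),
    M4 = list(rates = c(k_on = 2e-3, k_off = 5, k_replace = 1e-2,
                        k_cat = 2e-3), alpha = NULL),
    M5 = list(rates = c(k_on = 5e-3, k_off = 5e-3, k_cat = 2e-3),
              alpha = NULL),
    M6 = list(rates = c(k_on = 5e-3, k_off = 5e-3, k_cat = 2e-3),
              alpha = NULL),
    M7 = list(rates = c(k_on_low = 1e-2, k_off_low = 20, k_on_high = 0.1,
                        k_off_high = 4, k_cat = 4e-3), alpha = 50)
  )
}
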