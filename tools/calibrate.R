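# Calibration helper for the shipped base rate constants.
#
# The targets (see the methods vignette): at Itk0 = 100, PIP3_0 = 370,
# PIP2_0 = 17000 the dimer feedback models should peak near tau_p ~ 2 min
# with asymmetry ratio R ~ 2 and amplitude in the tens of molecules; the
# monomer feedback model should give intermediate R (~20-120) and the
# no-feedback models much larger R (~100-700).  Run from the repository
# root after installing the package:
#
#     Rscript tools/calibrate.R
#
# It prints the shape statistics of every model at its current default
# base parameters and a coarse sweep around them; pick values meeting
# the targets and record them in R/calibration.R.

suppressPackageStartupMessages(library(itkmaxent))

shape_at <- function(model_id, params, Itk0 = 100, PIP3_0 = 370) {
  m <- build_model(model_id)
  tr <- integrate_ode(m, params, initial_state(m, Itk0, PIP3_0, 17000))
  s <- summarize_trajectory(tr)
  sprintf("A = %6.1f  tau_p = %6.2f  tau_w = %7.1f  R = %7.2f  [%s]",
          s$A, s$tau_p, s$tau_w, s$R, s$status)
}

cat("Current defaults at Itk0 = 100, PIP3_0 = 370:\n")
for (id in paste0("M", 1:7)) {
  cat(sprintf("  %s: %s\n", id, shape_at(id, default_base_params(id))))
}

cat("\nSweep: scale one base rate at a time by 1/4 and 4:\n")
for (id in paste0("M", 1:7)) {
  base <- default_base_params(id)
  free <- setdiff(names(base$rates),
                  if (!is.null(base$alpha)) "k_off_high" else character(0))
  for (nm in free) for (f in c(0.25, 4)) {
    p <- base
    p$rates[[nm]] <- p$rates[[nm]] * f
    cat(sprintf("  %s %-10s x%-4s %s\n", id, nm, f, shape_at(id, p)))
  }
}
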