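# Immunoblot-derived PLCgamma1 phosphorylation kinetics: densitometry
# normalization, shape summaries, and the printed population constants.

#' Densitometry time series
#'
#' @param times Minutes; must include t = 0 (the unstimulated baseline).
#' @param phospho,total Positive band intensities (arbitrary units) of
#'   the phospho-protein and total-protein channels.
#' @return A `densitometry_series` (data frame with columns `time_min`,
#'   `phospho_au`, `total_au` and, after [normalize_series()],
#'   `fold_change`).
#' @export
densitometry_series <- function(times, phospho, total) {
  n <- length(times)
  if (length(phospho) != n || length(total) != n) {
    stop("times, phospho and total must have equal length")
  }
  if (!any(times == 0)) stop("the series must include t = 0")
  if (any(!is.finite(phospho)) || any(!is.finite(total)) ||
      any(phospho <= 0) || any(total <= 0)) {
    stop("intensities must be positive and finite")
  }
  ord <- order(times)
  structure(data.frame(time_min = times[ord], phospho_au = phospho[ord],
                       total_au = total[ord]),
            class = c("densitometry_series", "data.frame"))
}

#' Normalize a densitometry series to fold change over unstimulated
#'
#' The phospho-channel intensity is first normalized to the total-protein
#' loading control, then expressed as fold change over the t = 0
#' (unstimulated) ratio:
#' `fold_change(t) = (phospho(t)/total(t)) / (phospho(0)/total(0))`,
#' so `fold_change(0) = 1` by construction.
#'
#' @param series A [densitometry_series()].
#' @return The series with a `fold_change` column.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "densitometry_series"))
  i0 <- which(series$time_min == 0)[1]
  ratio <- series$phospho_au / series$total_au
  series$fold_change <- ratio / ratio[i0]
  series
}

#' Summarize an experimental series with the peak-shape statistics
#'
#' Delegates to [summarize_trajectory()] on the fold-change series
#' (piecewise-linear interpolation between the sampled time points).
#'
#' @param series A normalized [densitometry_series()] (normalization is
#'   applied if the `fold_change` column is missing).
#' @return A `trajectory_summary`.
#' @export
summarize_experiment <- function(series) {
  stopifnot(inherits(series, "densitometry_series"))
  if (is.null(series$fold_change)) series <- normalize_series(series)
  summarize_trajectory(series$time_min, series$fold_change)
}

#' Printed peak statistics of the tetramer-stimulation experiments
#'
#' Peak time, peak width and asymmetry ratio of the population-level
#' PLCgamma1 phosphorylation kinetics for the four MHC-tetramer ligands
#' (decreasing TCR affinity: OVA > Q4R7 > Q4H7 > G4), as printed at one
#' decimal.
#'
#' @return Data frame with columns `ligand`, `tau_p`, `tau_w`, `R`.
#' @export
table2_fixture <- function() {
  data.frame(
    ligand = c("OVA", "Q4R7", "Q4H7", "G4"),
    tau_p = c(2.0, 2.0, 2.0, 2.0),
    tau_w = c(3.9, 8.6, 7.5, 4.3),
    R = c(1.9, 4.3, 3.8, 2.1),
    stringsAsFactors = FALSE)
}

#' Stimulus to initial-concentration map
#'
#' Initial Itk and PIP3 counts emulating each stimulation condition
#' (stronger stimulation = larger initial Itk and PIP3), with
#' PIP2_0 = 17000 throughout, plus the peak-time constraint preset used
#' with each condition.
#'
#' @return Read-only data frame with columns `stimulus`, `Itk0`,
#'   `PIP3_0`, `PIP2_0`, `tau_p_expt`.
#' @export
stimulus_map <- function() {
  data.frame(
    stimulus = c("OVA", "Q4R7", "Q4H7", "G4",
                 "anti-CD3 1ug/ml", "anti-CD3 5ug/ml",
                 "anti-CD3/CD4 5ug/ml"),
    Itk0   = c(140, 100, 40, 20, 40, 100, 140),
    PIP3_0 = c(530, 370, 130, 50, 130, 370, 530),
    PIP2_0 = 17000,
    tau_p_expt = c(2, 2, 2, 2, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Amplitude-target presets
#'
#' The amplitude constraint is a scanned axis, not a measured molecule
#' count (blot amplitudes are fold changes, related to molecule numbers
#' only through an assay-dependent proportionality constant).  These are
#' the default values scanned with each stimulus preset.
#'
#' @return Named list of numeric vectors of amplitude targets.
#' @export
amplitude_presets <- function() {
  list(
    OVA = 40, Q4R7 = 20, Q4H7 = 10, G4 = 3,
    `anti-CD3 1ug/ml` = 16, `anti-CD3 5ug/ml` = 60,
    `anti-CD3/CD4 5ug/ml` = 80)
}
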