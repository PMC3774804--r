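# Parameter/initial-condition ensembles representing extrinsic
# cell-to-cell variability, and batch evaluation of the shape statistics.

#' Ensemble configuration
#'
#' Defaults follow the study conditions: every free rate constant is
#' drawn uniformly (linear scale) between 1/10 and 10 times its base
#' value; the initial concentrations (Itk0, PIP3_0, PIP2_0) are drawn
#' uniformly within +/- 35 percent of their base values; for the dimer
#' feedback models the affinity ratio alpha is drawn uniformly over its
#' per-model range and the high-affinity off-rate is derived from it via
#' KD_low = alpha * KD_high.
#'
#' @param n_samples Number of parameter draws (the full-scale analysis
#'   uses 100,000; tests and examples use far fewer).
#' @param seed Integer seed; together with the config it fully
#'   determines the ensemble.
#' @param rate_span Multiplicative lower/upper bounds on each base rate.
#' @param conc_window Fractional half-width of the uniform window around
#'   each base initial concentration.
#' @param alpha_range Optional override of [default_alpha_range()].
#' @param base_params Optional override of [default_base_params()].
#' @param base_init Named vector with `Itk0`, `PIP3_0`, `PIP2_0`.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_samples = 100000, seed = 1,
                            rate_span = c(1 / 10, 10), conc_window = 0.35,
                            alpha_range = NULL, base_params = NULL,
                            base_init = c(Itk0 = 100, PIP3_0 = 370,
                                          PIP2_0 = 17000)) {
  stopifnot(n_samples >= 1, length(rate_span) == 2,
            rate_span[1] <= rate_span[2], rate_span[1] > 0,
            conc_window >= 0, conc_window < 1,
            all(c("Itk0", "PIP3_0", "PIP2_0") %in% names(base_init)))
  if (any(base_init <= 0)) stop("base initial concentrations must be positive")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 rate_span = rate_span, conc_window = conc_window,
                 alpha_range = alpha_range, base_params = base_params,
                 base_init = base_init), class = "ensemble_config")
}

#' Draw a parameter / initial-condition ensemble
#'
#' @param config An [ensemble_config()].
#' @param model_id One of "M1".."M7" (or an `itk_model`).
#' @return List of length `n_samples`; each element has `params` (a list
#'   with `rates` and `alpha`) and `init` (named `Itk0`, `PIP3_0`,
#'   `PIP2_0` values).  Fully reproducible from `config$seed`.
#' @export
draw_ensemble <- function(config, model_id) {
  stopifnot(inherits(config, "ensemble_config"))
  spec <- if (inherits(model_id, "itk_model")) model_id else
    build_model(model_id)
  base <- config$base_params
  if (is.null(base)) base <- default_base_params(spec$model_id)
  if (!is.null(spec$nuisance_base)) {
    base$rates <- c(base$rates, spec$nuisance_base)
  }
  has_alpha <- spec$model_id %in% FEEDBACK_DIMER_MODELS
  arange <- config$alpha_range
  if (is.null(arange) && has_alpha) {
    arange <- default_alpha_range(spec$model_id)
  }
  free <- setdiff(spec$rate_parameter_names,
                  if (has_alpha) "k_off_high" else character(0))
  if (any(base$rates[free] <= 0)) stop("base rates must be positive")
  n <- config$n_samples
  span <- config$rate_span
  w <- config$conc_window

  set.seed(config$seed)
  rate_draws <- sapply(free, function(nm) {
    runif(n, span[1] * base$rates[[nm]], span[2] * base$rates[[nm]])
  })
  rate_draws <- matrix(rate_draws, nrow = n,
                       dimnames = list(NULL, free))
  init_draws <- sapply(c("Itk0", "PIP3_0", "PIP2_0"), function(nm) {
    b <- config$base_init[[nm]]
    runif(n, (1 - w) * b, (1 + w) * b)
  })
  init_draws <- matrix(init_draws, nrow = n,
                       dimnames = list(NULL, c("Itk0", "PIP3_0", "PIP2_0")))
  alphas <- if (has_alpha) runif(n, arange[1], arange[2]) else rep(NA, n)

  lapply(seq_len(n), function(i) {
    list(params = list(rates = setNames(rate_draws[i, ], free),
                       alpha = if (has_alpha) alphas[i] else NULL),
         init = init_draws[i, ])
  })
}

#' Evaluate the shape statistics over an ensemble
#'
#' Integrates the deterministic rate equations for every sample and
#' reduces each trajectory with [summarize_trajectory()].  Solver
#' failures and non-OK shape statuses are recorded per sample, never
#' dropped; results are independent of evaluation order.
#'
#' @param spec An `itk_model`.
#' @param samples Output of [draw_ensemble()] for the same model.
#' @param sim_config A [sim_config()] (default configuration when
#'   `NULL`).
#' @param progress_every Print a progress line every this many samples
#'   (0 = silent).
#' @return An `observable_table`: data frame with columns `id`, `A`,
#'   `tau_p`, `tau_w`, `R`, `status`, plus attributes `model_id` and
#'   `n_samples`.
#' @export
evaluate_ensemble <- function(spec, samples, sim_config = NULL,
                              progress_every = 0) {
  stopifnot(inherits(spec, "itk_model"))
  if (is.null(sim_config)) sim_config <- itkmaxent::sim_config()
  n <- length(samples)
  A <- tau_p <- tau_w <- R <- rep(NA_real_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    res <- tryCatch({
      init <- initial_state(spec, s$init[["Itk0"]], s$init[["PIP3_0"]],
                            s$init[["PIP2_0"]])
      tr <- integrate_ode(spec, s$params, init, sim_config)
      summarize_trajectory(tr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- "FAILED"
    } else {
      A[i] <- res$A; tau_p[i] <- res$tau_p; tau_w[i] <- res$tau_w
      R[i] <- res$R; status[i] <- res$status
    }
    if (progress_every > 0 && i %% progress_every == 0) {
      message(spec$model_id, ": ", i, "/", n)
    }
  }
  tbl <- data.frame(id = seq_len(n), A = A, tau_p = tau_p, tau_w = tau_w,
                    R = R, status = status, stringsAsFactors = FALSE)
  attr(tbl, "model_id") <- spec$model_id
  attr(tbl, "n_samples") <- n
  class(tbl) <- c("observable_table", "data.frame")
  tbl
}

#' @export
print.observable_table <- function(x, ...) {
  cat(sprintf("<observable_table %s: %d samples, %d OK, %d censored, %d other>\n",
              attr(x, "model_id"), nrow(x), sum(x$status == "OK"),
              sum(x$status == "CENSORED_WIDTH"),
              sum(!x$status %in% c("OK", "CENSORED_WIDTH"))))
  NextMethod()
}

#' Write an observable table (with provenance) to CSV / JSON manifest
#'
#' @param tbl An `observable_table`.
#' @param file CSV path; a `.manifest.json` sidecar records the model id,
#'   seed and configuration hash when `config` is supplied.
#' @param config Optional `ensemble_config` used to generate the table.
#' @export
write_observable_csv <- function(tbl, file, config = NULL) {
  write.csv(as.data.frame(tbl), file, row.names = FALSE)
  if (!is.null(config)) {
    manifest <- list(model_id = attr(tbl, "model_id"),
                     n_samples = attr(tbl, "n_samples"),
                     seed = config$seed, config_hash = config_hash(config))
    jsonlite::write_json(manifest, paste0(file, ".manifest.json"),
                         auto_unbox = TRUE)
  }
  invisible(file)
}

config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
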