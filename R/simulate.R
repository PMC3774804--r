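# Deterministic (ODE) and exact stochastic (Gillespie) simulation of any
# itk_model.  Both paths share the compiled mass-action kernels in
# src/massaction.c.

#' Simulation configuration
#'
#' @param t_end Initial integration horizon in minutes.
#' @param n_grid Number of output grid points; the grid is logarithmic in
#'   time so that the peak time of a transient anywhere on the horizon is
#'   resolved to well under 1 percent.
#' @param rel_tol,abs_tol Solver tolerances.
#' @param horizon_policy `"extend_x2_until_decay"` doubles the horizon
#'   until the readout has fallen below half of its maximum (the
#'   no-feedback models can decay very slowly, leaving the peak width
#'   undefined on a fixed horizon); `"fixed"` integrates `t_end` only.
#' @param horizon_cap Hard cap (minutes) on horizon doubling; a readout
#'   still above half-maximum at the cap is flagged as censored.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(t_end = 200, n_grid = 1200, rel_tol = 1e-10,
                       abs_tol = 1e-10, horizon_policy = c(
                         "extend_x2_until_decay", "fixed"),
                       horizon_cap = 5000) {
  horizon_policy <- match.arg(horizon_policy)
  stopifnot(t_end > 0, rel_tol > 0, abs_tol > 0, horizon_cap >= t_end,
            n_grid >= 10)
  structure(list(t_end = t_end, n_grid = n_grid, rel_tol = rel_tol,
                 abs_tol = abs_tol, horizon_policy = horizon_policy,
                 horizon_cap = horizon_cap), class = "sim_config")
}

log_time_grid <- function(t_end, n_grid) {
  t0 <- min(0.01, t_end / 1000)
  c(0, exp(seq(log(t0), log(t_end), length.out = n_grid)))
}

pack_parms <- function(spec, params) {
  st <- model_stoich(spec)
  k <- reaction_rates(spec, params)
  c(nrow(st$S), ncol(st$S), k, st$re1, st$re2, as.numeric(st$S))
}

make_trajectory <- function(spec, times, counts, censored = FALSE) {
  structure(list(model_id = spec$model_id, times = times, counts = counts,
                 readout = active_count(spec, counts),
                 censored = censored), class = "itk_trajectory")
}

#' @export
print.itk_trajectory <- function(x, ...) {
  cat(sprintf(
    "<itk_trajectory %s: %d time points on [0, %.4g] min, peak readout %.4g%s>\n",
    x$model_id, length(x$times), max(x$times), max(x$readout),
    if (x$censored) ", censored" else ""))
  invisible(x)
}

integrate_once <- function(spec, parms, y0, times, config) {
  .Call("C_set_ma_parms", as.numeric(parms), PACKAGE = "itkmaxent")
  out <- lsoda(y = y0, times = times, func = "massaction_derivs",
               parms = NULL, dllname = "itkmaxent",
               initfunc = NULL,
               rtol = config$rel_tol, atol = config$abs_tol,
               maxsteps = 50000)
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times)) {
    stop(structure(class = c("itkmaxent_solver_error", "error", "condition"),
                   list(message = sprintf(
                     "ODE integration failed for %s (istate = %s)",
                     spec$model_id, istate), call = NULL)))
  }
  out[, -1, drop = FALSE]
}

#' Integrate the deterministic mass-action rate equations
#'
#' Stiff-capable integration (LSODA with a compiled right-hand side) of
#' the ODE system generated from the model's reaction list, with dense
#' output on a logarithmic time grid.  Under the default horizon policy
#' the horizon is doubled (up to `horizon_cap`) until the readout has
#' decayed below half of its running maximum, so that the peak width is
#' well defined; trajectories still above half-maximum at the cap are
#' returned with `censored = TRUE`.
#'
#' @param spec An `itk_model`.
#' @param params Parameter list as accepted by [complete_params()].
#' @param init Named initial-count vector from [initial_state()].
#' @param config A [sim_config()].
#' @param times Optional explicit output time grid (first element 0);
#'   overrides the logarithmic grid and disables horizon extension.
#' @return An `itk_trajectory`: times (min), species counts matrix,
#'   active-Itk `readout` series, and a `censored` flag.
#' @export
integrate_ode <- function(spec, params, init, config = sim_config(),
                          times = NULL) {
  stopifnot(inherits(spec, "itk_model"))
  parms <- pack_parms(spec, params)
  y0 <- init[spec$species$name]
  if (anyNA(y0) || any(y0 < 0)) stop("init must be nonnegative and named")
  if (!is.null(times)) {
    counts <- integrate_once(spec, parms, y0, times, config)
    return(make_trajectory(spec, times, counts))
  }
  t_end <- config$t_end
  repeat {
    times_i <- log_time_grid(t_end, config$n_grid)
    counts <- integrate_once(spec, parms, y0, times_i, config)
    readout <- active_count(spec, counts)
    decayed <- readout[length(readout)] < max(readout) / 2 ||
      max(readout) == 0
    if (decayed || config$horizon_policy == "fixed" ||
        t_end >= config$horizon_cap) {
      return(make_trajectory(spec, times_i, counts,
                             censored = !decayed &&
                               config$horizon_policy != "fixed"))
    }
    t_end <- min(2 * t_end, config$horizon_cap)
  }
}

#' Run one exact stochastic (Gillespie direct-method) realization
#'
#' Propensities are `k*n1*n2` for second-order reactions (`k*n*(n-1)`
#' for identical reactants) and `k*n` for first-order ones.  The sampler
#' consumes R's RNG stream, so results are reproducible via the `seed`
#' argument (or a surrounding `set.seed()` when `seed = NULL`).
#'
#' @param spec An `itk_model`.
#' @param params Parameter list.
#' @param init Named integer initial counts.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param t_end Horizon in minutes.
#' @param times Optional output grid (defaults to 400 uniform points).
#' @param max_events Guard on the total number of reaction events.
#' @return An `itk_trajectory` (piecewise-constant counts sampled on the
#'   grid).
#' @export
run_ssa <- function(spec, params, init, seed = NULL, t_end = 200,
                    times = NULL, max_events = 5e7) {
  stopifnot(inherits(spec, "itk_model"))
  y0 <- init[spec$species$name]
  if (anyNA(y0) || any(y0 < 0)) stop("init must be nonnegative and named")
  if (any(y0 != round(y0))) stop("SSA requires integer initial counts")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times)) times <- seq(0, t_end, length.out = 400)
  st <- model_stoich(spec)
  k <- reaction_rates(spec, params)
  res <- .Call("C_ssa_run", as.numeric(y0), as.numeric(k),
               as.integer(st$re1), as.integer(st$re2),
               matrix(as.numeric(st$S), nrow = nrow(st$S)),
               as.numeric(times), as.numeric(max_events),
               PACKAGE = "itkmaxent")
  if (!res$completed) {
    warning("SSA stopped early: max_events reached for ", spec$model_id)
  }
  counts <- res$counts
  colnames(counts) <- spec$species$name
  tr <- make_trajectory(spec, times, counts)
  tr$n_events <- res$n_events
  tr
}

#' Ensemble mean of stochastic realizations
#'
#' Runs `n_realizations` Gillespie realizations from one RNG stream and
#' returns the pointwise mean and standard error of the active-Itk
#' readout on a common grid.
#'
#' @inheritParams run_ssa
#' @param n_realizations Number of realizations (>= 1).
#' @return List with `times`, `mean`, `se` (zero when `n_realizations`
#'   is 1) and `n_realizations`.
#' @export
ssa_ensemble_mean <- function(spec, params, init, n_realizations, seed,
                              t_end = 200, times = NULL) {
  stopifnot(n_realizations >= 1)
  if (is.null(times)) times <- seq(0, t_end, length.out = 400)
  set.seed(seed)
  acc <- matrix(0, nrow = length(times), ncol = n_realizations)
  for (r in seq_len(n_realizations)) {
    tr <- run_ssa(spec, params, init, seed = NULL, t_end = t_end,
                  times = times)
    acc[, r] <- tr$readout
  }
  m <- rowMeans(acc)
  se <- if (n_realizations > 1) {
    apply(acc, 1, sd) / sqrt(n_realizations)
  } else {
    rep(0, length(times))
  }
  list(times = times, mean = m, se = se, n_realizations = n_realizations)
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_min`, one column per species, `readout`.
#' @param traj An `itk_trajectory`.
#' @param file Path.
#' @export
write_trajectory_csv <- function(traj, file) {
  df <- data.frame(time_min = traj$times, traj$counts,
                   readout = traj$readout, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @param spec The `itk_model` the trajectory belongs to.
#' @export
read_trajectory_csv <- function(file, spec) {
  df <- read.csv(file, check.names = FALSE)
  counts <- as.matrix(df[, spec$species$name, drop = FALSE])
  make_trajectory(spec, df$time_min, counts)
}
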