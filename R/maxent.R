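# Constrained maximum-entropy reweighting of a parameter ensemble and
# the Kullback-Leibler robustness score.
#
# Given observables f_i = (tau_p, R[, A]) for each valid ensemble sample
# and population-average targets c, the MaxEnt distribution over samples
# is the exponential tilt w_i proportional to exp(-lambda . f_i) whose
# weighted means hit the targets.  Its Kullback-Leibler distance to the
# uniform prior over the n valid samples, reported in log10 units,
# D_KL = sum_i w_i log10(w_i n), is the robustness score: the smaller it
# is, the less the parameter distribution must be distorted to satisfy
# the constraints, i.e. the more robust the model.  The Lagrange
# multipliers are found by Newton iteration on the convex dual
#   g(lambda) = log mean_i exp(-lambda . f_i) + lambda . c,
# whose gradient is c - E_w[f] and Hessian the weighted covariance of f.

#' Solve the constrained maximum-entropy reweighting
#'
#' @param table An `observable_table` (only rows with status `"OK"` and
#'   finite observables enter the fit; the rest are counted and
#'   excluded).
#' @param constraints Named numeric vector or list of population-average
#'   targets; names among `tau_p`, `R`, `A` (omit `A` for the
#'   no-amplitude variant).  All targets must be positive.
#' @param tol Convergence tolerance on the relative constraint
#'   residuals.
#' @param max_iter Newton iteration cap.
#' @return A `maxent_solution`: `lambdas` (on the original observable
#'   scale), `weights` (per valid sample, summing to 1),
#'   `log_partition`, `entropy_S` (natural-log entropy), `D_KL` (log10
#'   units), `converged`, `feasible`, `residuals` (relative), `n_valid`,
#'   `n_excluded`.  Targets outside the sample range of any observable
#'   give `feasible = FALSE` with `D_KL = NA` (never a silent large
#'   number).
#' @export
solve_maxent <- function(table, constraints, tol = 1e-6, max_iter = 200) {
  constraints <- unlist(constraints)
  obs_names <- names(constraints)
  if (is.null(obs_names) || !all(obs_names %in% c("tau_p", "R", "A"))) {
    stop("constraints must be named among tau_p, R, A")
  }
  if (any(!is.finite(constraints)) || any(constraints <= 0)) {
    stop("constraint targets must be finite and positive")
  }
  ok <- table$status == "OK"
  F_all <- as.matrix(as.data.frame(table)[, obs_names, drop = FALSE])
  ok <- ok & apply(is.finite(F_all), 1, all)
  F_ok <- F_all[ok, , drop = FALSE]
  n <- nrow(F_ok)
  base <- list(model_id = attr(table, "model_id"), n_valid = n,
               n_excluded = nrow(table) - n, constraints = constraints)
  if (n < 2L) {
    return(infeasible_solution(base, "fewer than 2 valid samples"))
  }
  # per-axis feasibility screen: each target strictly inside the sample
  # range of its observable
  rng <- apply(F_ok, 2, range)
  inside <- constraints > rng[1, ] & constraints < rng[2, ]
  at_mean <- abs(constraints - colMeans(F_ok)) <=
    1e-12 * pmax(1, abs(constraints))
  if (!all(inside | at_mean)) {
    return(infeasible_solution(
      base, paste("target outside sample range for:",
                  paste(obs_names[!(inside | at_mean)], collapse = ", "))))
  }

  # standardize observables for conditioning (output-invariant)
  scl <- apply(F_ok, 2, sd)
  scl[scl == 0] <- 1
  Fs <- sweep(F_ok, 2, scl, "/")
  cs <- constraints / scl
  m <- length(cs)
  lam <- rep(0, m)

  weights_of <- function(lam) {
    u <- -as.numeric(Fs %*% lam)
    u <- u - max(u)
    w <- exp(u)
    w / sum(w)
  }
  dual_of <- function(lam) {
    u <- -as.numeric(Fs %*% lam)
    mx <- max(u)
    mx + log(mean(exp(u - mx))) + sum(lam * cs)
  }

  converged <- FALSE
  diverged <- FALSE
  g_val <- dual_of(lam)
  for (it in seq_len(max_iter)) {
    w <- weights_of(lam)
    mu <- as.numeric(crossprod(w, Fs))
    grad <- cs - mu
    rel_res <- abs(mu - cs) / abs(cs)
    if (max(rel_res) <= tol) { converged <- TRUE; break }
    Fc <- sweep(Fs, 2, mu, "-")
    H <- crossprod(Fc * sqrt(w), Fc * sqrt(w))
    step <- tryCatch(solve(H + diag(1e-12, m), grad),
                     error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    # backtracking line search on the dual
    t_step <- 1
    repeat {
      lam_new <- lam - t_step * step
      g_new <- dual_of(lam_new)
      if (is.finite(g_new) && g_new <= g_val + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-12) break
    }
    lam <- lam - t_step * step
    g_val <- dual_of(lam)
    if (sqrt(sum(lam^2)) > 1e10) { diverged <- TRUE; break }
  }
  w <- weights_of(lam)
  mu <- as.numeric(crossprod(w, Fs))
  rel_res <- abs(mu - cs) / abs(cs)
  converged <- max(rel_res) <= tol && !diverged
  if (!converged) {
    sol <- infeasible_solution(base, if (diverged)
      "dual iteration diverged (jointly infeasible targets)" else
      "dual iteration did not converge")
    sol$residuals <- setNames(rel_res, obs_names)
    return(sol)
  }
  structure(list(
    model_id = base$model_id,
    lambdas = setNames(lam / scl, obs_names),
    weights = w,
    log_partition = g_val - sum((lam / scl) * constraints),
    entropy_S = -sum(ifelse(w > 0, w * log(w), 0)),
    D_KL = kl_to_uniform(w),
    converged = TRUE,
    feasible = TRUE,
    residuals = setNames(rel_res, obs_names),
    n_valid = n,
    n_excluded = base$n_excluded,
    constraints = constraints,
    reason = NULL
  ), class = "maxent_solution")
}

infeasible_solution <- function(base, reason) {
  structure(list(
    model_id = base$model_id, lambdas = NULL, weights = NULL,
    log_partition = NA_real_, entropy_S = NA_real_, D_KL = NA_real_,
    converged = FALSE, feasible = FALSE, residuals = NULL,
    n_valid = base$n_valid, n_excluded = base$n_excluded,
    constraints = base$constraints, reason = reason
  ), class = "maxent_solution")
}

#' @export
print.maxent_solution <- function(x, ...) {
  if (isTRUE(x$feasible)) {
    cat(sprintf("<maxent_solution %s: D_KL = %.4g (log10), n_valid = %d>\n",
                x$model_id %||% "?", x$D_KL, x$n_valid))
  } else {
    cat(sprintf("<maxent_solution %s: INFEASIBLE (%s), n_valid = %d>\n",
                x$model_id %||% "?", x$reason, x$n_valid))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kullback-Leibler distance to the uniform distribution (log10 units)
#'
#' For weights `w` on the simplex over `N` samples,
#' `D_KL = sum_i w_i log10(w_i N)` with the convention `0 log 0 = 0`.
#' It is 0 exactly for uniform weights and `log10(N)` for a point mass.
#'
#' @param weights Nonnegative weights summing to 1 (tolerance 1e-8).
#' @return Scalar D_KL in log10 units.
#' @export
kl_to_uniform <- function(weights) {
  if (any(weights < -1e-12)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  n <- length(weights)
  sum(ifelse(weights > 0, weights * log10(weights * n), 0))
}

#' Rank models by robustness
#'
#' Ascending Kullback-Leibler distance; infeasible (or non-converged)
#' models are placed last, ties broken by model index.
#'
#' @param solutions Named list mapping model id to `maxent_solution`.
#' @return Data frame with columns `model`, `D_KL`, `feasible`, ordered
#'   by rank; zero rows when no model is feasible.
#' @export
rank_models <- function(solutions) {
  ids <- names(solutions)
  if (is.null(ids)) stop("solutions must be a named list (model id -> solution)")
  d <- vapply(solutions, function(s) {
    if (isTRUE(s$feasible) && isTRUE(s$converged)) s$D_KL else Inf
  }, numeric(1))
  feas <- is.finite(d)
  ord <- order(d, match(ids, MODEL_IDS, nomatch = length(MODEL_IDS) + 1))
  out <- data.frame(model = ids[ord], D_KL = ifelse(feas[ord], d[ord], NA),
                    feasible = feas[ord], stringsAsFactors = FALSE)
  if (!any(feas)) out <- out[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Robustness map over (R, A) targets at fixed peak time
#'
#' Solves the MaxEnt problem for every model in every grid cell and
#' records the per-cell Kullback-Leibler distances, a feasibility mask
#' and the most robust (lowest D_KL) model.  Passing `A_grid = NULL`
#' collapses the amplitude axis (the no-amplitude constraint variant).
#'
#' @param tables Named list mapping model id to `observable_table`.
#' @param R_grid Numeric grid of asymmetry-ratio targets.
#' @param A_grid Numeric grid of amplitude targets, or `NULL`.
#' @param tau_p_avg Peak-time target (min).
#' @param tol Passed to [solve_maxent()].
#' @return A `robustness_map`: list with `R_grid`, `A_grid`,
#'   `tau_p_avg`, `models`, `D_KL` (array R x A x model, `NA` where
#'   infeasible), `feasible` (logical array) and `best` (character
#'   matrix R x A; `NA` where no model is feasible).
#' @export
robustness_map <- function(tables, R_grid, A_grid = NULL, tau_p_avg,
                           tol = 1e-6) {
  stopifnot(length(R_grid) >= 1)
  ids <- names(tables)
  if (is.null(ids)) stop("tables must be a named list (model id -> table)")
  nA <- if (is.null(A_grid)) 1L else length(A_grid)
  D <- array(NA_real_, dim = c(length(R_grid), nA, length(ids)),
             dimnames = list(NULL, NULL, ids))
  feas <- array(FALSE, dim = dim(D), dimnames = dimnames(D))
  best <- matrix(NA_character_, nrow = length(R_grid), ncol = nA)
  for (ir in seq_along(R_grid)) {
    for (ia in seq_len(nA)) {
      targets <- c(tau_p = tau_p_avg, R = R_grid[ir])
      if (!is.null(A_grid)) targets <- c(targets, A = A_grid[ia])
      for (id in ids) {
        sol <- solve_maxent(tables[[id]], targets, tol = tol)
        if (isTRUE(sol$feasible)) {
          D[ir, ia, id] <- sol$D_KL
          feas[ir, ia, id] <- TRUE
        }
      }
      if (any(feas[ir, ia, ])) {
        d <- D[ir, ia, ]
        d[!feas[ir, ia, ]] <- Inf
        # ties broken by model index
        best[ir, ia] <- ids[order(d, match(ids, MODEL_IDS))][1]
      }
    }
  }
  structure(list(R_grid = R_grid, A_grid = A_grid, tau_p_avg = tau_p_avg,
                 models = ids, D_KL = D, feasible = feas, best = best),
            class = "robustness_map")
}

#' @export
print.robustness_map <- function(x, ...) {
  cat(sprintf("<robustness_map: %d R x %d A cells, tau_p = %g min, models: %s>\n",
              length(x$R_grid), if (is.null(x$A_grid)) 1 else length(x$A_grid),
              x$tau_p_avg, paste(x$models, collapse = ", ")))
  invisible(x)
}

#' @describeIn robustness_map Flatten a map to one row per (cell, model).
#' @param x A `robustness_map`.
#' @param ... Unused.
#' @export
as.data.frame.robustness_map <- function(x, ...) {
  nA <- if (is.null(x$A_grid)) 1L else length(x$A_grid)
  grid <- expand.grid(ir = seq_along(x$R_grid), ia = seq_len(nA),
                      model = x$models, stringsAsFactors = FALSE)
  data.frame(
    R_avg = x$R_grid[grid$ir],
    A_avg = if (is.null(x$A_grid)) NA_real_ else x$A_grid[grid$ia],
    tau_p_avg = x$tau_p_avg,
    model = grid$model,
    D_KL = x$D_KL[cbind(grid$ir, grid$ia, match(grid$model, x$models))],
    feasible = x$feasible[cbind(grid$ir, grid$ia, match(grid$model, x$models))],
    best = x$best[cbind(grid$ir, grid$ia)],
    stringsAsFactors = FALSE)
}

#' Serialize a MaxEnt solution to JSON
#'
#' @param sol A `maxent_solution`.
#' @param file Optional path; when `NULL` the JSON string is returned.
#' @export
maxent_to_json <- function(sol, file = NULL) {
  payload <- list(model_id = sol$model_id,
                  feasible = sol$feasible, converged = sol$converged,
                  D_KL = sol$D_KL, lambdas = as.list(sol$lambdas),
                  residuals = as.list(sol$residuals),
                  n_valid = sol$n_valid, n_excluded = sol$n_excluded,
                  constraints = as.list(sol$constraints),
                  reason = sol$reason)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
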