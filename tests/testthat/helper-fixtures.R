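# Shared fixtures: in-code observable tables and the brute-force primal
# oracle used to cross-check the maximum-entropy dual solver.

# Wrap an observables matrix (columns among tau_p, R, A) as the table
# structure produced by evaluate_ensemble().
mk_table <- function(F, status = "OK", model_id = "M0") {
  F <- as.matrix(F)
  tb <- data.frame(id = seq_len(nrow(F)),
                   A = if ("A" %in% colnames(F)) F[, "A"] else 10,
                   tau_p = if ("tau_p" %in% colnames(F)) F[, "tau_p"] else 2,
                   tau_w = NA_real_, R = if ("R" %in% colnames(F)) F[, "R"]
                   else 2,
                   status = status, stringsAsFactors = FALSE)
  tb$tau_w <- tb$tau_p * tb$R
  attr(tb, "model_id") <- model_id
  attr(tb, "n_samples") <- nrow(tb)
  class(tb) <- c("observable_table", "data.frame")
  tb
}

# Brute-force primal oracle: minimize sum p log10(p n) over the simplex
# subject to F^T p = targets, by BFGS on the null-space parameterization
# of the affine constraint set (independent of the dual solver's path).
primal_dkl <- function(F, targets) {
  F <- as.matrix(F)
  n <- nrow(F)
  A <- rbind(rep(1, n), t(F))
  b <- c(1, targets)
  # interior feasible start: project the uniform vector onto the affine
  # constraint set, re-centering away from the boundary if needed
  p0 <- rep(1 / n, n)
  for (i in 1:100) {
    p0 <- p0 + as.numeric(t(A) %*% qr.solve(A %*% t(A), b - A %*% p0))
    if (min(p0) > 1e-9) break
    p0 <- pmax(p0, 1 / (10 * n))
  }
  stopifnot(min(p0) > 0)                               # interior start
  Z <- svd(A, nu = 0, nv = n)$v[, (nrow(A) + 1):n, drop = FALSE]
  obj <- function(tpar) {
    p <- p0 + as.numeric(Z %*% tpar)
    if (min(p) <= 0) return(1e6 - 10 * min(p))
    sum(p * log(p))
  }
  gr <- function(tpar) {
    p <- p0 + as.numeric(Z %*% tpar)
    if (min(p) <= 0) return(rep(0, ncol(Z)))
    as.numeric(crossprod(Z, 1 + log(p)))
  }
  op <- optim(rep(0, ncol(Z)), obj, gr, method = "BFGS",
              control = list(maxit = 5000, reltol = 1e-16))
  p <- p0 + as.numeric(Z %*% op$par)
  sum(p * log10(p * n))
}

# Correlated two-observable toy ensemble.
mk_correlated_table <- function(n, seed = 5) {
  set.seed(seed)
  z <- rnorm(n)
  mk_table(cbind(tau_p = 2 + 0.5 * z + 0.2 * rnorm(n),
                 R = 2.5 + 0.8 * z + 0.3 * rnorm(n),
                 A = 20 + 4 * rnorm(n)))
}
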