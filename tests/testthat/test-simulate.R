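test_that("with no Itk the readout is identically zero and pools constant", {
  m <- build_model("M2")
  tr <- integrate_ode(m, default_base_params("M2"),
                      initial_state(m, 0, 370, 17000),
                      sim_config(t_end = 50, horizon_policy = "fixed"))
  expect_true(all(abs(tr$readout) < 1e-8))
  expect_true(all(abs(tr$counts[, "PIP3"] - 370) < 1e-6))
  expect_true(all(abs(tr$counts[, "PIP2"] - 17000) < 1e-6))
})

test_that("single-ligand binding relaxes to the closed-form equilibrium", {
  # M6 with catalysis off and no IP4 is a two-species binding reaction;
  # the equilibrium complex count is the root of
  # k_on (Itk0 - C)(P0 - C) = k_off C
  m <- build_model("M6")
  k_on <- 2e-3; k_off <- 0.5; Itk0 <- 80; P0 <- 200
  p <- list(rates = c(k_on = k_on, k_off = k_off, k_cat = 1e-300))
  K <- k_off / k_on
  C_eq <- ((Itk0 + P0 + K) - sqrt((Itk0 + P0 + K)^2 - 4 * Itk0 * P0)) / 2
  tr <- integrate_ode(m, p, initial_state(m, Itk0, P0, 17000),
                      sim_config(t_end = 400, horizon_policy = "fixed"))
  expect_equal(tr$readout[length(tr$readout)], C_eq, tolerance = 1e-6)
})

test_that("the calibrated feedback model produces a single interior peak", {
  m <- build_model("M3")
  tr <- integrate_ode(m, default_base_params("M3"),
                      initial_state(m, 100, 370, 17000))
  r <- tr$readout
  imax <- which.max(r)
  expect_lt(r[1], 1e-6)                      # starts from ~0
  expect_gt(imax, 1)                         # interior maximum ...
  expect_lt(imax, length(r))
  expect_lt(r[length(r)], max(r) / 2)        # ... then decays well below peak
  s <- summarize_trajectory(tr)
  expect_equal(s$status, "OK")
  expect_gt(s$A, 10)                         # tens of molecules
  expect_lt(abs(s$tau_p - 2), 1)             # peak near 2 min
})

test_that("conservation laws hold along ODE trajectories", {
  for (id in c("M1", "M4", "M6")) {
    m <- build_model(id)
    ec <- ensemble_config(n_samples = 5, seed = 11)
    for (s in draw_ensemble(ec, id)) {
      init <- initial_state(m, s$init[["Itk0"]], s$init[["PIP3_0"]],
                            s$init[["PIP2_0"]])
      tr <- integrate_ode(m, s$params, init,
                          sim_config(t_end = 200, horizon_policy = "fixed"))
      ct <- itkmaxent:::conservation_totals(m, tr$counts)
      drift <- apply(ct, 2, function(x) diff(range(x)) / max(x[1], 1))
      expect_lt(max(drift), 1e-8)
    }
  }
})

test_that("SSA propensities vanish with a zero-count reactant", {
  m <- build_model("M3")
  tr <- run_ssa(m, default_base_params("M3"),
                initial_state(m, 0, 50, 1000), seed = 1, t_end = 10)
  expect_equal(tr$n_events, 0)
  expect_true(all(tr$readout == 0))
})

test_that("SSA runs are reproducible from the seed and integer-valued", {
  m <- build_model("M3")
  p <- default_base_params("M3")
  init <- initial_state(m, 20, 50, 17000)
  a <- run_ssa(m, p, init, seed = 99, t_end = 20)
  b <- run_ssa(m, p, init, seed = 99, t_end = 20)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts == round(a$counts)))
  expect_error(run_ssa(m, p, init + 0.5, seed = 1), "integer")
})

test_that("SSA trajectories qualitatively track the ODE solution", {
  m <- build_model("M3")
  p <- default_base_params("M3")
  init <- initial_state(m, 20, 50, 17000)
  times <- seq(0, 30, by = 0.5)
  tr_ode <- integrate_ode(m, p, init,
                          sim_config(t_end = 30, horizon_policy = "fixed"),
                          times = times)
  ens <- ssa_ensemble_mean(m, p, init, n_realizations = 60, seed = 3,
                           times = times)
  # same rise-peak-decay shape on the same time scale
  expect_lt(abs(times[which.max(ens$mean)] - times[which.max(tr_ode$readout)]),
            1.5)
  expect_lt(abs(max(ens$mean) - max(tr_ode$readout)),
            0.35 * max(tr_ode$readout))
})

test_that("a single realization is its own ensemble mean", {
  m <- build_model("M6")
  p <- default_base_params("M6")
  init <- initial_state(m, 20, 50, 2000)
  times <- seq(0, 10, by = 0.5)
  ens <- ssa_ensemble_mean(m, p, init, 1, seed = 7, times = times)
  set.seed(7)
  single <- run_ssa(m, p, init, seed = NULL, times = times, t_end = 10)
  expect_equal(ens$mean, single$readout)
  expect_true(all(ens$se == 0))
})

test_that("the ensemble standard error scales as one over sqrt(n)", {
  m <- build_model("M6")
  p <- default_base_params("M6")
  init <- initial_state(m, 20, 50, 2000)
  times <- seq(0, 10, by = 0.5)
  e1 <- ssa_ensemble_mean(m, p, init, 50, seed = 21, times = times)
  e2 <- ssa_ensemble_mean(m, p, init, 200, seed = 22, times = times)
  w <- e1$se > 0 & e2$se > 0
  ratio <- mean(e1$se[w] / e2$se[w])        # expect ~ sqrt(200/50) = 2
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("the SSA mean approaches the ODE as copy numbers scale up", {
  m <- build_model("M3")
  p <- default_base_params("M3")
  times <- seq(0, 20, by = 0.5)
  dev_for <- function(scale, seed) {
    init <- initial_state(m, 20 * scale, 50 * scale, 17000 * scale)
    # second-order rates scale inversely with system size
    p2 <- p
    second <- c("k_on_low", "k_on_high", "k_cat")
    p2$rates[second] <- p2$rates[second] / scale
    ode <- integrate_ode(m, p2, init,
                         sim_config(t_end = 20, horizon_policy = "fixed"),
                         times = times)
    ens <- ssa_ensemble_mean(m, p2, init, 60, seed = seed, times = times)
    max(abs(ens$mean - ode$readout)) / max(ode$readout)
  }
  expect_lt(dev_for(10, 31), dev_for(1, 30))
})

test_that("trajectories round-trip through CSV", {
  m <- build_model("M5")
  tr <- integrate_ode(m, default_base_params("M5"),
                      initial_state(m, 50, 100, 5000),
                      sim_config(t_end = 20, horizon_policy = "fixed",
                                 n_grid = 50))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  tr2 <- read_trajectory_csv(f, m)
  expect_equal(tr2$counts, tr$counts, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(tr2$readout, tr$readout, tolerance = 1e-10)
  unlink(f)
})
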