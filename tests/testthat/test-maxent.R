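test_that("targets at the sample means give the uniform distribution", {
  tb <- mk_correlated_table(30)
  targets <- c(tau_p = mean(tb$tau_p), R = mean(tb$R), A = mean(tb$A))
  s <- solve_maxent(tb, targets)
  expect_true(s$converged)
  expect_true(all(abs(s$lambdas) < 1e-6))
  expect_equal(s$weights, rep(1 / 30, 30), tolerance = 1e-6)
  expect_lt(s$D_KL, 1e-10)
})

test_that("kl_to_uniform has its closed-form values", {
  expect_equal(kl_to_uniform(rep(1 / 7, 7)), 0)
  expect_equal(kl_to_uniform(c(1, rep(0, 9))), 1)          # log10(10)
  expect_equal(kl_to_uniform(c(0.5, 0.5, 0, 0)), log10(2))
  expect_error(kl_to_uniform(c(0.6, 0.6)), "sum to 1")
  expect_error(kl_to_uniform(c(1.2, -0.2)), "nonnegative")
})

test_that("dual solutions agree with the brute-force primal oracle", {
  # single constraint on a 5-sample table
  tb1 <- mk_table(cbind(tau_p = c(1, 1.5, 2, 2.8, 4)))
  tgt1 <- mean(tb1$tau_p) * 0.9
  s1 <- solve_maxent(tb1, c(tau_p = tgt1), tol = 1e-10)
  expect_true(s1$converged)
  expect_lt(abs(s1$D_KL - primal_dkl(cbind(tb1$tau_p), tgt1)), 1e-6)

  # two correlated constraints on a 20-sample table
  tb2 <- mk_correlated_table(20)
  tgt2 <- c(tau_p = mean(tb2$tau_p) * 1.05, R = mean(tb2$R) * 0.93)
  s2 <- solve_maxent(tb2, tgt2, tol = 1e-10)
  expect_true(s2$converged)
  w_means <- c(sum(s2$weights * tb2$tau_p), sum(s2$weights * tb2$R))
  expect_equal(w_means, unname(tgt2), tolerance = 1e-8)
  expect_lt(abs(s2$D_KL - primal_dkl(cbind(tb2$tau_p, tb2$R), tgt2)), 1e-6)

  # all three constraints on a 50-sample table
  tb3 <- mk_correlated_table(50, seed = 8)
  tgt3 <- c(tau_p = mean(tb3$tau_p) * 1.04, R = mean(tb3$R) * 0.95,
            A = mean(tb3$A) * 1.02)
  s3 <- solve_maxent(tb3, tgt3, tol = 1e-10)
  expect_lt(abs(s3$D_KL -
                  primal_dkl(cbind(tb3$tau_p, tb3$R, tb3$A), tgt3)), 1e-6)
})

test_that("adding a constraint never decreases the KL distance", {
  for (seed in c(1, 2, 3)) {
    tb <- mk_correlated_table(60, seed = seed)
    t2 <- c(tau_p = mean(tb$tau_p) * 1.06, R = mean(tb$R) * 0.94)
    t3 <- c(t2, A = mean(tb$A) * 1.03)
    d2 <- solve_maxent(tb, t2)$D_KL
    d3 <- solve_maxent(tb, t3)$D_KL
    expect_gte(d3 + 1e-10, d2)
    expect_gte(d2, 0)
  }
})

test_that("infeasible targets are flagged, never silently scored", {
  tb <- mk_correlated_table(25)
  s <- solve_maxent(tb, c(tau_p = max(tb$tau_p) * 2, R = mean(tb$R)))
  expect_false(s$feasible)
  expect_true(is.na(s$D_KL))
  expect_match(s$reason, "outside sample range")
  # jointly unreachable combination of marginally feasible targets:
  # tau_p and R are strictly anticorrelated, so both cannot be near
  # their minima at once
  n <- 200; set.seed(10)
  z <- rnorm(n)
  tbj <- mk_table(cbind(tau_p = 1 + exp(z), R = 1 + exp(-z)))
  sj <- solve_maxent(tbj, c(tau_p = min(tbj$tau_p) * 1.02,
                            R = min(tbj$R) * 1.02))
  expect_false(sj$feasible)
})

test_that("excluded statuses do not enter the fit but are counted", {
  tb <- mk_correlated_table(40)
  tb$status[1:10] <- "CENSORED_WIDTH"
  tb$R[1:10] <- NA
  tb$tau_w[1:10] <- NA
  targets <- c(tau_p = mean(tb$tau_p[11:40]), R = mean(tb$R[11:40]))
  s <- solve_maxent(tb, targets)
  expect_equal(s$n_valid, 30)
  expect_equal(s$n_excluded, 10)
  expect_lt(s$D_KL, 1e-10)
})

test_that("models rank by ascending D_KL with infeasible ones last", {
  tb_tight <- mk_table(cbind(R = 2 + 0.05 * rnorm(100))) # clusters at target
  tb_wide <- mk_table(cbind(R = 2 + 1.5 * abs(rnorm(100))))
  sols <- list(MA = solve_maxent(tb_wide, c(R = 2.05)),
               MB = solve_maxent(tb_tight, c(R = 2.05)))
  rk <- rank_models(sols)
  expect_equal(rk$model[1], "MB")   # tighter clustering needs less tilting
  expect_lt(rk$D_KL[1], rk$D_KL[2])

  sols2 <- list(M1 = solve_maxent(tb_tight, c(R = 50)),   # infeasible
                M2 = solve_maxent(tb_tight, c(R = 2.02)))
  rk2 <- rank_models(sols2)
  expect_equal(rk2$model, c("M2", "M1"))
  expect_false(rk2$feasible[2])

  all_inf <- list(M1 = solve_maxent(tb_tight, c(R = 50)))
  expect_equal(nrow(rank_models(all_inf)), 0L)
})

test_that("a table whose observables sit at the targets ranks first", {
  set.seed(6)
  tb_exact <- mk_correlated_table(40)
  targets <- c(tau_p = mean(tb_exact$tau_p), R = mean(tb_exact$R))
  tb_off <- mk_correlated_table(40, seed = 99)
  sols <- list(A = solve_maxent(tb_off, targets),
               B = solve_maxent(tb_exact, targets))
  rk <- rank_models(sols)
  expect_equal(rk$model[1], "B")
  expect_lt(rk$D_KL[1], 1e-10)
})

test_that("robustness maps are consistent with single solves", {
  tbs <- list(MA = mk_correlated_table(60, seed = 12),
              MB = mk_correlated_table(60, seed = 13))
  # 1x1 grid equals a direct solve + ranking
  mp <- robustness_map(tbs, R_grid = 2.4, A_grid = 20, tau_p_avg = 2)
  direct <- lapply(tbs, solve_maxent,
                   constraints = c(tau_p = 2, R = 2.4, A = 20))
  expect_equal(unname(mp$D_KL[1, 1, "MA"]), direct$MA$D_KL)
  expect_equal(mp$best[1, 1], rank_models(direct)$model[1])

  # single-model map is that model wherever feasible
  mp1 <- robustness_map(tbs["MA"], R_grid = c(2.2, 2.6, 50),
                        A_grid = c(20), tau_p_avg = 2)
  expect_true(all(mp1$best[1:2, 1] == "MA"))
  expect_true(is.na(mp1$best[3, 1]))            # infeasible cell masked

  # a cell only one model can reach belongs to that model
  tb_far <- mk_table(cbind(tau_p = 2 + 0.1 * rnorm(50),
                           R = 9 + 0.5 * rnorm(50), A = 20 + rnorm(50)))
  mp2 <- robustness_map(list(MA = tbs$MA, MF = tb_far), R_grid = 9,
                        A_grid = 20, tau_p_avg = 2)
  expect_equal(mp2$best[1, 1], "MF")

  # no-amplitude variant collapses the A axis
  mp3 <- robustness_map(tbs, R_grid = c(2.3, 2.5), A_grid = NULL,
                        tau_p_avg = 2)
  expect_equal(dim(mp3$D_KL), c(2L, 1L, 2L))
  df <- as.data.frame(mp3)
  expect_true(all(is.na(df$A_avg)))
  expect_equal(nrow(df), 4L)
})

test_that("maxent solutions serialize to JSON", {
  tb <- mk_correlated_table(20)
  s <- solve_maxent(tb, c(tau_p = mean(tb$tau_p) * 1.02))
  js <- jsonlite::fromJSON(maxent_to_json(s))
  expect_true(js$feasible)
  expect_equal(js$D_KL, s$D_KL)
  expect_equal(js$n_valid, 20)
})
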