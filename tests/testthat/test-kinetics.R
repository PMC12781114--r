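test_that("Beer-Lambert slope conversion", {
  # -0.00622 AU/s at eps 6220, 1 cm: v0 = 1 uM/s; at e = 0.1 uM, v0/e = 10/s
  expect_equal(absorbance_to_rate(-0.00622, 6220, 1, 0.1), 10)
  expect_equal(absorbance_to_rate(0, 6220, 1, 0.1), 0)
  expect_equal(formals(absorbance_to_rate)$extinction, 6220)
  expect_error(absorbance_to_rate(1, -1, 1, 1), "> 0")
})

test_that("noiseless steady-state data are recovered to better than 0.1%", {
  sp1 <- kinetics_sim_spec(true_kcat = 5.4, true_Ka = 130, true_Kb = 10,
                           true_Kis = NULL, noise_cv = 0, replicates = 1,
                           nadh_grid = p78g_grid$nadh,
                           coq0_grid = p78g_grid$coq0, rng_seed = 1)
  f1 <- fit_pingpong(simulate_rates(sp1))
  expect_lt(abs(f1$kcat - 5.4) / 5.4, 1e-3)
  expect_lt(abs(f1$Ka - 130) / 130, 1e-3)
  expect_lt(abs(f1$Kb - 10) / 10, 1e-3)
  expect_gt(f1$r_squared, 1 - 1e-9)
  sp2 <- kinetics_sim_spec(noise_cv = 0, replicates = 1, rng_seed = 1)
  f2 <- fit_pingpong_substrate_inhibition(simulate_rates(sp2))
  expect_lt(abs(f2$kcat - 11) / 11, 1e-3)
  expect_lt(abs(f2$Ka - 0.4) / 0.4, 1e-3)
  expect_lt(abs(f2$Kb - 35) / 35, 1e-3)
  expect_lt(abs(f2$Kis - 1.1) / 1.1, 1e-3)
})

test_that("inhibition model collapses to the plain model as Kis grows", {
  A <- seq(10, 100, by = 10); B <- c(2, 6, 10)
  g <- expand.grid(A = A, B = B)
  v1 <- pingpong_rate(g$A, g$B, 5.4, 130, 10)
  v2 <- pingpong_rate(g$A, g$B, 5.4, 130, 10, Kis = 1e9 * 130)
  expect_lt(max(abs(v2 - v1) / v1), 1e-6)
  # at fixed B the plain law is Michaelis-Menten in A with apparent
  # Vmax = kcat B / (Kb + B) and apparent Km = Ka B / (Kb + B)
  B0 <- 6
  vmax_app <- 5.4 * B0 / (10 + B0)
  km_app <- 130 * B0 / (10 + B0)
  expect_equal(pingpong_rate(A, B0, 5.4, 130, 10),
               vmax_app * A / (km_app + A), tolerance = 1e-12)
})

test_that("grid search + polish oracle agrees with the surface fitter", {
  sp <- kinetics_sim_spec(true_kcat = 5, true_Ka = 50, true_Kb = 8,
                          true_Kis = NULL, noise_cv = 0.02, replicates = 2,
                          nadh_grid = c(10, 30, 100),
                          coq0_grid = c(2, 5, 10), rng_seed = 23)
  r <- simulate_rates(sp)
  fit <- fit_pingpong(r)
  # oracle: coarse log-grid search then Nelder-Mead polish, no shared code
  sse <- function(p) sum((r$v0_over_e_per_s -
                            pingpong_rate(r$NADH_uM, r$CoQ0_uM,
                                          exp(p[1]), exp(p[2]),
                                          exp(p[3])))^2)
  grid <- expand.grid(k = log(c(1, 3, 5, 10, 30)),
                      a = log(c(5, 20, 50, 150, 500)),
                      b = log(c(1, 3, 8, 20, 60)))
  best <- grid[which.min(apply(grid, 1, sse)), ]
  pol <- optim(as.numeric(best), sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  pol <- optim(pol$par, sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(fit$kcat, exp(pol$par[1]), tolerance = 5e-4)
  expect_equal(fit$Ka, exp(pol$par[2]), tolerance = 5e-4)
  expect_equal(fit$Kb, exp(pol$par[3]), tolerance = 5e-4)
})

test_that("model selection prefers parsimony on identical residuals and is
           reported with AICc and F-test", {
  sp <- kinetics_sim_spec(true_kcat = 5.4, true_Ka = 130, true_Kb = 10,
                          true_Kis = NULL, noise_cv = 0.02, rng_seed = 9)
  r <- simulate_rates(sp)
  f1 <- fit_pingpong(r)
  f2 <- fit_pingpong_substrate_inhibition(r)
  sel <- select_model(f1, f2)
  # eq2 nests eq1: its RSS can only be <= eq1's, so equal-fit data must
  # fall to the simpler model through the AICc penalty
  expect_lte(f2$rss, f1$rss * (1 + 1e-9))
  expect_equal(sel$choice, "eq1")
  expect_named(sel$aicc, c("eq1", "eq2"))
  expect_gte(sel$p_value, 0)
})

test_that("biexponential fits recover truth, honour the relabeling
           convention and flag close rates", {
  t <- exp(seq(log(1e-3), log(60), length.out = 200))
  A <- 0.09 * exp(-3.2 * t) + 0.008 * exp(-0.1 * t) + 0.02
  tr <- structure(data.frame(time_s = t, A461 = A),
                  class = c("StoppedFlowTrace", "data.frame"))
  f <- fit_biexponential(tr)
  expect_lt(abs(f$B1 - 0.09) / 0.09, 5e-3)
  expect_lt(abs(f$kobs1 - 3.2) / 3.2, 5e-3)
  expect_lt(abs(f$B2 - 0.008) / 0.008, 5e-3)
  expect_lt(abs(f$kobs2 - 0.1) / 0.1, 5e-3)
  expect_lt(abs(f$C - 0.02) / 0.02, 5e-3)
  expect_gte(f$kobs1, f$kobs2)
  expect_true(f$rates_distinguishable)
  # single-exponential truth: slow amplitude collapses to ~0
  A1 <- 0.1 * exp(-2 * t) + 0.02
  f1 <- fit_biexponential(structure(data.frame(time_s = t, A461 = A1),
                                    class = c("StoppedFlowTrace",
                                              "data.frame")))
  expect_lt(min(f1$B1, f1$B2) / max(f1$B1, f1$B2), 1e-3)
  expect_lt(abs(max(f1$B1, f1$B2) - 0.1) / 0.1, 5e-3)
  # contract checks
  expect_error(fit_biexponential(
    structure(data.frame(time_s = t[1:5], A461 = A[1:5]),
              class = c("StoppedFlowTrace", "data.frame"))), "10")
  expect_error(fit_biexponential(
    structure(data.frame(time_s = t, A461 = rev(A)),
              class = c("StoppedFlowTrace", "data.frame"))), "decreasing")
})

test_that("simulated traces refit to their own generating parameters", {
  sp <- kinetics_sim_spec(rng_seed = 31)
  conc <- c(90, 150, 250, 350, 500)
  fits <- lapply(simulate_traces(sp, conc), fit_biexponential)
  for (i in seq_along(conc)) {
    true_k <- sp$true_kred * conc[i] / (sp$true_Kd + conc[i])
    expect_lt(abs(fits[[i]]$kobs1 - true_k) / true_k, 0.05)
    expect_gt(fits[[i]]$amplitude_fraction_fast, 0.9)
  }
})

test_that("saturation fit: noiseless recovery, midpoint identity and the
           unconstrained-Kd flag", {
  S <- c(90, 150, 250, 350, 500)
  f <- fit_saturation(data.frame(S = S, kobs = 4.8 * S / (450 + S)))
  expect_lt(abs(f$kred - 4.8) / 4.8, 5e-3)
  expect_lt(abs(f$Kd - 450) / 450, 5e-3)
  expect_true(f$kd_constrained)
  expect_equal(4.8 * 450 / (450 + 450), 4.8 / 2)  # kobs(S = Kd) = kred / 2
  # saturated design: kred ~ mean(kobs), Kd flagged unconstrained
  set.seed(2)
  ksat <- 4.8 * S / (0.01 + S) * (1 + rnorm(5, 0, 0.01))
  fs <- fit_saturation(data.frame(S = S, kobs = ksat))
  expect_false(fs$kd_constrained)
  expect_lt(abs(fs$kred - mean(ksat)) / mean(ksat), 0.02)
  expect_error(fit_saturation(data.frame(S = c(1, 2), kobs = c(1, 2))),
               "3 concentrations")
})

test_that("parameter bias stays below the standard error under noise", {
  # 200 seeded replicates of the no-inhibition regime at n = 50 points
  reps <- 200
  est <- matrix(NA_real_, reps, 3)
  ses <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    sp <- kinetics_sim_spec(true_kcat = 5.4, true_Ka = 130, true_Kb = 10,
                            true_Kis = NULL, noise_cv = 0.03,
                            replicates = 1, nadh_grid = p78g_grid$nadh,
                            coq0_grid = p78g_grid$coq0, rng_seed = 1000 + i)
    f <- fit_pingpong(simulate_rates(sp))
    est[i, ] <- c(f$kcat, f$Ka, f$Kb)
    ses[i, ] <- f$se[c("kcat", "Ka", "Kb")]
  }
  truth <- c(5.4, 130, 10)
  bias <- abs(colMeans(est) - truth)
  expect_true(all(bias < colMeans(ses)))
})

test_that("efficiency and fold-change arithmetic", {
  e <- efficiency(5.4, 10)
  expect_equal(e$value, 5.4e5)
  expect_equal(e$se, 0)
  e2 <- efficiency(11, 35, 1, 6)
  expect_equal(e2$value, 11 / 35e-6)
  expect_equal(e2$se, e2$value * sqrt((1 / 11)^2 + (6 / 35)^2))
  fc <- fold_change(35, 10, c("wt", "mut"))
  expect_equal(fc$ratio, 3.5)
  expect_equal(fc$direction, "decrease")
  expect_equal(fold_change(2, 2)$ratio, 1)
  inc <- fold_change(3.2e5, 5.6e5)
  expect_equal(inc$ratio, 1.75)
  expect_equal(inc$direction, "increase")
  expect_error(fold_change(-1, 2), "> 0")
})
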