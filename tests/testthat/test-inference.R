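fit_noisy_toy <- function(seed_ds = 31, seed_fit = 2, n_starts = 4, ...) {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 1, seed = seed_ds, ...)
  list(ds = ds, fit = fit_synthetic(ds, n_starts = n_starts, seed = seed_fit))
}

test_that("chi-square bookkeeping and degenerate cases", {
  r <- fit_noisy_toy()
  ct <- chi2_test(r$fit)
  expect_equal(ct$dof, r$fit$problem$n_meas_res - length(r$fit$theta))
  expect_equal(ct$lower, qchisq(0.025, ct$dof))
  expect_equal(ct$upper, qchisq(0.975, ct$dof))
  # noise-free data: objective collapses below the lower acceptance bound
  ds0 <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                    noise_molpct = 0, seed = 8)
  fit0 <- fit_synthetic(ds0, seed = 2)
  ct0 <- chi2_test(fit0)
  expect_false(ct0$accept)
  expect_lt(ct0$chi2, ct0$lower)
})

test_that("residual normality diagnostics behave", {
  # measure two extra intermediates so the residual vector is long enough
  # for a meaningful normal probability plot
  ds <- generate_synthetic_dataset(toy$net, toy$strategy,
                                   c(toy$targets_ss, "D_123", "C_12"),
                                   noise_molpct = 1, seed = 31)
  fit <- fit_synthetic(ds, n_starts = 4, seed = 2)
  rn <- residual_normality(fit)
  expect_true(is.finite(rn$statistic))
  expect_equal(nrow(rn$quantiles), nrow(fit$residuals))
  expect_false(is.unsorted(rn$quantiles$empirical))
  # constant residuals are degenerate
  fake <- fit
  fake$residuals$resid <- rep(1, nrow(fake$residuals))
  expect_error(residual_normality(fake), "constant")
  short <- fit
  short$residuals <- short$residuals[1:5, ]
  expect_error(residual_normality(short), ">= 8")
})

test_that("normality test calibrates on Gaussian and rejects heavy tails", {
  set.seed(99)
  p_gauss <- replicate(60, shapiro.test(rnorm(50))$p.value)
  expect_gt(mean(p_gauss > 0.05), 0.85)
  p_heavy <- replicate(60, shapiro.test(rt(50, df = 2))$p.value)
  expect_gt(mean(p_heavy < 0.05), 0.5)
})

test_that("local confidence intervals track declared measurement noise", {
  r <- fit_noisy_toy()
  ci <- local_confidence_intervals(r$fit)
  expect_true(all(ci$identifiable))
  expect_true(all(ci$lo <= ci$estimate & ci$estimate <= ci$hi))
  # linear-model limit: halving every sd halves the half-widths
  fit_half <- r$fit
  fit_half$J <- r$fit$J * 2  # J = W df/dtheta scales as 1/sd
  ci_half <- local_confidence_intervals(fit_half)
  expect_equal(ci$se / ci_half$se, rep(2, nrow(ci)), tolerance = 1e-9)
})

test_that("an unconstrained futile-cycle pair is flagged unidentifiable", {
  # P <-> Q cycling is invisible to labeling (identical atom maps) and to
  # the throughput measurement: fwd and bwd are individually unbounded
  net <- flux_network(data.frame(
    id = c("up", "fwd", "bwd", "out"),
    equation = c("Ain{a} -> P{a}", "P{a} -> Q{a}", "Q{a} -> P{a}",
                 "Q{a} -> W{a}")))
  st <- labeling_strategy(Ain = data.frame(mask = "1", fraction = 1,
                                           purity = 1))
  v <- c(up = 100, fwd = 120, bwd = 20, out = 100)
  mdvs <- simulate_steady_state(net, v, st, targets = "W_1")
  meas <- tibble::tibble(emu = "W_1", timepoint = "ss", shift = 0:1,
                         mean = mdv_num(mdvs$W_1), sd = 0.01)
  pr <- make_fit_problem(net, meas,
                         tibble::tibble(reaction = "up", mean = 100, sd = 1),
                         st)
  fit <- solve_fit(pr, n_starts = 3, seed = 1)
  ci <- local_confidence_intervals(fit)
  expect_false(ci$identifiable[ci$quantity == "fwd" & ci$type == "net"])
  expect_false(ci$identifiable[ci$quantity == "bwd" & ci$type == "net"])
  expect_true(is.infinite(ci$hi[ci$quantity == "fwd" & ci$type == "net"]))
  # the throughput itself stays identifiable
  expect_true(ci$identifiable[ci$quantity == "up" & ci$type == "net"])
  expect_true(ci$identifiable[ci$quantity == "out" & ci$type == "net"])
})

test_that("sensitivities match a finite-difference refit oracle", {
  r <- fit_noisy_toy()
  sm <- sensitivity_matrix(r$fit)
  pr <- r$fit$problem
  jcols <- which(sm$type == "net")
  # perturb a handful of measurements, refit from the optimum, compare slopes
  set.seed(7)
  for (j in sample(nrow(pr$meas), 3)) {
    d <- 1e-3
    mm <- pr$meas$mean
    mm[j] <- mm[j] + d
    ref <- emuflux:::run_one_fit(pr, r$fit$theta, meas_means = mm)
    dec <- emuflux:::decode_theta(pr, ref$theta)
    base <- setNames(r$fit$fluxes$net, r$fit$fluxes$reaction)
    num <- (dec$v_net[names(base)] - base) / d
    ana <- sm$S[jcols, j]
    expect_lt(max(abs(num - ana)), 1e-2 * max(1, max(abs(ana))))
  }
})

test_that("duplicated measurements split their influence equally", {
  r <- fit_noisy_toy()
  ds2 <- r$ds
  ds2$measurements <- dplyr::bind_rows(r$ds$measurements, r$ds$measurements)
  pr2 <- suppressWarnings(make_fit_problem(ds2$net, ds2$measurements,
                                           ds2$flux_measurements,
                                           ds2$strategy))
  fit2 <- solve_fit(pr2, n_starts = 4, seed = 2)
  sm2 <- sensitivity_matrix(fit2)
  n <- nrow(r$ds$measurements)
  i <- which(sm2$type == "net")[2]
  expect_equal(sm2$S[i, 1:n], sm2$S[i, n + (1:n)], tolerance = 1e-6)
  # and each copy carries half the influence of the original measurement
  sm1 <- sensitivity_matrix(r$fit)
  i1 <- which(sm1$type == "net")[2]
  expect_equal(sm2$S[i, 1:n], sm1$S[i1, 1:n] / 2, tolerance = 5e-3)
})

test_that("contribution matrix is a row-normalized variance decomposition", {
  r <- fit_noisy_toy()
  cm <- contribution_matrix(r$fit)
  ok <- !cm$flagged
  expect_true(any(ok))
  expect_equal(unname(rowSums(cm$C[ok, , drop = FALSE])),
               rep(1, sum(ok)), tolerance = 1e-9)
  expect_true(all(cm$C[ok, ] >= -1e-12))
  td <- tidy(cm)
  expect_equal(nrow(td), nrow(cm$C) * ncol(cm$C))
  expect_s3_class(plot_contribution(cm), "ggplot")
})

test_that("INST flux information concentrates in the transient window", {
  # a uniformly labeled tracer makes the steady-state pattern
  # flux-independent (the autotrophic-regime situation INST-MFA exists
  # for), so flux uncertainty must be dominated by transient timepoints,
  # not by the final near-steady sample
  ust <- labeling_strategy(A = data.frame(mask = "111", fraction = 1,
                                          purity = 1))
  ds <- generate_synthetic_dataset(toy$net, ust, toy$targets_inst,
                                   noise_molpct = 1, seed = 19,
                                   pools = toy$pools, timegrid = toy$timegrid)
  fit <- solve_fit_inst(make_fit_problem(
    ds$net, ds$measurements, ds$flux_measurements, ust,
    mode = "inst", pools = ds$pools), n_starts = 3, seed = 3)
  cm <- contribution_matrix(fit)
  res <- fit$residuals
  tps <- suppressWarnings(as.numeric(res$timepoint))
  t_last <- max(tps, na.rm = TRUE)
  for (q in c("v2", "v3", "v4", "v5")) {
    i <- which(cm$type == "net" & cm$quantity == q)
    w <- cm$C[i, !is.na(tps)]
    t_meas <- tps[!is.na(tps)]
    expect_lt(t_meas[which.max(w)], t_last)
  }
})
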