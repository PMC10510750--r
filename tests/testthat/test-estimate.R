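make_toy_problem <- function(ds, ...) {
  make_fit_problem(ds$net, ds$measurements, ds$flux_measurements, ds$strategy,
                   mode = ds$mode, pools = ds$pools, ...)
}

test_that("fit problems expose the expected free parameters", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 0, seed = 3)
  pr <- make_toy_problem(ds)
  # nullity of the net stoichiometric matrix: 5 reactions, rank 3
  expect_equal(length(pr$free_rids), 2L)
  expect_equal(sum(pr$ptype == "xch"), 1L)
  # a dilution spec adds exactly one parameter
  pr2 <- make_toy_problem(ds, dilution = "F")
  expect_equal(length(pr2$par_names), length(pr$par_names) + 1L)
  # unknown EMU rejected
  bad <- ds$measurements
  bad$emu[1] <- "Zz_1"
  expect_error(make_fit_problem(ds$net, bad, ds$flux_measurements,
                                ds$strategy), "not in network")
  expect_error(make_fit_problem(ds$net, ds$measurements,
                                ds$flux_measurements[0, ], ds$strategy),
               "anchor")
})

test_that("every parameter vector maps to an exactly balanced flux vector", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 0, seed = 3)
  pr <- make_toy_problem(ds)
  set.seed(42)
  for (i in 1:25) {
    th <- runif(length(pr$par_names), pr$lower,
                pmin(pr$upper, 1000))
    dec <- emuflux:::decode_theta(pr, th)
    S_net <- toy$net$S[, toy$net$total_fluxes$direction == 1, drop = FALSE]
    expect_lt(max(abs(S_net %*% dec$v_net)), 1e-9)
    expect_lt(max(abs(toy$net$S %*% dec$v_total)), 1e-9)
  }
})

test_that("noise-free steady-state data is recovered essentially exactly", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 0, seed = 8)
  fit <- fit_synthetic(ds, seed = 2)
  ref <- setNames(ds$reference$net$value, ds$reference$net$reaction)
  expect_lt(max(abs(fit$fluxes$net - ref[fit$fluxes$reaction])), 0.1)
  expect_lt(fit$objective, 1e-6)
  expect_true(fit$converged)
  # the exchange flux of the reversible shuttle is recovered too
  expect_equal(fit$fluxes$xch[fit$fluxes$reaction == "v2"],
               ds$reference$xch$value, tolerance = 0.05)
})

test_that("a G-value used to generate data is recovered", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 0, seed = 12)
  g_true <- 0.8
  diluted <- ds$measurements
  for (g in unique(diluted$emu)) {
    if (parse_emu(g)$met != "F") next
    sel <- diluted$emu == g
    nat <- mdv_num(natural_mdv(length(parse_emu(g)$idx)))
    diluted$mean[sel] <- g_true * diluted$mean[sel] + (1 - g_true) * nat
  }
  ds$measurements <- diluted
  fit <- fit_synthetic(ds, dilution = "F", seed = 4)
  expect_equal(fit$gvalues$G[fit$gvalues$metabolite == "F"], g_true,
               tolerance = 0.02)
  ref <- setNames(ds$reference$net$value, ds$reference$net$reaction)
  expect_lt(max(abs(fit$fluxes$net - ref[fit$fluxes$reaction])), 0.5)
})

test_that("objective respects measurement weighting arithmetic", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 1, seed = 21)
  pr <- make_toy_problem(ds)
  fit <- solve_fit(pr, n_starts = 4, seed = 1)
  # duplicating every measurement doubles the objective at the same optimum
  ds2 <- ds
  ds2$measurements <- dplyr::bind_rows(ds$measurements, ds$measurements)
  ds2$flux_measurements <- dplyr::bind_rows(ds$flux_measurements,
                                            ds$flux_measurements)
  pr2 <- suppressWarnings(make_toy_problem(ds2))
  th2 <- fit$theta
  expect_equal(sum(emuflux:::problem_residuals(pr2, th2)^2),
               2 * fit$objective, tolerance = 1e-6)
  # reordering measurements leaves the objective unchanged
  ds3 <- ds
  set.seed(1); ord <- sample(nrow(ds$measurements))
  ds3$measurements <- ds$measurements[ord, ]
  pr3 <- make_toy_problem(ds3)
  expect_equal(sum(emuflux:::problem_residuals(pr3, fit$theta)^2),
               fit$objective, tolerance = 1e-9)
})

test_that("noise-free INST fits recover fluxes and pools", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_inst,
                                   noise_molpct = 0, seed = 7,
                                   pools = toy$pools, timegrid = toy$timegrid)
  fit <- solve_fit_inst(make_toy_problem(ds), n_starts = 3, seed = 2)
  ref <- setNames(ds$reference$net$value, ds$reference$net$reaction)
  expect_lt(max(abs(fit$fluxes$net - ref[fit$fluxes$reaction])), 1)
  rel <- abs(fit$pools$size - toy$pools[fit$pools$metabolite]) /
    toy$pools[fit$pools$metabolite]
  expect_lt(max(rel), 0.01)
  # with pools fixed at truth, flux recovery sharpens
  fit2 <- solve_fit(make_toy_problem(ds, pools_free = FALSE),
                    n_starts = 3, seed = 2)
  expect_lt(max(abs(fit2$fluxes$net - ref[fit2$fluxes$reaction])), 0.1)
})

test_that("INST mode validates its inputs", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_inst,
                                   noise_molpct = 0, seed = 7,
                                   pools = toy$pools, timegrid = toy$timegrid)
  one_tp <- ds$measurements[ds$measurements$timepoint ==
                              ds$measurements$timepoint[1], ]
  expect_error(suppressWarnings(
    make_fit_problem(ds$net, one_tp, ds$flux_measurements,
                     ds$strategy, mode = "inst", pools = ds$pools)),
    ">= 2 timepoints")
  ss_tp <- ds$measurements
  ss_tp$timepoint <- "ss"
  expect_error(suppressWarnings(
    make_fit_problem(ds$net, ss_tp, ds$flux_measurements,
                     ds$strategy, mode = "inst", pools = ds$pools)),
    "numeric timepoints")
})

test_that("Monte-Carlo confidence machinery is seeded and consistent", {
  ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 1, seed = 33)
  fit <- fit_synthetic(ds, n_starts = 4, seed = 5)
  mc1 <- solve_with_confidence_intervals(fit, n_runs = 30, seed = 11)
  mc2 <- solve_with_confidence_intervals(fit, n_runs = 30, seed = 11)
  expect_identical(mc1$ci, mc2$ci)
  expect_equal(mc1$n_failed, 0L)
  ci <- mc1$ci
  expect_true(all(ci$lo <= ci$estimate + 1e-6 | ci$type != "net"))
  # shrinking the declared noise shrinks the CIs roughly proportionally
  fit_half <- fit
  fit_half$problem$meas$sd <- fit$problem$meas$sd / 2
  fit_half$problem$flux_meas$sd <- fit$problem$flux_meas$sd / 2
  fit_half$problem$groups <- local({
    m <- fit_half$problem$meas
    m |> dplyr::group_by(.data$emu, .data$timepoint) |> dplyr::group_split()
  })
  mc_half <- solve_with_confidence_intervals(fit_half, n_runs = 30, seed = 11)
  w1 <- (ci$hi - ci$lo)[ci$type == "net" & ci$quantity != "v1"]
  w2 <- (mc_half$ci$hi - mc_half$ci$lo)[ci$type == "net" & ci$quantity != "v1"]
  expect_equal(mean(w1 / w2), 2, tolerance = 0.35)
})
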