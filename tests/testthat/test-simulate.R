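test_that("steady-state simulation matches simple closed forms", {
  # pass-through chain: the product MDV is the substrate MDV, any flux
  net <- flux_network(data.frame(id = c("r1", "r2"),
                                 equation = c("A{ab} -> B{ab}",
                                              "B{ab} -> F{ab}")))
  st <- labeling_strategy(A = data.frame(mask = "10", fraction = 1, purity = 1))
  sim <- emu_simulator(net, "F_12", p13 = 0)
  for (f in c(1, 10, 250)) {
    out <- simulate_steady_state(sim, c(r1 = f, r2 = f), st)
    expect_equal(mdv_num(out$F_12), c(0, 1, 0))
  }
  # condensation: product equals the convolution of its precursors
  net2 <- flux_network(data.frame(
    id = c("i1", "i2", "cond"),
    equation = c("X{a} -> C{a}", "Y{b} -> D{b}", "C{a} + D{b} -> E{ab}")))
  st2 <- labeling_strategy(
    X = data.frame(mask = "1", fraction = 1, purity = 0.9),
    Y = data.frame(mask = "0", fraction = 1, purity = 1))
  out2 <- simulate_steady_state(net2, c(i1 = 5, i2 = 5, cond = 5), st2,
                                targets = c("E_12", "C_1", "D_1"))
  expect_equal(mdv_num(out2$E_12),
               mdv_num(conv(out2$C_1, out2$D_1)), tolerance = 1e-12)
})

test_that("EMU steady state equals the brute-force isotopomer oracle", {
  draws <- sample_toy_fluxes(n = 20, seed = 17)
  sim <- emu_simulator(toy$net, toy$targets_ss)
  for (i in seq_len(nrow(draws))) {
    v <- setNames(as.numeric(draws[i, ]), names(draws))
    emu <- simulate_steady_state(sim, v, toy$strategy)
    orc <- brute_force_mdvs(toy$net, v, toy$strategy, toy$targets_ss)
    for (tg in toy$targets_ss)
      expect_lt(max(abs(mdv_num(emu[[tg]]) - mdv_num(orc[[tg]]))), 1e-9)
  }
})

test_that("every simulated MDV is normalized", {
  draws <- sample_toy_fluxes(n = 5, seed = 23)
  sim <- emu_simulator(toy$net, toy$targets_ss)
  for (i in seq_len(nrow(draws))) {
    v <- setNames(as.numeric(draws[i, ]), names(draws))
    out <- simulate_steady_state(sim, v, toy$strategy)
    for (m in out) expect_equal(sum(mdv_num(m)), 1, tolerance = 1e-9)
  }
  tr <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy, toy$timegrid,
                      targets = toy$targets_inst)
  sums <- tapply(tr$value, paste(tr$emu, tr$t), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("all-zero fluxes make the balance singular", {
  v0 <- setNames(rep(0, 6), names(toy_v))
  expect_error(simulate_steady_state(toy$net, v0, toy$strategy,
                                     targets = "F_123"),
               "singular|zero total outflux")
})

test_that("INST trajectories start at natural abundance and reach steady state", {
  tg <- toy$targets_inst
  tr <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy, toy$timegrid,
                      targets = tg)
  at0 <- tr[tr$t == 0, ]
  for (g in tg) {
    n <- length(parse_emu(g)$idx)
    expect_equal(at0$value[at0$emu == g], mdv_num(natural_mdv(n)),
                 tolerance = 1e-9)
  }
  # endpoint at 50x the slowest turnover time matches the steady state
  outflux <- c(B = 110, C = 20, D = 90)  # consumption per pool at toy_v
  t_end <- 50 * max(toy$pools / outflux)
  tr2 <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy, c(0, t_end),
                       targets = tg)
  ss <- simulate_steady_state(toy$net, toy_v, toy$strategy, targets = tg)
  ends <- tr2[tr2$t == t_end, ]
  for (g in tg)
    expect_lt(max(abs(ends$value[ends$emu == g] - mdv_num(ss[[g]]))), 1e-6)
})

test_that("INST matches the brute-force isotopomer ODE oracle", {
  tg <- toy$targets_inst
  tr <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy, toy$timegrid,
                      targets = tg)
  orc <- brute_force_inst(toy$net, toy_v, toy$pools, toy$strategy, tg,
                          toy$timegrid)
  m <- dplyr::inner_join(tr, orc, by = c("emu", "t", "shift"),
                         suffix = c("_emu", "_orc"))
  expect_equal(nrow(m), nrow(tr))
  expect_lt(max(abs(m$value_emu - m$value_orc)), 2e-4)
})

test_that("halving every pool rescales time exactly", {
  tg <- toy$targets_inst
  half <- simulate_inst(toy$net, toy_v, toy$pools / 2, toy$strategy,
                        toy$timegrid, targets = tg)
  full <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy,
                        toy$timegrid * 2, targets = tg)
  expect_lt(max(abs(half$value - full$value)), 1e-8)
})

test_that("the first-order-hold integrator converges at second order", {
  tg <- "D_123"
  ref <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy, toy$timegrid,
                       targets = tg, dt_factor = 320)
  errs <- sapply(c(5, 10, 20), function(df) {
    tr <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy, toy$timegrid,
                        targets = tg, dt_factor = df)
    max(abs(tr$value - ref$value))
  })
  # halving the step should shrink the error ~4x; allow slack for
  # interpolation effects
  expect_gt(errs[1] / errs[2], 2.5)
  expect_gt(errs[2] / errs[3], 2.5)
})

test_that("label enrichment rises monotonically under a step input", {
  tg <- c("B_123", "D_123")
  tr <- simulate_inst(toy$net, toy_v, toy$pools, toy$strategy,
                      seq(0, 0.5, by = 0.025), targets = tg)
  for (g in tg) {
    d <- tr[tr$emu == g, ]
    enrich <- tapply(d$value * d$shift, d$t, sum)
    expect_true(all(diff(enrich[order(as.numeric(names(enrich)))]) > -1e-9))
  }
})

test_that("INST input validation", {
  expect_error(simulate_inst(toy$net, toy_v, toy$pools, toy$strategy,
                             c(0.1, 0.2), targets = "F_123"),
               "start at 0")
  bad_pools <- toy$pools; bad_pools["C"] <- 0
  expect_error(simulate_inst(toy$net, toy_v, bad_pools, toy$strategy,
                             c(0, 0.1), targets = "D_123"),
               "positive")
  expect_error(simulate_inst(toy$net, toy_v, toy$pools["B"], toy$strategy,
                             c(0, 0.1), targets = "D_123"),
               "missing pool")
})
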