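test_that("the canonical toy network is well formed", {
  expect_true(attr(validate_network(toy$net), "ok"))
  em <- decompose_network(toy$net, "F_123")
  expect_gt(nrow(em$reactions), 0L)
  # carbon routing: everything entering through A can leave through F
  r <- fba(toy$net, flux_bounds(toy$net, v1 = c(0, 100)), objective = "v5")
  expect_equal(r$objective_value, 100, tolerance = 1e-9)
  # at least one degree of freedom remains for fitting
  S_net <- toy$net$S[, toy$net$total_fluxes$direction == 1]
  expect_gte(ncol(S_net) - qr(S_net)$rank, 1L)
  # round trip through the embedded TSV text
  tf <- tempfile(fileext = ".tsv")
  writeLines(toy$reaction_table, tf)
  expect_equal(tidy(read_network(tf)), tidy(toy$net))
  unlink(tf)
})

test_that("random toy networks load, validate and stay feasible", {
  for (seed in c(5, 6, 7, 8)) {
    spec <- random_toy_network(seed)
    expect_true(attr(validate_network(spec$net), "ok"),
                label = spec$name)
    em <- decompose_network(spec$net, spec$targets_ss)
    src_sizes <- vapply(strsplit(em$reactions$sources, "+", fixed = TRUE),
                        function(ss) sum(vapply(ss, function(s)
                          length(parse_emu(s)$idx), 0L)), 0L)
    expect_equal(src_sizes, em$reactions$size)
    b <- flux_bounds(spec$net,
                     setNames(list(c(100, 100)),
                              spec$net$total_fluxes$flux_id[1]),
                     default_ub = 300)
    sm <- sample_feasible_fluxes(spec$net, b, n = 3, seed = seed)
    expect_lt(max(abs(spec$net$S %*% t(as.matrix(sm)))), 1e-8)
  }
})

test_that("oracle self-consistency on closed forms", {
  # pass-through chain
  net <- flux_network(data.frame(id = c("r1", "r2"),
                                 equation = c("A{ab} -> B{ab}",
                                              "B{ab} -> F{ab}")))
  st <- labeling_strategy(A = data.frame(mask = "10", fraction = 1, purity = 1))
  orc <- brute_force_mdvs(net, c(r1 = 7, r2 = 7), st, "F_12", p13 = 0)
  expect_equal(mdv_num(orc$F_12), c(0, 1, 0), tolerance = 1e-12)
  # condensation respects the convolution identity
  net2 <- flux_network(data.frame(
    id = c("i1", "i2", "cond"),
    equation = c("X{a} -> C{a}", "Y{b} -> D{b}", "C{a} + D{b} -> E{ab}")))
  st2 <- labeling_strategy(
    X = data.frame(mask = "1", fraction = 1, purity = 0.9),
    Y = data.frame(mask = "0", fraction = 1, purity = 1))
  orc2 <- brute_force_mdvs(net2, c(i1 = 2, i2 = 2, cond = 2), st2,
                           c("E_12", "C_1", "D_1"))
  expect_equal(mdv_num(orc2$E_12), mdv_num(conv(orc2$C_1, orc2$D_1)),
               tolerance = 1e-11)
  # transient endpoint converges to the steady state
  tr <- brute_force_inst(toy$net, toy_v, toy$pools, toy$strategy, "D_123",
                         c(0, 20))
  ss <- brute_force_mdvs(toy$net, toy_v, toy$strategy, "D_123")
  expect_lt(max(abs(tr$value[tr$t == 20] - mdv_num(ss$D_123))), 1e-7)
  # state-space cap enforced
  big <- flux_network(data.frame(id = "r",
                                 equation = "A{abcdefghijkl} -> B{abcdefghijkl}"))
  stb <- labeling_strategy(A = data.frame(mask = strrep("1", 12), fraction = 1))
  expect_error(brute_force_mdvs(big, c(r = 1), stb, "B_1", max_states = 64),
               "too large")
})

test_that("synthetic datasets are deterministic and noise-controlled", {
  d1 <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 1, seed = 5)
  d2 <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 1, seed = 5)
  expect_identical(d1$measurements, d2$measurements)
  expect_identical(d1$reference, d2$reference)
  d3 <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 1, seed = 6)
  expect_gt(max(abs(d1$measurements$mean - d3$measurements$mean)), 1e-6)
  # zero noise reproduces the simulation exactly
  d0 <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                   noise_molpct = 0, seed = 5)
  v <- setNames(d0$reference$total$value, d0$reference$total$flux_id)
  sim <- simulate_steady_state(toy$net, v, toy$strategy,
                               targets = toy$targets_ss)
  for (g in toy$targets_ss) {
    got <- d0$measurements$mean[d0$measurements$emu == g]
    expect_equal(got, mdv_num(sim[[g]]), tolerance = 1e-12)
  }
  expect_equal(d0$measurements$sd[1], 0.01)
  # the reference draw satisfies the declared study conditions
  expect_equal(d0$reference$net$value[d0$reference$net$reaction == "v1"], 100,
               tolerance = 1e-6)
  expect_lte(max(d0$reference$xch$value), 50 + 1e-8)
})

test_that("recovery quality degrades monotonically with noise", {
  err_at <- function(noise) {
    errs <- sapply(c(41, 42, 43), function(s) {
      ds <- generate_synthetic_dataset(toy$net, toy$strategy, toy$targets_ss,
                                       noise_molpct = noise, seed = s)
      fit <- fit_synthetic(ds, n_starts = 4, seed = s)
      ref <- setNames(ds$reference$net$value, ds$reference$net$reaction)
      mean(abs(fit$fluxes$net - ref[fit$fluxes$reaction]))
    })
    mean(errs)
  }
  e0 <- err_at(0); e1 <- err_at(1); e5 <- err_at(5)
  expect_lt(e0, e1)
  expect_lt(e1, e5)
})
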