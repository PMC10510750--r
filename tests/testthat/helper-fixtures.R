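# shared fixtures, built once per test run
toy <- toynet1()

# a balanced total-flux vector for ToyNet-1 (uptake 100, v3 = v4 = 20,
# exchange 10 on the reversible shuttle)
toy_v <- c(v1 = 100, v2_f = 70, v2_b = 10, v3 = 20, v4 = 20, v5 = 80)

# reference bounds used for sampling feasible ToyNet-1 fluxes in tests:
# same study conditions as the synthetic-data generator
toy_bounds <- local({
  flux_bounds(toy$net, v1 = c(100, 100), v2_b = c(0, 50), default_ub = 300)
})

sample_toy_fluxes <- function(n, seed) {
  sample_feasible_fluxes(toy$net, toy_bounds, n = n, seed = seed)
}

mdv_num <- function(x) as.numeric(x)

# independent backward atom-closure used as the decomposition oracle: works
# directly on the parsed reaction table, not on the package's EMU machinery
closure_oracle <- function(net, target) {
  want <- list(parse_emu(target))
  seen <- character()
  found <- character()
  while (length(want)) {
    cur <- want[[1]]; want <- want[-1]
    nm <- emu_name(cur$met, cur$idx)
    if (nm %in% seen) next
    seen <- c(seen, nm)
    found <- c(found, nm)
    if (net$metabolites$is_substrate[net$metabolites$id == cur$met]) next
    tf <- net$total_fluxes
    for (k in seq_len(nrow(tf))) {
      r <- net$reactions[[tf$reaction[k]]]
      prods <- if (tf$direction[k] == 1) r$products else r$substrates
      subs <- if (tf$direction[k] == 1) r$substrates else r$products
      for (i in which(prods$met == cur$met & nzchar(prods$map))) {
        letters_needed <- strsplit(prods$map[i], "")[[1]][cur$idx]
        for (j in seq_len(nrow(subs))) {
          smap <- strsplit(subs$map[j], "")[[1]]
          pos <- which(smap %in% letters_needed)
          if (length(pos))
            want <- c(want, list(list(met = subs$met[j], idx = sort(pos))))
        }
      }
    }
  }
  sort(found)
}
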