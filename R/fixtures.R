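#' The canonical toy network
#'
#' A five-reaction network exercising every EMU code path: a linear entry, a
#' reversible shuttle, a cleavage, a condensation, and an export.
#' Balanced metabolites are `B`, `C`, `D`; `E` and
#' `F` are excreted. `A` is fed as a 4:1 mixture of `[1-13C]` and fully
#' labeled `[U-13C]` tracer, so every atom position carries kinetic
#' information and all three pools are identifiable in INST mode (under a
#' pure 1-position tracer the atoms feeding `C` stay unlabeled).
#'
#' ```
#' v1: A{abc} -> B{abc}
#' v2: B{abc} <-> D{abc}
#' v3: B{abc} -> C{bc} + E{a}
#' v4: B{abc} + C{de} -> D{bcd} + E{a} + E{e}
#' v5: D{abc} -> F{abc}
#' ```
#'
#' The returned spec bundles the network, the tracer strategy, default pool
#' sizes and an INST sampling timegrid, the default measured EMUs for both
#' modes, and the list of identifiable net fluxes used by recovery checks.
#'
#' @return a `toy_network_spec` list: `name`, `reaction_table` (TSV text),
#'   `net`, `strategy`, `pools`, `timegrid`, `targets_ss`, `targets_inst`,
#'   `identifiable`, `uptake`.
#' @export
toynet1 <- function() {
  tsv <- paste(
    "id\tequation\treversible",
    "v1\tA{abc} -> B{abc}\tFALSE",
    "v2\tB{abc} -> D{abc}\tTRUE",
    "v3\tB{abc} -> C{bc} + E{a}\tFALSE",
    "v4\tB{abc} + C{de} -> D{bcd} + E{a} + E{e}\tFALSE",
    "v5\tD{abc} -> F{abc}\tFALSE",
    sep = "\n")
  tf <- tempfile(fileext = ".tsv")
  writeLines(tsv, tf)
  net <- read_network(tf)
  unlink(tf)
  structure(list(
    name = "ToyNet-1",
    reaction_table = tsv,
    net = net,
    strategy = labeling_strategy(A = data.frame(
      mask = c("100", "111"), fraction = c(0.8, 0.2), purity = 1)),
    pools = c(B = 15, C = 3, D = 10),
    timegrid = c(0, 0.05, 0.1, 0.2, 0.5),
    targets_ss = c("F_123", "E_1"),
    targets_inst = c("B_123", "C_12", "D_123", "E_1"),
    identifiable = c("v1", "v2", "v3", "v4", "v5"),
    uptake = "v1"), class = "toy_network_spec")
}

#' Random small atom-mapped networks
#'
#' Draws a feasible toy network from a family of three scaffold topologies
#' (chain with cleavage and condensation, a recycling cycle with
#' condensation, a reversible branch) whose atom mappings are randomized by
#' permutation — the randomized atom transitions are what stress EMU
#' decomposition, while the fixed scaffolds guarantee a nonempty flux
#' polytope.
#'
#' Atom permutations that leave an EMU loop disconnected from the substrate
#' (possible in the recycling scaffold) are rejected and redrawn, so every
#' returned network decomposes cleanly.
#'
#' @param seed RNG seed; also selects the scaffold.
#' @return a `toy_network_spec` (fields as in [toynet1()]; `pools` and
#'   `timegrid` provided for the INST-capable scaffolds).
#' @export
random_toy_network <- function(seed) {
  set.seed(seed)
  for (try_i in 1:50) {
    spec <- try(random_toy_network_once(), silent = TRUE)
    if (!inherits(spec, "try-error")) return(spec)
  }
  stop("could not draw a decomposable random network", call. = FALSE)
}

random_toy_network_once <- function() {
  scaffold <- sample(1:3, 1)
  pm <- function(k) paste(letters[sample(k)], collapse = "")
  split2 <- function(map, k1) {
    idx <- sample(nchar(map))
    chs <- strsplit(map, "")[[1]]
    list(paste(chs[sort(idx[1:k1])], collapse = ""),
         paste(chs[sort(idx[-(1:k1)])], collapse = ""))
  }
  if (scaffold == 1) {
    # chain with a reversible cleavage (whose backward direction is a
    # condensation) and a competing sink
    bmap <- pm(3)
    sp <- split2("abc", 2)
    rows <- c("id\tequation\treversible",
      sprintf("u1\tA{abc} -> B{%s}\tFALSE", bmap),
      sprintf("u2\tB{abc} -> C{%s} + D{%s}\tTRUE", sp[[1]], sp[[2]]),
      sprintf("u3\tC{ab} + D{c} -> F{%s}\tFALSE", pm(3)),
      sprintf("u4\tB{abc} -> G{%s}\tFALSE", pm(3)))
    targets <- c("F_123", "G_123")
    pools <- c(B = 12, C = 4, D = 2)
  } else if (scaffold == 2) {
    # recycling cycle with condensation (EMU cycles across sizes)
    sp <- split2("abcd", 2)
    rows <- c("id\tequation\treversible",
      sprintf("u1\tS{ab} + M{cd} -> T{%s}\tFALSE", pm(4)),
      sprintf("u2\tT{abcd} -> U{%s}\tTRUE", pm(4)),
      sprintf("u3\tU{abcd} -> M{%s} + W{%s}\tFALSE", sp[[1]], sp[[2]]),
      "u4\tW{ab} -> X{ab}\tFALSE")
    targets <- c("X_12", "T_1234")
    pools <- c(M = 5, T = 8, U = 6, W = 3)
  } else {
    # reversible branch with cleavage
    sp <- split2("abc", 2)
    rows <- c("id\tequation\treversible",
      sprintf("u1\tA{abc} -> B{%s}\tFALSE", pm(3)),
      sprintf("u2\tB{abc} -> C{%s}\tTRUE", pm(3)),
      sprintf("u3\tC{abc} -> D{%s} + E{%s}\tFALSE", sp[[1]], sp[[2]]),
      sprintf("u4\tD{ab} -> F{%s}\tFALSE", pm(2)),
      sprintf("u5\tB{abc} -> G{%s}\tFALSE", pm(3)))
    targets <- c("F_12", "G_123")
    pools <- c(B = 10, C = 6, D = 3)
  }
  tf <- tempfile(fileext = ".tsv")
  writeLines(rows, tf)
  net <- read_network(tf)
  unlink(tf)
  sub <- net$metabolites$id[net$metabolites$is_substrate]
  strat <- purrr::map(sub, function(m) {
    n <- net$metabolites$n_atoms[net$metabolites$id == m]
    data.frame(mask = paste0("1", strrep("0", n - 1L)), fraction = 1, purity = 1)
  })
  names(strat) <- sub
  out <- structure(list(
    name = sprintf("RandomNet (scaffold %d)", scaffold),
    reaction_table = paste(rows, collapse = "\n"),
    net = net,
    strategy = labeling_strategy(strat),
    pools = pools,
    timegrid = c(0, 0.05, 0.1, 0.2, 0.5),
    targets_ss = targets,
    targets_inst = targets,
    identifiable = unique(net$total_fluxes$reaction),
    uptake = names(net$reactions)[1]), class = "toy_network_spec")
  decompose_network(net, out$targets_ss)  # reject undecomposable atom draws
  out
}

# ---- brute-force full-isotopomer oracle ------------------------------------
# Independent of the EMU machinery: works on the complete 2^n isotopomer
# distribution of every non-substrate metabolite, by fixed-point iteration
# (steady state) or dense adaptive ODE integration (transient).

iso_pattern_mass <- function(n, idx) {
  # mass shift of each of the 2^n patterns restricted to atom subset idx
  sapply(0:(2^n - 1), function(p) sum(bitwAnd(p, 2^(idx - 1L)) > 0))
}

substrate_iso_dist <- function(n, iso_df, p13) {
  out <- numeric(2^n)
  if (is.null(iso_df$purity)) iso_df$purity <- 1
  for (k in seq_len(nrow(iso_df))) {
    bits <- strsplit(iso_df$mask[k], "")[[1]]
    pat <- rep(1, 1)
    dist <- 1
    for (j in seq_len(n)) {
      p <- if (bits[j] == "1") iso_df$purity[k] else p13
      dist <- c(dist * (1 - p), dist * p)  # low bit = atom 1 ... builds LSB-first
    }
    out <- out + iso_df$fraction[k] * dist
  }
  out
}

# production machinery: for each (total flux, product instance) of metabolite,
# a function mapping current isotopomer state -> product-pattern distribution
oracle_structure <- function(net, strategy, p13) {
  mets <- net$metabolites
  n_at <- stats::setNames(mets$n_atoms, mets$id)
  is_sub <- stats::setNames(mets$is_substrate, mets$id)
  states <- mets$id[!mets$is_substrate & mets$n_atoms > 0]
  sub_dist <- purrr::map(mets$id[mets$is_substrate], function(m)
    substrate_iso_dist(n_at[[m]], as.data.frame(strategy[[m]]), p13))
  names(sub_dist) <- mets$id[mets$is_substrate]

  prod_recs <- list()
  for (m in states) {
    recs <- producing_records(net, m)
    prod_recs[[m]] <- purrr::map(recs, function(rec) {
      pmap <- strsplit(rec$map, "")[[1]]
      ins <- list()
      for (i in seq_len(nrow(rec$sub_side))) {
        smap <- strsplit(rec$sub_side$map[i], "")[[1]]
        if (any(smap %in% pmap))
          ins <- c(ins, list(list(met = rec$sub_side$met[i], map = smap)))
      }
      # enumerate joint substrate patterns -> product pattern index map
      npat_each <- purrr::map_int(ins, ~ 2L^length(.x$map))
      grid <- expand.grid(purrr::map(npat_each, ~ 0:(.x - 1L)))
      tgt <- integer(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        labeled <- character()
        for (i in seq_along(ins)) {
          pat <- grid[g, i]
          on <- which(bitwAnd(pat, 2^(seq_along(ins[[i]]$map) - 1L)) > 0)
          labeled <- c(labeled, ins[[i]]$map[on])
        }
        tgt[g] <- sum(2^(which(pmap %in% labeled) - 1L))
      }
      list(flux_id = rec$flux_id, coef = rec$coef, ins = ins,
           grid = as.matrix(grid), tgt = tgt)
    })
  }
  cons <- purrr::map(states, ~ consumption_form(net, .x))
  names(cons) <- states
  list(states = states, n_at = n_at, sub_dist = sub_dist, prod_recs = prod_recs,
       cons = cons, tf_ids = net$total_fluxes$flux_id)
}

oracle_production <- function(os, m, xlist, v) {
  out <- numeric(2^os$n_at[[m]])
  total <- 0
  for (rec in os$prod_recs[[m]]) {
    w <- rec$coef * v[[rec$flux_id]]
    if (w == 0) next
    # joint probability of each grid row under current distributions
    pr <- rep(1, nrow(rec$grid))
    for (i in seq_along(rec$ins)) {
      met <- rec$ins[[i]]$met
      d <- if (!is.null(os$sub_dist[[met]])) os$sub_dist[[met]] else xlist[[met]]
      pr <- pr * d[rec$grid[, i] + 1L]
    }
    acc <- numeric(length(out))
    for (g in seq_along(rec$tgt))
      acc[rec$tgt[g] + 1L] <- acc[rec$tgt[g] + 1L] + pr[g]
    out <- out + w * acc
    total <- total + w
  }
  list(dist = out, weight = total)
}

#' Brute-force isotopomer oracle (steady state)
#'
#' Solves the complete isotopomer balance of every non-substrate metabolite
#' by fixed-point iteration, entirely independent of the EMU decomposition,
#' and marginalizes to the MDVs of the requested EMUs. Intended as the
#' verification oracle for the EMU simulator on networks with small
#' isotopomer state spaces.
#'
#' @inheritParams simulate_steady_state
#' @param net a `flux_network`.
#' @param p13 natural 13C abundance.
#' @param max_states cap on the summed isotopomer state space (default 4096).
#' @param tol fixed-point convergence tolerance (default 1e-13).
#' @return named list of `mdv` objects for `targets`.
#' @export
brute_force_mdvs <- function(net, fluxes, strategy, targets, p13 = 0.0107,
                             max_states = 4096, tol = 1e-13) {
  v <- as_total_vector(net, fluxes)
  os <- oracle_structure(net, strategy, p13)
  if (sum(2^os$n_at[os$states]) > max_states)
    stop("isotopomer state space too large for the oracle", call. = FALSE)
  x <- purrr::map(os$states, function(m) {
    n <- os$n_at[[m]]
    substrate_iso_dist(n, data.frame(mask = strrep("0", n), fraction = 1), p13)
  })
  names(x) <- os$states
  for (it in 1:200000) {
    delta <- 0
    for (m in os$states) {
      pr <- oracle_production(os, m, x, v)
      tot <- sum(pr$dist)
      if (tot <= 0)
        stop(sprintf("metabolite '%s' receives no labeled production", m),
             call. = FALSE)
      # normalize by the produced total rather than the consumption flux:
      # identical at flux balance, and it stops bilinear condensation loops
      # from doubling floating-point sum errors every sweep
      newx <- pr$dist / tot
      delta <- max(delta, max(abs(newx - x[[m]])))
      x[[m]] <- newx
    }
    if (delta < tol) break
  }
  if (delta >= tol) stop("oracle fixed point did not converge", call. = FALSE)
  oracle_marginalize(os, x, targets, strategy, p13)
}

oracle_marginalize <- function(os, x, targets, strategy, p13) {
  out <- purrr::map(targets, function(tg) {
    p <- parse_emu(tg)
    d <- if (!is.null(os$sub_dist[[p$met]])) os$sub_dist[[p$met]] else x[[p$met]]
    mass <- iso_pattern_mass(os$n_at[[p$met]], p$idx)
    mdv(as.numeric(tapply(d, factor(mass, levels = 0:length(p$idx)), sum,
                          default = 0)))
  })
  stats::setNames(out, targets)
}

#' Brute-force isotopomer oracle (transient)
#'
#' Integrates the complete isotopomer ODE system with an adaptive
#' high-accuracy method (`deSolve::lsoda`), independent of the EMU
#' first-order-hold integrator, and marginalizes to EMU MDV trajectories.
#'
#' @inheritParams brute_force_mdvs
#' @param pools named pool sizes for balanced metabolites.
#' @param timegrid output times starting at 0.
#' @return tibble `emu`, `t`, `shift`, `value` (same shape as
#'   [simulate_inst()]).
#' @export
brute_force_inst <- function(net, fluxes, pools, strategy, targets, timegrid,
                             p13 = 0.0107, max_states = 4096) {
  v <- as_total_vector(net, fluxes)
  os <- oracle_structure(net, strategy, p13)
  dyn <- os$states[os$states %in% names(pools)]
  alg <- setdiff(os$states, dyn)
  sizes <- stats::setNames(2^os$n_at[dyn], dyn)
  if (sum(2^os$n_at[os$states]) > max_states)
    stop("isotopomer state space too large for the oracle", call. = FALSE)
  offs <- c(0, cumsum(sizes))
  unpack <- function(y) {
    x <- purrr::map(seq_along(dyn), ~ y[(offs[.x] + 1):offs[.x + 1]])
    names(x) <- dyn
    x
  }
  deriv <- function(t, y, parms) {
    x <- unpack(y)
    # algebraic sinks appear only as targets; they never feed dynamics
    dy <- numeric(length(y))
    for (i in seq_along(dyn)) {
      m <- dyn[i]
      pr <- oracle_production(os, m, x, v)
      cw <- os$cons[[m]]
      out <- if (length(cw)) sum(cw * v[names(cw)]) else pr$weight
      dy[(offs[i] + 1):offs[i + 1]] <-
        (pr$dist - out * x[[m]]) / pools[[m]]
    }
    list(dy)
  }
  y0 <- unlist(purrr::map(dyn, function(m) {
    n <- os$n_at[[m]]
    substrate_iso_dist(n, data.frame(mask = strrep("0", n), fraction = 1), p13)
  }))
  sol <- deSolve::lsoda(y0, timegrid, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  rows <- purrr::map(targets, function(tg) {
    p <- parse_emu(tg)
    mass <- iso_pattern_mass(os$n_at[[p$met]], p$idx)
    vals <- purrr::map(seq_along(timegrid), function(k) {
      x <- unpack(sol[k, -1])
      d <- if (!is.null(os$sub_dist[[p$met]])) os$sub_dist[[p$met]]
        else if (p$met %in% dyn) x[[p$met]]
        else {  # algebraic sink: instantaneous inflow mixture
          pr <- oracle_production(os, p$met, x, v)
          pr$dist / pr$weight
        }
      as.numeric(tapply(d, factor(mass, levels = 0:length(p$idx)), sum,
                        default = 0))
    })
    tibble::tibble(emu = tg,
                   t = rep(timegrid, each = length(p$idx) + 1L),
                   shift = rep(0:length(p$idx), length(timegrid)),
                   value = unlist(vals))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$emu, .data$t, .data$shift)
}
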