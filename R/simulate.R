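#' Labeling strategies
#'
#' A labeling strategy declares, per tracer substrate, the isotopomers added
#' to the medium: a 0/1 mask over the substrate's atoms, the molar fraction
#' of that isotopomer, and its isotopic purity (probability that an atom
#' declared labeled really is heavy). Unlabeled positions carry natural
#' abundance.
#'
#' @param ... named arguments, one per substrate metabolite, each a data
#'   frame with columns `mask`, `fraction`, and optionally `purity`.
#' @return a named list, class `labeling_strategy`.
#' @examples
#' labeling_strategy(A = data.frame(mask = "100", fraction = 1, purity = 1))
#' @export
labeling_strategy <- function(...) {
  st <- list(...)
  if (length(st) == 1L && is.null(names(st)) && is.list(st[[1]]) &&
      !is.data.frame(st[[1]])) st <- st[[1]]
  for (nm in names(st)) {
    df <- as.data.frame(st[[nm]])
    if (is.null(df$purity)) df$purity <- 1
    if (abs(sum(df$fraction) - 1) > 1e-6)
      stop(sprintf("fractions for substrate '%s' must sum to 1", nm), call. = FALSE)
    st[[nm]] <- df
  }
  structure(st, class = "labeling_strategy")
}

# substrate-EMU MDV cache for one (strategy, p13): returns numeric vectors
substrate_cache <- function(strategy, p13) {
  env <- new.env(parent = emptyenv())
  function(emu) {
    got <- env[[emu]]
    if (!is.null(got)) return(got)
    p <- parse_emu(emu)
    if (!p$met %in% names(strategy))
      stop(sprintf("labeling strategy does not cover substrate '%s'", p$met),
           call. = FALSE)
    v <- as.numeric(substrate_mdv(p$idx, strategy[[p$met]], p13 = p13))
    env[[emu]] <- v
    v
  }
}

#' Build a reusable EMU simulator
#'
#' Decomposes the network for the requested target EMUs and compiles the
#' size-ordered balance systems into an index structure that can be
#' re-evaluated for many flux vectors cheaply — the workhorse behind both
#' simulation front ends and the estimation inner loop.
#'
#' @param net a `flux_network`.
#' @param targets character vector of EMU names.
#' @param p13 natural 13C abundance for unlabeled positions.
#' @return an `emu_simulator` object.
#' @export
emu_simulator <- function(net, targets, p13 = 0.0107) {
  emunet <- decompose_network(net, targets)
  structure(list(compiled = compile_emu_system(emunet), emunet = emunet,
                 p13 = p13, net = net, targets = targets),
            class = "emu_simulator")
}

# assemble A (with outflux diagonal), B, and row metadata for one size
assemble_size <- function(sys, v) {
  k <- length(sys$internal)
  m <- length(sys$ycombos)
  A <- matrix(0, k, k)
  B <- matrix(0, k, max(m, 1L))
  inflow <- numeric(k)
  if (!is.null(sys$A)) for (r in seq_len(nrow(sys$A))) {
    tr <- sys$A[r, ]
    w <- tr[4] * v[tr[3]]
    A[tr[1], tr[2]] <- A[tr[1], tr[2]] + w
    inflow[tr[1]] <- inflow[tr[1]] + w
  }
  if (!is.null(sys$B)) for (r in seq_len(nrow(sys$B))) {
    tr <- sys$B[r, ]
    w <- tr[4] * v[tr[3]]
    B[tr[1], tr[2]] <- B[tr[1], tr[2]] + w
    inflow[tr[1]] <- inflow[tr[1]] + w
  }
  out <- numeric(k)
  for (i in seq_len(k)) {
    cw <- sys$cons[[i]]
    out[i] <- if (nrow(cw)) sum(cw[, 2] * v[cw[, 1]]) else 0
    if (out[i] <= 0) out[i] <- inflow[i]  # excreted sink: instantaneous mixture
    if (out[i] <= 0)
      stop(sprintf("zero total outflux for EMU '%s': singular balance",
                   sys$internal[i]), call. = FALSE)
    A[i, i] <- A[i, i] - out[i]
  }
  list(A = A, B = B, out = out)
}

# Y block (combos x (size+1)) given a lookup for solved/source MDVs
y_block <- function(sys, lookup) {
  m <- length(sys$ycombos)
  Y <- matrix(0, max(m, 1L), sys$size + 1L)
  if (m) for (j in seq_len(m)) {
    srcs <- sys$ysources[[j]]
    val <- lookup(srcs[1])
    for (s in srcs[-1]) val <- conv_raw(val, lookup(s))
    Y[j, ] <- val
  }
  Y
}

# core steady-state cascade; returns an environment of solved MDVs
ss_core <- function(compiled, v, sub_lookup) {
  solved <- new.env(parent = emptyenv())
  lookup <- function(emu) {
    got <- solved[[emu]]
    if (!is.null(got)) return(got)
    sub_lookup(emu)
  }
  for (s in compiled$sizes) {
    sys <- compiled$systems[[as.character(s)]]
    if (is.null(sys)) next
    asm <- assemble_size(sys, v)
    Y <- y_block(sys, lookup)
    X <- solve(asm$A, -(asm$B %*% Y))
    for (i in seq_along(sys$internal)) solved[[sys$internal[i]]] <- X[i, ]
  }
  solved
}

#' Simulate MDVs at isotopic steady state
#'
#' Solves the size-ordered EMU balance systems `A X = -B Y` for a given
#' total-flux distribution and labeling strategy, where `Y` stacks substrate
#' MDVs and convolutions of already-solved smaller EMUs.
#'
#' @param sim an [emu_simulator()], or a `flux_network` (targets then
#'   required).
#' @param fluxes total fluxes: the tibble from [split_total_fluxes()] or a
#'   named vector over total-flux ids.
#' @param strategy a [labeling_strategy()].
#' @param targets EMU names (only needed when `sim` is a network).
#' @return named list of `mdv` objects, one per target.
#' @export
simulate_steady_state <- function(sim, fluxes, strategy, targets = NULL) {
  if (inherits(sim, "flux_network")) {
    if (is.null(targets)) stop("targets required", call. = FALSE)
    sim <- emu_simulator(sim, targets)
  }
  v <- as_total_vector(sim$net, fluxes)
  sub_lookup <- substrate_cache(strategy, sim$p13)
  solved <- ss_core(sim$compiled, v, sub_lookup)
  out <- purrr::map(sim$targets, function(tg) {
    val <- solved[[tg]]
    if (is.null(val)) val <- sub_lookup(tg)  # target on a substrate metabolite
    mdv(val)
  })
  stats::setNames(out, sim$targets)
}

# coerce user flux input to named vector over total-flux ids
as_total_vector <- function(net, fluxes) {
  ids <- net$total_fluxes$flux_id
  if (is.data.frame(fluxes)) fluxes <- stats::setNames(fluxes$value, fluxes$flux_id)
  if (is.null(names(fluxes))) {
    if (length(fluxes) != length(ids)) stop("flux vector length mismatch", call. = FALSE)
    return(stats::setNames(as.numeric(fluxes), ids))
  }
  miss <- setdiff(ids, names(fluxes))
  if (length(miss))
    stop(sprintf("missing total fluxes: %s", paste(miss, collapse = ", ")), call. = FALSE)
  as.numeric(fluxes[ids]) -> v
  stats::setNames(v, ids)
}

# first-order-hold step matrices for dX/dt = M X + N U(t), U piecewise linear:
# X1 = F X0 + G1 U0 + G2 (U1 - U0)/h  (exact for the held system)
foh_matrices <- function(M, N, h) {
  n <- nrow(M); m <- ncol(N)
  Z <- matrix(0, n + 2 * m, n + 2 * m)
  Z[1:n, 1:n] <- M
  Z[1:n, n + 1:m] <- N
  if (m) Z[n + 1:m, n + m + 1:m] <- diag(m)
  E <- as.matrix(Matrix::expm(Z * h))
  list(F = E[1:n, 1:n, drop = FALSE],
       G1 = E[1:n, n + 1:m, drop = FALSE],
       G2 = E[1:n, n + m + 1:m, drop = FALSE])
}

# transient EMU cascade on a shared uniform internal grid.
# Returns list(grid, traj): traj is an env of (n_steps+1) x (size+1) matrices.
inst_core <- function(compiled, v, pools, sub_lookup, t_end, n_steps, p13) {
  h <- t_end / n_steps
  tgrid <- seq(0, t_end, length.out = n_steps + 1L)
  traj <- new.env(parent = emptyenv())
  lookup_t <- function(emu, k) {
    got <- traj[[emu]]
    if (!is.null(got)) return(got[k, ])
    sub_lookup(emu)  # substrate: constant step input
  }
  for (s in compiled$sizes) {
    sys <- compiled$systems[[as.character(s)]]
    if (is.null(sys)) next
    asm <- assemble_size(sys, v)
    ints <- sys$internal
    met_of <- purrr::map_chr(ints, ~ parse_emu(.x)$met)
    dyn <- which(met_of %in% names(pools))
    alg <- setdiff(seq_along(ints), dyn)
    nat <- as.numeric(natural_mdv(s, p13))
    m <- length(sys$ycombos)
    # Y trajectory: combos x (size+1) at each grid point
    Yk <- function(k) y_block_t(sys, lookup_t, k)
    if (length(dyn)) {
      cvec <- as.numeric(pools[met_of[dyn]])
      if (any(!is.finite(cvec)) || any(cvec <= 0))
        stop("non-positive pool size in EMU network", call. = FALSE)
      Ad <- asm$A[dyn, dyn, drop = FALSE]
      # same-size inputs from algebraic nodes cannot occur (sinks only)
      Bd <- asm$B[dyn, , drop = FALSE]
      M <- Ad / cvec
      N <- Bd / cvec
      foh <- foh_matrices(M, N, h)
      X <- matrix(nat, length(dyn), s + 1L, byrow = TRUE)
      store <- array(0, dim = c(n_steps + 1L, length(dyn), s + 1L))
      store[1L, , ] <- X
      Y0 <- Yk(1L)
      for (k in seq_len(n_steps)) {
        Y1 <- Yk(k + 1L)
        X <- foh$F %*% X + foh$G1 %*% Y0 + foh$G2 %*% ((Y1 - Y0) / h)
        store[k + 1L, , ] <- X
        Y0 <- Y1
      }
      for (i in seq_along(dyn))
        traj[[ints[dyn[i]]]] <- store[, i, , drop = TRUE]
    }
    if (length(alg)) {
      # excreted sinks: instantaneous flux-weighted mixture of their inflows
      for (i in alg) {
        acc <- matrix(0, n_steps + 1L, s + 1L)
        if (!is.null(sys$A)) for (r in seq_len(nrow(sys$A))) {
          tr <- sys$A[r, ]
          if (tr[1] == i) {
            srcmat <- traj[[ints[tr[2]]]]
            acc <- acc + tr[4] * v[tr[3]] * srcmat
          }
        }
        if (!is.null(sys$B)) for (r in seq_len(nrow(sys$B))) {
          tr <- sys$B[r, ]
          if (tr[1] == i) for (k in 0:n_steps) {
            srcs <- sys$ysources[[tr[2]]]
            val <- lookup_t(srcs[1], k + 1L)
            for (sn in srcs[-1]) val <- conv_raw(val, lookup_t(sn, k + 1L))
            acc[k + 1L, ] <- acc[k + 1L, ] + tr[4] * v[tr[3]] * val
          }
        }
        traj[[ints[i]]] <- acc / asm$out[i]
      }
    }
  }
  list(grid = tgrid, traj = traj)
}

y_block_t <- function(sys, lookup_t, k) {
  m <- length(sys$ycombos)
  Y <- matrix(0, max(m, 1L), sys$size + 1L)
  if (m) for (j in seq_len(m)) {
    srcs <- sys$ysources[[j]]
    val <- lookup_t(srcs[1], k)
    for (s in srcs[-1]) val <- conv_raw(val, lookup_t(s, k))
    Y[j, ] <- val
  }
  Y
}

# linear interpolation of a trajectory matrix onto output times
interp_traj <- function(grid, mat, times) {
  out <- matrix(0, length(times), ncol(mat))
  for (j in seq_len(ncol(mat)))
    out[, j] <- stats::approx(grid, mat[, j], xout = times, rule = 2)$y
  out
}

#' Simulate transient (INST) MDV trajectories
#'
#' Integrates the isotopically nonstationary EMU cascade
#' `diag(c) dX/dt = A X + B Y(t)` size by size, starting every EMU at its
#' natural-abundance MDV with the tracer switched on at `t = 0`. The
#' integrator holds the inhomogeneous term piecewise linear over a uniform
#' internal grid and advances each step with the exact matrix-exponential
#' solution of the held system (noncausal first-order-hold equivalent); the
#' matrix exponentials are computed once per size and reused. The internal
#' step is `min(c_i / outflux_i) / 5`, refined geometrically if the unit-sum
#' invariant drifts beyond 1e-6.
#'
#' @inheritParams simulate_steady_state
#' @param pools named vector of pool sizes (concentrations) for every
#'   balanced metabolite in the EMU network; positive.
#' @param timegrid output times, starting at 0 (seconds or any unit
#'   consistent with fluxes and pools).
#' @param dt_factor internal-grid refinement factor (steps per fastest
#'   turnover time; default 20).
#' @return an `mdv_trajectory`: tibble with columns `emu`, `t`, `shift`,
#'   `value`.
#' @export
simulate_inst <- function(sim, fluxes, pools, strategy, timegrid,
                          targets = NULL, dt_factor = 20) {
  if (inherits(sim, "flux_network")) {
    if (is.null(targets)) stop("targets required", call. = FALSE)
    sim <- emu_simulator(sim, targets)
  }
  if (timegrid[1] != 0 || is.unsorted(timegrid, strictly = TRUE))
    stop("timegrid must start at 0 and be strictly increasing", call. = FALSE)
  v <- as_total_vector(sim$net, fluxes)
  pools <- check_pools(sim, pools)
  sub_lookup <- substrate_cache(strategy, sim$p13)
  t_end <- max(timegrid)
  n_steps <- inst_steps(sim, v, pools, t_end, dt_factor)
  for (attempt in 1:8) {
    res <- inst_core(sim$compiled, v, pools, sub_lookup, t_end, n_steps, sim$p13)
    drift <- 0
    for (tg in sim$targets) {
      mat <- target_traj(res, tg, sub_lookup)
      drift <- max(drift, max(abs(rowSums(mat) - 1)))
    }
    if (drift <= 1e-6) break
    n_steps <- n_steps * 2L
  }
  rows <- purrr::map(sim$targets, function(tg) {
    mat <- interp_traj(res$grid, target_traj(res, tg, sub_lookup), timegrid)
    tibble::tibble(emu = tg,
                   t = rep(timegrid, ncol(mat)),
                   shift = rep(0:(ncol(mat) - 1L), each = length(timegrid)),
                   value = as.vector(mat))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$emu, .data$t, .data$shift)
  class(out) <- c("mdv_trajectory", class(out))
  out
}

target_traj <- function(res, tg, sub_lookup) {
  mat <- res$traj[[tg]]
  if (is.null(mat)) {
    val <- sub_lookup(tg)
    mat <- matrix(val, length(res$grid), length(val), byrow = TRUE)
  }
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
  mat
}

check_pools <- function(sim, pools) {
  # every balanced metabolite appearing as an internal EMU needs a pool
  ints <- unlist(purrr::map(sim$compiled$systems, "internal"))
  need <- unique(purrr::map_chr(ints, ~ parse_emu(.x)$met))
  bal <- sim$net$metabolites$id[sim$net$metabolites$is_balanced]
  need <- intersect(need, bal)
  miss <- setdiff(need, names(pools))
  if (length(miss))
    stop(sprintf("missing pool sizes for: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (any(pools[need] <= 0)) stop("pool sizes must be positive", call. = FALSE)
  pools[need]
}

# shared internal grid: steps per fastest EMU turnover time
inst_steps <- function(sim, v, pools, t_end, dt_factor) {
  tau <- Inf
  for (s in names(sim$compiled$systems)) {
    sys <- sim$compiled$systems[[s]]
    for (i in seq_along(sys$internal)) {
      met <- parse_emu(sys$internal[i])$met
      if (!met %in% names(pools)) next
      cw <- sys$cons[[i]]
      out <- if (nrow(cw)) sum(cw[, 2] * v[cw[, 1]]) else 0
      if (out > 0) tau <- min(tau, pools[[met]] / out)
    }
  }
  if (!is.finite(tau)) stop("no dynamic EMU states", call. = FALSE)
  max(2L, as.integer(ceiling(t_end / (tau / dt_factor))))
}

#' @method autoplot mdv_trajectory
#' @export
autoplot.mdv_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value,
                                       colour = factor(.data$shift))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~emu) +
    ggplot2::labs(x = "time", y = "fractional abundance", colour = "mass shift") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
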