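# reduced row echelon form; returns the reduced matrix and pivot columns
rref <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  piv <- integer(0)
  r <- 1L
  for (j in seq_len(n)) {
    if (r > m) break
    i <- which.max(abs(A[r:m, j])) + r - 1L
    if (abs(A[i, j]) < tol) next
    if (i != r) A[c(i, r), ] <- A[c(r, i), ]
    A[r, ] <- A[r, ] / A[r, j]
    others <- setdiff(seq_len(m), r)
    A[others, ] <- A[others, ] - outer(A[others, j], A[r, ])
    piv <- c(piv, j)
    r <- r + 1L
  }
  list(R = A, pivots = piv)
}

# exchange-flux transform: u in [0, 1) -> xch in [0, inf), scaled so the
# typically identifiable range (xch of order the uptake scale) maps to a
# well-conditioned stretch of [0, 1)
xch_scale <- 20
xch_of_u <- function(u) xch_scale * tan(pi * u / 2)
dxch_du <- function(u) xch_scale * (pi / 2) / cos(pi * u / 2)^2
u_of_xch <- function(x) 2 / pi * atan(x / xch_scale)

#' Assemble a flux-estimation problem
#'
#' Sets up the weighted nonlinear least-squares problem for steady-state or
#' INST flux estimation. Net fluxes are parameterized by the free reactions
#' of the reduced row echelon form of the net stoichiometric matrix, so
#' every parameter vector maps to a flux vector satisfying `S v = 0`
#' exactly; exchange fluxes of reversible reactions use a tan-scaled
#' `[0, 1) -> [0, inf)` transform; pool sizes (INST) are estimated in log
#' space; each dilution entry adds one free G-value in `[0, 1]` modeling the
#' measured signal as `G * simulated + (1 - G) * natural`. Box bounds for
#' the free fluxes come from flux variability analysis with measured fluxes
#' anchored at +/- 5 sd.
#'
#' @param net a `flux_network`.
#' @param measurements long tibble of MDV measurements: columns `emu`,
#'   `timepoint` (`"ss"` or seconds), `shift`, `mean`, `sd`.
#' @param flux_measurements tibble: `reaction`, `mean`, `sd` (net fluxes).
#' @param strategy a [labeling_strategy()].
#' @param mode `"ss"` or `"inst"`.
#' @param dilution optional character vector of diluted metabolites (each
#'   gets a free G-value; substrate metabolites are diluted at the source,
#'   measured ones at the measurement).
#' @param pools named vector of pool sizes (INST): starting values, or fixed
#'   values when `pools_free = FALSE`.
#' @param pools_free estimate pool sizes (INST only)?
#' @param bounds optional [flux_bounds()] tibble for the FVA box.
#' @param p13 natural 13C abundance.
#' @param sd_floor minimum MDV measurement sd (default 0.001).
#' @param xch_cap upper bound on exchange fluxes (default 1000).
#' @return a `fit_problem` object.
#' @export
make_fit_problem <- function(net, measurements, flux_measurements, strategy,
                             mode = c("ss", "inst"), dilution = NULL,
                             pools = NULL, pools_free = TRUE, bounds = NULL,
                             p13 = 0.0107, sd_floor = 0.001, xch_cap = 1000) {
  mode <- match.arg(mode)
  meas <- tibble::as_tibble(measurements)
  if (nrow(meas) == 0L) stop("at least one MDV measurement required", call. = FALSE)
  if (nrow(flux_measurements) == 0L)
    stop("a measured flux is required to anchor the scale", call. = FALSE)
  meas$sd <- pmax(meas$sd, sd_floor)
  targets <- sort(unique(meas$emu))
  for (tg in targets) {
    m <- parse_emu(tg)$met
    if (!m %in% net$metabolites$id)
      stop(sprintf("measured EMU '%s' not in network", tg), call. = FALSE)
  }
  sums <- meas |>
    dplyr::group_by(.data$emu, .data$timepoint) |>
    dplyr::summarise(s = sum(.data$mean), .groups = "drop")
  if (any(abs(sums$s - 1) > 0.02))
    warning("some measured MDVs deviate from unit sum by more than 0.02")

  sim <- emu_simulator(net, targets, p13)

  # net-flux parameterization from rref of the net stoichiometric matrix
  tf <- net$total_fluxes
  fwd <- tf$direction == 1
  rids <- tf$reaction[fwd]
  S_net <- net$S[, fwd, drop = FALSE]
  colnames(S_net) <- rids
  rr <- rref(S_net)
  free_idx <- setdiff(seq_along(rids), rr$pivots)
  free_rids <- rids[free_idx]
  pivot_rids <- rids[rr$pivots]
  Fmat <- rr$R[seq_along(rr$pivots), free_idx, drop = FALSE]  # v_piv = -Fmat v_free
  rev_rids <- unique(tf$reaction[tf$direction == -1])

  for (rid in flux_measurements$reaction)
    if (!rid %in% rids) stop(sprintf("measured flux '%s' unknown", rid), call. = FALSE)

  # FVA box for free fluxes, anchored by measured fluxes at +/- 5 sd
  if (is.null(bounds)) bounds <- flux_bounds(net)
  Smat <- net$S[, bounds$flux_id, drop = FALSE]
  anchors_A <- NULL; anchors_b <- NULL
  for (k in seq_len(nrow(flux_measurements))) {
    o <- obj_vector(net, flux_measurements$reaction[k])
    lo <- flux_measurements$mean[k] - 5 * flux_measurements$sd[k]
    hi <- flux_measurements$mean[k] + 5 * flux_measurements$sd[k]
    anchors_A <- rbind(anchors_A, o, -o)
    anchors_b <- c(anchors_b, lo, -hi)
  }
  box <- purrr::map(free_rids, function(rid) {
    o <- obj_vector(net, rid)
    c(solve_lp(Smat, bounds, o, FALSE, anchors_A, anchors_b)$value,
      solve_lp(Smat, bounds, o, TRUE, anchors_A, anchors_b)$value)
  })
  box <- do.call(rbind, box)
  rownames(box) <- free_rids

  dil <- unique(dilution)
  dil_sub <- dil[dil %in% net$metabolites$id[net$metabolites$is_substrate]]
  dil_meas <- setdiff(dil, dil_sub)
  for (m in dil_meas)
    if (!m %in% purrr::map_chr(targets, ~ parse_emu(.x)$met))
      stop(sprintf("diluted metabolite '%s' is neither a substrate nor measured", m),
           call. = FALSE)

  # parameter template
  par_names <- paste0("v:", free_rids)
  lower <- box[, 1]; upper <- box[, 2]
  ptype <- rep("net", length(free_rids))
  if (length(rev_rids)) {
    par_names <- c(par_names, paste0("u:", rev_rids))
    u_cap <- u_of_xch(xch_cap)
    lower <- c(lower, rep(0, length(rev_rids)))
    upper <- c(upper, rep(u_cap, length(rev_rids)))
    ptype <- c(ptype, rep("xch", length(rev_rids)))
  }
  inst <- mode == "inst"
  pool_mets <- character(0)
  if (inst) {
    tps <- suppressWarnings(as.numeric(meas$timepoint))
    if (any(is.na(tps))) stop("INST mode needs numeric timepoints", call. = FALSE)
    if (length(unique(tps)) < 2L)
      stop("INST mode needs measurements at >= 2 timepoints", call. = FALSE)
    ints <- unlist(purrr::map(sim$compiled$systems, "internal"))
    need <- intersect(unique(purrr::map_chr(ints, ~ parse_emu(.x)$met)),
                      net$metabolites$id[net$metabolites$is_balanced])
    if (is.null(pools)) pools <- stats::setNames(rep(1, length(need)), need)
    miss <- setdiff(need, names(pools))
    if (length(miss))
      stop(sprintf("missing pools for: %s", paste(miss, collapse = ", ")), call. = FALSE)
    pool_mets <- need
    if (pools_free) {
      par_names <- c(par_names, paste0("logc:", need))
      lower <- c(lower, rep(log(1e-3), length(need)))
      upper <- c(upper, rep(log(1e4), length(need)))
      ptype <- c(ptype, rep("pool", length(need)))
    }
  }
  if (length(dil)) {
    par_names <- c(par_names, paste0("G:", dil))
    lower <- c(lower, rep(0, length(dil)))
    upper <- c(upper, rep(1, length(dil)))
    ptype <- c(ptype, rep("G", length(dil)))
  }
  names(lower) <- names(upper) <- par_names

  # measurement bookkeeping: one group per (emu, timepoint)
  meas$row <- seq_len(nrow(meas))
  groups <- meas |>
    dplyr::group_by(.data$emu, .data$timepoint) |>
    dplyr::group_split()
  timegrid <- NULL
  if (inst) timegrid <- sort(unique(c(0, as.numeric(meas$timepoint))))

  problem <- list(
    net = net, sim = sim, mode = mode, p13 = p13,
    meas = meas, groups = groups, flux_meas = tibble::as_tibble(flux_measurements),
    strategy = strategy, free_rids = free_rids, pivot_rids = pivot_rids,
    rids = rids, Fmat = Fmat, rev_rids = rev_rids, box = box,
    par_names = par_names, lower = lower, upper = upper, ptype = ptype,
    dil = dil, dil_sub = dil_sub, dil_meas = dil_meas,
    pools = pools, pools_free = pools_free && inst, pool_mets = pool_mets,
    timegrid = timegrid, penalty_w = 1e3,
    n_meas_res = nrow(meas) + nrow(flux_measurements))
  class(problem) <- "fit_problem"
  problem$n_steps <- if (inst) NA_integer_ else NULL
  problem
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf("<fit_problem (%s): %d parameters (%d free fluxes, %d exchange, %d pools, %d G), %d residuals>\n",
              x$mode, length(x$par_names), length(x$free_rids),
              length(x$rev_rids), if (x$pools_free) length(x$pool_mets) else 0L,
              length(x$dil), x$n_meas_res))
  invisible(x)
}

# theta -> named net fluxes, total fluxes, xch, pools, G
decode_theta <- function(problem, theta) {
  nfree <- length(problem$free_rids)
  v_free <- theta[seq_len(nfree)]
  v_piv <- if (length(problem$pivot_rids))
    as.numeric(-problem$Fmat %*% v_free) else numeric(0)
  v_net <- stats::setNames(numeric(length(problem$rids)), problem$rids)
  v_net[problem$free_rids] <- v_free
  v_net[problem$pivot_rids] <- v_piv
  k <- nfree
  xch <- stats::setNames(numeric(length(problem$rev_rids)), problem$rev_rids)
  if (length(problem$rev_rids)) {
    u <- theta[k + seq_along(problem$rev_rids)]
    xch[] <- xch_of_u(u)
    k <- k + length(problem$rev_rids)
  }
  pools <- problem$pools
  if (problem$pools_free) {
    pools[problem$pool_mets] <- exp(theta[k + seq_along(problem$pool_mets)])
    k <- k + length(problem$pool_mets)
  }
  G <- stats::setNames(rep(1, length(problem$dil)), problem$dil)
  if (length(problem$dil)) G[] <- theta[k + seq_along(problem$dil)]
  # total fluxes
  tf <- problem$net$total_fluxes
  v_total <- stats::setNames(numeric(nrow(tf)), tf$flux_id)
  for (i in seq_len(nrow(tf))) {
    rid <- tf$reaction[i]
    vn <- v_net[[rid]]
    if (!rid %in% problem$rev_rids) v_total[i] <- vn
    else {
      fwdv <- if (vn >= 0) vn + xch[[rid]] else xch[[rid]]
      v_total[i] <- if (tf$direction[i] == 1) fwdv else fwdv - vn
    }
  }
  list(v_net = v_net, v_total = v_total, xch = xch, pools = pools, G = G)
}

# measurement-model predictions for all groups; returns list per group
predict_groups <- function(problem, dec, meas_means = NULL) {
  sub_base <- substrate_cache(problem$strategy, problem$p13)
  G <- dec$G
  sub_lookup <- if (length(problem$dil_sub)) {
    function(emu) {
      val <- sub_base(emu)
      met <- parse_emu(emu)$met
      if (met %in% problem$dil_sub) {
        g <- G[[met]]
        nat <- as.numeric(natural_mdv(length(val) - 1L, problem$p13))
        val <- g * val + (1 - g) * nat
      }
      val
    }
  } else sub_base
  if (problem$mode == "ss") {
    solved <- ss_core(problem$sim$compiled, dec$v_total, sub_lookup)
    get_pred <- function(emu, timepoint) {
      val <- solved[[emu]]
      if (is.null(val)) val <- sub_lookup(emu)
      val
    }
  } else {
    res <- inst_core(problem$sim$compiled, dec$v_total, dec$pools, sub_lookup,
                     max(problem$timegrid), problem$n_steps, problem$p13)
    get_pred <- function(emu, timepoint) {
      mat <- target_traj(res, emu, sub_lookup)
      tq <- as.numeric(timepoint)
      # linear interpolation on the fixed internal grid
      g <- res$grid
      j <- findInterval(tq, g, all.inside = TRUE)
      w <- (tq - g[j]) / (g[j + 1] - g[j])
      (1 - w) * mat[j, ] + w * mat[j + 1, ]
    }
  }
  purrr::map(problem$groups, function(gr) {
    pred <- get_pred(gr$emu[1], gr$timepoint[1])
    met <- parse_emu(gr$emu[1])$met
    if (met %in% problem$dil_meas) {
      g <- G[[met]]
      nat <- as.numeric(natural_mdv(length(pred) - 1L, problem$p13))
      pred <- g * pred + (1 - g) * nat
    }
    pred[gr$shift + 1L]
  })
}

# full residual vector: MDV rows, flux rows, then nonnegativity penalties
problem_residuals <- function(problem, theta, meas_means = NULL,
                              flux_means = NULL) {
  dec <- decode_theta(problem, theta)
  preds <- tryCatch(predict_groups(problem, dec), error = function(e) NULL)
  if (is.null(preds)) {
    # degenerate point (e.g. a pathway flux exactly zero makes an EMU
    # balance singular): return a large finite misfit so the optimizer
    # rejects the step instead of aborting
    n <- problem$n_meas_res + nrow(problem$net$total_fluxes)
    return(rep(1e4, n))
  }
  mm <- if (is.null(meas_means)) problem$meas$mean else meas_means
  r_mdv <- numeric(nrow(problem$meas))
  for (i in seq_along(problem$groups)) {
    gr <- problem$groups[[i]]
    r_mdv[gr$row] <- (preds[[i]] - mm[gr$row]) / gr$sd
  }
  fm <- if (is.null(flux_means)) problem$flux_meas$mean else flux_means
  r_flux <- (dec$v_net[problem$flux_meas$reaction] - fm) / problem$flux_meas$sd
  pen <- pmin(dec$v_total, 0) * problem$penalty_w
  c(r_mdv, as.numeric(r_flux), as.numeric(pen))
}

# fix the INST internal grid from a reference parameter point (x2 margin),
# so the objective is smooth across evaluations
fix_inst_grid <- function(problem, theta) {
  if (problem$mode != "inst") return(problem)
  dec <- decode_theta(problem, theta)
  problem$n_steps <- as.integer(1.5 * inst_steps(problem$sim, dec$v_total, dec$pools,
                                                 max(problem$timegrid), 20))
  problem
}

# uniform draw in the FVA box, rejected until all total fluxes nonnegative
draw_start <- function(problem, max_tries = 500) {
  nfree <- length(problem$free_rids)
  for (i in seq_len(max_tries)) {
    th <- stats::setNames(numeric(length(problem$par_names)), problem$par_names)
    th[seq_len(nfree)] <- stats::runif(nfree, problem$box[, 1], problem$box[, 2])
    k <- nfree
    if (length(problem$rev_rids)) {
      th[k + seq_along(problem$rev_rids)] <-
        stats::runif(length(problem$rev_rids), 0, 0.9 * problem$upper[k + 1])
      k <- k + length(problem$rev_rids)
    }
    if (problem$pools_free) {
      th[k + seq_along(problem$pool_mets)] <-
        log(problem$pools[problem$pool_mets]) + stats::runif(length(problem$pool_mets), -1, 1)
      k <- k + length(problem$pool_mets)
    }
    if (length(problem$dil))
      th[k + seq_along(problem$dil)] <- stats::runif(length(problem$dil), 0.5, 1)
    dec <- decode_theta(problem, th)
    if (all(dec$v_net[problem$pivot_rids] >= -1e-9)) return(th)
  }
  stop("could not draw a feasible starting point in the FVA box", call. = FALSE)
}

# forward finite-difference Jacobian (relative step) of the measurement
# residuals at theta
fd_jacobian <- function(problem, theta, rel = 1e-6) {
  r0 <- problem_residuals(problem, theta)
  nm <- problem$n_meas_res
  J <- matrix(0, nm, length(theta))
  for (j in seq_along(theta)) {
    h <- rel * max(abs(theta[j]), 1e-2)
    # step inward at the upper bound to stay feasible
    if (theta[j] + h > problem$upper[j]) h <- -h
    th <- theta; th[j] <- th[j] + h
    r1 <- problem_residuals(problem, th)
    J[, j] <- (r1[seq_len(nm)] - r0[seq_len(nm)]) / h
  }
  colnames(J) <- problem$par_names
  J
}

run_one_fit <- function(problem, start, meas_means = NULL, flux_means = NULL,
                        maxiter = 500) {
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = problem$lower, upper = problem$upper,
      fn = function(th) problem_residuals(problem, th, meas_means, flux_means),
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-9,
                                           ptol = 1e-9)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  list(theta = stats::setNames(res$par, problem$par_names),
       deviance = res$deviance, info = res$info)
}

#' Estimate fluxes by multi-start weighted nonlinear least squares
#'
#' Minimizes the weighted residual sum of squares between simulated and
#' measured MDVs and net fluxes over the free parameters, restarting from
#' `n_starts` random points sampled uniformly in the FVA box, and keeps the
#' best local optimum. The Jacobian of the weighted residuals at convergence
#' (forward finite differences, relative step 1e-6) feeds the statistics
#' layer; the Gauss-Newton Hessian is `2 J'J`.
#'
#' @param problem a [make_fit_problem()] object.
#' @param n_starts number of random restarts (default 10 for steady state,
#'   5 for INST).
#' @param seed RNG seed.
#' @return a `flux_fit` object; see [tidy.flux_fit()] and [glance.flux_fit()].
#' @export
solve_fit <- function(problem, n_starts = if (problem$mode == "inst") 5 else 10,
                      seed = 1) {
  set.seed(seed)
  starts <- purrr::map(seq_len(n_starts), ~ draw_start(problem))
  if (problem$mode == "inst") problem <- fix_inst_grid(problem, starts[[1]])
  fits <- purrr::map(starts, ~ run_one_fit(problem, .x))
  fits <- purrr::compact(fits)
  if (!length(fits)) stop("all starts failed", call. = FALSE)
  best <- fits[[which.min(purrr::map_dbl(fits, "deviance"))]]
  finish_fit(problem, best, n_starts, seed)
}

finish_fit <- function(problem, best, n_starts, seed) {
  theta <- best$theta
  dec <- decode_theta(problem, theta)
  r <- problem_residuals(problem, theta)
  nm <- problem$n_meas_res
  phi <- sum(r[seq_len(nm)]^2)
  J <- fd_jacobian(problem, theta)
  preds <- predict_groups(problem, dec)
  res_tbl <- problem$meas |>
    dplyr::mutate(predicted = {
      p <- numeric(nrow(problem$meas))
      for (i in seq_along(problem$groups))
        p[problem$groups[[i]]$row] <- preds[[i]]
      p
    },
    resid = (.data$predicted - .data$mean) / .data$sd) |>
    dplyr::select("emu", "timepoint", "shift", measured = "mean", "sd",
                  "predicted", "resid")
  flux_res <- tibble::tibble(
    emu = problem$flux_meas$reaction, timepoint = "flux",
    shift = NA_integer_, measured = problem$flux_meas$mean,
    sd = problem$flux_meas$sd,
    predicted = as.numeric(dec$v_net[problem$flux_meas$reaction]),
    resid = (as.numeric(dec$v_net[problem$flux_meas$reaction]) -
               problem$flux_meas$mean) / problem$flux_meas$sd)
  structure(list(
    problem = problem, theta = theta,
    fluxes = tibble::tibble(
      reaction = problem$rids,
      net = as.numeric(dec$v_net[problem$rids]),
      xch = ifelse(problem$rids %in% problem$rev_rids,
                   as.numeric(dec$xch[problem$rids]), NA_real_)),
    pools = if (length(problem$pool_mets))
      tibble::tibble(metabolite = problem$pool_mets,
                     size = as.numeric(dec$pools[problem$pool_mets])) else NULL,
    gvalues = if (length(problem$dil))
      tibble::tibble(metabolite = problem$dil, G = as.numeric(dec$G)) else NULL,
    objective = phi, residuals = dplyr::bind_rows(res_tbl, flux_res),
    J = J, dof = nm - length(theta),
    converged = best$info %in% 1:3, n_starts = n_starts, seed = seed),
    class = "flux_fit")
}

#' Estimate fluxes and pool sizes from transient labeling data
#'
#' Convenience wrapper around [solve_fit()] for problems built in `"inst"`
#' mode: every objective evaluation integrates the EMU cascade over the
#' measurement timegrid.
#'
#' @inheritParams solve_fit
#' @export
solve_fit_inst <- function(problem, n_starts = 5, seed = 1) {
  if (problem$mode != "inst") stop("problem is not in INST mode", call. = FALSE)
  solve_fit(problem, n_starts = n_starts, seed = seed)
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit (%s): Phi = %.4g, dof = %d, converged = %s>\n",
              x$problem$mode, x$objective, x$dof, x$converged))
  print(x$fluxes)
  if (!is.null(x$pools)) print(x$pools)
  if (!is.null(x$gvalues)) print(x$gvalues)
  invisible(x)
}

#' Tidy a flux fit into one row per estimated quantity
#'
#' @param x a `flux_fit`.
#' @param ... unused.
#' @return tibble with columns `quantity`, `type` (`net`, `xch`, `pool`,
#'   `G`), `estimate`.
#' @method tidy flux_fit
#' @export
tidy.flux_fit <- function(x, ...) {
  out <- tibble::tibble(quantity = x$fluxes$reaction, type = "net",
                        estimate = x$fluxes$net)
  if (any(!is.na(x$fluxes$xch)))
    out <- dplyr::bind_rows(out, tibble::tibble(
      quantity = x$fluxes$reaction[!is.na(x$fluxes$xch)], type = "xch",
      estimate = x$fluxes$xch[!is.na(x$fluxes$xch)]))
  if (!is.null(x$pools))
    out <- dplyr::bind_rows(out, tibble::tibble(
      quantity = x$pools$metabolite, type = "pool", estimate = x$pools$size))
  if (!is.null(x$gvalues))
    out <- dplyr::bind_rows(out, tibble::tibble(
      quantity = x$gvalues$metabolite, type = "G", estimate = x$gvalues$G))
  out
}

#' One-row fit summary
#'
#' @param x a `flux_fit`.
#' @param ... unused.
#' @return tibble: `objective`, `dof`, `n_params`, `n_residuals`,
#'   `converged`, `n_starts`, `seed`.
#' @method glance flux_fit
#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, dof = x$dof,
                 n_params = length(x$theta),
                 n_residuals = x$problem$n_meas_res,
                 converged = x$converged, n_starts = x$n_starts, seed = x$seed)
}

#' Monte-Carlo confidence intervals
#'
#' Refits the problem `n_runs` times on data perturbed by Gaussian noise
#' with the declared measurement standard deviations (MDV entries and
#' measured fluxes alike), warm-starting each refit from the base optimum,
#' and reports empirical quantile confidence intervals per estimated
#' quantity. Per-run seeds derive deterministically from `seed`, so results
#' are identical regardless of parallelization.
#'
#' @param fit a `flux_fit` from [solve_fit()].
#' @param n_runs number of Monte-Carlo refits.
#' @param n_jobs parallel workers (forked; default 1).
#' @param seed RNG seed.
#' @param alpha two-sided miscoverage level (default 0.05 for 95% CIs).
#' @return a `flux_mc` object: tibble `quantity`, `type`, `estimate`, `lo`,
#'   `hi`, plus the draw matrix in `$draws`.
#' @export
solve_with_confidence_intervals <- function(fit, n_runs = 100, n_jobs = 1,
                                            seed = 1, alpha = 0.05) {
  problem <- fit$problem
  base_theta <- fit$theta
  run1 <- function(i) {
    set.seed((seed %% 2146483L) * 1000L + i)
    mm <- problem$meas$mean + stats::rnorm(nrow(problem$meas), 0, problem$meas$sd)
    fm <- problem$flux_meas$mean +
      stats::rnorm(nrow(problem$flux_meas), 0, problem$flux_meas$sd)
    res <- run_one_fit(problem, base_theta, meas_means = mm, flux_means = fm,
                       maxiter = 200)
    if (is.null(res)) return(NULL)
    dec <- decode_theta(problem, res$theta)
    q <- c(dec$v_net, stats::setNames(dec$xch, paste0("xch:", names(dec$xch))))
    if (problem$pools_free)
      q <- c(q, stats::setNames(dec$pools[problem$pool_mets],
                                paste0("pool:", problem$pool_mets)))
    if (length(problem$dil))
      q <- c(q, stats::setNames(dec$G, paste0("G:", names(dec$G))))
    q
  }
  runs <- if (n_jobs > 1)
    parallel::mclapply(seq_len(n_runs), run1, mc.cores = n_jobs)
  else lapply(seq_len(n_runs), run1)
  ok <- !purrr::map_lgl(runs, is.null)
  if (mean(!ok) > 0.2)
    stop(sprintf("%d of %d Monte-Carlo runs failed", sum(!ok), n_runs), call. = FALSE)
  draws <- do.call(rbind, runs[ok])
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  base <- tidy(fit)
  key <- ifelse(base$type == "net", base$quantity,
                paste0(base$type, ":", base$quantity))
  key[base$type == "net"] <- base$quantity[base$type == "net"]
  out <- tibble::tibble(quantity = base$quantity, type = base$type,
                        estimate = base$estimate,
                        lo = qs[1, match(key, colnames(draws))],
                        hi = qs[2, match(key, colnames(draws))])
  structure(list(ci = out, draws = draws, n_failed = sum(!ok),
                 n_runs = n_runs, alpha = alpha, seed = seed),
            class = "flux_mc")
}

#' @export
print.flux_mc <- function(x, ...) {
  cat(sprintf("<flux_mc: %d runs (%d failed), %d%% CIs>\n", x$n_runs,
              x$n_failed, round(100 * (1 - x$alpha))))
  print(x$ci)
  invisible(x)
}

#' @method tidy flux_mc
#' @export
tidy.flux_mc <- function(x, ...) x$ci
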