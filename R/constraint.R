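#' Flux bounds
#'
#' Box bounds on total fluxes (forward, backward, and irreversible fluxes
#' all live on `[0, default_ub]` unless overridden), in the units of the
#' normalization flux (typically per 100 substrate uptake).
#'
#' @param net a `flux_network`.
#' @param ... named overrides, each `flux_id = c(lb, ub)` (a single number
#'   fixes the flux to that value).
#' @param default_ub default upper bound (1000).
#' @return a tibble with columns `flux_id`, `lb`, `ub`.
#' @export
flux_bounds <- function(net, ..., default_ub = 1000) {
  ids <- net$total_fluxes$flux_id
  b <- tibble::tibble(flux_id = ids, lb = 0, ub = default_ub)
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  for (nm in names(ov)) {
    if (!nm %in% ids) stop(sprintf("unknown flux id '%s'", nm), call. = FALSE)
    val <- ov[[nm]]
    if (length(val) == 1L) val <- c(val, val)
    if (val[1] > val[2]) stop(sprintf("lb > ub for '%s'", nm), call. = FALSE)
    b$lb[b$flux_id == nm] <- val[1]
    b$ub[b$flux_id == nm] <- val[2]
  }
  b
}

# one LP over the flux polytope: optimize c'v s.t. S v = 0, lb <= v <= ub,
# optionally extra >= rows (over the full flux vector). Fluxes fixed by
# their bounds are substituted out before calling the simplex solver, and
# constraint rows are canonicalized to the nonnegative right-hand sides the
# solver expects. Ties broken by a tiny lexicographic secondary objective so
# degenerate optima are deterministic.
solve_lp <- function(S, bounds, obj, maximize, extra_A2 = NULL, extra_b2 = NULL,
                     tie_break = TRUE) {
  n <- nrow(bounds)
  fixed <- which(bounds$ub - bounds$lb < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  if (!length(free)) {
    v <- bounds$lb
    if (max(abs(S %*% v)) > 1e-8) stop("infeasible flux polytope", call. = FALSE)
    return(list(value = sum(obj * v), v = stats::setNames(v, bounds$flux_id)))
  }
  vfix <- bounds$lb[fixed]
  a <- obj[free]
  if (tie_break) a <- a + (if (maximize) -1 else 1) * 1e-9 * seq_along(free)
  # accumulate constraints as (row, rhs, type) over the free fluxes
  rows <- list()
  add <- function(row, rhs, type) rows[[length(rows) + 1L]] <<- list(row, rhs, type)
  for (i in seq_len(nrow(S))) {
    rhs <- if (length(fixed)) -sum(S[i, fixed] * vfix) else 0
    add(S[i, free], rhs, "eq")
  }
  for (j in seq_along(free)) {
    add(replace(numeric(length(free)), j, 1), bounds$ub[free[j]], "le")
    if (bounds$lb[free[j]] > 0)
      add(replace(numeric(length(free)), j, 1), bounds$lb[free[j]], "ge")
  }
  if (!is.null(extra_A2)) for (i in seq_len(nrow(extra_A2))) {
    rhs <- extra_b2[i] - if (length(fixed)) sum(extra_A2[i, fixed] * vfix) else 0
    add(extra_A2[i, free], rhs, "ge")
  }
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL; A3 <- NULL; b3 <- NULL
  A3full <- NULL; b3full <- NULL
  eq_rows <- Filter(function(r) r[[3]] == "eq", rows)
  if (length(eq_rows)) {
    A3full <- do.call(rbind, lapply(eq_rows, `[[`, 1))
    b3full <- vapply(eq_rows, `[[`, 0, 2)
    # drop linearly dependent balance rows (common once fluxes are fixed):
    # boot's simplex silently returns NaN on redundant equality systems
    qe <- qr(t(A3full))
    keep <- sort(qe$pivot[seq_len(qe$rank)])
    rows <- c(lapply(keep, function(i) list(A3full[i, ], b3full[i], "eq")),
              Filter(function(r) r[[3]] != "eq", rows))
  }
  for (r in rows) {
    row <- r[[1]]; rhs <- r[[2]]; type <- r[[3]]
    if (type == "eq") {
      if (rhs < 0) { row <- -row; rhs <- -rhs }
      A3 <- rbind(A3, row); b3 <- c(b3, rhs)
    } else if (type == "le") {
      if (rhs < 0) { A2 <- rbind(A2, -row); b2 <- c(b2, -rhs) }
      else { A1 <- rbind(A1, row); b1 <- c(b1, rhs) }
    } else {
      if (rhs <= 0) {
        # implied by v >= 0 only when the row is nonnegative; else flip
        if (any(row < 0)) { A1 <- rbind(A1, -row); b1 <- c(b1, -rhs) }
      } else { A2 <- rbind(A2, row); b2 <- c(b2, rhs) }
    }
  }
  args <- list(a = a, maxi = maximize, n.iter = max(200L, length(free) * 50L))
  if (!is.null(A1)) { args$A1 <- A1; args$b1 <- b1 }
  if (!is.null(A2)) { args$A2 <- A2; args$b2 <- b2 }
  if (!is.null(A3)) { args$A3 <- A3; args$b3 <- b3 }
  res <- tryCatch(do.call(boot::simplex, args), error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$soln))) {
    # boot's simplex trips on some degenerate bases; fall back to pracma
    soln <- lp_fallback(a, A1, b1, A2, b2, A3, b3, maximize)
    if (is.null(soln)) stop("infeasible flux polytope", call. = FALSE)
    res <- list(soln = soln, solved = 1L)
  }
  if (res$solved < 0) stop("infeasible flux polytope", call. = FALSE)
  if (res$solved == 0) stop("LP did not converge", call. = FALSE)
  if (!is.null(A3full) &&
      max(abs(A3full %*% res$soln - b3full)) > 1e-6)
    stop("infeasible flux polytope", call. = FALSE)
  v <- numeric(n)
  v[free] <- res$soln
  if (length(fixed)) v[fixed] <- vfix
  list(value = sum(obj * v), v = stats::setNames(v, bounds$flux_id))
}

# secondary LP route for bases where boot::simplex errors internally
lp_fallback <- function(a, A1, b1, A2, b2, A3, b3, maximize) {
  Ale <- A1; ble <- b1
  if (!is.null(A2)) { Ale <- rbind(Ale, -A2); ble <- c(ble, -b2) }
  r <- tryCatch(suppressWarnings(pracma::linprog(
    cc = a, A = Ale, b = ble, Aeq = A3, beq = b3,
    maximize = maximize, maxiter = 1000)), error = function(e) NULL)
  if (is.null(r) || is.null(r$x) || r$errno < 0) return(NULL)
  r$x
}

obj_vector <- function(net, objective) {
  ids <- net$total_fluxes$flux_id
  if (is.numeric(objective) && !is.null(names(objective))) {
    o <- stats::setNames(numeric(length(ids)), ids)
    o[names(objective)] <- objective
    return(as.numeric(o))
  }
  # a reaction or flux id: net flux of that reaction
  tf <- net$total_fluxes
  o <- numeric(length(ids))
  if (objective %in% ids) { o[match(objective, ids)] <- 1; return(o) }
  hit <- tf$reaction == objective
  if (!any(hit)) stop(sprintf("unknown objective '%s'", objective), call. = FALSE)
  o[hit] <- tf$direction[hit]
  o
}

#' Flux balance analysis
#'
#' Optimizes a linear flux objective over the mass-balance polytope
#' `S v = 0`, `lb <= v <= ub`.
#'
#' @param net a `flux_network`.
#' @param bounds a [flux_bounds()] tibble (defaults to `flux_bounds(net)`).
#' @param objective a reaction id (its net flux), a total-flux id, or a named
#'   coefficient vector over total fluxes.
#' @param sense `"max"` or `"min"`.
#' @return a `fba_results`: list with `objective_id`, `objective_value`, and
#'   `fluxes` (tibble `flux_id`, `value`).
#' @export
fba <- function(net, bounds = flux_bounds(net), objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  o <- obj_vector(net, objective)
  sol <- solve_lp(net$S[, bounds$flux_id, drop = FALSE], bounds, o, sense == "max")
  structure(list(objective_id = objective, objective_value = sol$value,
                 fluxes = tibble::tibble(flux_id = bounds$flux_id,
                                         value = as.numeric(sol$v))),
            class = "fba_results")
}

#' @export
print.fba_results <- function(x, ...) {
  cat(sprintf("<fba: objective %s = %.6g>\n",
              paste(x$objective_id, collapse = ","), x$objective_value))
  print(x$fluxes)
  invisible(x)
}

#' Flux variability analysis
#'
#' Per total flux, the attainable minimum and maximum subject to the
#' mass-balance polytope and, when an objective is given, the constraint
#' that the objective stays within a fraction `gamma` of its FBA optimum.
#' `gamma = 0` (default) is plain variability of the polytope.
#'
#' @inheritParams fba
#' @param gamma objective fraction in `[0, 1]`.
#' @return an `fva_results` tibble: `flux_id`, `min`, `max`.
#' @export
fva <- function(net, bounds = flux_bounds(net), objective = NULL, gamma = 0) {
  Smat <- net$S[, bounds$flux_id, drop = FALSE]
  extra_A2 <- NULL; extra_b2 <- NULL
  if (!is.null(objective) && gamma > 0) {
    o <- obj_vector(net, objective)
    opt <- solve_lp(Smat, bounds, o, TRUE)$value
    extra_A2 <- matrix(o, 1L); extra_b2 <- gamma * opt
  }
  n <- nrow(bounds)
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    o <- numeric(n); o[i] <- 1
    lo[i] <- solve_lp(Smat, bounds, o, FALSE, extra_A2, extra_b2)$value
    hi[i] <- solve_lp(Smat, bounds, o, TRUE, extra_A2, extra_b2)$value
  }
  out <- tibble::tibble(flux_id = bounds$flux_id, min = lo, max = hi)
  class(out) <- c("fva_results", class(out))
  out
}

# feasible interior-ish point: average of the 2n FVA vertex solutions
polytope_center <- function(Smat, bounds) {
  n <- nrow(bounds)
  acc <- numeric(n); cnt <- 0L
  for (i in seq_len(n)) {
    o <- numeric(n); o[i] <- 1
    acc <- acc + solve_lp(Smat, bounds, o, FALSE)$v + solve_lp(Smat, bounds, o, TRUE)$v
    cnt <- cnt + 2L
  }
  acc / cnt
}

#' Sample the feasible flux polytope
#'
#' Hit-and-run sampling of `{v : S v = 0, lb <= v <= ub}` on the null-space
#' parameterization of the mass-balance constraint, with burn-in and
#' thinning. Fluxes fixed by their bounds are held exactly.
#'
#' @inheritParams fba
#' @param n number of samples.
#' @param seed RNG seed.
#' @param burn burn-in steps (default 1000).
#' @param thin thinning interval (default 10).
#' @return a tibble of `n` rows, one column per total flux.
#' @export
sample_feasible_fluxes <- function(net, bounds = flux_bounds(net), n, seed,
                                   burn = 1000, thin = 10) {
  set.seed(seed)
  Smat <- net$S[, bounds$flux_id, drop = FALSE]
  fixed <- which(bounds$ub - bounds$lb < 1e-9)
  Seff <- Smat
  if (length(fixed))
    Seff <- rbind(Smat, diag(nrow(bounds))[fixed, , drop = FALSE])
  Nmat <- MASS::Null(t(Seff))
  if (is.null(dim(Nmat)) || ncol(Nmat) == 0L)
    stop("flux polytope has no degrees of freedom to sample", call. = FALSE)
  x <- polytope_center(Smat, bounds)
  lb <- bounds$lb; ub <- bounds$ub
  x <- pmin(pmax(x, lb), ub)
  draws <- matrix(0, n, nrow(bounds))
  kept <- 0L; step <- 0L
  while (kept < n) {
    d <- as.numeric(Nmat %*% stats::rnorm(ncol(Nmat)))
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next
    d <- d / nd
    tlo <- -Inf; thi <- Inf
    for (i in seq_along(d)) {
      if (abs(d[i]) < 1e-12) next
      r1 <- (lb[i] - x[i]) / d[i]; r2 <- (ub[i] - x[i]) / d[i]
      tlo <- max(tlo, min(r1, r2)); thi <- min(thi, max(r1, r2))
    }
    if (!is.finite(tlo) || !is.finite(thi) || thi < tlo) next
    x <- x + stats::runif(1, tlo, thi) * d
    x <- pmin(pmax(x, lb), ub)
    step <- step + 1L
    if (step > burn && step %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- x
    }
  }
  out <- tibble::as_tibble(as.data.frame(draws))
  names(out) <- bounds$flux_id
  out
}
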