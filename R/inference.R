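# pseudo-inverse of J'J with rank detection; returns cov and null-space basis
gn_covariance <- function(J, rank_tol = 1e-8) {
  sv <- svd(J)
  keep <- sv$d > rank_tol * max(sv$d, .Machine$double.eps)
  cov <- sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]^2) * t(sv$v[, keep, drop = FALSE]))
  null_basis <- sv$v[, !keep, drop = FALSE]
  list(cov = cov, null = null_basis, rank = sum(keep))
}

#' Chi-square goodness-of-fit test
#'
#' At the optimum of a correctly weighted least-squares fit, the objective
#' is chi-square distributed with `dof = n_residuals - n_parameters` degrees
#' of freedom. The fit is accepted when the objective lies within the
#' central `1 - alpha` band; values below the lower bound flag overfitting
#' or overestimated measurement sds, values above flag model misfit.
#'
#' @param fit a `flux_fit`.
#' @param alpha test level (default 0.05).
#' @return tibble: `chi2`, `dof`, `lower`, `upper`, `accept`, plus residual
#'   normality statistic and p-value (Shapiro-Wilk, when n >= 8).
#' @export
chi2_test <- function(fit, alpha = 0.05) {
  dof <- fit$dof
  if (dof < 1) stop("no degrees of freedom: dof <= 0", call. = FALSE)
  lo <- stats::qchisq(alpha / 2, dof)
  hi <- stats::qchisq(1 - alpha / 2, dof)
  r <- fit$residuals$resid
  sw <- if (length(r) >= 8 && stats::sd(r) > 0)
    stats::shapiro.test(r) else list(statistic = NA_real_, p.value = NA_real_)
  tibble::tibble(chi2 = fit$objective, dof = dof, lower = lo, upper = hi,
                 accept = fit$objective >= lo && fit$objective <= hi,
                 normality_W = unname(sw$statistic),
                 normality_p = sw$p.value)
}

#' Residual normality diagnostics
#'
#' Shapiro-Wilk statistic of the weighted residuals plus the ordered
#' (theoretical, empirical) quantile pairs for a normal probability plot.
#'
#' @param fit a `flux_fit`.
#' @return list with `statistic`, `p_value`, and `quantiles` (tibble
#'   `theoretical`, `empirical`).
#' @export
residual_normality <- function(fit) {
  r <- fit$residuals$resid
  if (length(r) < 8) stop("need >= 8 residuals", call. = FALSE)
  if (stats::sd(r) == 0) stop("residuals are constant", call. = FALSE)
  sw <- stats::shapiro.test(r)
  n <- length(r)
  qq <- tibble::tibble(
    theoretical = stats::qnorm(stats::ppoints(n)),
    empirical = sort(r))
  list(statistic = unname(sw$statistic), p_value = sw$p.value, quantiles = qq)
}

# derivative of every reported quantity w.r.t. theta at the optimum:
# net fluxes are linear in the free-flux block; xch/pool transforms are
# differentiated analytically; G and pools map one-to-one.
quantity_jacobian <- function(fit) {
  p <- fit$problem
  th <- fit$theta
  npar <- length(th)
  rows <- list(); nms <- character(); typ <- character()
  # net fluxes
  for (rid in p$rids) {
    d <- numeric(npar)
    if (rid %in% p$free_rids) d[match(rid, p$free_rids)] <- 1
    else {
      i <- match(rid, p$pivot_rids)
      d[seq_along(p$free_rids)] <- -p$Fmat[i, ]
    }
    rows <- c(rows, list(d)); nms <- c(nms, rid); typ <- c(typ, "net")
  }
  k <- length(p$free_rids)
  for (j in seq_along(p$rev_rids)) {
    d <- numeric(npar)
    d[k + j] <- dxch_du(th[k + j])
    rows <- c(rows, list(d)); nms <- c(nms, p$rev_rids[j]); typ <- c(typ, "xch")
  }
  k <- k + length(p$rev_rids)
  if (p$pools_free) for (j in seq_along(p$pool_mets)) {
    d <- numeric(npar)
    d[k + j] <- exp(th[k + j])
    rows <- c(rows, list(d)); nms <- c(nms, p$pool_mets[j]); typ <- c(typ, "pool")
  }
  if (p$pools_free) k <- k + length(p$pool_mets)
  for (j in seq_along(p$dil)) {
    d <- numeric(npar)
    d[k + j] <- 1
    rows <- c(rows, list(d)); nms <- c(nms, p$dil[j]); typ <- c(typ, "G")
  }
  list(D = do.call(rbind, rows), quantity = nms, type = typ)
}

#' Local (Hessian-based) confidence intervals
#'
#' Symmetric CIs from the Gauss-Newton covariance `(J'J)^-1` at
#' convergence (pseudo-inverse on rank deficiency), propagated to net and
#' exchange fluxes, pool sizes, and G-values through the linear null-space
#' map and the analytic transform derivatives. Quantities with a component
#' in the unidentifiable null space are flagged and reported with infinite
#' half-width.
#'
#' @param fit a `flux_fit`.
#' @param alpha two-sided miscoverage level (default 0.05).
#' @param rank_tol singular values below `rank_tol * s_max` are treated as
#'   null directions (default 1e-8).
#' @return tibble: `quantity`, `type`, `estimate`, `se`, `lo`, `hi`,
#'   `identifiable`.
#' @export
local_confidence_intervals <- function(fit, alpha = 0.05, rank_tol = 1e-8) {
  gc_ <- gn_covariance(fit$J, rank_tol)
  qj <- quantity_jacobian(fit)
  est <- tidy(fit)
  ord <- match(paste(qj$type, qj$quantity), paste(est$type, est$quantity))
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(pmax(rowSums((qj$D %*% gc_$cov) * qj$D), 0))
  unident <- if (ncol(gc_$null))
    sqrt(rowSums((qj$D %*% gc_$null)^2)) > rank_tol * max(1, max(abs(qj$D)))
  else rep(FALSE, nrow(qj$D))
  se[unident] <- Inf
  tibble::tibble(quantity = qj$quantity, type = qj$type,
                 estimate = est$estimate[ord],
                 se = se,
                 lo = est$estimate[ord] - z * se,
                 hi = est$estimate[ord] + z * se,
                 identifiable = !unident)
}

#' Sensitivity of estimates to measurements
#'
#' First-order influence of each measurement on each estimated quantity at
#' convergence: `S = D (J'J)^- J' W` with `W = diag(1/sd)`, the
#' generalized-least-squares influence form, where `D` maps parameters to
#' reported quantities. Entry `[i, j]` is d(estimate i)/d(measurement j).
#'
#' @param fit a `flux_fit`.
#' @param rank_tol as in [local_confidence_intervals()].
#' @return a `sensitivity_matrix`: list with `S` (quantities x
#'   measurements), `quantity`, `type`, `measurement_id`, `sd`.
#' @export
sensitivity_matrix <- function(fit, rank_tol = 1e-8) {
  gc_ <- gn_covariance(fit$J, rank_tol)
  qj <- quantity_jacobian(fit)
  sds <- fit$residuals$sd
  S <- qj$D %*% gc_$cov %*% t(fit$J) %*% diag(1 / sds, length(sds))
  meas_id <- ifelse(fit$residuals$timepoint == "flux",
                    paste0("flux:", fit$residuals$emu),
                    paste0(fit$residuals$emu, " M+", fit$residuals$shift,
                           ifelse(fit$residuals$timepoint == "ss", "",
                                  paste0(" @", fit$residuals$timepoint))))
  rownames(S) <- paste(qj$type, qj$quantity)
  colnames(S) <- meas_id
  structure(list(S = S, quantity = qj$quantity, type = qj$type,
                 measurement_id = meas_id, sd = sds,
                 rank = gc_$rank), class = "sensitivity_matrix")
}

#' Contribution of measurement variances to estimate variances
#'
#' Row-normalized first-order variance decomposition: the fractional
#' contribution of measurement `j` to the variance of estimate `i` is
#' `S[i,j]^2 sd_j^2 / sum_j S[i,j]^2 sd_j^2`. Rows of estimates that are
#' insensitive to every measurement are flagged rather than normalized.
#'
#' @param fit a `flux_fit` (or a precomputed [sensitivity_matrix()]).
#' @param rank_tol as in [local_confidence_intervals()].
#' @return a `contribution_matrix`: list with `C`, `quantity`, `type`,
#'   `measurement_id`, `flagged` (zero-variance rows).
#' @export
contribution_matrix <- function(fit, rank_tol = 1e-8) {
  sm <- if (inherits(fit, "sensitivity_matrix")) fit
        else sensitivity_matrix(fit, rank_tol)
  V <- sweep(sm$S^2, 2, sm$sd^2, `*`)
  tot <- rowSums(V)
  flagged <- !is.finite(tot) | tot <= 0
  C <- V
  C[!flagged, ] <- V[!flagged, , drop = FALSE] / tot[!flagged]
  C[flagged, ] <- NA_real_
  structure(list(C = C, quantity = sm$quantity, type = sm$type,
                 measurement_id = sm$measurement_id, flagged = flagged),
            class = "contribution_matrix")
}

#' @method tidy contribution_matrix
#' @export
tidy.contribution_matrix <- function(x, ...) {
  tibble::tibble(
    quantity = rep(x$quantity, ncol(x$C)),
    type = rep(x$type, ncol(x$C)),
    measurement = rep(x$measurement_id, each = nrow(x$C)),
    contribution = as.vector(x$C))
}

#' Heatmap of the contribution matrix
#'
#' @param x a `contribution_matrix`.
#' @param types quantity types to show (default net fluxes).
#' @return a ggplot object.
#' @export
plot_contribution <- function(x, types = "net") {
  df <- tidy(x)
  df <- df[df$type %in% types & !is.na(df$contribution), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measurement, y = .data$quantity,
                                   fill = .data$contribution)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "measurement", y = "estimate",
                  fill = "fractional\ncontribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Compare simulated and measured MDVs of a fit
#'
#' @param object a `flux_fit`.
#' @param ... unused.
#' @return a ggplot object: measured vs predicted abundances with residual
#'   z-scores in the point colour.
#' @method autoplot flux_fit
#' @export
autoplot.flux_fit <- function(object, ...) {
  df <- object$residuals[object$residuals$timepoint != "flux", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$predicted,
                                   colour = abs(.data$resid))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~emu) +
    ggplot2::labs(x = "measured abundance", y = "simulated abundance",
                  colour = "|z|") +
    ggplot2::theme_minimal()
}
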