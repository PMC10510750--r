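#' Generate a synthetic labeling dataset
#'
#' Implements the synthetic-data validation protocol: sample one reference
#' flux distribution from the feasible polytope (substrate uptake fixed at
#' 100), simulate the MDVs of the target EMUs under the labeling strategy
#' (at steady state, or as a trajectory when `pools` and `timegrid` are
#' given), perturb every MDV entry with Gaussian noise of `noise_molpct`
#' mol % (then renormalize), and package the result as measurement tables
#' ready for [make_fit_problem()]. The measured uptake flux receives
#' Gaussian noise with sd `flux_sd`.
#'
#' With `noise_molpct = 0` the measurements equal the simulation exactly and
#' carry a formal sd of 0.01.
#'
#' @param net a `flux_network`.
#' @param strategy a [labeling_strategy()].
#' @param targets measured EMU names.
#' @param noise_molpct Gaussian noise level in mol % per MDV entry
#'   (default 1).
#' @param seed RNG seed (sampler and noise).
#' @param pools,timegrid INST mode: pool sizes and sampling times.
#' @param uptake reaction id of the substrate uptake (defaults to the first
#'   reaction); its net flux is fixed to 100 for the reference draw and
#'   reported as the measured flux.
#' @param bounds optional [flux_bounds()]; the default fixes the uptake at
#'   100, caps forward/irreversible fluxes at 300 and backward (exchange)
#'   fluxes at 50, so the reference polytope is bounded and exchange stays
#'   in the identifiable range.
#' @param renormalize renormalize each noisy MDV to unit sum (default TRUE).
#' @param flux_sd sd of the measured uptake flux (default 1).
#' @return a `synthetic_dataset`: list with `reference` (tibble of total
#'   fluxes and per-reaction net/xch), `measurements`, `flux_measurements`,
#'   `pools`, `timegrid`, `noise_molpct`, `seed`, `mode`.
#' @export
generate_synthetic_dataset <- function(net, strategy, targets,
                                       noise_molpct = 1, seed = 1,
                                       pools = NULL, timegrid = NULL,
                                       uptake = names(net$reactions)[1],
                                       bounds = NULL, renormalize = TRUE,
                                       flux_sd = 1) {
  inst <- !is.null(pools) && !is.null(timegrid)
  if (is.null(bounds)) {
    # study conditions of the reference draw: uptake fixed at 100, forward
    # and irreversible fluxes free up to 300, exchange (backward) fluxes
    # capped at half the uptake scale
    args <- list(net = net, default_ub = 300)
    tfr <- net$total_fluxes
    for (fid in tfr$flux_id[tfr$direction == -1]) args[[fid]] <- c(0, 50)
    for (fid in tfr$flux_id[tfr$reaction == uptake & tfr$direction == 1])
      args[[fid]] <- c(100, 100)
    bounds <- do.call(flux_bounds, args)
  }
  draw <- sample_feasible_fluxes(net, bounds, n = 1, seed = seed)
  v <- stats::setNames(as.numeric(draw[1, ]), names(draw))
  v_net <- net_from_total(net, v)
  tfr <- net$total_fluxes
  xch <- purrr::map_dbl(unique(tfr$reaction[tfr$direction == -1]), function(r)
    min(v[paste0(r, "_f")], v[paste0(r, "_b")]))
  names(xch) <- unique(tfr$reaction[tfr$direction == -1])

  if (inst) {
    traj <- simulate_inst(net, v, pools, strategy, timegrid, targets = targets)
    clean <- traj[traj$t > 0, ]
    clean$timepoint <- as.character(clean$t)
  } else {
    mdvs <- simulate_steady_state(net, v, strategy, targets = targets)
    clean <- dplyr::bind_rows(purrr::imap(mdvs, function(m, nm)
      tibble::tibble(emu = nm, timepoint = "ss",
                     shift = seq_along(as.numeric(m)) - 1L,
                     value = as.numeric(m))))
  }

  set.seed(seed + 1000003L)
  sdv <- if (noise_molpct > 0) noise_molpct / 100 else 0.01
  noisy <- clean
  if (noise_molpct > 0) {
    noisy$value <- noisy$value + stats::rnorm(nrow(noisy), 0, noise_molpct / 100)
    noisy$value[noisy$value < 0] <- 0
    if (renormalize) {
      noisy <- noisy |>
        dplyr::group_by(.data$emu, .data$timepoint) |>
        dplyr::mutate(value = .data$value / sum(.data$value)) |>
        dplyr::ungroup()
    }
  }
  measurements <- tibble::tibble(emu = noisy$emu, timepoint = noisy$timepoint,
                                 shift = noisy$shift, mean = noisy$value,
                                 sd = sdv)
  up_meas <- v_net[[uptake]] +
    if (noise_molpct > 0) stats::rnorm(1, 0, flux_sd) else 0
  flux_measurements <- tibble::tibble(reaction = uptake, mean = up_meas,
                                      sd = flux_sd)
  structure(list(
    net = net, strategy = strategy, targets = targets,
    reference = list(
      total = tibble::tibble(flux_id = names(v), value = as.numeric(v)),
      net = tibble::tibble(reaction = names(v_net), value = as.numeric(v_net)),
      xch = tibble::tibble(reaction = names(xch), value = as.numeric(xch))),
    measurements = measurements, flux_measurements = flux_measurements,
    pools = pools, timegrid = timegrid, mode = if (inst) "inst" else "ss",
    noise_molpct = noise_molpct, seed = seed, uptake = uptake),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset (%s): %d MDV rows, noise %.3g mol%%, seed %d>\n",
              x$mode, nrow(x$measurements), x$noise_molpct, x$seed))
  invisible(x)
}

#' Fit a synthetic dataset
#'
#' Convenience round trip: build the estimation problem matching the
#' dataset's mode and solve it.
#'
#' @param ds a [generate_synthetic_dataset()] result.
#' @param n_starts,seed passed to [solve_fit()].
#' @param dilution,pools_free passed to [make_fit_problem()].
#' @return a `flux_fit`.
#' @export
fit_synthetic <- function(ds, n_starts = if (ds$mode == "inst") 5 else 10,
                          seed = 1, dilution = NULL, pools_free = TRUE) {
  problem <- make_fit_problem(
    ds$net, ds$measurements, ds$flux_measurements, ds$strategy,
    mode = ds$mode, dilution = dilution,
    pools = ds$pools, pools_free = pools_free)
  solve_fit(problem, n_starts = n_starts, seed = seed)
}
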