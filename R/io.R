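#' Read and write MDV measurement tables
#'
#' The on-disk layout is wide TSV with columns `emu_id`, `timepoint`
#' (`"ss"` or seconds), `mean_0 ... mean_n`, `sd_0 ... sd_n`; in memory the
#' package works with the long tibble `emu`, `timepoint`, `shift`, `mean`,
#' `sd`.
#'
#' @param path file path.
#' @return `read_mdv_measurements()`: a long tibble.
#' @export
read_mdv_measurements <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  mean_cols <- grep("^mean_[0-9]+$", names(df), value = TRUE)
  sd_cols <- grep("^sd_[0-9]+$", names(df), value = TRUE)
  rows <- purrr::map(seq_len(nrow(df)), function(i) {
    mns <- as.numeric(df[i, mean_cols])
    sds <- as.numeric(df[i, sd_cols])
    ok <- !is.na(mns)
    tibble::tibble(emu = df$emu_id[i], timepoint = as.character(df$timepoint[i]),
                   shift = as.integer(sub("mean_", "", mean_cols[ok])),
                   mean = mns[ok], sd = sds[ok])
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_mdv_measurements
#' @param measurements long measurement tibble.
#' @export
write_mdv_measurements <- function(measurements, path) {
  wide <- measurements |>
    tidyr::pivot_wider(id_cols = c("emu", "timepoint"),
                       names_from = "shift", values_from = c("mean", "sd"),
                       names_sep = "_") |>
    dplyr::rename(emu_id = "emu")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read measured net fluxes
#'
#' TSV with columns `reaction`, `mean`, `sd`.
#' @param path file path.
#' @return tibble.
#' @export
read_flux_measurements <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Read a tracer (labeling strategy) YAML file
#'
#' Layout: one key per substrate, each a list of entries with fields
#' `mask`, `fraction`, and optionally `purity`:
#' ```yaml
#' A:
#'   - {mask: "100", fraction: 1.0, purity: 0.997}
#' ```
#' @param path file path.
#' @return a [labeling_strategy()].
#' @export
read_tracer <- function(path) {
  raw <- yaml::read_yaml(path)
  st <- purrr::map(raw, function(entries) {
    df <- dplyr::bind_rows(purrr::map(entries, tibble::as_tibble))
    df$mask <- as.character(df$mask)
    df
  })
  labeling_strategy(st)
}

#' Read flux bounds from TSV
#'
#' Columns `flux_id`, `lb`, `ub`; unlisted fluxes keep the defaults.
#' @param net a `flux_network`.
#' @param path file path.
#' @param default_ub default upper bound.
#' @return a [flux_bounds()] tibble.
#' @export
read_bounds <- function(net, path, default_ub = 1000) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  ov <- purrr::map(seq_len(nrow(df)), ~ c(df$lb[.x], df$ub[.x]))
  names(ov) <- df$flux_id
  flux_bounds(net, ov, default_ub = default_ub)
}

#' Read metabolite pool sizes from TSV
#'
#' Columns `metabolite`, `size`.
#' @param path file path.
#' @return named numeric vector.
#' @export
read_pools <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df$size, df$metabolite)
}

#' Import a supplementary-style network table
#'
#' Reads the two-column atom-transition layout used by published model
#' supplements: columns `id` (or the first column),
#' `reactants_with_atoms`, `products_with_atoms`, and optionally
#' `reversible`, where each side lists `Met{abc}` terms joined by `+`.
#' XLSX files go through readxl; `.tsv`/`.csv` files with the same columns
#' are read directly.
#'
#' @param path XLSX/TSV/CSV path.
#' @param sheet sheet name or index for XLSX input (default 1).
#' @inheritParams flux_network
#' @return a `flux_network`.
#' @export
import_supplementary_network <- function(path, sheet = 1, substrates = NULL,
                                         excreted = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("package 'readxl' is required for XLSX import", call. = FALSE)
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- utils::read.delim(path, sep = if (ext == "csv") "," else "\t",
                            stringsAsFactors = FALSE)
  }
  names(df) <- tolower(names(df))
  idcol <- if ("id" %in% names(df)) "id" else names(df)[1]
  eq <- paste(df$reactants_with_atoms, "->", df$products_with_atoms)
  tab <- data.frame(id = df[[idcol]], equation = eq,
                    reversible = if ("reversible" %in% names(df))
                      df$reversible else FALSE)
  flux_network(tab, substrates = substrates, excreted = excreted)
}

#' Write a simulated trajectory as long TSV
#'
#' Columns `emu_id`, `t`, `M0 ... Mn` (wide in mass, long in time).
#' @param traj an `mdv_trajectory` from [simulate_inst()].
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  wide <- traj |>
    dplyr::mutate(col = paste0("M", .data$shift)) |>
    tidyr::pivot_wider(id_cols = c("emu", "t"), names_from = "col",
                       values_from = "value") |>
    dplyr::rename(emu_id = "emu")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
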