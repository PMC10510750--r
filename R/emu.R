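#' EMU naming
#'
#' An elementary metabolite unit (EMU) is a specific subset of a metabolite's
#' carbon atoms. Canonical text form is `Met_1,2,3`; when every index is a
#' single digit the compact run form `Met_123` is used. `emu_name()` renders
#' a name, `parse_emu()` splits one back into metabolite and 1-based atom
#' indices.
#'
#' @param met metabolite id.
#' @param idx strictly increasing 1-based atom indices.
#' @return `emu_name()`: a string; `parse_emu()`: list with `met`, `idx`.
#' @export
emu_name <- function(met, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (all(idx <= 9)) paste0(met, "_", paste(idx, collapse = ""))
  else paste0(met, "_", paste(idx, collapse = ","))
}

#' @rdname emu_name
#' @param name an EMU name in either text form.
#' @export
parse_emu <- function(name) {
  m <- regmatches(name, regexec("^(.*)_([0-9,]+)$", name))[[1]]
  if (length(m) != 3L) stop(sprintf("malformed EMU name '%s'", name), call. = FALSE)
  idx <- if (grepl(",", m[3], fixed = TRUE))
    as.integer(strsplit(m[3], ",", fixed = TRUE)[[1]])
  else as.integer(strsplit(m[3], "")[[1]])
  list(met = m[2], idx = sort(idx))
}

# producing fluxes of a metabolite: one record per (total flux, product
# instance) with the product's atom map and instance coefficient
producing_records <- function(net, met) {
  out <- list()
  tf <- net$total_fluxes
  for (k in seq_len(nrow(tf))) {
    r <- net$reactions[[tf$reaction[k]]]
    prods <- if (tf$direction[k] == 1) r$products else r$substrates
    subs <- if (tf$direction[k] == 1) r$substrates else r$products
    hit <- which(prods$met == met & nzchar(prods$map))
    for (i in hit)
      out <- c(out, list(list(flux_id = tf$flux_id[k], coef = prods$coef[i],
                              map = prods$map[i], sub_side = subs)))
  }
  out
}

# total consumption flux weight of a metabolite, as a linear form over total
# fluxes: named coefficient vector
consumption_form <- function(net, met) {
  tf <- net$total_fluxes
  w <- stats::setNames(numeric(nrow(tf)), tf$flux_id)
  for (k in seq_len(nrow(tf))) {
    r <- net$reactions[[tf$reaction[k]]]
    subs <- if (tf$direction[k] == 1) r$substrates else r$products
    hit <- which(subs$met == met)
    if (length(hit)) w[k] <- w[k] + sum(subs$coef[hit])
  }
  w[w != 0]
}

#' Decompose a network into size-ordered EMU reaction networks
#'
#' Backward traversal from each target EMU: every producing reaction's atom
#' map carries the target's atoms to the substrate side, yielding one EMU
#' reaction per producing instance whose sources are the substrate EMUs that
#' contribute atoms (two or more sources denote a condensation node, whose
#' MDV is the convolution of its sources). Traversal recurses, memoized on
#' canonical EMU names, until substrate metabolites are reached; the result
#' is combined by EMU size, which is the order in which the balance systems
#' are later solved.
#'
#' @param net a `flux_network`.
#' @param targets character vector of EMU names (e.g. `"F_123"`).
#' @return an `emu_network`: list with `reactions` (tibble: `size`, `target`,
#'   `sources` ("+"-joined names), `flux_id`, `coef`), `internal` and
#'   `sources` per size, and the original targets.
#' @export
decompose_network <- function(net, targets) {
  mets <- net$metabolites
  is_sub <- stats::setNames(mets$is_substrate, mets$id)
  n_at <- stats::setNames(mets$n_atoms, mets$id)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  queue <- character()

  push <- function(name) {
    if (!is.null(seen[[name]])) return(invisible())
    seen[[name]] <- TRUE
    queue <<- c(queue, name)
  }

  for (tg in targets) {
    p <- parse_emu(tg)
    if (!p$met %in% mets$id)
      stop(sprintf("target EMU '%s': unknown metabolite", tg), call. = FALSE)
    if (any(p$idx < 1L) || any(p$idx > n_at[[p$met]]))
      stop(sprintf("target EMU '%s': atom index out of range", tg), call. = FALSE)
    push(emu_name(p$met, p$idx))
  }

  while (length(queue)) {
    nm <- queue[1]; queue <- queue[-1]
    p <- parse_emu(nm)
    if (isTRUE(is_sub[[p$met]])) next  # substrate EMUs are terminal sources
    recs <- producing_records(net, p$met)
    if (length(recs) == 0L)
      stop(sprintf("EMU '%s' is unreachable: metabolite is never produced with an atom map", nm),
           call. = FALSE)
    for (rec in recs) {
      letters_needed <- strsplit(rec$map, "")[[1]][p$idx]
      # locate each needed letter in the substrate-side molecule instances
      src <- list()
      for (i in seq_len(nrow(rec$sub_side))) {
        smap <- strsplit(rec$sub_side$map[i], "")[[1]]
        pos <- which(smap %in% letters_needed)
        if (length(pos))
          src <- c(src, list(emu_name(rec$sub_side$met[i], pos)))
      }
      found <- sum(purrr::map_int(src, ~ length(parse_emu(.x)$idx)))
      if (found != length(letters_needed))
        stop(sprintf("EMU '%s': atoms lost through reaction flux '%s' (unbalanced atom map?)",
                     nm, rec$flux_id), call. = FALSE)
      src <- sort(unlist(src))
      rows <- c(rows, list(tibble::tibble(
        size = length(p$idx), target = nm,
        sources = paste(src, collapse = "+"),
        flux_id = rec$flux_id, coef = rec$coef)))
      for (s in src) push(s)
    }
  }

  tbl <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$size, .data$target, .data$sources, .data$flux_id) |>
    dplyr::summarise(coef = sum(.data$coef), .groups = "drop") |>
    dplyr::arrange(.data$size, .data$target, .data$sources, .data$flux_id)

  # ground-reachability: every internal EMU must draw label, directly or
  # transitively, from a substrate EMU; a closed same-size loop with no
  # grounded inflow leaves its balance singular and is reported here
  all_targets <- unique(tbl$target)
  grounded <- new.env(parent = emptyenv())
  emu_is_sub <- function(nm) isTRUE(is_sub[[parse_emu(nm)$met]])
  for (s in sort(unique(tbl$size))) {
    sub_tbl <- tbl[tbl$size == s, ]
    pend <- unique(sub_tbl$target)
    repeat {
      newly <- character()
      for (tg2 in pend) {
        rows_tg <- sub_tbl[sub_tbl$target == tg2, ]
        ok <- FALSE
        for (r2 in seq_len(nrow(rows_tg))) {
          srcs <- strsplit(rows_tg$sources[r2], "+", fixed = TRUE)[[1]]
          if (all(vapply(srcs, function(x) emu_is_sub(x) ||
                           isTRUE(grounded[[x]]), TRUE))) { ok <- TRUE; break }
        }
        if (ok) newly <- c(newly, tg2)
      }
      if (!length(newly)) break
      for (x in newly) grounded[[x]] <- TRUE
      pend <- setdiff(pend, newly)
    }
    if (length(pend))
      stop(sprintf("EMU(s) unreachable from any substrate: %s",
                   paste(pend, collapse = ", ")), call. = FALSE)
  }

  all_emus <- sort(unique(c(tbl$target, unlist(strsplit(tbl$sources, "+", fixed = TRUE)))))
  emu_met <- purrr::map_chr(all_emus, ~ parse_emu(.x)$met)
  emu_size <- purrr::map_int(all_emus, ~ length(parse_emu(.x)$idx))
  internal <- split(all_emus[!is_sub[emu_met]], emu_size[!is_sub[emu_met]])
  src_emus <- split(all_emus[is_sub[emu_met]], emu_size[is_sub[emu_met]])

  structure(list(reactions = tbl, internal = internal, source = src_emus,
                 targets = targets, net = net),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("<emu_network: %d EMU reactions over sizes {%s}; targets: %s>\n",
              nrow(x$reactions), paste(sort(unique(x$reactions$size)), collapse = ","),
              paste(x$targets, collapse = ", ")))
  print(x$reactions, n = 20)
  invisible(x)
}

#' @method tidy emu_network
#' @export
tidy.emu_network <- function(x, ...) x$reactions

#' Export an EMU network as TSV
#'
#' Columns `size`, `target`, `sources`, `flux_id`, `coefficient`.
#' @param x an `emu_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_emu_network <- function(x, path) {
  out <- dplyr::rename(x$reactions, coefficient = "coef")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- compiled EMU balance structure (internal) -----------------------------
# Precomputes, for each size, the index bookkeeping that lets the simulator
# refill A and B from a flux vector in microseconds: triplets of (row, col,
# flux index, coefficient) for A and B, the list of Y source combos, and the
# consumption linear form per internal EMU.
compile_emu_system <- function(emunet) {
  net <- emunet$net
  tf_ids <- net$total_fluxes$flux_id
  sizes <- sort(unique(emunet$reactions$size))
  mets <- net$metabolites
  is_sub <- stats::setNames(mets$is_substrate, mets$id)
  systems <- list()
  for (s in sizes) {
    ints <- emunet$internal[[as.character(s)]]
    if (is.null(ints) || !length(ints)) next
    rx <- emunet$reactions[emunet$reactions$size == s, ]
    rx <- rx[rx$target %in% ints, , drop = FALSE]
    ycombos <- character()
    A_trip <- list(); B_trip <- list()
    for (k in seq_len(nrow(rx))) {
      tgt <- match(rx$target[k], ints)
      srcs <- strsplit(rx$sources[k], "+", fixed = TRUE)[[1]]
      fidx <- match(rx$flux_id[k], tf_ids)
      if (length(srcs) == 1L && !is_sub[[parse_emu(srcs)$met]] &&
          srcs %in% ints) {
        A_trip <- c(A_trip, list(c(tgt, match(srcs, ints), fidx, rx$coef[k])))
      } else {
        key <- rx$sources[k]
        j <- match(key, ycombos)
        if (is.na(j)) { ycombos <- c(ycombos, key); j <- length(ycombos) }
        B_trip <- c(B_trip, list(c(tgt, j, fidx, rx$coef[k])))
      }
    }
    cons <- purrr::map(ints, function(nm) {
      w <- consumption_form(net, parse_emu(nm)$met)
      cbind(idx = match(names(w), tf_ids), coef = as.numeric(w))
    })
    systems[[as.character(s)]] <- list(
      size = s, internal = ints,
      A = do.call(rbind, A_trip), B = do.call(rbind, B_trip),
      ycombos = ycombos,
      ysources = purrr::map(ycombos, ~ strsplit(.x, "+", fixed = TRUE)[[1]]),
      cons = cons)
  }
  list(sizes = sizes, systems = systems, tf_ids = tf_ids, net = net,
       targets = emunet$targets)
}
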