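#' Parse one atom-mapped reaction
#'
#' Reactions are written in a compact text dialect:
#'
#' ```
#' id: coef Met{abc} + ... -> coef Met{ab} + ... [rev] [nocheck]
#' ```
#'
#' Atom maps are lowercase letter strings in braces, one letter per carbon,
#' unique within a molecule instance; the same letter on both sides of the
#' arrow identifies the atom transition. Stoichiometric coefficients default
#' to 1 and accept fractions (`1/2`) — a symmetric metabolite is written as
#' the same product twice with its two atom maps and coefficient 1/2 each.
#' A trailing `[rev]` (or the arrow `<->`) marks the reaction reversible;
#' `[nocheck]` suppresses the carbon-balance check for pseudo-reactions such
#' as biomass drains.
#'
#' @param line a single reaction string.
#' @return a `flux_reaction`: list with `id`, `substrates` and `products`
#'   (tibbles with columns `met`, `coef`, `map`), `reversible`, `nocheck`.
#' @examples
#' parse_reaction("v3: B{abc} -> C{bc} + E{a}")
#' parse_reaction("ppc: PEP{abc} + CO2{d} -> OAA{abcd}")
#' @export
parse_reaction <- function(line) {
  line <- trimws(line)
  nocheck <- grepl("\\[nocheck\\]", line)
  rev_flag <- grepl("\\[rev\\]", line)
  line <- trimws(gsub("\\[(rev|nocheck)\\]", "", line))
  m <- regmatches(line, regexec("^([^:]+):(.*)$", line))[[1]]
  if (length(m) != 3L) stop("malformed reaction line (missing 'id:')", call. = FALSE)
  id <- trimws(m[2])
  eq <- trimws(m[3])
  if (grepl("<->", eq, fixed = TRUE)) {
    rev_flag <- TRUE
    sides <- strsplit(eq, "<->", fixed = TRUE)[[1]]
  } else {
    sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  }
  if (length(sides) != 2L) stop("malformed reaction arrow", call. = FALSE)
  parse_side <- function(s) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L) stop("empty reaction side", call. = FALSE)
    out <- purrr::map(terms, function(tm) {
      mm <- regmatches(tm, regexec(
        "^(?:([0-9./]+)\\s+)?([A-Za-z0-9_.]+)(?:\\{([a-z]*)\\})?$", tm))[[1]]
      if (length(mm) != 4L || !nzchar(mm[3]))
        stop(sprintf("malformed term '%s'", tm), call. = FALSE)
      coef <- if (nzchar(mm[2])) {
        if (grepl("/", mm[2], fixed = TRUE)) {
          pq <- as.numeric(strsplit(mm[2], "/", fixed = TRUE)[[1]])
          pq[1] / pq[2]
        } else as.numeric(mm[2])
      } else 1
      if (!is.finite(coef) || coef <= 0)
        stop(sprintf("non-positive coefficient in '%s'", tm), call. = FALSE)
      map <- mm[4]
      if (nzchar(map) && anyDuplicated(strsplit(map, "")[[1]]))
        stop(sprintf("duplicate atom letter within '%s'", tm), call. = FALSE)
      tibble::tibble(met = mm[3], coef = coef, map = map)
    })
    dplyr::bind_rows(out)
  }
  subs <- parse_side(sides[1])
  prods <- parse_side(sides[2])
  if (!nocheck) {
    ls <- sort(unlist(strsplit(subs$map, "")))
    lp <- sort(unlist(strsplit(prods$map, "")))
    if (!identical(ls, lp))
      stop(sprintf("reaction '%s': atom letters unbalanced (%s vs %s)", id,
                   paste(ls, collapse = ""), paste(lp, collapse = "")),
           call. = FALSE)
  }
  structure(list(id = id, substrates = subs, products = prods,
                 reversible = rev_flag, nocheck = nocheck),
            class = "flux_reaction")
}

#' @export
print.flux_reaction <- function(x, ...) {
  fmt <- function(tb) paste(sprintf("%s%s%s",
    ifelse(tb$coef == 1, "", paste0(format(tb$coef), " ")), tb$met,
    ifelse(nzchar(tb$map), paste0("{", tb$map, "}"), "")), collapse = " + ")
  cat(sprintf("%s: %s %s %s%s\n", x$id, fmt(x$substrates),
              if (x$reversible) "<->" else "->", fmt(x$products),
              if (x$nocheck) " [nocheck]" else ""))
  invisible(x)
}

normalize_reversible <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y", "rev")
}

#' Assemble a metabolic network from reactions
#'
#' Builds the network object that drives everything downstream: the
#' metabolite table (with substrate / excreted / balanced status), the
#' ordered list of total fluxes (each reversible reaction contributes a
#' forward `id_f` and backward `id_b` column), and the stoichiometric matrix
#' `S` over balanced metabolites and total fluxes, so that `S %*% v = 0`
#' defines the feasible flux space.
#'
#' Substrate status defaults to "never produced" and excreted status to
#' "never consumed"; both can be overridden. Balanced (mass-conserved)
#' metabolites are the ones that are neither.
#'
#' @param reactions a list of [parse_reaction()] results, or a data frame
#'   with columns `id`, `equation`, `reversible`.
#' @param substrates,excreted optional character vectors overriding the
#'   inferred roles.
#' @return a `flux_network` object.
#' @export
flux_network <- function(reactions, substrates = NULL, excreted = NULL) {
  if (is.data.frame(reactions)) {
    df <- reactions
    req <- c("id", "equation")
    if (!all(req %in% names(df))) stop("need columns id, equation", call. = FALSE)
    rxns <- purrr::map(seq_len(nrow(df)), function(i) {
      r <- parse_reaction(paste0(df$id[i], ": ", df$equation[i]))
      if ("reversible" %in% names(df))
        r$reversible <- r$reversible || normalize_reversible(df$reversible[i])
      r
    })
  } else rxns <- reactions
  if (length(rxns) == 0L) stop("no reactions", call. = FALSE)
  ids <- purrr::map_chr(rxns, "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate reaction id '%s'", ids[duplicated(ids)][1]), call. = FALSE)
  names(rxns) <- ids

  # metabolite registry with consistent carbon counts
  occ <- dplyr::bind_rows(purrr::map(rxns, function(r) {
    dplyr::bind_rows(
      dplyr::mutate(r$substrates, side = "s", rid = r$id),
      dplyr::mutate(r$products, side = "p", rid = r$id))
  }))
  mets <- occ |>
    dplyr::group_by(.data$met) |>
    dplyr::summarise(
      n_atoms = {
        lens <- unique(nchar(.data$map[nzchar(.data$map)]))
        if (length(lens) > 1L)
          stop(sprintf("metabolite '%s' has inconsistent carbon counts", .data$met[1]),
               call. = FALSE)
        if (length(lens) == 0L) 0L else as.integer(lens)
      },
      produced = any(.data$side == "p" | (.data$side == "s" &
                       purrr::map_lgl(.data$rid, ~ rxns[[.x]]$reversible))),
      consumed = any(.data$side == "s" | (.data$side == "p" &
                       purrr::map_lgl(.data$rid, ~ rxns[[.x]]$reversible))),
      .groups = "drop")
  # role inference over the irreversible skeleton: a reversible reaction does
  # not by itself make its substrate "produced" unless nothing else does
  prod_irr <- unique(occ$met[occ$side == "p"])
  cons_irr <- unique(occ$met[occ$side == "s"])
  rev_ids <- ids[purrr::map_lgl(rxns, "reversible")]
  prod_rev <- unique(occ$met[occ$side == "s" & occ$rid %in% rev_ids])
  cons_rev <- unique(occ$met[occ$side == "p" & occ$rid %in% rev_ids])
  mets$is_substrate <- !(mets$met %in% union(prod_irr, prod_rev))
  mets$is_excreted <- !(mets$met %in% union(cons_irr, cons_rev)) & !mets$is_substrate
  if (!is.null(substrates)) mets$is_substrate <- mets$met %in% substrates
  if (!is.null(excreted)) mets$is_excreted <- mets$met %in% excreted & !mets$is_substrate
  mets$is_balanced <- !mets$is_substrate & !mets$is_excreted
  mets <- dplyr::rename(mets, id = "met")

  # total flux ordering: file order, reversible split into _f then _b
  total <- purrr::map(rxns, function(r)
    if (r$reversible) tibble::tibble(reaction = r$id, flux_id = paste0(r$id, c("_f", "_b")),
                                     direction = c(1, -1))
    else tibble::tibble(reaction = r$id, flux_id = r$id, direction = 1))
  total <- dplyr::bind_rows(total)

  net <- structure(list(metabolites = mets, reactions = rxns,
                        total_fluxes = total), class = "flux_network")
  net$S <- stoichiometric_matrix(net)
  net
}

#' Read an atom-mapped network from a TSV/CSV file
#'
#' Expects a delimited file with header columns `id`, `equation`,
#' `reversible` (TRUE/1/yes accepted). See [parse_reaction()] for the
#' equation dialect and [flux_network()] for role inference and overrides.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @inheritParams flux_network
#' @return a `flux_network`.
#' @export
read_network <- function(path, sep = "\t", substrates = NULL, excreted = NULL) {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          strip.white = TRUE, comment.char = "#")
  if (nrow(df) == 0L) stop("no reactions in file", call. = FALSE)
  flux_network(df, substrates = substrates, excreted = excreted)
}

#' Stoichiometric matrix over total fluxes
#'
#' `S[m, r]` is the net stoichiometric coefficient of balanced metabolite `m`
#' in total flux `r`; the backward column of a reversible reaction is the
#' negation of its forward column.
#'
#' @param net a `flux_network`.
#' @return a numeric matrix, balanced metabolites x total fluxes.
#' @export
stoichiometric_matrix <- function(net) {
  bal <- net$metabolites$id[net$metabolites$is_balanced]
  tf <- net$total_fluxes
  S <- matrix(0, length(bal), nrow(tf), dimnames = list(bal, tf$flux_id))
  for (k in seq_len(nrow(tf))) {
    r <- net$reactions[[tf$reaction[k]]]
    dirn <- tf$direction[k]
    for (i in seq_len(nrow(r$substrates)))
      if (r$substrates$met[i] %in% bal)
        S[r$substrates$met[i], k] <- S[r$substrates$met[i], k] - dirn * r$substrates$coef[i]
    for (i in seq_len(nrow(r$products)))
      if (r$products$met[i] %in% bal)
        S[r$products$met[i], k] <- S[r$products$met[i], k] + dirn * r$products$coef[i]
  }
  S
}

#' Split net and exchange fluxes into total (forward/backward) fluxes
#'
#' A reversible reaction with net flux `v_net` and exchange flux `v_xch >= 0`
#' carries forward flux `v_net + v_xch` when `v_net >= 0` (else `v_xch`) and
#' backward flux `forward - v_net`, so `v_f - v_b = v_net` holds exactly.
#' Irreversible reactions require `v_net >= 0`.
#'
#' @param net a `flux_network`.
#' @param net_fluxes named numeric vector of net fluxes per reaction id.
#' @param xch_fluxes named numeric vector of exchange fluxes per reversible
#'   reaction id (missing ids default to 0).
#' @return a tibble with columns `reaction`, `flux_id`, `value` over all
#'   total fluxes, in network order.
#' @export
split_total_fluxes <- function(net, net_fluxes, xch_fluxes = NULL) {
  tf <- net$total_fluxes
  rev_ids <- unique(tf$reaction[tf$direction == -1])
  xch <- stats::setNames(numeric(length(rev_ids)), rev_ids)
  if (!is.null(xch_fluxes)) xch[names(xch_fluxes)] <- xch_fluxes
  if (any(xch < 0)) stop("negative exchange flux", call. = FALSE)
  missing <- setdiff(unique(tf$reaction), names(net_fluxes))
  if (length(missing))
    stop(sprintf("missing net flux for %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  val <- numeric(nrow(tf))
  for (k in seq_len(nrow(tf))) {
    rid <- tf$reaction[k]
    vn <- net_fluxes[[rid]]
    if (!rid %in% rev_ids) {
      if (vn < 0) stop(sprintf("negative net flux on irreversible '%s'", rid),
                       call. = FALSE)
      val[k] <- vn
    } else {
      fwd <- if (vn >= 0) vn + xch[[rid]] else xch[[rid]]
      val[k] <- if (tf$direction[k] == 1) fwd else fwd - vn
    }
  }
  tibble::tibble(reaction = tf$reaction, flux_id = tf$flux_id, value = val)
}

# named total-flux vector from the split tibble (internal hot-path form)
flux_vector <- function(split_tbl) {
  stats::setNames(split_tbl$value, split_tbl$flux_id)
}

# net fluxes per reaction from a total-flux vector
net_from_total <- function(net, v) {
  tf <- net$total_fluxes
  agg <- tapply(v[tf$flux_id] * tf$direction, tf$reaction, sum)
  out <- as.numeric(agg)[match(unique(tf$reaction), names(agg))]
  stats::setNames(out, unique(tf$reaction))
}

#' Structural validation report for a network
#'
#' Flags dead-end balanced metabolites (never produced or never consumed),
#' carbon-unbalanced reactions not marked `nocheck`, and duplicate ids.
#' Report-only: never raises.
#'
#' @param net a `flux_network`.
#' @return a tibble with columns `check`, `object`, `message`; attribute
#'   `ok` is `TRUE` when no issues were found.
#' @export
validate_network <- function(net) {
  issues <- list()
  for (m in net$metabolites$id[net$metabolites$is_balanced]) {
    row <- net$S[m, ]
    if (all(row <= 0) || all(row >= 0))
      issues <- c(issues, list(tibble::tibble(
        check = "dead_end", object = m,
        message = "balanced metabolite is never produced or never consumed")))
  }
  for (r in net$reactions) {
    ls <- sort(unlist(strsplit(r$substrates$map, "")))
    lp <- sort(unlist(strsplit(r$products$map, "")))
    if (!identical(ls, lp) && !r$nocheck)
      issues <- c(issues, list(tibble::tibble(
        check = "carbon_balance", object = r$id,
        message = "atom letters unbalanced")))
  }
  out <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(check = character(), object = character(), message = character())
  attr(out, "ok") <- nrow(out) == 0L
  out
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network: %d metabolites (%d balanced), %d reactions, %d total fluxes>\n",
              nrow(x$metabolites), sum(x$metabolites$is_balanced),
              length(x$reactions), nrow(x$total_fluxes)))
  for (r in x$reactions) print(r)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network into its reaction table
#'
#' @param x a `flux_network`.
#' @param ... unused.
#' @return a tibble with one row per reaction: `id`, `equation`, `reversible`.
#' @method tidy flux_network
#' @export
tidy.flux_network <- function(x, ...) {
  fmt <- function(tb) paste(sprintf("%s%s%s",
    ifelse(tb$coef == 1, "", paste0(format(tb$coef), " ")), tb$met,
    ifelse(nzchar(tb$map), paste0("{", tb$map, "}"), "")), collapse = " + ")
  tibble::tibble(
    id = purrr::map_chr(x$reactions, "id"),
    equation = purrr::map_chr(x$reactions, ~ paste(fmt(.x$substrates), "->",
                                                   fmt(.x$products))),
    reversible = purrr::map_lgl(x$reactions, "reversible"))
}
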