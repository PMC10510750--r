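#' Mass isotopomer distribution vectors (MDVs)
#'
#' An MDV is the length-(n+1) vector of fractional abundances of the mass
#' shifts M+0 ... M+n of an n-atom metabolite fragment (EMU). It is the
#' universal unit of both measurement and simulation in carbon-13 metabolic
#' flux analysis: every simulated labeling state and every mass-spectrometric
#' measurement is an MDV.
#'
#' `mdv()` validates and normalizes a numeric vector into an `mdv` object.
#' Entries must be non-negative and are renormalized to sum to one (a sum
#' deviating from 1 by more than `tol` is an error unless `normalize = TRUE`,
#' the default, in which case any positive-sum vector is accepted).
#'
#' @param x numeric vector of length n+1, abundances of M+0 ... M+n.
#' @param normalize logical; rescale to unit sum (default `TRUE`).
#' @param tol tolerance on the unit-sum invariant when `normalize = FALSE`.
#' @return an object of class `mdv`: a numeric vector with attribute
#'   `n_atoms = length(x) - 1`.
#' @examples
#' mdv(c(0.25, 0.5, 0.25))
#' mdv(c(1, 0)) * mdv(c(0, 1)) # convolution via the product operator
#' @export
mdv <- function(x, normalize = TRUE, tol = 1e-9) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("an MDV needs at least the M+0 entry", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite MDV entries", call. = FALSE)
  if (any(x < -1e-12)) stop("negative MDV entries", call. = FALSE)
  x[x < 0] <- 0
  s <- sum(x)
  if (normalize) {
    if (s <= 0) stop("MDV has zero total abundance", call. = FALSE)
    x <- x / s
  } else if (abs(s - 1) > tol) {
    stop(sprintf("MDV sums to %.6g, not 1", s), call. = FALSE)
  }
  structure(x, n_atoms = length(x) - 1L, class = "mdv")
}

#' @export
print.mdv <- function(x, ...) {
  cat(sprintf("<mdv: %d atom(s)>\n", attr(x, "n_atoms")))
  v <- as.numeric(x)
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(round(v, 6))
  invisible(x)
}

#' Number of tracer atoms of an MDV
#' @param x an `mdv`.
#' @return integer atom count n (the vector has n+1 entries).
#' @export
n_atoms <- function(x) length(as.numeric(x)) - 1L

#' Convolution of two MDVs
#'
#' The MDV of a fragment assembled from two independent precursor fragments
#' (a condensation reaction) is the discrete convolution of the precursor
#' MDVs. Also available as the `*` operator on `mdv` objects.
#'
#' @param a,b MDVs (or bare numeric probability vectors).
#' @return an `mdv` of length `length(a) + length(b) - 1`.
#' @examples
#' conv(mdv(c(0.5, 0.5)), mdv(c(0.5, 0.5))) # binomial: 0.25 0.5 0.25
#' @export
conv <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  mdv(convolve(a, rev(b), type = "open"), normalize = TRUE)
}

#' @export
`*.mdv` <- function(e1, e2) conv(e1, e2)

# fast path used by the simulator kernels: plain numeric in/out, no class
conv_raw <- function(a, b) convolve(a, rev(b), type = "open")

#' Natural-isotope mass-shift distributions
#'
#' Per-element probability vectors over mass shifts (+0, +1, +2, ...) for the
#' stable isotopes of the elements that occur in typical derivatized MS
#' fragments. Carbon's value (0.0107 for 13C) is the default tracer-element
#' natural abundance throughout the package and can be overridden here.
#'
#' @param p13 natural 13C abundance (default 0.0107).
#' @return a named list of numeric probability vectors, one per element.
#' @export
isotope_constants <- function(p13 = 0.0107) {
  stopifnot(p13 >= 0, p13 < 1)
  list(
    C  = c(1 - p13, p13),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    S  = c(0.9499, 0.0075, 0.0425, 0.0001),
    Si = c(0.92223, 0.04685, 0.03092)
  )
}

#' Natural-abundance MDV of an unlabeled fragment
#'
#' Binomial distribution of mass shifts for n tracer atoms each independently
#' heavy with probability `p13`.
#'
#' @param n number of tracer (carbon) atoms, >= 0.
#' @param p13 natural 13C abundance.
#' @return an `mdv` of length n+1.
#' @examples
#' natural_mdv(1) # 0.9893 0.0107
#' @export
natural_mdv <- function(n, p13 = 0.0107) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  mdv(stats::dbinom(0:n, size = n, prob = p13), normalize = TRUE)
}

#' MDV of an EMU drawn from a labeled substrate
#'
#' Builds the mass isotopomer distribution of a specific atom subset of a
#' tracer substrate under a labeling strategy: a mixture of declared
#' isotopomers, each given as a 0/1 mask over the substrate's atoms, a molar
#' fraction, and an isotopic purity. Atoms marked `1` are heavy with
#' probability `purity`; atoms marked `0` are heavy with the natural
#' probability `p13`. The EMU restricts to `atom_idx` and the per-atom
#' Bernoulli distributions convolve into the fragment MDV.
#'
#' @param atom_idx 1-based atom indices of the EMU within the substrate.
#' @param isotopomers a data frame (or tibble) with columns `mask` (string of
#'   0/1 per atom), `fraction`, and optionally `purity` (default 1).
#' @param p13 natural 13C abundance used for unlabeled positions.
#' @return an `mdv` of length `length(atom_idx) + 1`.
#' @examples
#' # 80% [1-13C] + 20% [U-13C] glucose, first two atoms, ignoring natural 13C
#' substrate_mdv(1:2, data.frame(mask = c("100000", "111111"),
#'                               fraction = c(0.8, 0.2)), p13 = 0)
#' @export
substrate_mdv <- function(atom_idx, isotopomers, p13 = 0.0107) {
  iso <- as.data.frame(isotopomers)
  if (is.null(iso$purity)) iso$purity <- 1
  if (abs(sum(iso$fraction) - 1) > 1e-6)
    stop("isotopomer fractions must sum to 1", call. = FALSE)
  nlen <- unique(nchar(iso$mask))
  if (length(nlen) != 1L)
    stop("isotopomer masks have inconsistent lengths", call. = FALSE)
  if (any(atom_idx < 1L | atom_idx > nlen))
    stop("EMU atom index outside the substrate's atoms", call. = FALSE)
  out <- numeric(length(atom_idx) + 1L)
  for (k in seq_len(nrow(iso))) {
    bits <- strsplit(iso$mask[k], "")[[1]]
    if (!all(bits %in% c("0", "1")))
      stop("isotopomer masks must be strings of 0/1", call. = FALSE)
    m <- c(1)
    for (j in atom_idx) {
      p <- if (bits[j] == "1") iso$purity[k] else p13
      m <- conv_raw(m, c(1 - p, p))
    }
    out <- out + iso$fraction[k] * m
  }
  mdv(out)
}

# lower-triangular Toeplitz correction matrix for one mass-shift pmf,
# truncated to (n+1) x (n+1)
shift_matrix <- function(pmf, n) {
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    kmax <- min(length(pmf) - 1L, n - j)
    M[j + 1L + 0:kmax, j + 1L] <- pmf[1L + 0:kmax]
  }
  M
}

#' Correct a raw MDV for natural isotope abundance of non-tracer atoms
#'
#' A measured fragment carries, besides its tracer carbons, a fixed elemental
#' backbone (derivatization groups, heteroatoms) whose natural heavy isotopes
#' inflate higher mass shifts. The forward effect is the convolution cascade
#' of each element's mass-shift distribution raised to its atom count; the
#' correction solves that linear system by least squares, clips tiny negative
#' values, and renormalizes.
#'
#' @param raw measured `mdv` (length = tracer atoms + 1).
#' @param formula named integer vector of non-tracer atom counts, e.g.
#'   `c(C = 9, H = 20, O = 3, Si = 2)` for a TMS-derivatized fragment. Carbon
#'   counts here are backbone carbons outside the tracer fragment.
#' @param constants isotope table from [isotope_constants()].
#' @param neg_tol entries below `-neg_tol` after solving signal an
#'   inconsistent formula and raise an error (default 1e-3); entries in
#'   `(-neg_tol, 0)` are clipped to zero.
#' @return corrected `mdv` over the tracer atoms only.
#' @export
correct_natural_abundance <- function(raw, formula = integer(),
                                      constants = isotope_constants(),
                                      neg_tol = 1e-3) {
  x <- as.numeric(raw)
  n <- length(x) - 1L
  if (length(formula) == 0L) return(mdv(x))
  cascade <- c(1)
  for (el in names(formula)) {
    if (!el %in% names(constants))
      stop(sprintf("no isotope data for element '%s'", el), call. = FALSE)
    cnt <- formula[[el]]
    if (cnt < 0) stop("negative atom count in formula", call. = FALSE)
    for (i in seq_len(cnt)) cascade <- conv_raw(cascade, constants[[el]])
  }
  M <- shift_matrix(cascade, n)
  sv <- svd(M)$d
  if (min(sv) < 1e-12 * max(sv))
    stop("correction matrix is singular or ill-conditioned", call. = FALSE)
  corrected <- qr.solve(M, x)
  if (any(corrected < -neg_tol))
    stop("correction produced large negative abundances; check the formula",
         call. = FALSE)
  corrected[corrected < 0] <- 0
  mdv(corrected)
}

#' Correct an MDV for the unlabeled fraction introduced by the inoculum
#'
#' Cultures started from unlabeled seed material measure a mixture
#' `raw = f * natural + (1 - f) * true`. Given the unlabeled fraction `f`,
#' this inverts the mixture and renormalizes.
#'
#' @param raw measured `mdv`.
#' @param f inoculum (unlabeled) fraction in `[0, 1)`.
#' @param p13 natural 13C abundance for the unlabeled component.
#' @param neg_tol as in [correct_natural_abundance()].
#' @return corrected `mdv`.
#' @export
correct_inoculum <- function(raw, f, p13 = 0.0107, neg_tol = 1e-3) {
  if (f < 0 || f >= 1) stop("inoculum fraction must be in [0, 1)", call. = FALSE)
  x <- as.numeric(raw)
  if (f == 0) return(mdv(x))
  nat <- as.numeric(natural_mdv(length(x) - 1L, p13))
  corrected <- (x - f * nat) / (1 - f)
  if (any(corrected < -neg_tol))
    stop("inoculum correction produced large negative abundances; f too large?",
         call. = FALSE)
  corrected[corrected < 0] <- 0
  mdv(corrected)
}
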