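#' @keywords internal
"_PACKAGE"

# Monoisotopic masses and natural isotope abundances (NIST / CODATA).
# Each element: mass shifts are relative to the lightest isotope and
# indexed by nominal neutron-count difference.
.isotopes <- list(
  C  = list(mass = c(12.0000000000, 13.0033548351), abundance = c(0.9893, 0.0107)),
  H  = list(mass = c(1.0078250319, 2.0141017779),   abundance = c(0.999885, 0.000115)),
  N  = list(mass = c(14.0030740052, 15.0001088984), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146221, 16.9991315000, 17.9991604000),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = c(30.9737615100), abundance = c(1.0)),
  S  = list(mass = c(31.9720707300, 32.9714585400, 33.9678668700, 35.9670808800),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = c(22.9897696700), abundance = c(1.0)),
  K  = list(mass = c(38.9637069000, 39.9639986700, 40.9618259700),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Cl = list(mass = c(34.9688527100, 36.9659026000), abundance = c(0.7576, 0.2424))
)

.electron_mass <- 0.00054857990907
.proton_mass <- 1.0078250319 - .electron_mass

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula (e.g. \code{"C12H24O2"}) into a
#' named vector of element counts.  Supported elements are C, H, N, O, P,
#' S, Na, K and Cl.  A missing count means one atom.
#'
#' @param formula character scalar, e.g. \code{"C28H37N5O7"}.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C12H24O2")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a single non-empty character string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  elements <- sub("[0-9]+$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elements, names(.isotopes))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  if (any(counts <= 0L)) stop("element counts must be positive", call. = FALSE)
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of lightest-isotope masses times element counts.
#'
#' @param formula character formula or a named count vector from
#'   [parse_formula()].
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.0106
#' monoisotopic_mass("C12H24O2")  # dodecanoic acid
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(vapply(names(counts),
             function(el) .isotopes[[el]]$mass[1L] * counts[[el]],
             numeric(1L)))
}

# Convolve two aggregated isotopologue distributions.  Each distribution is
# a list(prob, mass) indexed by nominal shift 0,1,2,...; 'mass' holds the
# probability-weighted mean mass at each shift.
.convolve_iso <- function(a, b, max_len) {
  na <- length(a$prob); nb <- length(b$prob)
  n <- min(na + nb - 1L, max_len)
  prob <- numeric(n)
  wmass <- numeric(n)
  for (i in seq_len(na)) {
    jmax <- min(nb, n - i + 1L)
    if (jmax < 1L) break
    j <- seq_len(jmax)
    k <- i + j - 1L
    pij <- a$prob[i] * b$prob[j]
    prob[k] <- prob[k] + pij
    wmass[k] <- wmass[k] + pij * (a$mass[i] + b$mass[j])
  }
  mass <- ifelse(prob > 0, wmass / prob, 0)
  list(prob = prob, mass = mass)
}

# Aggregated isotopologue distribution of a single element (one atom).
.element_iso <- function(el, max_len) {
  iso <- .isotopes[[el]]
  shift <- round(iso$mass - iso$mass[1L])
  n <- min(max(shift) + 1L, max_len)
  prob <- numeric(n); mass <- numeric(n)
  keep <- shift < n
  prob[shift[keep] + 1L] <- iso$abundance[keep]
  mass[shift[keep] + 1L] <- iso$mass[keep]
  list(prob = prob, mass = mass)
}

#' Theoretical isotopic envelope
#'
#' Computes the first \code{n_isotopologues} aggregated isotopologue peaks
#' (M, M+1, M+2, ...) of a formula, optionally as an adduct ion, by
#' convolving the elemental isotope distributions.  Abundances are
#' normalized so the most abundant isotopologue equals 1.
#'
#' @param formula character formula or named count vector.
#' @param adduct adduct label (see [adduct_mz()]) or \code{NULL} for the
#'   neutral molecule.
#' @param n_isotopologues number of isotopologue peaks to return (>= 2).
#' @return data.frame with columns \code{mz} (Th; neutral mass if no
#'   adduct) and \code{abundance} (max-normalized).
#' @examples
#' theoretical_envelope("C1", n_isotopologues = 2)  # M+1 ~ 0.0108
#' theoretical_envelope("C12H24O2", adduct = "[M-H]-")
#' @export
theoretical_envelope <- function(formula, adduct = NULL, n_isotopologues = 3L) {
  if (n_isotopologues < 2L) stop("'n_isotopologues' must be >= 2", call. = FALSE)
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  charge <- 1L
  if (!is.null(adduct)) {
    spec <- .adduct_spec(adduct)
    counts <- .apply_adduct_formula(counts, spec)
    charge <- spec$charge
  }
  max_len <- n_isotopologues + 3L
  dist <- list(prob = 1, mass = 0)
  for (el in names(counts)) {
    el_dist <- .element_iso(el, max_len)
    # repeated squaring over the atom count
    k <- counts[[el]]
    acc <- NULL
    base <- el_dist
    while (k > 0L) {
      if (k %% 2L == 1L) {
        acc <- if (is.null(acc)) base else .convolve_iso(acc, base, max_len)
      }
      k <- k %/% 2L
      if (k > 0L) base <- .convolve_iso(base, base, max_len)
    }
    dist <- .convolve_iso(dist, acc, max_len)
  }
  n <- min(n_isotopologues, length(dist$prob))
  mass <- dist$mass[seq_len(n)]
  ab <- dist$prob[seq_len(n)]
  mz <- if (is.null(adduct)) {
    mass
  } else {
    (mass - charge * .electron_mass) / abs(charge)
  }
  data.frame(mz = mz, abundance = ab / max(ab))
}
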