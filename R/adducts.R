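# Adduct table: formula deltas (atoms added/removed) and ion charge.
.adducts <- list(
  "[M+H]+"    = list(add = c(H = 1L),  remove = NULL,        charge = 1L),
  "[M+2H]2+"  = list(add = c(H = 2L),  remove = NULL,        charge = 2L),
  "[M+Na]+"   = list(add = c(Na = 1L), remove = NULL,        charge = 1L),
  "[M+K]+"    = list(add = c(K = 1L),  remove = NULL,        charge = 1L),
  "[M-H]-"    = list(add = NULL,       remove = c(H = 1L),   charge = -1L),
  "[M+Cl]-"   = list(add = c(Cl = 1L), remove = NULL,        charge = -1L)
)

.adduct_spec <- function(adduct) {
  # tolerate the unicode minus occasionally seen in vendor exports
  adduct <- gsub("−", "-", adduct)
  spec <- .adducts[[adduct]]
  if (is.null(spec)) {
    stop("unsupported adduct: '", adduct, "' (supported: ",
         paste(names(.adducts), collapse = ", "), ")", call. = FALSE)
  }
  spec
}

.apply_adduct_formula <- function(counts, spec) {
  for (el in names(spec$add)) {
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + spec$add[[el]]
  }
  for (el in names(spec$remove)) {
    if (!el %in% names(counts) || counts[[el]] < spec$remove[[el]]) {
      stop("adduct removes more ", el, " atoms than the formula contains",
           call. = FALSE)
    }
    counts[el] <- counts[[el]] - spec$remove[[el]]
  }
  counts[counts > 0L]
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' Computes the ion m/z for a supported adduct, accounting for the
#' electron mass (a sub-ppm effect, but within the 5 ppm annotation
#' regime).
#'
#' @param neutral_mass neutral monoisotopic mass in Da, or a formula
#'   string which is converted via [monoisotopic_mass()].
#' @param adduct adduct label: one of \code{"[M+H]+"}, \code{"[M+2H]2+"},
#'   \code{"[M+Na]+"}, \code{"[M+K]+"}, \code{"[M-H]-"}, \code{"[M+Cl]-"}.
#' @return m/z in Th.
#' @examples
#' adduct_mz("C28H37N5O7", "[M+H]+")   # leucine enkephalin lock mass
#' adduct_mz("C12H24O2", "[M-H]-")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (is.character(neutral_mass)) neutral_mass <- monoisotopic_mass(neutral_mass)
  spec <- .adduct_spec(adduct)
  delta <- 0
  for (el in names(spec$add)) delta <- delta + .isotopes[[el]]$mass[1L] * spec$add[[el]]
  for (el in names(spec$remove)) delta <- delta - .isotopes[[el]]$mass[1L] * spec$remove[[el]]
  (neutral_mass + delta - spec$charge * .electron_mass) / abs(spec$charge)
}

#' Adduct ion polarity
#'
#' @param adduct adduct label.
#' @return \code{"positive"} or \code{"negative"}.
#' @export
adduct_polarity <- function(adduct) {
  if (.adduct_spec(adduct)$charge > 0) "positive" else "negative"
}

#' Lock-mass reference m/z
#'
#' Reference m/z of the leucine enkephalin lock-mass compound
#' (C28H37N5O7, present in the DESI spray solvent) for a given polarity.
#' Computed from the formula, never hard-coded.
#'
#' @param polarity \code{"positive"} (\code{[M+H]+}) or \code{"negative"}
#'   (\code{[M-H]-}).
#' @param formula lock-mass compound formula; default leucine enkephalin.
#' @return m/z in Th.
#' @export
lockmass_mz <- function(polarity = c("positive", "negative"),
                        formula = "C28H37N5O7") {
  polarity <- match.arg(polarity)
  adduct_mz(formula, if (polarity == "positive") "[M+H]+" else "[M-H]-")
}

#' Parts-per-million mass error
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z.
#' @return Signed error in ppm, \code{(observed - theoretical) /
#'   theoretical * 1e6}.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
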