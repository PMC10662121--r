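# Molecular-formula arithmetic: parsing, monoisotopic mass, deprotonated-ion
# m/z and degree of unsaturation, as used to check high-resolution negative-
# mode ESI assignments (e.g. a C15H28O2 fatty acid, [M-H]- calcd 239.2017).

# Monoisotopic (most abundant isotope) atomic masses in Da, CODATA/NIST
# values to >= 6 decimal places. Embedded so no lookup is needed at run time.
MONOISOTOPIC_MASS <- c(
  H  = 1.0078250319,
  D  = 2.0141017781,
  B  = 11.0093054,
  C  = 12.0000000,
  N  = 14.0030740052,
  O  = 15.9949146221,
  F  = 18.9984031627,
  Na = 22.9897692820,
  Mg = 23.9850417,
  Si = 27.9769265347,
  P  = 30.9737615120,
  S  = 31.9720706912,
  Cl = 34.9688527128,
  K  = 38.9637064864,
  Ca = 39.9625909,
  Fe = 55.9349375,
  Cu = 62.9295977,
  Zn = 63.9291420,
  Se = 79.9165218,
  Br = 78.9183376,
  I  = 126.9044719
)

ELECTRON_MASS <- 0.000548579909  # Da
HALOGENS <- c("F", "Cl", "Br", "I")

#' Parse a molecular formula string
#'
#' Parses element symbols with optional multi-digit counts, in any order
#' (Hill order not required). An omitted count means 1.
#'
#' @param text Formula string, e.g. `"C15H28O2"` or `"H2O"`.
#' @return An object of class `molecular_formula`: a list with
#'   `element_counts` (named integer vector) and `charge` (0 for the parsed
#'   neutral species).
#' @examples
#' parse_formula("C15H28O2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text))
    stop("malformed formula string: ", sQuote(text), call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(element_counts = counts, charge = 0L),
            class = "molecular_formula")
}

#' Format a molecular formula back to a string
#'
#' Inverse of [parse_formula()] up to element ordering: elements are written
#' in Hill order (C, H, then alphabetical).
#'
#' @param f A `molecular_formula`.
#' @return A formula string.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  cnt <- f$element_counts
  cnt <- cnt[cnt > 0L]
  els <- names(cnt)
  ord <- if ("C" %in% els)
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  else sort(els)
  paste0(ord, ifelse(cnt[ord] == 1L, "", cnt[ord]), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("Molecular formula:", format_formula(x), "\n")
  cat("Monoisotopic mass:", sprintf("%.4f", monoisotopic_mass(x)), "Da\n")
  invisible(x)
}

as_formula_obj <- function(f) {
  if (is.character(f)) parse_formula(f) else {
    stopifnot(inherits(f, "molecular_formula"))
    f
  }
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope atomic masses, with an electron-mass
#' correction of \eqn{-q m_e} for a net charge of \eqn{q}.
#'
#' @param f A `molecular_formula` or a formula string.
#' @return Mass in Da (for charged species, the mass of the ion).
#' @examples
#' monoisotopic_mass("H2O")       # 18.0106
#' monoisotopic_mass("C15H28O2")  # 240.2089
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula_obj(f)
  cnt <- f$element_counts
  sum(cnt * MONOISOTOPIC_MASS[names(cnt)]) - f$charge * ELECTRON_MASS
}

#' m/z of the deprotonated ion [M-H]-
#'
#' Monoisotopic mass minus one hydrogen atom plus one electron; the charge
#' state is -1 so m/z equals the ion mass.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z of the singly deprotonated anion.
#' @examples
#' mz_deprotonated("C15H28O2")  # 239.2017
#' @export
mz_deprotonated <- function(f) {
  f <- as_formula_obj(f)
  if (is.na(f$element_counts["H"]) || f$element_counts["H"] < 1L)
    stop("formula has no hydrogen to remove", call. = FALSE)
  monoisotopic_mass(f) - MONOISOTOPIC_MASS[["H"]] + ELECTRON_MASS
}

#' Degree of unsaturation (ring and double-bond equivalents)
#'
#' Computed as \eqn{(2C + 2 + N - H - X)/2} where halogens X count like
#' hydrogen and O/S are ignored.
#'
#' @inheritParams monoisotopic_mass
#' @return Degree of unsaturation (integer or half-integer).
#' @examples
#' degree_of_unsaturation("C15H28O2")  # 2
#' degree_of_unsaturation("C6H6")      # 4
#' @export
degree_of_unsaturation <- function(f) {
  f <- as_formula_obj(f)
  cnt <- function(el) {
    v <- f$element_counts[el]
    sum(v[!is.na(v)])
  }
  (2 * cnt("C") + 2 + cnt("N") - cnt("H") - cnt(HALOGENS)) / 2
}
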