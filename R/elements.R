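# IUPAC conventional standard atomic weights (2021 abridged values) for the
# elements that occur in drug-like molecules and common counterions. Used for
# the mass weighting scheme; isotope-specific masses are unsupported.
.ATOMIC_WEIGHTS <- c(
    H = 1.008,  He = 4.003, Li = 6.94,   Be = 9.012, B = 10.81,
    C = 12.011, N = 14.007, O = 15.999,  F = 18.998, Ne = 20.180,
    Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
    S = 32.06,  Cl = 35.45, Ar = 39.95,  K = 39.098, Ca = 40.078,
    Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
    Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904, I = 126.904)

.elementTable <- local({
    tab <- NULL
    function() {
        if (is.null(tab)) {
            e <- new.env()
            utils::data("elements", package = "bio3d", envir = e)
            tab <<- e$elements
        }
        tab
    }
})

.normalizeSymbol <- function(symbols) {
    s <- sub("^\\s+|\\s+$", "", symbols)
    paste0(toupper(substr(s, 1L, 1L)),
           tolower(substr(s, 2L, nchar(s))))
}

#' Atomic masses normalized to carbon
#'
#' The weight used by the mass-weighted R-GETAWAY descriptors: the IUPAC
#' conventional standard atomic weight of each element divided by that of
#' carbon (12.011), so carbon maps to exactly 1.
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @return numeric vector of carbon-normalized masses.
#' @examples
#' normalizedMasses(c("C", "H", "S"))  # 1, 0.0839, 2.669
#' @export
normalizedMasses <- function(elements) {
    sym <- .normalizeSymbol(elements)
    w <- .ATOMIC_WEIGHTS[sym]
    if (anyNA(w))
        stop("unknown element symbol(s): ",
             paste(unique(sym[is.na(w)]), collapse = ", "))
    unname(w) / .ATOMIC_WEIGHTS[["C"]]
}

#' Single-bond covalent radii
#'
#' Cordero-style covalent radii (Angstrom) looked up from the periodic-table
#' data shipped with \pkg{bio3d}; used by [perceiveBonds()].
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
covalentRadii <- function(elements) {
    tab <- .elementTable()
    sym <- .normalizeSymbol(elements)
    idx <- match(sym, tab$symb)
    r <- tab$rcov[idx]
    if (anyNA(r) || any(r <= 0, na.rm = TRUE))
        stop("no covalent radius for element symbol(s): ",
             paste(unique(sym[is.na(r) | r <= 0]), collapse = ", "))
    r
}
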