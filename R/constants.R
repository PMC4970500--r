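## Physical constants (CODATA 2018) and element data used throughout.

#' Physical constants
#'
#' Named list of the physical constants the simulator relies on, in SI units:
#' Planck constant `h` (J s), speed of light `c` (m/s), elementary charge
#' `e` (C, also J/eV), Avogadro constant `N_A` (1/mol), and the Thomson
#' scattering length (classical electron radius) `r0` (m).
#'
#' @return Named list of numeric constants.
#' @export
#' @examples
#' fxi_constants()$r0
fxi_constants <- function() {
  list(
    h   = 6.62607015e-34,
    c   = 299792458,
    e   = 1.602176634e-19,
    N_A = 6.02214076e23,
    r0  = 2.8179403262e-15
  )
}

## internal shorthands
.const <- fxi_constants()

## element symbol -> atomic number, for the elements with bundled
## scattering-factor tables plus the common PDB heteroatom set
.element_z <- c(
  H = 1L, HE = 2L, C = 6L, N = 7L, O = 8L, F = 9L, `NA` = 11L, MG = 12L,
  AL = 13L, SI = 14L, P = 15L, S = 16L, CL = 17L, K = 19L, CA = 20L,
  MN = 25L, FE = 26L, CU = 29L, ZN = 30L, SE = 34L, BR = 35L, I = 53L
)

## standard atomic weights (g/mol), IUPAC 2021 conventional values
.atomic_weight <- c(
  H = 1.008, HE = 4.0026, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  `NA` = 22.990, MG = 24.305, AL = 26.982, SI = 28.085, P = 30.974,
  S = 32.06, CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904,
  I = 126.904
)

#' Atomic number of an element symbol
#'
#' @param symbol Character vector of element symbols (case-insensitive).
#' @return Integer vector of atomic numbers Z.
#' @export
element_number <- function(symbol) {
  key <- toupper(trimws(symbol))
  z <- .element_z[key]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

#' Element symbol for an atomic number
#'
#' @param z Integer vector of atomic numbers.
#' @return Character vector of element symbols.
#' @export
element_symbol <- function(z) {
  idx <- match(as.integer(z), .element_z)
  if (anyNA(idx)) {
    stop("no element symbol known for Z = ",
         paste(unique(z[is.na(idx)]), collapse = ", "))
  }
  ## symbols in conventional capitalisation
  sym <- names(.element_z)[idx]
  paste0(substr(sym, 1, 1), tolower(substr(sym, 2, nchar(sym))))
}

.atomic_weight_of_z <- function(z) {
  idx <- match(as.integer(z), .element_z)
  if (anyNA(idx)) stop("no atomic weight known for Z = ",
                       paste(unique(z[is.na(idx)]), collapse = ", "))
  unname(.atomic_weight[idx])
}
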