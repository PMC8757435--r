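## Pinned per-element reference data (H through Kr).
##
## Sources of the numerical values, frozen here so that models and
## electrostatics are reproducible independently of any external table:
##   - atomic numbers and masses (amu): IUPAC standard atomic weights;
##   - Pauling electronegativities;
##   - covalent radii (Angstrom): Cordero et al. single-bond radii, used as
##     the Gaussian charge-smearing widths of the charge-equilibration model.

.element_data <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
           "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
           "Ga", "Ge", "As", "Se", "Br", "Kr")
  z <- seq_along(sym)
  mass <- c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
            18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
            35.45, 39.948, 39.098, 40.078, 44.956, 47.867, 50.942, 51.996,
            54.938, 55.845, 58.933, 58.693, 63.546, 65.38, 69.723, 72.630,
            74.922, 78.971, 79.904, 83.798)
  chi <- c(2.20, NA, 0.98, 1.57, 2.04, 2.55, 3.04, 3.44, 3.98, NA,
           0.93, 1.31, 1.61, 1.90, 2.19, 2.58, 3.16, NA, 0.82, 1.00,
           1.36, 1.54, 1.63, 1.66, 1.55, 1.83, 1.88, 1.91, 1.90, 1.65,
           1.81, 2.01, 2.18, 2.55, 2.96, 3.00)
  rcov <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
            1.70, 1.60, 1.53, 1.39, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22,
            1.22, 1.20, 1.19, 1.20, 1.20, 1.16)
  data.frame(symbol = sym, number = z, mass = mass,
             electronegativity = chi, covalent_radius = rcov,
             stringsAsFactors = FALSE)
})

.element_lookup <- function(symbols, column) {
  idx <- match(symbols, .element_data$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  out <- .element_data[[column]][idx]
  if (anyNA(out)) {
    stop("no tabulated ", column, " for element(s): ",
         paste(unique(symbols[is.na(out)]), collapse = ", "))
  }
  out
}

#' Look up pinned element properties
#'
#' Returns values from the internal element table (H--Kr) used throughout the
#' package: atomic masses for molecular dynamics, Pauling electronegativities
#' and atomic numbers for fixed descriptor weights, and covalent radii for the
#' Gaussian charge widths of the charge-equilibration model.
#'
#' @param symbols Character vector of element symbols (e.g. `c("N", "O")`).
#' @param property One of `"mass"` (amu), `"number"`, `"electronegativity"`
#'   (Pauling) or `"covalent_radius"` (Angstrom).
#' @return Numeric vector of the requested property, one entry per symbol.
#' @examples
#' element_property(c("C", "H", "N", "O"), "number")
#' @export
element_property <- function(symbols,
                             property = c("mass", "number",
                                          "electronegativity",
                                          "covalent_radius")) {
  property <- match.arg(property)
  .element_lookup(symbols, property)
}

## Physical constants (CODATA-derived), in the package's working units:
## lengths in Angstrom, energies in eV, time in fs, masses in amu, charge in e.
.kB_eV <- 8.617333262e-5       # Boltzmann constant, eV / K
.coulomb_k <- 14.399645        # e^2 / (4 pi eps_0), eV * Angstrom / e^2
.acc_unit <- 9.648533212e-3    # (eV / Angstrom / amu) expressed in Angstrom / fs^2
.D_unit <- 1e-5                # Angstrom^2 / fs expressed in m^2 / s
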