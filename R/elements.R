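## Element data and physical constants (units fixed repo-wide: A, eV, fs, K, amu).

# 1 eV / (amu * A^2 / fs^2): converts F/m [eV/(A*amu)] into acceleration [A/fs^2]
.EV_PER_AMU_A2_FS2 <- 103.642696562
.ACC_CONV <- 1 / .EV_PER_AMU_A2_FS2
.KB_EV <- 8.617333262e-5        # Boltzmann constant, eV/K
.COULOMB_EV_A <- 14.399645      # e^2/(4 pi eps0), eV*A

.ELEMENT_DATA <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
           "Fe", "Cu", "Zn", "Br", "Pd", "I")
  mass <- c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
            18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
            35.45, 39.948, 39.098, 40.078, 55.845, 63.546, 65.38, 79.904,
            106.42, 126.90)
  # covalent radii (Cordero 2008), A
  rcov <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
            1.32, 1.32, 1.22, 1.20, 1.39, 1.39)
  data.frame(symbol = sym, mass = mass, r_cov = rcov,
             stringsAsFactors = FALSE)
})

#' Atomic masses for element symbols
#'
#' @param species character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_masses <- function(species) {
  i <- match(species, .ELEMENT_DATA$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(i)]), collapse = ", "))
  }
  .ELEMENT_DATA$mass[i]
}

#' Covalent radii for element symbols
#'
#' @param species character vector of element symbols.
#' @return numeric vector of covalent radii in Angstrom.
#' @export
covalent_radii <- function(species) {
  i <- match(species, .ELEMENT_DATA$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(i)]), collapse = ", "))
  }
  .ELEMENT_DATA$r_cov[i]
}

is_element_symbol <- function(x) x %in% .ELEMENT_DATA$symbol
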