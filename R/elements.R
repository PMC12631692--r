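# Element property tables, atomic numbers 1-86.
#
# Electronegativities are Pauling-scale values; noble gases without a defined
# Pauling value carry NA and are reported with has_electronegativity = 0.
# Van der Waals radii follow Bondi-style compilations (2.00 A where no
# measured value is tabulated), covalent radii follow Cordero et al.-style
# single-bond compilations, masses are standard atomic weights.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn")

.element_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.811, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.086, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 98.0, 101.07, 102.906, 106.42, 107.868, 112.414, 114.818, 118.710,
  121.760, 127.60, 126.904, 131.293, 132.905, 137.327, 138.905, 140.116, 140.908, 144.242,
  145.0, 150.36, 151.964, 157.25, 158.925, 162.500, 164.930, 167.259, 168.934, 173.045,
  174.967, 178.49, 180.948, 183.84, 186.207, 190.23, 192.217, 195.084, 196.967, 200.592,
  204.38, 207.2, 208.980, 209.0, 210.0, 222.0)

.element_electronegativity <- c(
  2.20, NA, 0.98, 1.57, 2.04, 2.55, 3.04, 3.44, 3.98, NA,
  0.93, 1.31, 1.61, 1.90, 2.19, 2.58, 3.16, NA, 0.82, 1.00,
  1.36, 1.54, 1.63, 1.66, 1.55, 1.83, 1.88, 1.91, 1.90, 1.65,
  1.81, 2.01, 2.18, 2.55, 2.96, 3.00, 0.82, 0.95, 1.22, 1.33,
  1.60, 2.16, 1.90, 2.20, 2.28, 2.20, 1.93, 1.69, 1.78, 1.96,
  2.05, 2.10, 2.66, 2.60, 0.79, 0.89, 1.10, 1.12, 1.13, 1.14,
  1.13, 1.17, 1.20, 1.20, 1.20, 1.22, 1.23, 1.24, 1.25, 1.10,
  1.27, 1.30, 1.50, 2.36, 1.90, 2.20, 2.20, 2.28, 2.54, 2.00,
  1.62, 2.33, 2.02, 2.00, 2.20, NA)

.element_vdw_radius <- c(
  1.20, 1.40, 1.82, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
  2.27, 1.73, 1.84, 2.10, 1.80, 1.80, 1.75, 1.88, 2.75, 2.31,
  2.11, 2.00, 2.00, 2.00, 2.00, 2.00, 2.00, 1.63, 1.40, 1.39,
  1.87, 2.11, 1.85, 1.90, 1.85, 2.02, 3.03, 2.49, 2.00, 2.00,
  2.00, 2.00, 2.00, 2.00, 2.00, 1.63, 1.72, 1.58, 1.93, 2.17,
  2.06, 2.06, 1.98, 2.16, 3.43, 2.68, 2.00, 2.00, 2.00, 2.00,
  2.00, 2.00, 2.00, 2.00, 2.00, 2.00, 2.00, 2.00, 2.00, 2.00,
  2.00, 2.00, 2.00, 2.00, 2.00, 2.00, 2.00, 1.75, 1.66, 1.55,
  1.96, 2.02, 2.07, 1.97, 2.02, 2.20)

.element_covalent_radius <- c(
  0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
  1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
  1.70, 1.60, 1.53, 1.39, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22,
  1.22, 1.20, 1.19, 1.20, 1.20, 1.16, 2.20, 1.95, 1.90, 1.75,
  1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44, 1.42, 1.39,
  1.39, 1.38, 1.39, 1.40, 2.44, 2.15, 2.07, 2.04, 2.03, 2.01,
  1.99, 1.98, 1.98, 1.96, 1.94, 1.92, 1.92, 1.89, 1.90, 1.87,
  1.87, 1.75, 1.70, 1.62, 1.51, 1.44, 1.41, 1.36, 1.36, 1.32,
  1.45, 1.46, 1.48, 1.40, 1.50, 1.50)

# Usual valences of the SMILES organic subset, used only to infer radical
# electrons on bracket atoms (non-bracket atoms carry no radicals by the
# SMILES implicit-hydrogen convention).
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)

atomic_number_of <- function(symbol) {
  idx <- match(symbol, .element_symbols)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    rlang::abort(paste0("unknown element symbol(s): ",
                        paste(bad, collapse = ", ")),
                 class = "molgat_parse_error")
  }
  idx
}

element_mass <- function(z) .element_masses[z]

element_electronegativity <- function(z) .element_electronegativity[z]

element_vdw_radius <- function(z) .element_vdw_radius[z]

element_covalent_radius <- function(z) .element_covalent_radius[z]
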