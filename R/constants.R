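# Physical reference tables. Values are pinned so that every geometry and
# scattering result is reproducible without external parameter files.

# Average isotopic atomic masses (Da).
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38
)

# Atomic numbers, used as constant per-element scattering weights.
.atomic_numbers <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34, F = 9,
  CL = 17, BR = 35, I = 53, NA. = 11, MG = 12, K = 19, CA = 20, MN = 25,
  FE = 26, CO = 27, NI = 28, CU = 29, ZN = 30
)

# Bondi-type van der Waals radii (Angstrom) for surface-area calculations.
.vdw_radii <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27,
  MG = 1.73, K = 2.75, CA = 2.31, MN = 2.05, FE = 2.05, CO = 2.00,
  NI = 1.63, CU = 1.40, ZN = 1.39
)

# Reference maximum accessible surface areas per residue type (Angstrom^2),
# theoretical Gly-X-Gly values of Tien et al. (2013), backbone + side chain
# combined.  Used for relative (%) accessibility.
.max_asa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
  GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)

.lookup_element <- function(elements, table, what) {
  key <- toupper(trimws(elements))
  key[key == "NA"] <- "NA."
  val <- table[key]
  if (anyNA(val)) {
    bad <- unique(elements[is.na(val)])
    stop(sprintf("unknown element(s) for %s lookup: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  unname(val)
}

atomic_masses <- function(elements) {
  .lookup_element(elements, .atomic_masses, "atomic mass")
}

vdw_radii <- function(elements) {
  .lookup_element(elements, .vdw_radii, "van der Waals radius")
}

atomic_numbers <- function(elements) {
  .lookup_element(elements, .atomic_numbers, "atomic number")
}
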