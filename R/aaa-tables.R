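# Embedded reference tables: amino-acid codes, AAindex property scales,
# van der Waals radii and per-residue maximum ASA reference values.

#' @keywords internal
AA3_TO_AA1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @keywords internal
AA1_TO_AA3 <- structure(names(AA3_TO_AA1), names = unname(AA3_TO_AA1))

#' Amino-acid property table (AAindex scales)
#'
#' Returns the six AAindex property scales used throughout the package as a
#' numeric matrix with one row per AAindex accession and one column per
#' one-letter amino-acid code. The scales are: ARGP820101 (hydrophobicity
#' index), FAUJ880108 (localized electrical effect), FAUJ880109 (number of
#' hydrogen-bond donors), FAUJ880103 (normalized van der Waals volume),
#' LEVM760101 (hydrophobic parameter) and ZIMJ680104 (isoelectric point).
#'
#' The first three of ARGP820101, FAUJ880109 and FAUJ880103 parameterise the
#' individual-residue and shell-environment descriptor blocks; all six are
#' available for region-level property comparisons.
#'
#' @return Numeric matrix, 6 rows (AAindex accessions) by 20 columns
#'   (one-letter amino-acid codes).
#' @examples
#' tab <- aaindex_table()
#' tab["ARGP820101", "W"]  # tryptophan hydrophobicity
#' @export
aaindex_table <- function() {
  aa <- unname(AA3_TO_AA1)
  tab <- rbind(
    ARGP820101 = c(ALA = 0.61, ARG = 0.60, ASN = 0.06, ASP = 0.46, CYS = 1.07,
                   GLN = 0.00, GLU = 0.47, GLY = 0.07, HIS = 0.61, ILE = 2.22,
                   LEU = 1.53, LYS = 1.15, MET = 1.18, PHE = 2.02, PRO = 1.95,
                   SER = 0.05, THR = 0.05, TRP = 2.65, TYR = 1.88, VAL = 1.32),
    FAUJ880108 = c(ALA = -0.01, ARG = 0.04, ASN = 0.06, ASP = 0.15, CYS = 0.12,
                   GLN = 0.05, GLU = 0.07, GLY = 0.00, HIS = 0.08, ILE = -0.01,
                   LEU = -0.01, LYS = 0.00, MET = 0.04, PHE = 0.03, PRO = 0.00,
                   SER = 0.11, THR = 0.04, TRP = 0.00, TYR = 0.03, VAL = 0.01),
    FAUJ880109 = c(ALA = 0, ARG = 4, ASN = 2, ASP = 1, CYS = 0,
                   GLN = 2, GLU = 1, GLY = 0, HIS = 1, ILE = 0,
                   LEU = 0, LYS = 2, MET = 0, PHE = 0, PRO = 0,
                   SER = 1, THR = 1, TRP = 1, TYR = 1, VAL = 0),
    FAUJ880103 = c(ALA = 1.00, ARG = 6.13, ASN = 2.95, ASP = 2.78, CYS = 2.43,
                   GLN = 3.95, GLU = 3.78, GLY = 0.00, HIS = 4.66, ILE = 4.00,
                   LEU = 4.00, LYS = 4.77, MET = 4.43, PHE = 5.89, PRO = 2.72,
                   SER = 1.60, THR = 2.60, TRP = 8.08, TYR = 6.47, VAL = 3.00),
    LEVM760101 = c(ALA = 0.5, ARG = -3.0, ASN = -0.2, ASP = -2.5, CYS = 1.0,
                   GLN = -0.2, GLU = -2.5, GLY = 0.0, HIS = -0.5, ILE = 1.8,
                   LEU = 1.8, LYS = -3.0, MET = 1.3, PHE = 2.5, PRO = -1.4,
                   SER = -0.3, THR = 0.4, TRP = 3.4, TYR = 2.3, VAL = 1.5),
    ZIMJ680104 = c(ALA = 6.00, ARG = 10.76, ASN = 5.41, ASP = 2.77, CYS = 5.05,
                   GLN = 5.65, GLU = 3.22, GLY = 5.97, HIS = 7.59, ILE = 6.02,
                   LEU = 5.98, LYS = 9.74, MET = 5.74, PHE = 5.48, PRO = 6.30,
                   SER = 5.68, THR = 5.66, TRP = 5.89, TYR = 5.66, VAL = 5.96)
  )
  colnames(tab) <- aa
  tab
}

# The three scales entering the per-residue descriptor blocks, in block order.
#' @keywords internal
DESCRIPTOR_INDICES <- c("ARGP820101", "FAUJ880109", "FAUJ880103")

# van der Waals radii (Angstrom) by element; fallback handled in compute_asa.
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80)

#' Reference maximum accessible surface areas
#'
#' Theoretical per-residue maximum ASA values (Angstrom^2, Tien et al. 2013
#' theoretical set) used as denominators for relative ASA. Named by
#' three-letter residue code.
#'
#' @return Named numeric vector of length 20.
#' @export
max_asa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}
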