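#' The twenty canonical amino-acid one-letter codes
#'
#' Alphabetically ordered vector of the one-letter codes accepted by every
#' sequence-handling function in the package.
#'
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Standard average residue (i.e. water-free) masses in g/mol.
.AVG_RESIDUE_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)

# Lehninger-style pKa set for the ionizable groups of a free peptide.
.DEFAULT_PKA <- c(
  Nterm = 9.60, Cterm = 2.34,
  D = 3.65, E = 4.25, C = 8.33, Y = 10.07,
  H = 6.00, K = 10.53, R = 12.48
)

# Residue class assignment used for composition percentages.  Histidine and
# glycine are counted as hydrophobic; only D/E are acidic, only K/R basic,
# and N/Q/S/T neutral.
.DEFAULT_CLASS <- c(
  A = "hydrophobic", C = "hydrophobic", F = "hydrophobic", G = "hydrophobic",
  H = "hydrophobic", L = "hydrophobic", M = "hydrophobic", P = "hydrophobic",
  V = "hydrophobic", W = "hydrophobic", Y = "hydrophobic",
  I = "hydrophobic",
  D = "acidic", E = "acidic",
  K = "basic", R = "basic",
  N = "neutral", Q = "neutral", S = "neutral", T = "neutral"
)

#' Residue property tables
#'
#' Bundles the residue-level constants used by the physicochemical
#' calculators: average residue masses, the mass of one water molecule,
#' pKa values for the ionizable groups, and the residue class map used
#' for composition percentages.  All components are swappable so that a
#' different mass table or pKa set can be plugged in without touching the
#' calculators.
#'
#' @param avg_mass Named numeric vector of average residue masses (g/mol),
#'   one entry per canonical residue.
#' @param water_mass Mass of water in g/mol, added once per peptide chain.
#' @param pka Named numeric vector of pKa values.  Must contain `Nterm` and
#'   `Cterm` plus any ionizable side chains among `D`, `E`, `C`, `Y`
#'   (acidic) and `H`, `K`, `R` (basic).
#' @param class_of Named character vector mapping each of the 20 residues to
#'   one of `"hydrophobic"`, `"acidic"`, `"basic"`, `"neutral"`.
#'
#' @return An object of class `residue_tables`.
#' @examples
#' tab <- residue_tables()
#' tab$avg_mass[["G"]]
#' @export
residue_tables <- function(avg_mass = .AVG_RESIDUE_MASS,
                           water_mass = 18.015,
                           pka = .DEFAULT_PKA,
                           class_of = .DEFAULT_CLASS) {
  missing_mass <- setdiff(AA_ALPHABET20, names(avg_mass))
  if (length(missing_mass) > 0) {
    stop("avg_mass is missing residues: ", paste(missing_mass, collapse = ", "))
  }
  if (!all(c("Nterm", "Cterm") %in% names(pka))) {
    stop("pka must include 'Nterm' and 'Cterm'")
  }
  missing_class <- setdiff(AA_ALPHABET20, names(class_of))
  if (length(missing_class) > 0) {
    stop("class_of is missing residues: ",
         paste(missing_class, collapse = ", "))
  }
  ok <- class_of %in% c("hydrophobic", "acidic", "basic", "neutral")
  if (!all(ok)) {
    stop("class_of contains unknown classes: ",
         paste(unique(class_of[!ok]), collapse = ", "))
  }
  structure(
    list(avg_mass = avg_mass, water_mass = water_mass,
         pka = pka, class_of = class_of),
    class = "residue_tables"
  )
}

#' @export
print.residue_tables <- function(x, ...) {
  cat("<residue_tables>\n")
  cat("  water mass:", x$water_mass, "g/mol\n")
  cat("  pKa groups:", paste(names(x$pka), collapse = " "), "\n")
  cat("  classes   :",
      paste(names(table(x$class_of)), table(x$class_of),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}
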