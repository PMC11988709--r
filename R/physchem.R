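#' Average molecular weight of a peptide
#'
#' Sum of the standard average residue masses plus one water molecule for
#' the chain termini.  Vectorized over sequences.
#'
#' @param sequence Character vector of validated peptide sequences.
#' @param tables A [residue_tables()] object.
#' @return Numeric vector of masses in g/mol (full precision; round to two
#'   decimals for reporting).
#' @examples
#' molecular_weight("QCCDFMK")
#' @export
molecular_weight <- function(sequence, tables = residue_tables()) {
  vapply(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(tables$avg_mass[chars]) + tables$water_mass
  }, numeric(1), USE.NAMES = FALSE)
}

# Counts of each ionizable group present in one peptide, split into basic
# (protonated form carries +1) and acidic (deprotonated form carries -1).
.ionizable_groups <- function(sequence, tables) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pka <- tables$pka
  basic_res <- intersect(c("H", "K", "R"), names(pka))
  acidic_res <- intersect(c("D", "E", "C", "Y"), names(pka))
  basic <- c(pka[["Nterm"]],
             unlist(lapply(basic_res, function(r) {
               rep(pka[[r]], sum(chars == r))
             })))
  acidic <- c(pka[["Cterm"]],
              unlist(lapply(acidic_res, function(r) {
                rep(pka[[r]], sum(chars == r))
              })))
  list(basic = basic, acidic = acidic)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over all ionizable groups (both termini and
#' the D, E, C, Y, H, K, R side chains):
#' the positive contribution of each basic group is
#' \eqn{10^{pKa-pH} / (1 + 10^{pKa-pH})} and the negative contribution of
#' each acidic group is \eqn{10^{pH-pKa} / (1 + 10^{pH-pKa})}.
#' The result is strictly decreasing in pH.  Vectorized over `ph`.
#'
#' @param sequence A single validated peptide sequence.
#' @param ph Numeric vector of pH values in `[0, 14]`.
#' @param tables A [residue_tables()] object.
#' @return Numeric vector of net charges (elementary charge units).
#' @examples
#' net_charge("RHWLPR", ph = 7)
#' @export
net_charge <- function(sequence, ph = 7, tables = residue_tables()) {
  stopifnot(all(ph >= 0 & ph <= 14))
  g <- .ionizable_groups(sequence, tables)
  pos <- colSums(1 / (1 + 10 ^ outer(-g$basic, ph, "+")))
  neg <- colSums(1 / (1 + 10 ^ outer(g$acidic, ph, function(a, p) a - p)))
  pos - neg
}

#' Isoelectric point of a peptide
#'
#' The pH at which [net_charge()] is zero, located by bisection on
#' `[0, 14]`.  The root is unique because the charge curve is strictly
#' decreasing in pH.
#'
#' @param sequence Character vector of validated peptide sequences.
#' @param tables A [residue_tables()] object.
#' @param tol Bracket width at which bisection stops (pH units, default
#'   `1e-7`).  This pins the root itself, so the residual `|net_charge|`
#'   at the returned pH is far below `1e-4` even where the charge curve is
#'   nearly flat around its zero.
#' @return Numeric vector of pI values (pH units).
#' @examples
#' isoelectric_point("GG")  # (pKa N-term + pKa C-term) / 2
#' @export
isoelectric_point <- function(sequence, tables = residue_tables(),
                              tol = 1e-7) {
  vapply(sequence, function(s) {
    lo <- 0
    hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (net_charge(s, mid, tables) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Residue-class composition percentages
#'
#' Percentage of residues falling in each of the four classes
#' (hydrophobic, acidic, basic, neutral) defined by the residue tables:
#' hydrophobic A, C, F, G, H, I, L, M, P, V, W, Y; acidic D, E; basic
#' K, R; neutral N, Q, S, T.  Percentages are rounded to two decimals.
#'
#' @param sequence Character vector of validated peptide sequences.
#' @param tables A [residue_tables()] object.
#' @return A data frame with columns `pct_hydrophobic`, `pct_acidic`,
#'   `pct_basic`, `pct_neutral`, one row per sequence.
#' @examples
#' composition_percentages("PSPSLVWR")
#' @export
composition_percentages <- function(sequence, tables = residue_tables()) {
  out <- t(vapply(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    cls <- tables$class_of[chars]
    n <- length(chars)
    round(100 * c(
      hydrophobic = sum(cls == "hydrophobic"),
      acidic = sum(cls == "acidic"),
      basic = sum(cls == "basic"),
      neutral = sum(cls == "neutral")
    ) / n, 2)
  }, numeric(4)))
  rownames(out) <- NULL
  stats::setNames(as.data.frame(out),
                  c("pct_hydrophobic", "pct_acidic",
                    "pct_basic", "pct_neutral"))
}

#' Length class of a peptide
#'
#' Peptides are binned into short (2-5 residues), medium (6-10) and long
#' (more than 10) classes.
#'
#' @param sequence Character vector of validated peptide sequences, each of
#'   length at least 2.
#' @return Character vector with values `"short"`, `"medium"` or `"long"`.
#' @examples
#' length_class(c("AG", "RHWLPR", "EWGGGGCGGGGGVSSLR"))
#' @export
length_class <- function(sequence) {
  n <- nchar(sequence)
  if (any(n < 2)) stop("length classes are defined for peptides of >= 2 residues")
  ifelse(n <= 5, "short", ifelse(n <= 10, "medium", "long"))
}

#' Rule-based solubility verdict
#'
#' A composition-only heuristic in the style of web peptide calculators:
#' a peptide is called soluble if it is very short (< 5 residues) or if its
#' charged-residue content (counts of D, E, K, R, plus one for the charged
#' termini) reaches one fifth of its length.  The rule is deterministic and
#' invariant under sequence reversal.
#'
#' @param sequence Character vector of validated peptide sequences.
#' @param tables A [residue_tables()] object (reserved for rule overrides).
#' @return Logical vector: `TRUE` for predicted good water solubility.
#' @examples
#' solubility_estimate(c("DKDKDK", "LLLLLLLLLL"))
#' @export
solubility_estimate <- function(sequence, tables = residue_tables()) {
  vapply(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    charged <- sum(chars %in% c("D", "E", "K", "R")) + 1
    n < 5 || charged >= n / 5
  }, logical(1), USE.NAMES = FALSE)
}

#' Full physicochemical profile of a peptide pool
#'
#' Computes, per peptide, the descriptors used to characterize digestion-
#' resistant peptides: length and length class, average molecular weight,
#' isoelectric point, net charge at pH 7, residue-class composition
#' percentages and the solubility verdict.
#'
#' @param pool A `peptide_pool`.
#' @param tables A [residue_tables()] object.
#' @param ph pH at which the net charge is reported (default 7).
#' @return A data frame with one row per peptide: `id`, `sequence`,
#'   `length`, `length_class`, `mw`, `pi`, `net_charge`,
#'   `pct_hydrophobic`, `pct_acidic`, `pct_basic`, `pct_neutral`,
#'   `soluble`.  `mw` is rounded to 2 decimals, `pi` and `net_charge` to 2.
#' @export
physchem_profile <- function(pool, tables = residue_tables(), ph = 7) {
  stopifnot(inherits(pool, "peptide_pool"))
  s <- pool$sequence
  comp <- composition_percentages(s, tables)
  data.frame(
    id = pool$id,
    sequence = s,
    length = nchar(s),
    length_class = length_class(s),
    mw = round(molecular_weight(s, tables), 2),
    pi = round(isoelectric_point(s, tables), 2),
    net_charge = round(vapply(s, net_charge, numeric(1), ph = ph,
                              tables = tables, USE.NAMES = FALSE), 2),
    comp,
    soluble = solubility_estimate(s, tables),
    stringsAsFactors = FALSE
  )
}

#' Write a physicochemical profile report
#'
#' Tab-separated report with two-decimal formatting of the numeric columns.
#'
#' @param profile Output of [physchem_profile()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_physchem_tsv <- function(profile, path) {
  num <- vapply(profile, is.numeric, logical(1)) &
    !(names(profile) %in% c("length"))
  profile[num] <- lapply(profile[num], function(x) sprintf("%.2f", x))
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
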