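.CRITERIA_POSITIONS <- c("N1", "N2", "N3", "C1", "C2", "C3")

#' Terminal-position criteria set
#'
#' A criteria set maps each of the six terminal positions -- ultimate
#' (N1/C1), penultimate (N2/C2) and antepenultimate (N3/C3) residues from
#' the amino and carboxyl ends -- to a set of residues considered
#' favourable for alpha-amylase inhibition at that position.  Positions
#' absent from the set are simply not evaluated.
#'
#' @param rules Named list; names are among `N1`, `N2`, `N3`, `C1`, `C2`,
#'   `C3` and each element is a character vector (or single string) of
#'   allowed residue letters.
#' @param name Label for the criteria set.
#' @return An object of class `criteria_set`.
#' @examples
#' criteria_set(list(N1 = "RK", C1 = "RK"), name = "basic-termini")
#' @export
criteria_set <- function(rules, name = "criteria") {
  if (length(rules) == 0) {
    return(structure(list(rules = list(), name = name),
                     class = "criteria_set"))
  }
  bad <- setdiff(names(rules), .CRITERIA_POSITIONS)
  if (length(bad) > 0) {
    stop("unknown criteria positions: ", paste(bad, collapse = ", "))
  }
  rules <- lapply(rules, function(r) {
    r <- unique(toupper(unlist(strsplit(paste(r, collapse = ""), "",
                                        fixed = TRUE))))
    if (length(r) == 0) stop("each rule needs at least one residue")
    unknown <- setdiff(r, AA_ALPHABET20)
    if (length(unknown) > 0) {
      stop("non-canonical residues in rule: ",
           paste(unknown, collapse = ", "))
    }
    r
  })
  structure(list(rules = rules, name = name), class = "criteria_set")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat(sprintf("<criteria_set '%s'> %d rule(s)\n", x$name, length(x$rules)))
  for (pos in names(x$rules)) {
    cat(sprintf("  %s: %s\n", pos, paste(x$rules[[pos]], collapse = "")))
  }
  invisible(x)
}

#' Default terminal criteria for alpha-amylase inhibitor screening
#'
#' A demonstration criteria set capturing the terminal preferences commonly
#' described for alpha-amylase inhibitory peptides: basic residues (R/K) at
#' both ultimate positions, aromatic residues at N2, hydrophobic at N3,
#' His/Pro at C2, and bulky hydrophobics (W/L/F) at C3.  It is an
#' approximation intended for demonstration and simulation; real screens
#' should load a curated criteria set via [read_criteria_yaml()].
#'
#' @return A `criteria_set`.
#' @export
default_criteria_set <- function() {
  criteria_set(list(
    N1 = "RK",
    N2 = "FWY",
    N3 = "AVLIMFWPC",
    C1 = "RK",
    C2 = "HP",
    C3 = "WLF"
  ), name = "amylase-default")
}

#' Read a criteria set from a YAML file
#'
#' The file maps positions to residue strings, e.g. `N1: RK`.
#'
#' @param path YAML file path.
#' @param name Criteria-set label; defaults to the file name.
#' @return A `criteria_set`.
#' @export
read_criteria_yaml <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  criteria_set(yaml::read_yaml(path), name = name)
}

# Residue index of each defined terminal position for a given length, or
# NA when the position does not exist (length < 3 has no N3/C3 etc.).
.position_index <- function(pos, n) {
  idx <- switch(pos,
                N1 = 1, N2 = 2, N3 = 3,
                C1 = n, C2 = n - 1, C3 = n - 2)
  if (idx < 1 || idx > n) NA_integer_ else as.integer(idx)
}

#' Count terminal criteria met by a peptide
#'
#' Each rule is evaluated independently at its own index (N1 = first
#' residue, C1 = last, N2/C2 one inward, N3/C3 two inward).  For short
#' peptides the same residue may sit at two positions (e.g. N3 and C2 in a
#' 4-mer) and then counts once per rule it satisfies; rules whose position
#' does not exist are skipped.
#'
#' @param sequence Character vector of validated peptide sequences.
#' @param criteria A `criteria_set`.
#' @return Integer vector: number of criteria met per peptide, bounded by
#'   the number of rules.
#' @examples
#' criteria_met("RHWLPR", default_criteria_set())
#' @export
criteria_met <- function(sequence, criteria) {
  stopifnot(inherits(criteria, "criteria_set"))
  vapply(sequence, function(s) {
    n <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hits <- 0L
    for (pos in names(criteria$rules)) {
      idx <- .position_index(pos, n)
      if (!is.na(idx) && chars[idx] %in% criteria$rules[[pos]]) {
        hits <- hits + 1L
      }
    }
    hits
  }, integer(1), USE.NAMES = FALSE)
}

.CRITERIA_BINS <- c("zero", "one", "two", "three", "four_plus")

# Clamp criteria counts into the reported bins 0 / 1 / 2 / 3 / >=4.
.bin_of <- function(k) {
  .CRITERIA_BINS[pmin(k, 4L) + 1L]
}

#' Screen a pool against a criteria set
#'
#' @param pool A `peptide_pool`.
#' @param criteria A `criteria_set`, by default [default_criteria_set()].
#' @return Data frame with one row per peptide: `id`, `sequence`,
#'   `length_class`, `criteria_met`, `bin` and the `candidate` flag
#'   (medium peptides meeting at least 3 criteria, long peptides meeting
#'   at least 4; short peptides are never candidates).
#' @export
screen_peptides <- function(pool, criteria = default_criteria_set()) {
  stopifnot(inherits(pool, "peptide_pool"))
  lc <- length_class(pool$sequence)
  k <- criteria_met(pool$sequence, criteria)
  data.frame(
    id = pool$id,
    sequence = pool$sequence,
    length_class = lc,
    criteria_met = k,
    bin = .bin_of(k),
    candidate = (lc == "medium" & k >= 3) | (lc == "long" & k >= 4),
    stringsAsFactors = FALSE
  )
}

#' Distribution of peptides over criteria-count bins
#'
#' Percentage of the pool meeting zero, one, two, three, or four-or-more
#' criteria; the five percentages sum to 100.
#'
#' @param pool A non-empty `peptide_pool`.
#' @param criteria A `criteria_set`.
#' @return Named numeric vector of percentages over
#'   `zero`/`one`/`two`/`three`/`four_plus`.
#' @export
bin_distribution <- function(pool, criteria = default_criteria_set()) {
  stopifnot(inherits(pool, "peptide_pool"))
  if (nrow(pool) == 0) stop("bin_distribution requires a non-empty pool")
  bins <- factor(.bin_of(criteria_met(pool$sequence, criteria)),
                 levels = .CRITERIA_BINS)
  out <- 100 * as.vector(table(bins)) / nrow(pool)
  names(out) <- .CRITERIA_BINS
  out
}

#' Select alpha-amylase inhibitor candidates
#'
#' Medium-length peptides (6-10 residues) meeting at least 3 criteria and
#' long peptides (> 10 residues) meeting at least 4 are retained; short
#' peptides are never selected.  Order-stable subset of the input pool.
#'
#' @param pool A `peptide_pool`.
#' @param criteria A `criteria_set`.
#' @return The selected `peptide_pool`.
#' @export
select_candidates <- function(pool, criteria = default_criteria_set()) {
  stopifnot(inherits(pool, "peptide_pool"))
  scr <- screen_peptides(pool, criteria)
  .as_pool(pool[scr$candidate, , drop = FALSE],
           paste0(pool_name(pool), "_candidates"))
}

#' Write a screen report to TSV
#'
#' @param screen Output of [screen_peptides()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
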