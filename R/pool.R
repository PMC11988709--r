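#' Validate a peptide sequence
#'
#' Upper-cases a raw sequence and checks that every character is one of the
#' 20 canonical amino-acid one-letter codes.  The first offending character
#' is reported with its position.
#'
#' @param raw A single non-empty character string.
#' @return The validated, upper-cased sequence (character scalar).
#' @examples
#' validate_sequence("rhwlpr")
#' @export
validate_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || nchar(raw) == 0) {
    stop("sequence must be a single non-empty string")
  }
  seq <- toupper(raw)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET20))
  if (length(bad) > 0) {
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 chars[bad[1]], bad[1], raw))
  }
  seq
}

.POOL_SOURCES <- c("SPC", "GD", "ID", "GD1", "GD2", "GD3",
                   "ID1", "ID2", "ID3", "SYNTHETIC")

#' Construct a peptide pool
#'
#' A peptide pool is a named, ordered collection of validated peptides.  It
#' is represented as a `data.frame` (class `peptide_pool`) with columns
#' `id`, `sequence`, `source` and `alc`, plus a `pool_name` attribute.
#' Sources follow the study's sample naming: the undigested protein
#' concentrate (`SPC`), gastric and intestinal digests (`GD`, `ID`) and
#' their ultrafiltration size fractions (`GD1`..`ID3`), or `SYNTHETIC`.
#'
#' @param sequences Character vector of peptide sequences (validated and
#'   upper-cased on construction).
#' @param name Pool name (e.g. `"ID"`).
#' @param source Source label, one of `SPC`, `GD`, `ID`, `GD1`-`GD3`,
#'   `ID1`-`ID3`, `SYNTHETIC`; recycled to the pool length.
#' @param alc Optional numeric vector of average local confidence (ALC)
#'   scores in `[0, 100]`; `NA` for unscored peptides.
#' @param id Optional record identifiers; defaults to `pep1`, `pep2`, ...
#' @return A `peptide_pool` data frame.
#' @examples
#' p <- peptide_pool(c("RHWLPR", "PSPSLVWR"), name = "demo", source = "ID",
#'                   alc = c(96, 91))
#' nrow(p)
#' @export
peptide_pool <- function(sequences, name = "pool", source = "SYNTHETIC",
                         alc = NA_real_, id = NULL) {
  sequences <- vapply(sequences, validate_sequence, character(1),
                      USE.NAMES = FALSE)
  n <- length(sequences)
  source <- rep_len(as.character(source), n)
  bad_src <- setdiff(unique(source), .POOL_SOURCES)
  if (length(bad_src) > 0 && n > 0) {
    stop("unknown source label(s): ", paste(bad_src, collapse = ", "))
  }
  alc <- rep_len(as.numeric(alc), n)
  if (any(!is.na(alc) & (alc < 0 | alc > 100))) {
    stop("ALC scores must lie in [0, 100]")
  }
  if (is.null(id)) id <- if (n > 0) paste0("pep", seq_len(n)) else character(0)
  out <- data.frame(id = as.character(id), sequence = sequences,
                    source = source, alc = alc,
                    stringsAsFactors = FALSE)
  attr(out, "pool_name") <- as.character(name)
  class(out) <- c("peptide_pool", "data.frame")
  out
}

#' @export
print.peptide_pool <- function(x, ...) {
  cat(sprintf("<peptide_pool '%s'> %d peptide(s)\n",
              pool_name(x), nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Pool name accessor
#' @param pool A `peptide_pool`.
#' @return The pool's name attribute.
#' @export
pool_name <- function(pool) {
  nm <- attr(pool, "pool_name")
  if (is.null(nm)) "pool" else nm
}

# Rebuild the class/attribute decoration after a data.frame subset.
.as_pool <- function(df, name) {
  rownames(df) <- NULL
  attr(df, "pool_name") <- name
  class(df) <- c("peptide_pool", "data.frame")
  df
}

#' Filter a pool by ALC confidence score
#'
#' Retains peptides whose de novo average local confidence (ALC) score is at
#' least `min_alc`; the boundary is inclusive.  Peptides without a score are
#' dropped by default, since the filter is meant for scored de novo output.
#'
#' @param pool A `peptide_pool`.
#' @param min_alc Minimum ALC score (percent), default 85.
#' @param keep_unscored If `TRUE`, peptides with `NA` ALC pass through.
#' @return The filtered pool, original order preserved.
#' @export
filter_by_alc <- function(pool, min_alc = 85, keep_unscored = FALSE) {
  stopifnot(inherits(pool, "peptide_pool"))
  keep <- !is.na(pool$alc) & pool$alc >= min_alc
  if (keep_unscored) keep <- keep | is.na(pool$alc)
  .as_pool(pool[keep, , drop = FALSE], pool_name(pool))
}

# Equality key used for deduplication / matching bookkeeping.  De novo
# sequencing cannot distinguish isoleucine from leucine, so merge_il folds
# I into L for comparison only; stored sequences are never rewritten.
.seq_key <- function(sequences, merge_il = FALSE) {
  if (merge_il) chartr("I", "L", sequences) else sequences
}

#' Deduplicate a peptide pool
#'
#' Keeps the first occurrence of each sequence.  With `merge_il = TRUE`,
#' isoleucine and leucine are treated as equivalent for equality testing
#' only (the retained sequence is stored unchanged); this reflects the
#' I/L mass degeneracy of de novo sequencing.
#'
#' @param pool A `peptide_pool`.
#' @param merge_il Treat I and L as the same residue for equality.
#' @return The deduplicated pool.
#' @export
deduplicate <- function(pool, merge_il = FALSE) {
  stopifnot(inherits(pool, "peptide_pool"))
  keep <- !duplicated(.seq_key(pool$sequence, merge_il))
  .as_pool(pool[keep, , drop = FALSE], pool_name(pool))
}

#' Read a peptide pool from FASTA
#'
#' Headers of the form `name|source|alc=NN.N` round-trip the record id,
#' source label and ALC score; a bare header is kept as the id with the
#' pool-level `source` default and no ALC.
#'
#' @param path FASTA file path.
#' @param name Pool name; defaults to the file name without extension.
#' @param source Fallback source label for headers that do not carry one.
#' @return A `peptide_pool`.
#' @export
read_pool_fasta <- function(path, name = NULL, source = "SYNTHETIC") {
  xs <- Biostrings::readAAStringSet(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  headers <- names(xs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  srcs <- vapply(parts, function(p) {
    if (length(p) >= 2 && p[2] %in% .POOL_SOURCES) p[2] else NA_character_
  }, character(1))
  alcs <- vapply(parts, function(p) {
    hit <- grep("^alc=", p, value = TRUE)
    if (length(hit) > 0) as.numeric(sub("^alc=", "", hit[1])) else NA_real_
  }, numeric(1))
  srcs[is.na(srcs)] <- source
  peptide_pool(as.character(xs), name = name, source = srcs,
               alc = alcs, id = ids)
}

#' Write a peptide pool to FASTA
#'
#' Emits one record per peptide with header `id|source|alc=NN.N` (the ALC
#' field is omitted for unscored peptides), so that
#' `read_pool_fasta(write_pool_fasta(pool))` restores sequences and
#' metadata exactly.
#'
#' @param pool A `peptide_pool`.
#' @param path Output file path.
#' @param width Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_pool_fasta <- function(pool, path, width = 60) {
  stopifnot(inherits(pool, "peptide_pool"))
  headers <- ifelse(is.na(pool$alc),
                    paste(pool$id, pool$source, sep = "|"),
                    paste0(pool$id, "|", pool$source, "|alc=",
                           formatC(pool$alc, format = "fg")))
  xs <- Biostrings::AAStringSet(pool$sequence)
  names(xs) <- headers
  Biostrings::writeXStringSet(xs, filepath = path, width = width)
  invisible(path)
}

#' Read a plain-text peptide list
#'
#' One sequence per line, optionally followed by a tab and an ALC score.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path Text file path.
#' @param name Pool name; defaults to the file name without extension.
#' @param source Source label applied to every peptide.
#' @return A `peptide_pool`.
#' @export
read_pool_text <- function(path, name = NULL, source = "SYNTHETIC") {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(peptide_pool(character(0), name = name, source = source))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  seqs <- vapply(parts, `[`, character(1), 1)
  alcs <- vapply(parts, function(p) {
    if (length(p) >= 2) suppressWarnings(as.numeric(p[2])) else NA_real_
  }, numeric(1))
  peptide_pool(seqs, name = name, source = source, alc = alcs)
}
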