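#' Amino-acid composition vector
#'
#' Residue counts over the 20-letter alphabet, the object on which the
#' cosine similarity between peptides is computed.  With `merge_il = TRUE`
#' isoleucine counts are folded into the leucine bin (19 effective
#' dimensions), reflecting the I/L degeneracy of de novo sequencing.
#'
#' @param sequence A single validated peptide sequence.
#' @param merge_il Fold I into the L bin.
#' @return Named integer vector of length 20; entries sum to the peptide
#'   length.
#' @examples
#' composition_vector("RHWLPR")
#' @export
composition_vector <- function(sequence, merge_il = FALSE) {
  composition_matrix(sequence, merge_il)[1, ]
}

#' Composition matrix of several sequences
#'
#' @param sequences Character vector of validated peptide sequences.
#' @param merge_il Fold I into the L bin.
#' @return Integer matrix, one row per sequence, 20 residue columns.
#' @export
composition_matrix <- function(sequences, merge_il = FALSE) {
  if (merge_il) sequences <- chartr("I", "L", sequences)
  m <- t(vapply(strsplit(sequences, "", fixed = TRUE), function(chars) {
    tabulate(match(chars, AA_ALPHABET20), nbins = 20L)
  }, integer(20)))
  colnames(m) <- AA_ALPHABET20
  rownames(m) <- NULL
  m
}

#' Cosine similarity between two composition vectors
#'
#' `dot(a, b) / (|a| |b|)`.  Because counts are non-negative the value lies
#' in `[0, 1]`; it equals 1 exactly when the compositions are proportional
#' (so a peptide and its double are indistinguishable to this measure, and
#' only the length-difference guard separates them).
#'
#' @param a,b Numeric vectors of residue counts (same length).
#' @return Similarity in `[0, 1]`.
#' @examples
#' cosine_similarity(composition_vector("AAK"), composition_vector("AAR"))
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Identify digestion-resistant peptides
#'
#' For every peptide in the intestinal-digest (query) pool, finds the best
#' reference in the undigested-concentrate pool under the study's rule:
#' amino-acid composition cosine similarity strictly greater than
#' `threshold`, with pairs whose sequence lengths differ by more than
#' `max_len_diff` residues discarded.  Each query yields one match record
#' (its best length-eligible reference); ties on similarity are broken by
#' smaller length difference, then reference pool order.  The resistant
#' pool collects the accepted queries, deduplicated and in query order.
#'
#' @param id_pool Query `peptide_pool` (intestinal digest), ideally already
#'   ALC-filtered and deduplicated.
#' @param spc_pool Reference `peptide_pool` (protein concentrate).
#' @param threshold Cosine similarity that must be strictly exceeded
#'   (default 0.95).
#' @param max_len_diff Maximum allowed absolute length difference in
#'   residues (default 8).
#' @param merge_il Fold I into L when counting residues.
#' @param audit If `TRUE`, `matches` additionally contains every passing
#'   (not just the best) pair per query.
#' @return A list with elements `matches` (data frame: `query`,
#'   `reference`, `similarity`, `length_diff`, `accepted`) and `resistant`
#'   (a `peptide_pool` of accepted queries).
#' @examples
#' spc <- peptide_pool(c("RHWLPR", "AAKAAR"), source = "SPC", name = "SPC")
#' id  <- peptide_pool(c("RHWLPR", "GGGGGG"), source = "ID", name = "ID")
#' find_resistant(id, spc)$resistant$sequence
#' @export
find_resistant <- function(id_pool, spc_pool, threshold = 0.95,
                           max_len_diff = 8, merge_il = FALSE,
                           audit = FALSE) {
  stopifnot(inherits(id_pool, "peptide_pool"),
            inherits(spc_pool, "peptide_pool"))
  if (nrow(id_pool) == 0 || nrow(spc_pool) == 0) {
    stop("find_resistant requires non-empty query and reference pools")
  }
  qseq <- id_pool$sequence
  rseq <- spc_pool$sequence
  qm <- composition_matrix(qseq, merge_il)
  rm_ <- composition_matrix(rseq, merge_il)
  # cosine of every query x reference pair in one matrix product
  qn <- qm / sqrt(rowSums(qm^2))
  rn <- rm_ / sqrt(rowSums(rm_^2))
  sim <- qn %*% t(rn)
  # proportional compositions have similarity exactly 1; absorb the
  # floating-point drift of the normalized matrix product
  sim[sim > 1 - 1e-12] <- 1
  sim[sim < 0] <- 0
  ldiff <- abs(outer(nchar(qseq), nchar(rseq), "-"))
  eligible <- ldiff <= max_len_diff

  rows <- lapply(seq_along(qseq), function(i) {
    el <- which(eligible[i, ])
    if (length(el) == 0) {
      return(data.frame(query = qseq[i], reference = NA_character_,
                        similarity = NA_real_, length_diff = NA_integer_,
                        accepted = FALSE, stringsAsFactors = FALSE))
    }
    s <- sim[i, el]
    ld <- ldiff[i, el]
    best <- el[order(-s, ld, el)[1]]
    rec <- data.frame(query = qseq[i], reference = rseq[best],
                      similarity = sim[i, best],
                      length_diff = ldiff[i, best],
                      accepted = sim[i, best] > threshold,
                      stringsAsFactors = FALSE)
    if (audit) {
      pass <- el[s > threshold]
      if (length(pass) > 1) {
        extra <- data.frame(query = qseq[i], reference = rseq[pass],
                            similarity = sim[i, pass],
                            length_diff = ldiff[i, pass],
                            accepted = TRUE, stringsAsFactors = FALSE)
        rec <- unique(rbind(rec, extra))
      }
    }
    rec
  })
  matches <- do.call(rbind, rows)
  rownames(matches) <- NULL

  best_per_query <- matches[!duplicated(matches$query), , drop = FALSE]
  acc <- best_per_query$accepted[match(qseq, best_per_query$query)]
  res <- .as_pool(id_pool[acc, , drop = FALSE], "resistant")
  res <- deduplicate(res, merge_il = merge_il)
  list(matches = matches, resistant = res, best = best_per_query)
}

#' Write the match table of [find_resistant()] to TSV
#'
#' @param matches The `matches` element returned by [find_resistant()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_match_tsv <- function(matches, path) {
  matches$similarity <- sprintf("%.4f", matches$similarity)
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a resistant-peptide pool as FASTA
#'
#' Deduplicates, then writes FASTA via [write_pool_fasta()]; the output
#' round-trips through [read_pool_fasta()] unchanged.
#'
#' @param pool A non-empty `peptide_pool`.
#' @param path Output FASTA path.
#' @param merge_il I/L equivalence for the deduplication step.
#' @return `path`, invisibly.
#' @export
export_resistant_fasta <- function(pool, path, merge_il = FALSE) {
  stopifnot(inherits(pool, "peptide_pool"))
  if (nrow(pool) == 0) stop("refusing to export an empty pool")
  write_pool_fasta(deduplicate(pool, merge_il), path)
}
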