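#' Protease cleavage rules
#'
#' Simplified specificity rules for the proteases of the two digestion
#' phases: pepsin cleaves C-terminal to F, L, W or Y; trypsin C-terminal
#' to K or R; chymotrypsin C-terminal to F, W or Y.  All three carry the
#' proline guard (no cleavage when the following residue is proline).
#'
#' @param enzyme One of `"pepsin"`, `"trypsin"`, `"chymotrypsin"`, or
#'   `"custom"` (then `residues` must be given).
#' @param residues Residues after which to cut, for `enzyme = "custom"`.
#' @param proline_guard Suppress cleavage before proline (default `TRUE`).
#' @return An object of class `cleavage_rules`.
#' @examples
#' cleavage_rules("trypsin")
#' @export
cleavage_rules <- function(enzyme = c("pepsin", "trypsin", "chymotrypsin",
                                      "custom"),
                           residues = NULL, proline_guard = TRUE) {
  enzyme <- match.arg(enzyme)
  if (enzyme == "custom") {
    if (is.null(residues)) stop("custom rules need 'residues'")
  } else {
    residues <- switch(enzyme,
                       pepsin = c("F", "L", "W", "Y"),
                       trypsin = c("K", "R"),
                       chymotrypsin = c("F", "W", "Y"))
  }
  residues <- unique(toupper(residues))
  bad <- setdiff(residues, AA_ALPHABET20)
  if (length(bad) > 0) stop("non-canonical rule residues: ",
                            paste(bad, collapse = ", "))
  structure(list(enzyme = enzyme, residues = residues,
                 proline_guard = proline_guard),
            class = "cleavage_rules")
}

#' In-silico cleavage of a protein
#'
#' Cuts C-terminal to the rule residues (respecting the proline guard);
#' each eligible site is independently skipped with probability
#' `missed_cleavage_prob`, emulating incomplete digestion.  The returned
#' fragments tile the parent exactly, with 0-based half-open coordinates.
#'
#' @param protein A validated protein/peptide sequence.
#' @param rules A [cleavage_rules()] object.
#' @param missed_cleavage_prob Probability that an eligible site is left
#'   uncut (default 0).
#' @param seed Optional integer; when given, the site-skipping draws are
#'   seeded so the digest is reproducible on its own.
#' @return Data frame with columns `fragment`, `start`, `end` (0-based,
#'   half-open).
#' @examples
#' cleave("AAFAAA", cleavage_rules("pepsin"))
#' @export
cleave <- function(protein, rules, missed_cleavage_prob = 0, seed = NULL) {
  stopifnot(inherits(rules, "cleavage_rules"))
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sites <- which(chars %in% rules$residues)
  sites <- sites[sites < n]                       # no cut after last residue
  if (rules$proline_guard) {
    sites <- sites[chars[sites + 1] != "P"]
  }
  if (missed_cleavage_prob > 0 && length(sites) > 0) {
    sites <- sites[stats::runif(length(sites)) >= missed_cleavage_prob]
  }
  bounds <- c(0L, sites, n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  data.frame(
    fragment = substring(protein, starts + 1, ends),
    start = starts, end = ends,
    stringsAsFactors = FALSE
  )
}

# Sequentially digest fragments with a list of cleavage_rules, keeping
# coordinates relative to the original parent.
.digest_multi <- function(frags, rule_list, missed_cleavage_prob) {
  for (rules in rule_list) {
    pieces <- lapply(seq_len(nrow(frags)), function(i) {
      sub <- cleave(frags$fragment[i], rules, missed_cleavage_prob)
      sub$start <- sub$start + frags$start[i]
      sub$end <- sub$end + frags$start[i]
      sub
    })
    frags <- do.call(rbind, pieces)
  }
  frags
}

#' Generate random parent proteins
#'
#' Seeded random sequences over the 20-letter alphabet.  The default
#' residue distribution is uniform; `residue_weights = "gly_rich"` uses a
#' glycine/serine-weighted distribution mimicking the low-complexity,
#' glycine-rich peptides typical of seed-storage protein digests.
#'
#' @param n Number of proteins.
#' @param length_range Integer vector `c(min, max)` of protein lengths.
#' @param seed Integer seed.
#' @param residue_weights `"uniform"`, `"gly_rich"`, or a named numeric
#'   vector of sampling weights over the 20 residues.
#' @return Character vector of `n` protein sequences.
#' @examples
#' generate_parent_proteins(2, c(50, 60), seed = 1)
#' @export
generate_parent_proteins <- function(n, length_range = c(200, 400),
                                     seed = 1, residue_weights = "uniform") {
  stopifnot(n >= 1, length(length_range) == 2,
            length_range[1] >= 2, length_range[2] >= length_range[1])
  if (is.character(residue_weights)) {
    residue_weights <- switch(
      match.arg(residue_weights, c("uniform", "gly_rich")),
      uniform = stats::setNames(rep(1, 20), AA_ALPHABET20),
      gly_rich = {
        w <- stats::setNames(rep(1, 20), AA_ALPHABET20)
        w["G"] <- 5
        w["S"] <- 3
        w
      })
  }
  w <- residue_weights[AA_ALPHABET20]
  if (anyNA(w)) stop("residue_weights must cover all 20 residues")
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(AA_ALPHABET20, L, replace = TRUE, prob = w), collapse = "")
  }, character(1))
}

#' Digestion specification
#'
#' Parameters of the two-phase in-silico digestion: the ordered enzyme
#' rule sets of the gastric phase (pepsin) and the intestinal phase
#' (trypsin and chymotrypsin standing in for pancreatin), the missed-
#' cleavage probability, the observable peptide length window and the
#' seed governing the structural randomness.
#'
#' @param gastric List of [cleavage_rules()] for the gastric phase.
#' @param intestinal List of [cleavage_rules()] for the intestinal phase.
#' @param missed_cleavage_prob Per-site probability of a missed cleavage.
#' @param min_len,max_len Length window of observable peptides (residues).
#' @param seed Integer seed.
#' @return An object of class `digestion_spec`.
#' @export
digestion_spec <- function(gastric = list(cleavage_rules("pepsin")),
                           intestinal = list(cleavage_rules("trypsin"),
                                             cleavage_rules("chymotrypsin")),
                           missed_cleavage_prob = 0.1,
                           min_len = 5, max_len = 30, seed = 1) {
  stopifnot(min_len >= 2, max_len >= min_len,
            missed_cleavage_prob >= 0, missed_cleavage_prob <= 1)
  structure(list(gastric = gastric, intestinal = intestinal,
                 missed_cleavage_prob = missed_cleavage_prob,
                 min_len = min_len, max_len = max_len,
                 seed = as.integer(seed)),
            class = "digestion_spec")
}

#' Sequencing-noise specification
#'
#' Parameters of the de novo sequencing-noise model: per-residue
#' substitution rate, per-I/L swap rate, terminal truncation probability,
#' and the ALC confidence model.  Observations carrying at least one
#' sequencing error draw their ALC from a distribution shifted down by
#' `alc_error_penalty`, so that the standard ALC >= 85 filter removes most
#' miscalled sequences, as it does for real de novo output.
#'
#' @param substitution_rate Per-residue probability of a miscalled residue.
#' @param il_swap_rate Per-I/L-residue probability of an I/L swap.
#' @param truncation_prob Per-observation probability of losing one
#'   terminal residue.
#' @param alc_mean,alc_sd Mean and SD (percent) of the ALC score of
#'   error-free observations; scores are clipped to `[0, 100]`.
#' @param alc_error_penalty Downward shift of the ALC mean for erroneous
#'   observations.
#' @param seed Integer seed for the noise phase.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(substitution_rate = 0.02, il_swap_rate = 0.01,
                       truncation_prob = 0.01, alc_mean = 92, alc_sd = 5,
                       alc_error_penalty = 20, seed = 1) {
  rates <- c(substitution_rate, il_swap_rate, truncation_prob)
  stopifnot(all(rates >= 0 & rates <= 1), alc_sd >= 0)
  structure(list(substitution_rate = substitution_rate,
                 il_swap_rate = il_swap_rate,
                 truncation_prob = truncation_prob,
                 alc_mean = alc_mean, alc_sd = alc_sd,
                 alc_error_penalty = alc_error_penalty,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# One noisy observation of a sequence.  Returns the observed sequence and
# whether any error was introduced.
.observe <- function(sequence, nspec) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  err <- FALSE
  if (nspec$substitution_rate > 0) {
    hit <- stats::runif(length(chars)) < nspec$substitution_rate
    if (any(hit)) {
      err <- TRUE
      chars[hit] <- vapply(chars[hit], function(orig) {
        sample(setdiff(AA_ALPHABET20, orig), 1)
      }, character(1))
    }
  }
  if (nspec$il_swap_rate > 0) {
    il <- which(chars %in% c("I", "L"))
    if (length(il) > 0) {
      hit <- il[stats::runif(length(il)) < nspec$il_swap_rate]
      if (length(hit) > 0) {
        err <- TRUE
        chars[hit] <- ifelse(chars[hit] == "I", "L", "I")
      }
    }
  }
  if (nspec$truncation_prob > 0 && length(chars) > 2 &&
      stats::runif(1) < nspec$truncation_prob) {
    err <- TRUE
    if (stats::runif(1) < 0.5) chars <- chars[-1] else
      chars <- chars[-length(chars)]
  }
  list(sequence = paste(chars, collapse = ""), error = err)
}

# Observe each sequence n_obs times with noise and ALC scores.
.observe_pool <- function(sequences, nspec, n_obs, name, source) {
  if (length(sequences) == 0) {
    return(peptide_pool(character(0), name = name, source = source))
  }
  obs <- lapply(rep(sequences, each = n_obs), .observe, nspec = nspec)
  seqs <- vapply(obs, `[[`, character(1), "sequence")
  errs <- vapply(obs, `[[`, logical(1), "error")
  alc_mu <- ifelse(errs, nspec$alc_mean - nspec$alc_error_penalty,
                   nspec$alc_mean)
  alc <- pmin(100, pmax(0, stats::rnorm(length(seqs), alc_mu, nspec$alc_sd)))
  peptide_pool(seqs, name = name, source = source, alc = alc)
}

# TRUE for each query with at least one reference whose composition
# cosine exceeds `thr` within a length difference of `ld` residues.
.near_match <- function(queries, refs, thr, ld) {
  if (length(queries) == 0 || length(refs) == 0) {
    return(logical(length(queries)))
  }
  qm <- composition_matrix(queries)
  rm_ <- composition_matrix(refs)
  sim <- (qm / sqrt(rowSums(qm^2))) %*% t(rm_ / sqrt(rowSums(rm_^2)))
  ok <- abs(outer(nchar(queries), nchar(refs), "-")) <= ld
  rowSums(sim > thr & ok) > 0
}

# Sample random substrings of the parents: one row per substring with
# parent index and 0-based half-open coordinates.
.sample_substrings <- function(proteins, n, length_range) {
  parent <- sample(seq_along(proteins), n, replace = TRUE)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  lens <- pmin(lens, nchar(proteins)[parent])
  start0 <- vapply(seq_len(n), function(i) {
    sample.int(nchar(proteins[parent[i]]) - lens[i] + 1L, 1L) - 1L
  }, integer(1))
  data.frame(
    sequence = substring(proteins[parent], start0 + 1, start0 + lens),
    parent = parent, start = start0, end = start0 + lens,
    stringsAsFactors = FALSE
  )
}

#' Simulate an SGID experiment with ground truth
#'
#' Emulates the study's input data: de novo peptide pools from the
#' undigested protein concentrate (SPC), the gastric digest (GD) and the
#' intestinal digest (ID), derived from a common set of parent proteins.
#' A planted subset of parent substrings represents digestion-resistant
#' peptides: it appears intact in the SPC pool and passes through both
#' digestion phases uncleaved into the ID pool.  All other ID peptides are
#' genuine enzymatic fragments (pepsin, then trypsin + chymotrypsin), and
#' the non-planted SPC peptides are longer random parent substrings,
#' filtered so they never exactly coincide with an ID sequence -- with
#' zero noise the SPC/ID sequence intersection therefore equals the
#' planted set exactly.  Every underlying peptide is observed `n_obs`
#' times (mirroring replicate digests) through the sequencing-noise model,
#' which assigns each observation an ALC confidence score.
#'
#' @param proteins Character vector of parent proteins, e.g. from
#'   [generate_parent_proteins()].
#' @param dspec A [digestion_spec()].
#' @param nspec A [noise_spec()].
#' @param n_resistant Number of planted resistant peptides (default 200).
#' @param n_spc_extra Number of non-resistant SPC peptides (default 300).
#' @param n_obs Observations per underlying peptide (default 3).
#' @param planted_length Length range of planted resistant peptides.
#' @param spc_extra_length Length range of non-resistant SPC peptides;
#'   longer than digest fragments, as undigested material skews long.
#' @return A list with `pools` (list of `peptide_pool`s `SPC`, `GD`, `ID`,
#'   raw: not yet ALC-filtered or deduplicated) and `truth` (list with
#'   `resistant_set`, the planted sequences, and `provenance`, a data
#'   frame of parent indices and 0-based half-open coordinates for every
#'   underlying peptide).
#' @examples
#' pr <- generate_parent_proteins(3, c(80, 120), seed = 7)
#' sim <- simulate_sgid(pr, digestion_spec(seed = 7), noise_spec(seed = 7),
#'                      n_resistant = 10, n_spc_extra = 15)
#' length(sim$truth$resistant_set)
#' @export
simulate_sgid <- function(proteins, dspec = digestion_spec(),
                          nspec = noise_spec(), n_resistant = 200,
                          n_spc_extra = 300, n_obs = 3,
                          planted_length = c(6, 15),
                          spc_extra_length = c(12, 30)) {
  stopifnot(inherits(dspec, "digestion_spec"), inherits(nspec, "noise_spec"),
            length(proteins) >= 1)
  in_range <- function(s) {
    nchar(s) >= dspec$min_len & nchar(s) <= dspec$max_len
  }

  ## structural phase -------------------------------------------------
  set.seed(dspec$seed)
  gd_frags <- do.call(rbind, lapply(seq_along(proteins), function(i) {
    fr <- .digest_multi(data.frame(fragment = proteins[i], start = 0L,
                                   end = nchar(proteins[i]),
                                   stringsAsFactors = FALSE),
                        dspec$gastric, dspec$missed_cleavage_prob)
    fr$parent <- i
    fr
  }))
  id_frags <- do.call(rbind, lapply(seq_along(proteins), function(i) {
    fr <- gd_frags[gd_frags$parent == i,
                   c("fragment", "start", "end"), drop = FALSE]
    fr <- .digest_multi(fr, dspec$intestinal, dspec$missed_cleavage_prob)
    fr$parent <- i
    fr
  }))

  gd_obs_seq <- gd_frags$fragment[in_range(gd_frags$fragment)]
  id_obs_seq <- id_frags$fragment[in_range(id_frags$fragment)]

  # Ground-truth separation guard: a planted peptide must not be a
  # near-copy (match rule plus a small margin) of a genuine digest
  # fragment, and a non-resistant SPC peptide must not be a near-copy of
  # any ID-pool sequence; otherwise the negatives would be ambiguous and
  # the planted labels meaningless.  Candidates violating the guard are
  # rejected during sampling.
  guard_thr <- 0.93
  guard_ld <- 10
  planted <- .sample_substrings(proteins, 2L * n_resistant,
                                c(max(planted_length[1], dspec$min_len),
                                  min(planted_length[2], dspec$max_len)))
  planted <- planted[!duplicated(planted$sequence), , drop = FALSE]
  shadow <- .near_match(planted$sequence, unique(id_obs_seq),
                        guard_thr, guard_ld) &
    !(planted$sequence %in% id_obs_seq)
  planted <- planted[!shadow, , drop = FALSE]
  planted <- utils::head(planted, n_resistant)

  id_all <- unique(c(id_obs_seq, planted$sequence))
  extras <- .sample_substrings(proteins, n_spc_extra, spc_extra_length)
  drop <- extras$sequence %in% id_all |
    extras$sequence %in% planted$sequence |
    duplicated(extras$sequence) |
    .near_match(extras$sequence, id_all, guard_thr, guard_ld)
  extras <- extras[!drop, , drop = FALSE]

  spc_seq <- c(planted$sequence, extras$sequence)
  gd_seq <- c(planted$sequence, gd_obs_seq)
  id_seq <- c(planted$sequence, id_obs_seq)

  ## observation / noise phase ----------------------------------------
  set.seed(nspec$seed)
  pools <- list(
    SPC = .observe_pool(spc_seq, nspec, n_obs, "SPC", "SPC"),
    GD = .observe_pool(gd_seq, nspec, n_obs, "GD", "GD"),
    ID = .observe_pool(id_seq, nspec, n_obs, "ID", "ID")
  )

  provenance <- rbind(
    cbind(planted[, c("sequence", "parent", "start", "end")],
          origin = "planted"),
    cbind(extras[, c("sequence", "parent", "start", "end")],
          origin = "spc_extra"),
    data.frame(sequence = gd_frags$fragment, parent = gd_frags$parent,
               start = gd_frags$start, end = gd_frags$end,
               origin = "gastric_fragment", stringsAsFactors = FALSE),
    data.frame(sequence = id_frags$fragment, parent = id_frags$parent,
               start = id_frags$start, end = id_frags$end,
               origin = "intestinal_fragment", stringsAsFactors = FALSE)
  )
  rownames(provenance) <- NULL

  list(pools = pools,
       truth = list(resistant_set = planted$sequence,
                    provenance = provenance))
}

#' Split a pool into molecular-weight fractions
#'
#' Emulates ultrafiltration with sharp molecular-weight cutoffs: peptides
#' are assigned to half-open bins `[0, c1)`, `[c1, c2)`, ..., `[ck, Inf)`.
#' The default cutoffs `c(3000, 10000)` reproduce the study's <3 kDa,
#' 3-10 kDa and >10 kDa fractions.
#'
#' @param pool A `peptide_pool`.
#' @param cutoffs Ascending numeric cutoffs in g/mol.
#' @param tables A [residue_tables()] object for the mass computation.
#' @return Named list of `peptide_pool`s, one per bin; their union is the
#'   input pool and the bins are disjoint.
#' @export
fractionate_by_size <- function(pool, cutoffs = c(3000, 10000),
                                tables = residue_tables()) {
  stopifnot(inherits(pool, "peptide_pool"),
            length(cutoffs) >= 1, !is.unsorted(cutoffs, strictly = TRUE))
  labels <- c(paste0("<", cutoffs[1]),
              if (length(cutoffs) > 1) {
                paste0("[", cutoffs[-length(cutoffs)], ",", cutoffs[-1], ")")
              },
              paste0(">=", cutoffs[length(cutoffs)]))
  if (nrow(pool) == 0) {
    out <- lapply(labels, function(lb) {
      .as_pool(pool[0, , drop = FALSE], paste(pool_name(pool), lb))
    })
    names(out) <- labels
    return(out)
  }
  mw <- molecular_weight(pool$sequence, tables)
  bin <- findInterval(mw, cutoffs) + 1L
  out <- lapply(seq_along(labels), function(b) {
    .as_pool(pool[bin == b, , drop = FALSE],
             paste(pool_name(pool), labels[b]))
  })
  names(out) <- labels
  out
}
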