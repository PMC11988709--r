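#' Pipeline run configuration
#'
#' Collects every tunable parameter of the screening pipeline with the
#' study's defaults: ALC filter at 85, cosine similarity threshold 0.95
#' (strict), maximum length difference 8 residues, and the 2-5 / 6-10 /
#' >10 length classes implied by the screening rules.
#'
#' @param id_path,spc_path Optional FASTA paths for the query (intestinal
#'   digest) and reference (concentrate) pools; when `NULL`,
#'   [run_pipeline()] simulates pools instead.
#' @param out_dir Output directory for the report bundle.
#' @param min_alc ALC filter threshold (percent).
#' @param threshold Cosine similarity threshold (strictly exceeded).
#' @param max_len_diff Maximum length difference (residues).
#' @param merge_il Treat I and L as equivalent in dedup and matching.
#' @param criteria A `criteria_set` or path to a YAML criteria file;
#'   `NULL` uses [default_criteria_set()].
#' @param tables A [residue_tables()] object.
#' @param seed Integer seed used for simulation when no input pools are
#'   given.
#' @param sim Named list of overrides passed to [simulate_sgid()]
#'   (`n_proteins`, `n_resistant`, `n_spc_extra`, ...).
#' @return An object of class `run_config`.
#' @export
run_config <- function(id_path = NULL, spc_path = NULL, out_dir = "sgidpep_out",
                       min_alc = 85, threshold = 0.95, max_len_diff = 8,
                       merge_il = FALSE, criteria = NULL,
                       tables = residue_tables(), seed = 1, sim = list()) {
  if (is.character(criteria)) criteria <- read_criteria_yaml(criteria)
  if (is.null(criteria)) criteria <- default_criteria_set()
  structure(list(id_path = id_path, spc_path = spc_path, out_dir = out_dir,
                 min_alc = min_alc, threshold = threshold,
                 max_len_diff = max_len_diff, merge_il = merge_il,
                 criteria = criteria, tables = tables,
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

#' Length-class summary of one or more pools
#'
#' Per-pool counts of short (2-5), medium (6-10) and long (>10) peptides,
#' the histogram used to describe how digestion reshapes the peptide
#' population.
#'
#' @param pools A `peptide_pool` or a list of them.
#' @return Data frame with columns `pool`, `short`, `medium`, `long`,
#'   `total`.
#' @export
summarize_pools <- function(pools) {
  if (inherits(pools, "peptide_pool")) pools <- list(pools)
  rows <- lapply(pools, function(p) {
    lc <- if (nrow(p) > 0) length_class(p$sequence) else character(0)
    data.frame(pool = pool_name(p),
               short = sum(lc == "short"),
               medium = sum(lc == "medium"),
               long = sum(lc == "long"),
               total = nrow(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full screening pipeline
#'
#' Executes the study workflow end to end: load (or simulate) the SPC and
#' ID pools, apply the ALC filter and deduplication to each, identify
#' digestion-resistant peptides by composition cosine matching, screen the
#' resistant pool against the terminal criteria, profile its
#' physicochemical properties, and write the report bundle:
#' `resistant.fasta`, `matches.tsv`, `screen.tsv`, `physchem.tsv` and
#' `summary.yaml` (parameters, pool length-class histograms and the
#' criteria-bin distribution).  Runs are deterministic given the config.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the `resistant` pool, `matches` table,
#'   `screen` table, `profile` table, `candidates` pool, pool `summary`
#'   and `bin_pct`, plus the written `paths`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(cfg$id_path) && !is.null(cfg$spc_path)) {
    id_pool <- read_pool_fasta(cfg$id_path, name = "ID", source = "ID")
    spc_pool <- read_pool_fasta(cfg$spc_path, name = "SPC", source = "SPC")
  } else {
    sim_args <- cfg$sim
    n_proteins <- sim_args$n_proteins %||% 20
    sim_args$n_proteins <- NULL
    proteins <- generate_parent_proteins(n_proteins, seed = cfg$seed)
    sim <- do.call(simulate_sgid,
                   c(list(proteins = proteins,
                          dspec = digestion_spec(seed = cfg$seed),
                          nspec = noise_spec(seed = cfg$seed)),
                     sim_args))
    id_pool <- sim$pools$ID
    spc_pool <- sim$pools$SPC
    truth <- sim$truth
  }

  prep <- function(p) deduplicate(filter_by_alc(p, cfg$min_alc),
                                  merge_il = cfg$merge_il)
  id_f <- prep(id_pool)
  spc_f <- prep(spc_pool)

  res <- tryCatch(
    find_resistant(id_f, spc_f, threshold = cfg$threshold,
                   max_len_diff = cfg$max_len_diff,
                   merge_il = cfg$merge_il),
    error = function(e) stop("match stage failed: ", conditionMessage(e))
  )
  screen <- tryCatch(screen_peptides(res$resistant, cfg$criteria),
                     error = function(e) {
                       stop("screen stage failed: ", conditionMessage(e))
                     })
  profile <- tryCatch(physchem_profile(res$resistant, cfg$tables),
                      error = function(e) {
                        stop("profile stage failed: ", conditionMessage(e))
                      })
  candidates <- select_candidates(res$resistant, cfg$criteria)
  bins <- bin_distribution(res$resistant, cfg$criteria)
  summary_tab <- summarize_pools(list(id_f, spc_f, res$resistant))

  paths <- list(
    resistant = file.path(cfg$out_dir, "resistant.fasta"),
    matches = file.path(cfg$out_dir, "matches.tsv"),
    screen = file.path(cfg$out_dir, "screen.tsv"),
    physchem = file.path(cfg$out_dir, "physchem.tsv"),
    summary = file.path(cfg$out_dir, "summary.yaml")
  )
  export_resistant_fasta(res$resistant, paths$resistant,
                         merge_il = cfg$merge_il)
  write_match_tsv(res$matches, paths$matches)
  write_screen_tsv(screen, paths$screen)
  write_physchem_tsv(profile, paths$physchem)

  summary_list <- list(
    parameters = list(min_alc = cfg$min_alc, threshold = cfg$threshold,
                      max_len_diff = cfg$max_len_diff,
                      merge_il = cfg$merge_il, seed = cfg$seed,
                      criteria = cfg$criteria$name),
    pools = lapply(seq_len(nrow(summary_tab)), function(i) {
      as.list(summary_tab[i, ])
    }),
    criteria_bins_pct = as.list(round(bins, 2)),
    n_resistant = nrow(res$resistant),
    n_candidates = nrow(candidates)
  )
  yaml::write_yaml(summary_list, paths$summary)

  invisible(list(resistant = res$resistant, matches = res$matches,
                 screen = screen, profile = profile,
                 candidates = candidates, summary = summary_tab,
                 bin_pct = bins, truth = truth, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
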