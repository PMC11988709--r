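test_that("parent protein generation is seeded and bounded", {
  p1 <- generate_parent_proteins(5, c(200, 400), seed = 3)
  p2 <- generate_parent_proteins(5, c(200, 400), seed = 3)
  expect_identical(p1, p2)
  expect_true(all(nchar(p1) >= 200 & nchar(p1) <= 400))
  expect_false(identical(p1, generate_parent_proteins(5, c(200, 400),
                                                      seed = 4)))
})

test_that("glycine weighting shifts the residue distribution as expected", {
  p <- generate_parent_proteins(25, c(380, 400), seed = 5,
                                residue_weights = "gly_rich")
  chars <- strsplit(paste(p, collapse = ""), "")[[1]]
  g_frac <- mean(chars == "G")
  # ~10 kres sample; expected G fraction 5/27 ~ 0.185 vs 0.05 uniform;
  # binomial 3-sigma band around the weighted expectation
  n <- length(chars)
  expect_gt(n, 9000)
  expect_gt(g_frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
  expect_equal(g_frac, 5 / 27, tolerance = 0.15)
})

test_that("cleavage follows enzyme specificity and the proline guard", {
  frag <- cleave("AAFAAA", cleavage_rules("pepsin"))
  expect_equal(frag$fragment, c("AAF", "AAA"))
  expect_equal(frag$start, c(0, 3))
  expect_equal(frag$end, c(3, 6))

  expect_equal(cleave("AKPA", cleavage_rules("trypsin"))$fragment, "AKPA")
  expect_equal(cleave("AKGA", cleavage_rules("trypsin"))$fragment,
               c("AK", "GA"))
  # no cut after the final residue
  expect_equal(cleave("AAK", cleavage_rules("trypsin"))$fragment, "AAK")
  # chymotrypsin ignores leucine
  expect_equal(cleave("ALAWA", cleavage_rules("chymotrypsin"))$fragment,
               c("ALAW", "A"))
})

test_that("fragments tile their parents exactly", {
  proteins <- generate_parent_proteins(100, c(100, 300), seed = 17)
  rules <- list(cleavage_rules("pepsin"), cleavage_rules("trypsin"),
                cleavage_rules("chymotrypsin"))
  set.seed(17)
  for (pr in proteins) {
    fr <- cleave(pr, rules[[sample(3, 1)]],
                 missed_cleavage_prob = runif(1, 0, 0.3))
    expect_identical(paste(fr$fragment, collapse = ""), pr)
    expect_equal(fr$start[1], 0)
    expect_equal(fr$end[nrow(fr)], nchar(pr))
    if (nrow(fr) > 1) {
      expect_equal(fr$start[-1], fr$end[-nrow(fr)])
    }
    expect_equal(nchar(fr$fragment), fr$end - fr$start)
  }
})

test_that("size fractionation partitions a pool at sharp MW cutoffs", {
  pool <- peptide_pool(c("PSPSLVWR",
                         random_peptides(40, c(3, 120))), name = "mix")
  fr <- fractionate_by_size(pool, c(3000, 10000))
  expect_named(fr, c("<3000", "[3000,10000)", ">=10000"))
  # PSPSLVWR (MW ~941) lands in the <3 kDa fraction
  expect_true("PSPSLVWR" %in% fr[["<3000"]]$sequence)
  # partition: disjoint union equal to the input
  all_seqs <- unlist(lapply(fr, function(p) p$sequence))
  expect_equal(sum(vapply(fr, nrow, integer(1))), nrow(pool))
  expect_setequal(all_seqs, pool$sequence)
  mw <- molecular_weight(fr[["[3000,10000)"]]$sequence)
  if (length(mw) > 0) expect_true(all(mw >= 3000 & mw < 10000))

  empty <- fractionate_by_size(peptide_pool(character(0)), c(3000, 10000))
  expect_equal(vapply(empty, nrow, integer(1)),
               c("<3000" = 0L, "[3000,10000)" = 0L, ">=10000" = 0L))
})

test_that("identical seeds reproduce identical pools bit-for-bit", {
  pr <- generate_parent_proteins(5, c(150, 250), seed = 19)
  sim1 <- simulate_sgid(pr, digestion_spec(seed = 19), noise_spec(seed = 19),
                        n_resistant = 30, n_spc_extra = 40)
  sim2 <- simulate_sgid(pr, digestion_spec(seed = 19), noise_spec(seed = 19),
                        n_resistant = 30, n_spc_extra = 40)
  expect_identical(sim1$pools, sim2$pools)
  expect_identical(sim1$truth, sim2$truth)

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_pool_fasta(sim1$pools$ID, f1)
  write_pool_fasta(sim2$pools$ID, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("with zero noise the SPC/ID overlap is exactly the planted set", {
  pr <- generate_parent_proteins(8, c(200, 350), seed = 23)
  zero <- noise_spec(substitution_rate = 0, il_swap_rate = 0,
                     truncation_prob = 0, seed = 23)
  sim <- simulate_sgid(pr, digestion_spec(seed = 23), zero,
                       n_resistant = 50, n_spc_extra = 60)
  truth <- sim$truth$resistant_set
  expect_setequal(intersect(sim$pools$SPC$sequence, sim$pools$ID$sequence),
                  truth)

  # and the matcher recovers it perfectly after the standard preprocessing
  prep <- function(p) deduplicate(filter_by_alc(p, 85))
  res <- find_resistant(prep(sim$pools$ID), prep(sim$pools$SPC))
  expect_setequal(intersect(res$resistant$sequence, truth), truth)
  precision <- mean(res$resistant$sequence %in% truth)
  recall <- mean(truth %in% res$resistant$sequence)
  expect_equal(recall, 1)
  expect_equal(precision, 1)
})

test_that("ground-truth provenance coordinates address the parent substrings", {
  pr <- generate_parent_proteins(4, c(120, 200), seed = 29)
  sim <- simulate_sgid(pr, digestion_spec(seed = 29), noise_spec(seed = 29),
                       n_resistant = 20, n_spc_extra = 20)
  prov <- sim$truth$provenance
  extracted <- substring(pr[prov$parent], prov$start + 1, prov$end)
  expect_identical(extracted, prov$sequence)
  planted <- prov[prov$origin == "planted", ]
  expect_setequal(planted$sequence, sim$truth$resistant_set)
})
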