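test_that("molecular weights match the published peptide table", {
  mw <- molecular_weight(table3_peptides$sequence)
  expect_true(all(abs(mw - table3_peptides$mw) <= 0.05))
  # single glycine is free glycine
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.02)
})

test_that("molecular weight is additive up to one water", {
  set.seed(7)
  a <- random_peptides(20, c(2, 15))
  b <- random_peptides(20, c(2, 15))
  tab <- residue_tables()
  expect_equal(molecular_weight(paste0(a, b), tab),
               molecular_weight(a, tab) + molecular_weight(b, tab) -
                 tab$water_mass,
               tolerance = 1e-6)
})

test_that("composition percentages follow the residue classes and sum to 100", {
  comp <- composition_percentages(c("PSPSLVWR", "SDTLFFAR", "GGGG"))
  expect_equal(comp$pct_hydrophobic, c(62.50, 50.00, 100.00))
  expect_equal(comp$pct_acidic, c(0.00, 12.50, 0.00))
  expect_equal(comp$pct_basic, c(12.50, 12.50, 0.00))
  expect_equal(comp$pct_neutral, c(25.00, 25.00, 0.00))

  set.seed(13)
  rnd <- composition_percentages(random_peptides(200, c(2, 25)))
  expect_true(all(abs(rowSums(rnd) - 100) <= 0.01 + 1e-9))
})

test_that("length classes use the 2-5 / 6-10 / >10 bins", {
  expect_equal(length_class(c("AG", "AAGAG", "RHWLPR", "AAGAGAAGAG",
                              "AAGAGAAGAGA")),
               c("short", "short", "medium", "medium", "long"))
  expect_error(length_class("A"), ">= 2")
})

test_that("net charge decreases strictly with pH", {
  set.seed(23)
  for (s in c("RHWLPR", "QCCDFMK", random_peptides(20, c(2, 20)))) {
    q <- net_charge(s, seq(0, 14, by = 0.5))
    expect_true(all(diff(q) < 0), label = paste("monotone for", s))
  }
  expect_gt(net_charge("KKKK", 7), net_charge("DDDD", 7))
})

test_that("net charge agrees with the direct Henderson-Hasselbalch formula", {
  set.seed(29)
  ph <- c(1, 3.5, 7, 10, 13)
  for (s in random_peptides(20, c(2, 20))) {
    expect_equal(net_charge(s, ph), charge_oracle(s, ph), tolerance = 1e-10)
  }
})

test_that("pI has a closed form for a two-group peptide", {
  tab <- residue_tables()
  expect_equal(isoelectric_point("GG"),
               (tab$pka[["Nterm"]] + tab$pka[["Cterm"]]) / 2,
               tolerance = 1e-3)
})

test_that("appending lysine never lowers the pI", {
  set.seed(31)
  for (s in random_peptides(15, c(2, 12))) {
    expect_gte(isoelectric_point(paste0(s, "K")) + 1e-6,
               isoelectric_point(s))
  }
})

test_that("bisection pI agrees with the fine-grid sign-change oracle", {
  seqs <- table3_peptides$sequence
  set.seed(37)
  seqs <- c(seqs, random_peptides(50, c(2, 25)))
  pi_fast <- isoelectric_point(seqs)
  pi_grid <- vapply(seqs, grid_pi_oracle, numeric(1), USE.NAMES = FALSE)
  expect_true(all(abs(pi_fast - pi_grid) < 1e-3))
})

test_that("solubility verdict is composition-driven and reversal-invariant", {
  expect_true(solubility_estimate("DKDKDK"))
  expect_false(solubility_estimate("LLLLLLLLLL"))
  set.seed(41)
  for (s in random_peptides(25, c(2, 20))) {
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_identical(solubility_estimate(s), solubility_estimate(rev_s))
  }
})

test_that("physchem profiles satisfy their internal invariants", {
  pool <- peptide_pool(table3_peptides$sequence, name = "t3")
  prof <- physchem_profile(pool)
  expect_equal(prof$length, nchar(prof$sequence))
  expect_true(all(abs(prof$pct_hydrophobic + prof$pct_acidic +
                        prof$pct_basic + prof$pct_neutral - 100) <=
                    0.01 + 1e-9))
  expect_true(all(prof$pi > 0 & prof$pi < 14))
  expect_identical(prof$length_class, length_class(prof$sequence))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_physchem_tsv(prof, path)
  reread <- read.delim(path)
  expect_equal(nrow(reread), nrow(prof))
  expect_equal(reread$sequence, prof$sequence)
})
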