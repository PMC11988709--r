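test_that("composition vectors count residues and sum to the length", {
  v <- composition_vector("RHWLPR")
  expect_equal(v[["R"]], 2)
  expect_equal(v[["H"]], 1)
  expect_equal(v[["W"]], 1)
  expect_equal(v[["L"]], 1)
  expect_equal(v[["P"]], 1)
  expect_equal(sum(v), 6)

  expect_equal(composition_vector("AAK")[["A"]], 2)

  set.seed(43)
  seqs <- random_peptides(300, c(2, 30))
  m <- composition_matrix(seqs)
  expect_equal(unname(rowSums(m)), nchar(seqs))
  for (s in sample(seqs, 20)) {
    expect_equal(unname(composition_vector(s)), unname(count_oracle(s)))
  }
})

test_that("I/L merging folds isoleucine into the leucine bin", {
  v <- composition_vector("AIL", merge_il = TRUE)
  expect_equal(v[["I"]], 0)
  expect_equal(v[["L"]], 2)
  expect_equal(sum(v), 3)
})

test_that("cosine similarity is symmetric, bounded and scale-invariant", {
  cv <- composition_vector
  expect_equal(cosine_similarity(cv("RHWLPR"), cv("RHWLPR")), 1)
  expect_equal(cosine_similarity(cv("AAAA"), cv("AA")), 1)
  expect_equal(cosine_similarity(cv("AR"), cv("ND")), 0)

  set.seed(47)
  for (i in 1:30) {
    a <- random_peptides(1, c(2, 20))
    b <- random_peptides(1, c(2, 20))
    s_ab <- cosine_similarity(cv(a), cv(b))
    expect_equal(s_ab, cosine_similarity(cv(b), cv(a)))
    expect_gte(s_ab, 0)
    expect_lte(s_ab, 1)
    expect_equal(s_ab, cosine_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(cosine_similarity(numeric(20), cv("AA")), "zero vector")
})

test_that("exact copies are all recovered with similarity 1", {
  set.seed(53)
  seqs <- unique(random_peptides(30, c(5, 15)))
  spc <- peptide_pool(c(seqs, random_peptides(10, c(5, 15))),
                      name = "SPC", source = "SPC")
  id <- peptide_pool(seqs, name = "ID", source = "ID")
  res <- find_resistant(id, spc)
  expect_setequal(res$resistant$sequence, seqs)
  expect_true(all(res$matches$similarity[res$matches$accepted] <= 1))
  expect_true(all(res$best$similarity[res$best$query %in% seqs] == 1))
})

test_that("pairs differing by more than 8 residues are discarded", {
  q <- paste(rep("A", 20), collapse = "")
  r <- paste(rep("A", 11), collapse = "")   # identical composition, diff 9
  res <- find_resistant(peptide_pool(q, source = "ID"),
                        peptide_pool(r, source = "SPC"))
  expect_equal(nrow(res$resistant), 0)
  # at diff 8 the same pair is accepted
  r8 <- paste(rep("A", 12), collapse = "")
  res8 <- find_resistant(peptide_pool(q, source = "ID"),
                         peptide_pool(r8, source = "SPC"))
  expect_equal(res8$resistant$sequence, q)
})

test_that("matcher agrees exactly with the all-pairs brute-force oracle", {
  set.seed(59)
  id_seqs <- unique(c(random_peptides(80, c(4, 25)),
                      random_peptides(20, c(4, 8))))
  spc_seqs <- unique(c(sample(id_seqs, 15), random_peptides(85, c(4, 30))))
  res <- find_resistant(peptide_pool(id_seqs, source = "ID"),
                        peptide_pool(spc_seqs, source = "SPC"))
  expect_setequal(res$resistant$sequence,
                  brute_force_resistant(id_seqs, spc_seqs))
})

test_that("the resistant set is invariant under input permutation", {
  set.seed(61)
  id_seqs <- unique(random_peptides(50, c(4, 15)))
  spc_seqs <- unique(c(sample(id_seqs, 10), random_peptides(40, c(4, 15))))
  base <- find_resistant(peptide_pool(id_seqs, source = "ID"),
                         peptide_pool(spc_seqs, source = "SPC"))
  perm <- find_resistant(peptide_pool(sample(id_seqs), source = "ID"),
                         peptide_pool(sample(spc_seqs), source = "SPC"))
  expect_setequal(base$resistant$sequence, perm$resistant$sequence)
})

test_that("raising the threshold or tightening the length filter never grows the set", {
  set.seed(67)
  id <- peptide_pool(unique(random_peptides(60, c(4, 20))), source = "ID")
  spc <- peptide_pool(unique(random_peptides(60, c(4, 20))), source = "SPC")
  prev <- NULL
  for (thr in c(0.5, 0.7, 0.9, 0.95, 0.99)) {
    cur <- find_resistant(id, spc, threshold = thr)$resistant$sequence
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (mld in c(12, 8, 4, 0)) {
    cur <- find_resistant(id, spc, max_len_diff = mld)$resistant$sequence
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("empty pools are rejected", {
  p <- peptide_pool("AAK", source = "ID")
  empty <- peptide_pool(character(0), source = "SPC")
  expect_error(find_resistant(empty, p), "non-empty")
  expect_error(find_resistant(p, empty), "non-empty")
})

test_that("resistant FASTA export round-trips and never emits duplicates", {
  pool <- peptide_pool(c("RHWLPR", "PSPSLVWR", "RHWLPR"),
                       name = "resistant", source = "ID")
  path <- withr::local_tempfile(fileext = ".fasta")
  export_resistant_fasta(pool, path)
  back <- read_pool_fasta(path)
  expect_equal(back$sequence, c("RHWLPR", "PSPSLVWR"))
  expect_false(any(duplicated(back$sequence)))
  expect_error(export_resistant_fasta(peptide_pool(character(0)),
                                      tempfile()), "empty")
})

test_that("audit mode reports every passing pair", {
  spc <- peptide_pool(c("AAKR", "AARK", "GGGG"), source = "SPC")
  id <- peptide_pool("AAKR", source = "ID")
  aud <- find_resistant(id, spc, audit = TRUE)
  expect_equal(sum(aud$matches$accepted), 2)
  plain <- find_resistant(id, spc)
  expect_equal(nrow(plain$matches), 1)
})
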