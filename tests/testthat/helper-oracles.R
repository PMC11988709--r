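# Independent oracles and fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, len_range = c(5, 20)) {
  vapply(seq_len(n), function(i) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Residue counting written independently of composition_matrix().
count_oracle <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  vapply(AA20, function(a) sum(chars == a), numeric(1))
}

cosine_oracle <- function(a, b) {
  ca <- count_oracle(a)
  cb <- count_oracle(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# All-pairs brute-force matcher: the set of query sequences having any
# reference with cosine > threshold and length difference <= max_len_diff.
brute_force_resistant <- function(id_seqs, spc_seqs, threshold = 0.95,
                                  max_len_diff = 8) {
  qc <- lapply(id_seqs, count_oracle)
  rc <- lapply(spc_seqs, count_oracle)
  qn <- nchar(id_seqs)
  rn <- nchar(spc_seqs)
  accepted <- vapply(seq_along(id_seqs), function(i) {
    for (j in seq_along(spc_seqs)) {
      if (abs(qn[i] - rn[j]) > max_len_diff) next
      s <- sum(qc[[i]] * rc[[j]]) /
        sqrt(sum(qc[[i]]^2) * sum(rc[[j]]^2))
      if (s > threshold) return(TRUE)
    }
    FALSE
  }, logical(1))
  unique(id_seqs[accepted])
}

# Henderson-Hasselbalch net charge written from the formula directly.
charge_oracle <- function(seq, ph, tables = residue_tables()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pka <- tables$pka
  basic <- c(pka[["Nterm"]],
             rep(pka[["H"]], sum(chars == "H")),
             rep(pka[["K"]], sum(chars == "K")),
             rep(pka[["R"]], sum(chars == "R")))
  acidic <- c(pka[["Cterm"]],
              rep(pka[["D"]], sum(chars == "D")),
              rep(pka[["E"]], sum(chars == "E")),
              rep(pka[["C"]], sum(chars == "C")),
              rep(pka[["Y"]], sum(chars == "Y")))
  vapply(ph, function(p) {
    sum(10^(basic - p) / (1 + 10^(basic - p))) -
      sum(10^(p - acidic) / (1 + 10^(p - acidic)))
  }, numeric(1))
}

# pI located by scanning for the charge sign change: coarse 0.01 grid to
# bracket the crossing, then a 1e-4 grid inside the bracket.
grid_pi_oracle <- function(seq, tables = residue_tables()) {
  ph <- seq(0, 14, by = 0.01)
  q <- charge_oracle(seq, ph, tables)
  i <- which(q <= 0)[1]
  phf <- seq(ph[max(1, i - 1)], ph[i], by = 1e-4)
  qf <- charge_oracle(seq, phf, tables)
  phf[which(qf <= 0)[1]]
}

# The 13 peptides characterized in the study's TLR4/MD-2 table, with the
# printed length and molecular weight columns.
table3_peptides <- data.frame(
  sequence = c("QCCDFMK", "HGGGGGGFGGGGFSR", "KCCDMMK", "PSPSLVWR",
               "EWGGGGCGGGGGVSSLR", "SGGFGGNFGNR", "RHWLPR", "SDWPELLGR",
               "SGGGGGGLGSGGSLR", "YNLPMLR", "HGGGGGGFGGGGFDK",
               "SDTLFFAR", "LLFPMSR"),
  length = c(7L, 15L, 7L, 8L, 17L, 11L, 6L, 9L, 15L, 7L, 15L, 8L, 7L),
  mw = c(874.07, 1263.28, 858.14, 941.08, 1492.58, 1069.09, 864.01,
         1072.17, 1175.21, 906.11, 1263.28, 956.05, 863.08),
  stringsAsFactors = FALSE
)
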