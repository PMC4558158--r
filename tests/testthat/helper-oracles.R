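# Independent brute-force oracles, deliberately sharing no code with the
# package: hand-entered codon table, character-walk translation,
# string-reversal complement, closed-form Pearson statistic.

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(s) {
  out <- character()
  i <- 1L
  while (i + 2L <= nchar(s)) {
    cod <- substr(s, i, i + 2L)
    aa <- ORACLE_CODE[cod]
    out <- c(out, if (is.na(aa)) "X" else aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# codon-walk six-frame translation, split at stops, length filter
oracle_six_frames <- function(s, min_len) {
  one <- function(x) {
    frag <- strsplit(oracle_translate(x), "*", fixed = TRUE)[[1]]
    frag[nchar(frag) >= min_len]
  }
  rc <- oracle_revcomp(s)
  list(F1 = one(s), F2 = one(substring(s, 2)), F3 = one(substring(s, 3)),
       R1 = one(rc), R2 = one(substring(rc, 2)), R3 = one(substring(rc, 3)))
}

oracle_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small ready-made study used by several test files
tiny_reference <- function(seed = 3L) generate_reference(6L, seed = seed)
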