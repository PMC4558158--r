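make_psms <- function(peptides, scores, decoys, accs = NULL,
                      sample_id = "s") {
  n <- length(peptides)
  if (is.null(accs)) accs <- ifelse(decoys, "rev_P1", "P1")
  data.frame(spectrum_id = sprintf("sp%04d", seq_len(n)),
             peptide = peptides, accessions = accs,
             score = scores, is_decoy = decoys, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

test_that("FDR filter retains targets at the most permissive threshold", {
  # 1000 target peptides above the decoys' best score region: 4 decoys slip
  # above the chosen threshold -> fdr 0.004 < 0.005, all targets retained
  set.seed(1)
  p <- make_psms(c(sprintf("TARG%04dK", 1:1000), sprintf("DEC%04dK", 1:4)),
                 c(seq(10, 60, length.out = 1000), rep(55, 4)),
                 c(rep(FALSE, 1000), rep(TRUE, 4)))
  res <- peptide_fdr_filter(p, 0.005)
  expect_equal(res$operating_point$n_target, 1000L)
  expect_equal(res$operating_point$n_decoy, 4L)
  expect_equal(res$operating_point$fdr, 0.004)
  expect_equal(nrow(res$psms), 1000L)
  expect_false(any(res$psms$is_decoy))
})

test_that("FDR filter degenerate cases behave as specified", {
  # all decoys outscore all targets -> nothing qualifies
  p <- make_psms(c("AK", "CK", "DK"), c(1, 2, 9),
                 c(FALSE, FALSE, TRUE))
  res <- peptide_fdr_filter(p, 0.005)
  expect_equal(nrow(res$psms), 0L)

  # fdr_max 1 -> all target peptides retained
  res <- peptide_fdr_filter(p, 1.0)
  expect_equal(sort(unique(res$psms$peptide)), c("AK", "CK"))

  # zero decoys -> warning, fdr treated as 0
  p2 <- make_psms(c("AK", "CK"), c(1, 2), c(FALSE, FALSE))
  expect_warning(res <- peptide_fdr_filter(p2, 0.005), "no decoy")
  expect_equal(nrow(res$psms), 2L)
  expect_error(peptide_fdr_filter(p[p$is_decoy, ], 0.005), "no target")
})

test_that("raising fdr_max never shrinks the retained peptide set", {
  set.seed(23)
  n <- 400
  p <- make_psms(sprintf("PEP%04dK", 1:n),
                 c(rnorm(n * 0.9, 40, 6), rnorm(n * 0.1, 25, 6)),
                 c(rep(FALSE, n * 0.9), rep(TRUE, n * 0.1)))
  prev <- character()
  for (fmax in c(0.002, 0.01, 0.05, 0.2, 0.9)) {
    got <- unique(peptide_fdr_filter(p, fmax)$psms$peptide)
    expect_true(all(prev %in% got))
    prev <- got
  }
})

test_that("protein inference applies uniqueness and spectra rules", {
  # P1: 2 unique peptides, plus a peptide shared with P2 -> retained, s = 4
  # P2: only the shared peptide -> excluded
  p <- make_psms(c("AAAK", "CCCK", "DDDK", "DDDK"),
                 c(30, 31, 32, 33), rep(FALSE, 4),
                 accs = c("P1", "P1", "P1;P2", "P1;P2"))
  id <- infer_proteins(p, min_unique = 2L)
  expect_equal(id$accession, "P1")
  expect_equal(id$n_unique_peptides, 2L)
  expect_equal(id$n_significant_spectra, 4L)

  # a single unique peptide is not enough
  p1 <- make_psms(c("AAAK", "AAAK"), c(30, 31), c(FALSE, FALSE),
                  accs = c("P1", "P1"))
  expect_equal(nrow(infer_proteins(p1, 2L)), 0L)
  expect_equal(infer_proteins(p1, 1L)$n_significant_spectra, 2L)
  expect_error(infer_proteins(make_psms("AK", 1, TRUE), 2L), "target-only")
})

test_that("mutant calls require novel variant-spanning evidence", {
  wt <- data.frame(accession = "TX1", sequence = "MAAAKLLLKDDDK",
                   stringsAsFactors = FALSE)
  mdb <- data.frame(accession = "mut|G|TX1|c:1:A>T|sub",
                    sequence = "MAAAKLVLKDDDK", gene = "G",
                    transcript_id = "TX1", chrom = "c", pos = 1L,
                    ref = "A", alt = "T", kind = "missense",
                    frame = "substitution", aa_pos = 7L,
                    wt_accession = "TX1", stringsAsFactors = FALSE)
  # variant peptide LVLK (covers residue 7, absent from wild type) plus a
  # shared peptide; both map to the mutant entry
  p <- make_psms(c("LVLK", "LVLK", "DDDK"), c(40, 41, 39), rep(FALSE, 3),
                 accs = c("mut|G|TX1|c:1:A>T|sub", "mut|G|TX1|c:1:A>T|sub",
                          "TX1;mut|G|TX1|c:1:A>T|sub"))
  id <- infer_proteins(p, min_unique = 1L)
  calls <- call_mutants(id, p, mdb, wt)
  expect_equal(calls$accession, "mut|G|TX1|c:1:A>T|sub")
  expect_equal(calls$evidence_peptides, "LVLK")

  # only shared peptides -> no call
  p2 <- make_psms(c("DDDK", "MAAAK"), c(40, 41), c(FALSE, FALSE),
                  accs = rep("TX1;mut|G|TX1|c:1:A>T|sub", 2))
  id2 <- infer_proteins(p2, min_unique = 1L)
  expect_equal(nrow(call_mutants(id2, p2, mdb, wt)), 0L)

  # identified mutant accession missing from the database is an error
  id3 <- id
  id3$accession <- "mut|G|TX9|c:1:A>T|sub"
  expect_error(call_mutants(id3, p, mdb, wt), "absent")
})

test_that("novel peptides not covering the substituted residue are ignored", {
  wt <- data.frame(accession = "TX1", sequence = "MAAAKLLLKDDDK",
                   stringsAsFactors = FALSE)
  mdb <- data.frame(accession = "m1", sequence = "MTAAKLLLKDDDK",
                    gene = "G", transcript_id = "TX1", chrom = "c",
                    pos = 1L, ref = "A", alt = "T", kind = "missense",
                    frame = "substitution", aa_pos = 2L,
                    wt_accession = "TX1", stringsAsFactors = FALSE)
  # peptide LLLK does not overlap residue 2 and exists in the wild type
  p <- make_psms(c("MTAAK", "LLLK"), c(40, 41), c(FALSE, FALSE),
                 accs = c("m1", "TX1;m1"))
  id <- infer_proteins(p, min_unique = 1L)
  calls <- call_mutants(id, p, mdb, wt)
  expect_equal(calls$evidence_peptides, "MTAAK")
})

test_that("venn counts satisfy the exclusive-total identity", {
  v <- venn_from_counts(60L, 71L, 16L)
  expect_equal(v$exclusive_total, 99L)
  expect_equal(v$only_a, 44L)
  expect_equal(v$only_b, 55L)

  a <- c("x", "y", "z")
  expect_equal(venn_counts(a, a)$exclusive_total, 0L)
  expect_equal(venn_counts(a, c("q", "r"))$exclusive_total, 5L)

  set.seed(17)
  pool <- sprintf("P%03d", 1:60)
  for (i in 1:50) {
    A <- sample(pool, sample(0:40, 1))
    B <- sample(pool, sample(0:40, 1))
    v <- venn_counts(A, B)
    expect_equal(v$exclusive_total,
                 length(A) + length(B) - 2L * length(intersect(A, B)))
    expect_equal(v$only_a + v$only_b + v$common,
                 length(union(A, B)))
  }
})

test_that("count matrices validate totals against protein counts", {
  ids <- list(
    exosome = data.frame(accession = c("P1", "P2"), sample_id = "exosome",
                         n_unique_peptides = c(2L, 3L),
                         n_significant_spectra = c(10L, 5L)),
    ectosome = data.frame(accession = "P1", sample_id = "ectosome",
                          n_unique_peptides = 2L,
                          n_significant_spectra = 4L))
  cm <- count_matrix(ids, c(exosome = 20L, ectosome = 9L))
  expect_equal(cm$counts["P1", "exosome"], 10L)
  expect_equal(cm$counts["P2", "ectosome"], 0L)
  expect_error(count_matrix(ids, c(exosome = 8L, ectosome = 9L)),
               "totals")
})

test_that("decoys never reach identification outputs on simulated data", {
  ref <- generate_reference(8L, seed = 6L)
  wt <- wildtype_proteins(ref$models)
  truth <- plant_truth(wt, data.frame(accession = character(),
                                      sequence = character()),
                       n_diff = 2L, n_exclusive_each = 1L,
                       n_secreted_mutants = 0L, seed = 6L)
  psms <- simulate_psms(wt[, c("accession", "sequence")], make_decoys(wt),
                        truth, 2000L, decoy_fraction = 0.1, seed = 6L,
                        samples = "exosome")$exosome
  f <- peptide_fdr_filter(psms, 0.005)
  id <- infer_proteins(f$psms, 2L)
  expect_false(any(startsWith(id$accession, "rev_")))
  expect_false(any(f$psms$is_decoy))
  # empirical FDR of retained peptides at most twice the nominal ceiling:
  # a retained peptide is false if no correctly-matched spectrum supports it
  true_peps <- unique(psms$peptide[psms$true_match & !psms$is_decoy])
  retained <- unique(f$psms$peptide)
  emp <- mean(!retained %in% true_peps)
  expect_lte(emp, 2 * 0.005)
})
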