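make_model <- function(cds = "ATGGCTAAA", strand = "+",
                       id = "TX1", gene = "G1", chrom = "chr1") {
  genomic <- if (strand == "+") cds else oracle_revcomp(cds)
  list(model = transcript_model(id, gene, chrom, strand,
                                cbind(1L, nchar(cds)), cds),
       chrom_seq = genomic)
}

test_that("SNV consequences are called through codon retranslation", {
  m <- make_model()$model  # MAK
  v <- normalize_variants("chr1", 4L, "G", "A")
  cons <- call_consequence(v, m)
  expect_equal(cons$kind, "missense")
  expect_equal(cons$aa_pos, 2L)
  expect_equal(cons$ref_aa, "A")
  expect_equal(cons$alt_aa, "T")

  # GCT -> GCC, both alanine
  v <- normalize_variants("chr1", 6L, "T", "C")
  expect_equal(call_consequence(v, m)$kind, "synonymous")

  # outside the CDS -> noncoding, not an error
  m2 <- transcript_model("TX2", "G2", "chr1", "+", cbind(11L, 19L),
                         "ATGGCTAAA")
  v <- normalize_variants("chr1", 5L, "A", "T")
  expect_equal(call_consequence(v, m2)$kind, "noncoding")
})

test_that("minus-strand SNVs are mapped and reverse-complemented", {
  mk <- make_model(strand = "-")
  # CDS position 4 (G of GCT) sits at genomic position 6, base C
  expect_equal(substr(mk$chrom_seq, 6L, 6L), "C")
  v <- normalize_variants("chr1", 6L, "C", "T")  # cds G>A
  cons <- call_consequence(v, mk$model)
  expect_equal(cons$kind, "missense")
  expect_equal(cons$ref_aa, "A")
  expect_equal(cons$alt_aa, "T")
  # mismatching reference allele is a hard error
  v <- normalize_variants("chr1", 6L, "A", "T")
  expect_error(call_consequence(v, mk$model), "reference mismatch")
})

test_that("INDEL consequences classify by length change mod 3", {
  m <- make_model(cds = "ATGGCTGCTGCTAAA")$model
  ins1 <- normalize_variants("chr1", 5L, "", "T")
  expect_equal(call_consequence(ins1, m)$kind, "frameshift")
  del2 <- normalize_variants("chr1", 5L, "CT", "")
  expect_equal(call_consequence(del2, m)$kind, "frameshift")
  ins3 <- normalize_variants("chr1", 5L, "", "AAA")
  expect_equal(call_consequence(ins3, m)$kind, "inframe_indel")
})

test_that("substitution entries apply the single edit or truncation", {
  m <- make_model()$model
  wt <- wildtype_proteins(list(m))$sequence
  expect_equal(wt, "MAK")
  cons <- call_consequence(normalize_variants("chr1", 4L, "G", "A"), m)
  expect_equal(build_snv_entry(cons, wt), "MTK")

  syn <- call_consequence(normalize_variants("chr1", 6L, "T", "C"), m)
  expect_null(build_snv_entry(syn, wt))

  stop_gain <- structure(list(kind = "stop_gain", aa_pos = 2L,
                              ref_aa = "A", alt_aa = "*"),
                         class = "consequence")
  expect_equal(build_snv_entry(stop_gain, "MAK"), "M")

  bad <- structure(list(kind = "missense", aa_pos = 9L, ref_aa = "A",
                        alt_aa = "T"), class = "consequence")
  expect_error(build_snv_entry(bad, "MAK"), "mismatch")
})

test_that("INDEL windows splice the mutant allele between truncated flanks", {
  set.seed(21)
  s <- random_dna(2000)
  pos <- 1000L
  del <- data.frame(chrom = "c", pos = pos,
                    ref = substr(s, pos, pos), alt = "", vtype = "DEL",
                    stringsAsFactors = FALSE)
  expect_equal(indel_window(s, del, 150L),
               paste0(substr(s, 850, 999), substr(s, 1001, 1150)))

  ins <- data.frame(chrom = "c", pos = 1L, ref = "", alt = "TT",
                    vtype = "INS", stringsAsFactors = FALSE)
  expect_equal(indel_window(s, ins, 150L), paste0("TT", substr(s, 1, 150)))

  hand <- data.frame(chrom = "c", pos = 5L, ref = "G", alt = "",
                     vtype = "DEL", stringsAsFactors = FALSE)
  expect_equal(indel_window("AAACGTTTT", hand, 3L), "AACTTT")

  wrong <- data.frame(chrom = "c", pos = 5L, ref = "T", alt = "",
                      vtype = "DEL", stringsAsFactors = FALSE)
  expect_error(indel_window("AAACGTTTT", wrong, 3L), "reference mismatch")
})

test_that("six-frame translation matches the worked example", {
  fr <- six_frame_translate("ATGAAA", min_fragment_aa = 1L)
  expect_equal(fr, list(F1 = "MK", F2 = character(), F3 = "E",
                        R1 = "FH", R2 = "F", R3 = "S"))
  # length filter empties every frame
  fr7 <- six_frame_translate("ATGAAA", min_fragment_aa = 7L)
  expect_true(all(lengths(fr7) == 0L))
})

test_that("six-frame translation matches a brute-force codon walk", {
  set.seed(101)
  for (i in 1:1000) {
    s <- random_dna(sample(3:300, 1))
    min_len <- sample(c(1L, 7L), 1)
    expect_identical(six_frame_translate(s, min_len),
                     oracle_six_frames(s, min_len))
  }
})

test_that("reverse-complement frame symmetry holds", {
  set.seed(13)
  for (i in 1:50) {
    s <- random_dna(sample(10:120, 1))
    a <- six_frame_translate(s, 1L)
    b <- six_frame_translate(revcomp(s), 1L)
    expect_identical(b[c("F1", "F2", "F3")],
                     stats::setNames(a[c("R1", "R2", "R3")],
                                     c("F1", "F2", "F3")))
  }
})

test_that("database construction follows the per-variant entry rules", {
  ref <- tiny_reference()
  cfg <- vesiprot_config()
  spiked <- spike_variants(ref, n_nonsyn_snv = 2L, n_syn_snv = 1L,
                           n_indel = 1L, seed = 8L)
  db <- build_database(spiked$variants, ref$models, ref$chrom_seqs, cfg)

  # expected count by construction: one entry per missense x transcript,
  # none for the synonymous variant, one per surviving window fragment
  idx_indel <- which(spiked$variants$vtype != "SNV")
  win <- indel_window(ref$chrom_seqs[[spiked$variants$chrom[idx_indel]]],
                      spiked$variants[idx_indel, ], cfg$flank_nt)
  n_frag <- sum(lengths(oracle_six_frames(win, cfg$min_fragment_aa)))
  expect_equal(nrow(db$mutant), 2L + n_frag)
  expect_false(any(grepl("*", db$mutant$sequence, fixed = TRUE)))

  # substitution entries differ from wild type exactly at the mutated residue
  wt <- wildtype_proteins(ref$models)
  subs <- db$mutant[db$mutant$frame == "substitution", ]
  for (i in seq_len(nrow(subs))) {
    w <- wt$sequence[wt$accession == subs$wt_accession[i]]
    a <- strsplit(w, "")[[1]]
    b <- strsplit(subs$sequence[i], "")[[1]]
    expect_equal(length(a), length(b))
    expect_equal(which(a != b), subs$aa_pos[i])
  }

  # decoys cover wild type + mutants, reversed with the rev_ prefix
  expect_equal(nrow(db$decoy), nrow(wt) + nrow(db$mutant))
  expect_true(all(startsWith(db$decoy$accession, "rev_")))
  first_wt <- db$decoy$sequence[db$decoy$accession ==
                                  paste0("rev_", wt$accession[1])]
  expect_equal(first_wt,
               paste(rev(strsplit(wt$sequence[1], "")[[1]]), collapse = ""))
})

test_that("zero variants give an empty mutant DB and wild-type decoys only", {
  ref <- tiny_reference()
  none <- normalize_variants(character(), integer(), character(),
                             character())
  db <- build_database(none, ref$models, ref$chrom_seqs, vesiprot_config())
  expect_equal(nrow(db$mutant), 0L)
  expect_equal(nrow(db$decoy), length(ref$models))
})

test_that("database FASTA output is deterministic", {
  ref <- tiny_reference()
  spiked <- spike_variants(ref, 2L, 1L, 1L, seed = 8L)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  for (f in c(f1, f2)) {
    db <- build_database(spiked$variants, ref$models, ref$chrom_seqs,
                         vesiprot_config())
    write_fasta(db$mutant[, c("accession", "sequence")], f)
  }
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
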