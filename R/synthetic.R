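STOP_CODONS <- c("TAA", "TAG", "TGA")

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

random_codons <- function(n_codons) {
  # random sense codons (no stops)
  out <- character(n_codons)
  i <- 1L
  while (i <= n_codons) {
    cod <- random_nt(3L)
    if (!cod %in% STOP_CODONS) { out[i] <- cod; i <- i + 1L }
  }
  paste(out, collapse = "")
}

#' Generate a toy reference transcriptome
#'
#' Each transcript gets its own chromosome: random flanking sequence, a CDS
#' with a valid start codon, no internal stop and a terminal stop codon, and
#' (for about half the models) an intron splitting the CDS in two. Both
#' strands are represented. Fully reproducible for a seed.
#'
#' @param n_transcripts Number of transcripts (one per chromosome).
#' @param cds_length_range Length range of the CDS in nt, bounds multiples of
#'   3 and >= 30 (includes start and stop codons).
#' @param seed Integer seed.
#' @param flank_len Plain-sequence flank placed on each side of the gene
#'   (sized to accommodate INDEL windows).
#' @param intron_prob Probability that a model is split into two CDS segments
#'   by an intron.
#' @return List with `chrom_seqs` (named character vector) and `models`
#'   (list of `transcript_model`).
#' @export
generate_reference <- function(n_transcripts, cds_length_range = c(300L, 900L),
                               seed = 1L, flank_len = 300L,
                               intron_prob = 0.5) {
  if (any(cds_length_range %% 3L != 0L) || any(cds_length_range < 30L))
    stop("cds_length_range bounds must be multiples of 3 and >= 30")
  if (n_transcripts < 1L) stop("n_transcripts must be >= 1")
  set.seed(seed)
  chrom_seqs <- character(n_transcripts)
  names(chrom_seqs) <- paste0("chr", seq_len(n_transcripts))
  models <- vector("list", n_transcripts)
  for (i in seq_len(n_transcripts)) {
    n_codons <- sample(seq(cds_length_range[1L] %/% 3L,
                           cds_length_range[2L] %/% 3L), 1L)
    cds <- paste0("ATG", random_codons(n_codons - 2L),
                  sample(STOP_CODONS, 1L))
    strand <- if (i %% 2L == 0L) "-" else "+"
    # optionally split the CDS by one intron (transcript-space split point)
    if (stats::runif(1L) < intron_prob && nchar(cds) >= 60L) {
      cut <- sample(seq(30L, nchar(cds) - 30L), 1L)
      intron <- random_nt(sample(50:150, 1L))
      exons_tx <- c(substr(cds, 1L, cut), substring(cds, cut + 1L))
    } else {
      intron <- ""
      exons_tx <- cds
    }
    sense_gene <- paste0(exons_tx[1L], intron,
                         if (length(exons_tx) > 1L) exons_tx[2L] else "")
    gene_genomic <- if (strand == "+") sense_gene else revcomp(sense_gene)
    chrom <- paste0(random_nt(flank_len), gene_genomic, random_nt(flank_len))
    chrom_seqs[i] <- chrom
    # segment coordinates: transcript-space offsets mapped onto the genome
    Ls <- nchar(sense_gene)
    offs <- cumsum(c(0L, nchar(exons_tx[1L]) + nchar(intron)))
    segs_tx <- cbind(start = c(1L, offs[2L] + 1L)[seq_along(exons_tx)],
                     end = c(nchar(exons_tx[1L]),
                             offs[2L] + nchar(exons_tx)[2L])[seq_along(exons_tx)])
    if (strand == "+") {
      segs <- segs_tx + flank_len
    } else {
      segs <- cbind(flank_len + Ls - segs_tx[, 2L] + 1L,
                    flank_len + Ls - segs_tx[, 1L] + 1L)
      segs <- segs[order(segs[, 1L]), , drop = FALSE]
    }
    models[[i]] <- transcript_model(
      transcript_id = sprintf("TX%04d", i),
      gene_symbol = sprintf("GENE%04d", i),
      chrom = names(chrom_seqs)[i], strand = strand,
      cds_segments = segs, cds_sequence = cds)
  }
  list(chrom_seqs = chrom_seqs, models = models)
}

#' Spike coding variants into a toy reference
#'
#' Plants non-synonymous SNVs (missense), synonymous SNVs (found by
#' codon-table search at third codon positions) and small INDELs (split
#' between frameshift, 1-2 nt, and in-frame, 3 nt) into transcript CDS
#' regions, converting CDS-space edits to genomic coordinates and alleles
#' honoring strand. The intended consequence is recorded per variant.
#'
#' @param reference Output of [generate_reference()].
#' @param n_nonsyn_snv,n_syn_snv,n_indel Counts of each variant class.
#' @param seed Integer seed.
#' @return List with `variants` (normalized variant table) and `truth`
#'   (data.frame: variant columns plus `transcript_id`, `intended_kind`).
#' @export
spike_variants <- function(reference, n_nonsyn_snv, n_syn_snv, n_indel,
                           seed = 1L) {
  set.seed(seed)
  models <- reference$models
  n_total <- n_nonsyn_snv + n_syn_snv + n_indel
  if (n_total > 3L * length(models))
    stop("requested more variants than the reference can comfortably host")
  rows <- list()
  used <- list()  # per transcript: codon indices already touched
  kinds <- c(rep("missense", n_nonsyn_snv), rep("synonymous", n_syn_snv),
             rep("indel", n_indel))
  indel_fs <- rep(c(TRUE, FALSE), length.out = n_indel)  # frameshift split
  fs_i <- 0L
  for (k in kinds) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      mi <- sample(seq_along(models), 1L)
      m <- models[[mi]]
      n_codons <- nchar(m$cds_sequence) %/% 3L
      ci <- sample(seq(2L, n_codons - 1L), 1L)  # spare start & stop codons
      key <- as.character(mi)
      if (ci %in% used[[key]]) next
      row <- switch(k,
        missense = spike_missense(m, ci),
        synonymous = spike_synonymous(m, ci),
        indel = {
          fs_i <- fs_i + 1L
          spike_indel(m, ci, frameshift = indel_fs[fs_i])
        })
      if (is.null(row)) {
        if (k == "indel") fs_i <- fs_i - 1L
        next
      }
      used[[key]] <- c(used[[key]], ci)
      rows[[length(rows) + 1L]] <- row
      placed <- TRUE
      break
    }
    if (!placed)
      stop("no codon position admitting a ", k,
           " change found after bounded search")
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  variants <- normalize_variants(truth$chrom, truth$pos, truth$ref, truth$alt)
  list(variants = variants, truth = truth)
}

# CDS-space point edit at codon ci mapped to a genomic variant row.
cds_point_to_genomic <- function(m, cpos, ref_cds, alt_cds, intended) {
  gpos <- cds_to_genomic(m, cpos)
  ref <- ref_cds; alt <- alt_cds
  if (m$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  data.frame(chrom = m$chrom, pos = gpos, ref = ref, alt = alt,
             transcript_id = m$transcript_id, intended_kind = intended,
             stringsAsFactors = FALSE)
}

spike_missense <- function(m, ci) {
  cstart <- (ci - 1L) * 3L + 1L
  codon <- substr(m$cds_sequence, cstart, cstart + 2L)
  ref_aa <- translate_nt(codon)
  for (off in sample(1:3)) {
    for (b in sample(setdiff(c("A", "C", "G", "T"),
                             substr(codon, off, off)))) {
      mcodon <- codon
      substr(mcodon, off, off) <- b
      aa <- translate_nt(mcodon)
      if (aa != ref_aa && aa != "*")
        return(cds_point_to_genomic(m, cstart + off - 1L,
                                    substr(codon, off, off), b, "missense"))
    }
  }
  NULL
}

spike_synonymous <- function(m, ci) {
  cstart <- (ci - 1L) * 3L + 1L
  codon <- substr(m$cds_sequence, cstart, cstart + 2L)
  ref_aa <- translate_nt(codon)
  for (b in sample(setdiff(c("A", "C", "G", "T"), substr(codon, 3L, 3L)))) {
    mcodon <- codon
    substr(mcodon, 3L, 3L) <- b
    if (translate_nt(mcodon) == ref_aa)
      return(cds_point_to_genomic(m, cstart + 2L, substr(codon, 3L, 3L), b,
                                  "synonymous"))
  }
  NULL
}

# INDEL inside codon ci; placed only where the CDS positions involved sit in
# one genomic segment, so genomic alleles are contiguous.
spike_indel <- function(m, ci, frameshift) {
  cstart <- (ci - 1L) * 3L + 1L
  len <- if (frameshift) sample(1:2, 1L) else 3L
  del <- stats::runif(1L) < 0.5
  cpos_span <- if (del) cstart:(cstart + len - 1L) else cstart:(cstart + 1L)
  gpos <- vapply(cpos_span, function(p) cds_to_genomic(m, p), 1L)
  if (any(abs(diff(gpos)) != 1L)) return(NULL)  # spans an intron boundary
  intended <- if (frameshift) "frameshift" else "inframe_indel"
  if (del) {
    ref_cds <- substr(m$cds_sequence, cstart, cstart + len - 1L)
    if (m$strand == "+") {
      data.frame(chrom = m$chrom, pos = gpos[1L], ref = ref_cds, alt = "",
                 transcript_id = m$transcript_id, intended_kind = intended,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = m$chrom, pos = min(gpos), ref = revcomp(ref_cds),
                 alt = "", transcript_id = m$transcript_id,
                 intended_kind = intended, stringsAsFactors = FALSE)
    }
  } else {
    ins_cds <- if (frameshift) random_nt(len) else random_codons(1L)
    # insert between CDS positions cstart and cstart+1
    if (m$strand == "+") {
      data.frame(chrom = m$chrom, pos = gpos[2L], ref = "", alt = ins_cds,
                 transcript_id = m$transcript_id, intended_kind = intended,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = m$chrom, pos = gpos[1L], ref = "",
                 alt = revcomp(ins_cds), transcript_id = m$transcript_id,
                 intended_kind = intended, stringsAsFactors = FALSE)
    }
  }
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and returns all
#' peptides carrying 0 to `max_missed_cleavages` internal cleavage sites
#' (duplicates retained).
#'
#' @param protein_sequence Protein string.
#' @param max_missed_cleavages Maximum internal missed cleavages.
#' @return Character vector of peptides (empty for empty input).
#' @export
digest <- function(protein_sequence, max_missed_cleavages = 0L) {
  if (!nzchar(protein_sequence)) return(character())
  ch <- strsplit(protein_sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & ch[pmin(cut_after + 1L, n)] != "P" |
                         cut_after == n]
  bounds <- c(0L, cut_after[cut_after < n], n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  base <- substring(protein_sequence, starts, ends)
  out <- character()
  for (miss in 0:max_missed_cleavages) {
    k <- length(base) - miss
    if (k < 1L) break
    idx <- seq_len(k)
    out <- c(out, substring(protein_sequence, starts[idx], ends[idx + miss]))
  }
  out
}

#' Plant per-protein abundances, fold changes and exclusivity
#'
#' Assigns each wild-type protein a log-normal base abundance, plants log2
#' fold changes (exosome vs ectosome) of ±\{1.5, 2, 2.5\} on a subset, marks
#' compartment-exclusive proteins, and selects secreted mutants among mutant
#' entries that have at least two distinct variant-spanning tryptic peptides.
#'
#' Differential proteins are planted in abundance-matched pairs carrying the
#' same fold magnitude with opposite signs, and exclusive proteins are
#' likewise paired across compartments, so the per-sample spectral mass
#' stays balanced: under fixed sequencing depth only composition is
#' observable, and unbalanced planting would systematically attenuate every
#' observed ratio.
#'
#' @param wt Wild-type protein table.
#' @param mutant Mutant entry table from [build_database()].
#' @param n_diff Number of differential proteins.
#' @param n_exclusive_each Exclusive proteins per compartment (exosome and
#'   ectosome).
#' @param n_secreted_mutants Planted secreted mutant entries (split across
#'   exosome-only / ectosome-only / both).
#' @param seed Integer seed.
#' @param abundance_sdlog sdlog of the log-normal base abundance.
#' @return List of class `simulation_truth`: `base_abundance` (named),
#'   `planted_log2_fold` (named; exosome relative to ectosome),
#'   `exclusive_proteins` (named compartment vector),
#'   `mutant_secretion` (named list accession -> compartments), `seed`.
#' @export
plant_truth <- function(wt, mutant, n_diff = 15L, n_exclusive_each = 2L,
                        n_secreted_mutants = 6L, seed = 1L,
                        abundance_sdlog = 0.6) {
  set.seed(seed)
  accs <- wt$accession
  base <- stats::setNames(stats::rlnorm(length(accs), 0, abundance_sdlog),
                          accs)
  if (n_diff + 2L * n_exclusive_each > length(accs))
    stop("not enough proteins for the requested planting")
  picked <- sample(accs, n_diff + 2L * n_exclusive_each)
  diff_accs <- picked[seq_len(n_diff)]
  excl <- picked[-seq_len(n_diff)]
  # expected spectral mass, the pairing weight for balanced planting
  mass <- base * nchar(wt$sequence[match(accs, wt$accession)])
  fold <- stats::setNames(rep(0, length(accs)), accs)
  diff_accs <- diff_accs[order(-mass[diff_accs])]
  mags <- sample(c(1.5, 2, 2.5), n_diff, replace = TRUE)
  signs <- numeric(n_diff)
  i <- 1L
  while (i + 1L <= n_diff) {
    s <- sample(c(-1, 1), 1L)
    signs[i] <- s
    signs[i + 1L] <- -s
    mags[i + 1L] <- mags[i]
    i <- i + 2L
  }
  if (i == n_diff) signs[i] <- sample(c(-1, 1), 1L)
  fold[diff_accs] <- signs * mags
  excl <- excl[order(-mass[excl])]
  comp <- rep(c("exosome", "ectosome"), length.out = length(excl))
  for (j in seq(1L, length(excl) - 1L, by = 2L)) {
    if (stats::runif(1L) < 0.5) comp[j:(j + 1L)] <- rev(comp[j:(j + 1L)])
  }
  exclusive <- stats::setNames(comp, excl)
  # candidate secreted mutants: >= 2 distinct variant-spanning peptides
  wt_seqs <- wt$sequence
  candidates <- mutant$accession[vapply(seq_len(nrow(mutant)), function(i) {
    length(variant_spanning_peptides(mutant$sequence[i], wt_seqs)) >= 2L
  }, TRUE)]
  n_sec <- min(n_secreted_mutants, length(candidates))
  sec <- if (n_sec > 0L) sample(candidates, n_sec) else character()
  comp_cycle <- list("exosome", "ectosome", c("exosome", "ectosome"))
  secretion <- stats::setNames(
    lapply(seq_len(n_sec), function(i) comp_cycle[[(i - 1L) %% 3L + 1L]]),
    sec)
  structure(list(base_abundance = base, planted_log2_fold = fold,
                 exclusive_proteins = exclusive,
                 mutant_secretion = secretion, seed = as.integer(seed)),
            class = "simulation_truth")
}

# Tryptic peptides (up to 1 missed cleavage, 7-35 aa) of `sequence` that are
# not substrings of any wild-type protein.
variant_spanning_peptides <- function(sequence, wt_seqs,
                                      min_len = 7L, max_len = 35L) {
  peps <- unique(digest(sequence, 1L))
  peps <- peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
  in_wt <- vapply(peps, function(p) any(grepl(p, wt_seqs, fixed = TRUE)),
                  TRUE)
  peps[!in_wt]
}

#' Simulate per-sample PSM streams
#'
#' Per-protein spectral counts follow a multinomial draw with rates
#' proportional to length × base abundance × the planted per-compartment fold
#' factor (a log2 fold f is split symmetrically: exosome ×2^(f/2), ectosome
#' ×2^(-f/2)); sampled spectra draw a tryptic peptide (up to 1 missed cleavage,
#' 7-35 residues) with replacement from the protein's digest. Correct matches
#' score N(40, 6). A `decoy_fraction` of spectra are incorrect matches
#' scoring N(25, 6), split evenly between decoy hits and false target hits.
#' Exclusive proteins receive zero spectra in the excluded compartment;
#' mutant entries generate only variant-spanning peptides, only in their
#' planted compartments.
#'
#' @param target_db Combined wild-type + mutant sequence table.
#' @param decoy_db Decoy sequence table.
#' @param truth A `simulation_truth`.
#' @param depth_per_sample Total spectra per sample (>= 100).
#' @param decoy_fraction Fraction of incorrect matches (0 <= f < 0.5).
#' @param seed Integer seed.
#' @param samples Sample (compartment) identifiers.
#' @return Named list (by sample) of PSM data.frames with columns
#'   `spectrum_id`, `peptide`, `accessions`, `score`, `is_decoy`,
#'   `sample_id`, and the truth-only column `true_match`.
#' @export
simulate_psms <- function(target_db, decoy_db, truth, depth_per_sample,
                          decoy_fraction = 0.05, seed = 1L,
                          samples = c("exosome", "ectosome", "tenk", "wcl")) {
  if (nrow(target_db) == 0L) stop("empty target database")
  if (depth_per_sample < 100L) stop("depth_per_sample must be >= 100")
  if (decoy_fraction < 0 || decoy_fraction >= 0.5)
    stop("decoy_fraction must be in [0, 0.5)")
  set.seed(seed)
  wt_accs <- names(truth$base_abundance)
  mut_accs <- names(truth$mutant_secretion)
  wt_seqs <- target_db$sequence[match(wt_accs, target_db$accession)]
  # digest index: peptide -> accessions over the full target database
  idx <- peptide_index(target_db)
  decoy_idx <- peptide_index(decoy_db)
  # per-protein sampling pools
  wt_pool <- lapply(wt_seqs, function(s) {
    p <- digest(s, 1L)
    p[nchar(p) >= 7L & nchar(p) <= 35L]
  })
  names(wt_pool) <- wt_accs
  mut_pool <- lapply(mut_accs, function(a) {
    s <- target_db$sequence[target_db$accession == a]
    variant_spanning_peptides(s, wt_seqs)
  })
  names(mut_pool) <- mut_accs
  wt_len <- nchar(wt_seqs)

  out <- vector("list", length(samples))
  names(out) <- samples
  for (smp in samples) {
    ff <- fold_factor(truth, smp, wt_accs)
    rate <- truth$base_abundance * wt_len * ff
    mut_rate <- stats::setNames(rep(0, length(mut_accs)), mut_accs)
    for (a in mut_accs) {
      if (smp %in% truth$mutant_secretion[[a]])
        mut_rate[a] <- stats::median(rate[rate > 0]) * 0.25
    }
    rates <- c(rate, mut_rate)
    pools <- c(wt_pool, mut_pool)
    usable <- lengths(pools) > 0L & rates > 0
    rates[!usable] <- 0
    n_true <- round(depth_per_sample * (1 - decoy_fraction))
    counts <- stats::rmultinom(1L, n_true, rates / sum(rates))[, 1L]
    # draw a digest peptide per spectrum, protein by protein
    peptides <- character(n_true)
    pos <- 1L
    for (ai in which(counts > 0L)) {
      k <- counts[ai]
      pool <- pools[[names(counts)[ai]]]
      peptides[pos:(pos + k - 1L)] <-
        pool[sample.int(length(pool), k, replace = TRUE)]
      pos <- pos + k
    }
    scores <- stats::rnorm(n_true, 40, 6)
    # incorrect matches: half hit targets, half hit decoys
    n_inc <- depth_per_sample - n_true
    n_dec <- n_inc %/% 2L
    n_false_t <- n_inc - n_dec
    all_target_peps <- names(idx)
    all_decoy_peps <- names(decoy_idx)
    inc_t_pep <- if (n_false_t > 0L)
      sample(all_target_peps, n_false_t, replace = TRUE) else character()
    dec_pep <- if (n_dec > 0L)
      sample(all_decoy_peps, n_dec, replace = TRUE) else character()
    pep_all <- c(peptides, inc_t_pep, dec_pep)
    score_all <- c(scores, stats::rnorm(n_inc, 25, 6))
    acc_all <- c(unname(idx[match(c(peptides, inc_t_pep), names(idx))]),
                 unname(decoy_idx[match(dec_pep, names(decoy_idx))]))
    true_match <- c(rep(TRUE, n_true), rep(FALSE, n_inc))
    ord <- sample.int(length(pep_all))  # shuffle spectra
    is_dec <- vapply(strsplit(acc_all[ord], ";", fixed = TRUE),
                     function(a) all(startsWith(a, "rev_")), TRUE)
    out[[smp]] <- data.frame(
      spectrum_id = sprintf("%s_scan%06d", smp, seq_along(pep_all)),
      peptide = pep_all[ord], accessions = acc_all[ord],
      score = round(score_all[ord], 4), is_decoy = is_dec,
      sample_id = smp, true_match = true_match[ord],
      stringsAsFactors = FALSE)
    rownames(out[[smp]]) <- NULL
  }
  out
}

# A planted log2 fold f between exosome and ectosome is realized
# symmetrically (exosome x 2^(f/2), ectosome x 2^(-f/2)): the expected count
# ratio is 2^f while the per-sample rate sums stay close, which keeps the
# fixed-depth (compositional) normalization from attenuating observed ratios.
fold_factor <- function(truth, sample, wt_accs) {
  ff <- stats::setNames(rep(1, length(wt_accs)), wt_accs)
  if (sample == "exosome")
    ff <- 2 ^ (truth$planted_log2_fold[wt_accs] / 2)
  if (sample == "ectosome")
    ff <- 2 ^ (-truth$planted_log2_fold[wt_accs] / 2)
  excl <- truth$exclusive_proteins
  for (a in names(excl)) {
    if (sample %in% c("exosome", "ectosome") && excl[[a]] != sample)
      ff[a] <- 0
  }
  ff
}

# peptide -> semicolon-joined accessions, over tryptic peptides (<=1 missed
# cleavage, 7-35 aa) of every database protein
peptide_index <- function(db, min_len = 7L, max_len = 35L) {
  pep_lists <- lapply(db$sequence, function(s) {
    p <- unique(digest(s, 1L))
    p[nchar(p) >= min_len & nchar(p) <= max_len]
  })
  pep <- unlist(pep_lists, use.names = FALSE)
  acc <- rep(db$accession, lengths(pep_lists))
  tapply(acc, pep, function(a) paste(sort(unique(a)), collapse = ";"),
         simplify = TRUE)
}
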