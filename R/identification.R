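#' Peptide-level target-decoy FDR filter
#'
#' Collapses PSMs to the best-scoring match per peptide, sweeps thresholds at
#' the observed scores, and retains target peptides at the most permissive
#' (lowest) threshold whose estimated FDR (n_decoy / max(n_target, 1)) is
#' below `fdr_max`. Decoys never appear in the output. The returned PSMs are
#' all target PSMs of retained peptides (the spectra that feed spectral
#' counting), not just the collapsed best hits.
#'
#' @param psms PSM data.frame for one sample (see [read_psm_table()]).
#' @param fdr_max FDR ceiling (exclusive).
#' @return List with `psms` (retained target PSMs), `operating_point`
#'   (one-row data.frame: `score_threshold`, `n_target`, `n_decoy`, `fdr`)
#'   and `curve` (the full sweep, one row per candidate threshold).
#' @export
peptide_fdr_filter <- function(psms, fdr_max) {
  if (!any(!psms$is_decoy)) stop("no target PSMs", call. = FALSE)
  if (!any(psms$is_decoy)) {
    warning("no decoy PSMs: FDR treated as 0, all target peptides retained")
  }
  # best score per (peptide, decoy status)
  key <- paste(psms$peptide, psms$is_decoy)
  best <- tapply(psms$score, key, max)
  is_dec <- grepl("TRUE$", names(best))
  score <- as.numeric(best)
  # sweep thresholds at the observed scores (cumulative counts, high to low)
  o <- order(score, decreasing = TRUE)
  s_sorted <- score[o]
  d_sorted <- is_dec[o]
  runs <- rle(s_sorted)
  last_idx <- cumsum(runs$lengths)
  thr <- runs$values
  n_target <- cumsum(!d_sorted)[last_idx]
  n_decoy <- cumsum(d_sorted)[last_idx]
  fdr <- n_decoy / pmax(n_target, 1L)
  curve <- data.frame(score_threshold = thr, n_target = n_target,
                      n_decoy = n_decoy, fdr = fdr)
  ok <- which(fdr < fdr_max)
  if (length(ok) == 0L) {
    op <- data.frame(score_threshold = Inf, n_target = 0L, n_decoy = 0L,
                     fdr = 0)
    return(list(psms = psms[0L, , drop = FALSE], operating_point = op,
                curve = curve))
  }
  pick <- max(ok)  # most permissive qualifying threshold
  op <- curve[pick, , drop = FALSE]
  rownames(op) <- NULL
  retained_peps <- names(best)[!is_dec & score >= op$score_threshold]
  retained_peps <- sub(" FALSE$", "", retained_peps)
  keep <- !psms$is_decoy & psms$peptide %in% retained_peps
  list(psms = psms[keep, , drop = FALSE], operating_point = op,
       curve = curve)
}

#' Infer identified proteins from retained PSMs
#'
#' A peptide is unique iff it maps to exactly one accession in the combined
#' search database (as recorded in the PSM's accession set). Proteins with at
#' least `min_unique` unique peptides are retained; their significant
#' spectral count includes all their spectra, unique and shared.
#'
#' @param psms Retained target PSMs of one sample.
#' @param min_unique Minimum distinct unique peptides.
#' @return data.frame with `accession`, `sample_id`, `n_unique_peptides`,
#'   `n_significant_spectra`, sorted by accession.
#' @export
infer_proteins <- function(psms, min_unique = 2L) {
  if (nrow(psms) == 0L)
    return(data.frame(accession = character(), sample_id = character(),
                      n_unique_peptides = integer(),
                      n_significant_spectra = integer(),
                      stringsAsFactors = FALSE))
  if (any(psms$is_decoy)) stop("infer_proteins expects target-only PSMs")
  accs <- strsplit(psms$accessions, ";", fixed = TRUE)
  is_unique <- lengths(accs) == 1L
  # spectra tally: every PSM counts toward every mapped accession
  spectra <- table(unlist(accs))
  # unique-peptide tally: distinct unique peptides per accession
  upep <- unique(data.frame(acc = unlist(accs[is_unique]),
                            pep = rep(psms$peptide[is_unique],
                                      lengths(accs[is_unique])),
                            stringsAsFactors = FALSE))
  n_unique <- table(upep$acc)
  keep <- sort(names(n_unique)[n_unique >= min_unique])
  if (length(keep) == 0L)
    return(data.frame(accession = character(), sample_id = character(),
                      n_unique_peptides = integer(),
                      n_significant_spectra = integer(),
                      stringsAsFactors = FALSE))
  data.frame(accession = keep, sample_id = psms$sample_id[1L],
             n_unique_peptides = as.integer(n_unique[keep]),
             n_significant_spectra = as.integer(spectra[keep]),
             stringsAsFactors = FALSE)
}

#' Call mutant proteins with variant-spanning evidence
#'
#' An identified mutant entry is called iff at least one of its retained
#' peptides covers a variant-altered residue (any peptide, for frameshift /
#' six-frame window fragments) and that peptide is not a substring of any
#' wild-type protein.
#'
#' @param identified Output of [infer_proteins()] for one sample.
#' @param psms The retained PSMs the identifications came from.
#' @param mutant_db Mutant entry table from [build_database()].
#' @param wildtype_db Wild-type protein table.
#' @return data.frame with `accession`, `sample_id`, `gene`, `kind` and
#'   `evidence_peptides` (semicolon-joined) for called mutants.
#' @export
call_mutants <- function(identified, psms, mutant_db, wildtype_db) {
  mut_idents <- identified[identified$accession %in% mutant_db$accession |
                           startsWith(identified$accession, "mut|"), ,
                           drop = FALSE]
  missing <- setdiff(mut_idents$accession, mutant_db$accession)
  if (length(missing))
    stop("mutant accession(s) absent from database: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- list()
  accs_list <- strsplit(psms$accessions, ";", fixed = TRUE)
  for (acc in mut_idents$accession) {
    e <- mutant_db[mutant_db$accession == acc, , drop = FALSE]
    hit <- vapply(accs_list, function(a) acc %in% a, TRUE)
    peps <- unique(psms$peptide[hit])
    if (length(peps) == 0L) next
    novel <- vapply(peps, function(p)
      !any(grepl(p, wildtype_db$sequence, fixed = TRUE)), TRUE)
    peps <- peps[novel]
    if (e$frame == "substitution" && !is.na(e$aa_pos)) {
      covers <- vapply(peps, function(p) {
        at <- regexpr(p, e$sequence, fixed = TRUE)
        at > 0L && e$aa_pos >= at && e$aa_pos <= at + nchar(p) - 1L
      }, TRUE)
      peps <- peps[covers]
    }
    if (length(peps) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      accession = acc, sample_id = mut_idents$sample_id[1L], gene = e$gene,
      kind = e$kind, evidence_peptides = paste(sort(peps), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(accession = character(), sample_id = character(),
                      gene = character(), kind = character(),
                      evidence_peptides = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-set Venn counts
#'
#' @param list_a,list_b Character vectors of accessions (duplicates ignored).
#' @return Named list: `only_a`, `only_b`, `common`, `exclusive_total`
#'   (= `only_a + only_b`).
#' @export
venn_counts <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  common <- length(intersect(a, b))
  venn_from_counts(length(a), length(b), common)
}

#' Venn arithmetic from set sizes
#'
#' @param n_a,n_b Set sizes.
#' @param n_common Size of the intersection.
#' @return Named list: `only_a`, `only_b`, `common`, `exclusive_total`
#'   (= |A| + |B| - 2|A∩B|).
#' @export
venn_from_counts <- function(n_a, n_b, n_common) {
  stopifnot(n_common <= n_a, n_common <= n_b)
  list(only_a = n_a - n_common, only_b = n_b - n_common, common = n_common,
       exclusive_total = n_a + n_b - 2L * n_common)
}

#' Assemble a protein-by-sample count matrix
#'
#' @param identified_list Named list (by sample) of [infer_proteins()]
#'   outputs.
#' @param totals Named integer vector of per-sample total significant spectra
#'   (all retained PSMs, including those of proteins filtered out by the
#'   unique-peptide rule). Because a shared spectrum counts toward every
#'   protein it maps to, a column sum can exceed its total; each total must
#'   still be at least the largest single protein count in its sample.
#' @return List of class `count_matrix`: `counts` (protein × sample integer
#'   matrix), `totals`.
#' @export
count_matrix <- function(identified_list, totals) {
  samples <- names(identified_list)
  stopifnot(!is.null(samples), all(samples %in% names(totals)))
  proteins <- sort(unique(unlist(lapply(identified_list,
                                        `[[`, "accession"))))
  m <- matrix(0L, nrow = length(proteins), ncol = length(samples),
              dimnames = list(proteins, samples))
  for (smp in samples) {
    id <- identified_list[[smp]]
    m[id$accession, smp] <- id$n_significant_spectra
  }
  totals <- as.integer(totals[samples])
  names(totals) <- samples
  if (length(proteins) && any(apply(m, 2L, max) > totals))
    stop("totals smaller than a protein's spectral count")
  structure(list(counts = m, totals = totals), class = "count_matrix")
}
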