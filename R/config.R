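#' Pipeline configuration
#'
#' Collects the tunable thresholds of the pipeline. Defaults reproduce the
#' standard operating point of label-free EV proteogenomics: 150-nt INDEL
#' windows, spectral-count correction factor c = 1.25, peptide-level FDR
#' below 0.5\%, at least 2 unique peptides per protein, a 2-fold differential
#' threshold and chi-square enrichment at alpha = 0.05.
#'
#' @param flank_nt Nucleotides of reference sequence fetched on each side of
#'   an INDEL before six-frame translation ("up to": truncated at sequence
#'   ends).
#' @param spectral_correction_c Additive correction factor c of the RSc
#'   formula; keeps ratios finite when a spectral count is zero.
#' @param peptide_fdr_max Peptide-level target-decoy FDR ceiling (exclusive).
#' @param min_unique_peptides Minimum number of unique peptides for a protein
#'   to be retained.
#' @param fold_change_min Minimum |signed RSc| for a differential call.
#' @param enrichment_alpha Raw-p significance level for category enrichment.
#' @param min_fragment_aa Minimum length (residues) of a six-frame fragment
#'   kept in the mutant database.
#' @param ratio_orientation `"as_printed"` keeps the literal direction of the
#'   RSc formula (numerator carries the second sample's count, so
#'   signed ratio >= threshold means "up in y"); `"flipped"` swaps the
#'   reported direction labels.
#' @param rng_seed Integer seed recorded in run manifests and used by any
#'   stage that draws random numbers.
#' @return A list of class `vesiprot_config`.
#' @export
vesiprot_config <- function(flank_nt = 150L,
                            spectral_correction_c = 1.25,
                            peptide_fdr_max = 0.005,
                            min_unique_peptides = 2L,
                            fold_change_min = 2,
                            enrichment_alpha = 0.05,
                            min_fragment_aa = 7L,
                            ratio_orientation = c("as_printed", "flipped"),
                            rng_seed = 1L) {
  ratio_orientation <- match.arg(ratio_orientation)
  cfg <- list(
    flank_nt = as.integer(flank_nt),
    spectral_correction_c = as.numeric(spectral_correction_c),
    peptide_fdr_max = as.numeric(peptide_fdr_max),
    min_unique_peptides = as.integer(min_unique_peptides),
    fold_change_min = as.numeric(fold_change_min),
    enrichment_alpha = as.numeric(enrichment_alpha),
    min_fragment_aa = as.integer(min_fragment_aa),
    ratio_orientation = ratio_orientation,
    rng_seed = as.integer(rng_seed)
  )
  num <- c("flank_nt", "spectral_correction_c", "peptide_fdr_max",
           "min_unique_peptides", "fold_change_min", "enrichment_alpha",
           "min_fragment_aa")
  for (k in num) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config: '", k, "' must be strictly positive", call. = FALSE)
  }
  if (cfg$peptide_fdr_max >= 1)
    stop("config: 'peptide_fdr_max' must be < 1", call. = FALSE)
  if (cfg$fold_change_min < 1)
    stop("config: 'fold_change_min' must be >= 1", call. = FALSE)
  class(cfg) <- "vesiprot_config"
  cfg
}

#' Write a configuration as a flat key=value text file
#' @param config A `vesiprot_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vesiprot_config"))
  writeLines(paste0(names(config), "=", vapply(config, as.character, "")),
             path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path Input path.
#' @return A `vesiprot_config`.
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  do.call(vesiprot_config, as.list(vals))
}
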