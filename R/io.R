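NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "*", "X")

#' Read a FASTA file into a sequence table
#'
#' @param path FASTA file.
#' @param type `"auto"` guesses per record; `"nt"`/`"aa"` enforce the
#'   nucleotide (ACGTN) or protein alphabet.
#' @return A data.frame with columns `accession` (first whitespace-delimited
#'   token of the header), `description` (remainder, possibly `""`) and
#'   `sequence` (uppercased). Zero rows for an empty file.
#' @export
read_fasta <- function(path, type = c("auto", "nt", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) {
    return(data.frame(accession = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(as.character(set))
  if (any(!nzchar(sequence)))
    stop("FASTA record with empty sequence: ",
         accession[!nzchar(sequence)][1L], call. = FALSE)
  check_alphabet(sequence, accession, type)
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE)
}

check_alphabet <- function(sequence, accession, type) {
  if (type == "auto") return(invisible())
  alpha <- if (type == "nt") NT_ALPHABET else AA_ALPHABET
  pat <- paste0("[^", paste(alpha, collapse = ""), "]")
  bad <- grepl(pat, sequence, fixed = FALSE)
  if (any(bad)) {
    ch <- regmatches(sequence[bad][1L], regexpr(pat, sequence[bad][1L]))
    stop("illegal ", if (type == "nt") "nucleotide" else "residue",
         " character '", ch, "' in record '", accession[bad][1L], "'",
         call. = FALSE)
  }
  invisible()
}

#' Write a sequence table as FASTA
#'
#' Protein sequences must not contain `*`: stop markers are internal only and
#' are never written to protein FASTA output.
#'
#' @param records data.frame with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("accession", "sequence") %in% names(records)))
  if (any(grepl("*", records$sequence, fixed = TRUE)))
    stop("refusing to write '*' (internal stop marker) to FASTA output",
         call. = FALSE)
  desc <- if ("description" %in% names(records)) records$description
          else character(nrow(records))
  header <- ifelse(nzchar(desc),
                   paste0(">", records$accession, " ", desc),
                   paste0(">", records$accession))
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    substring(s, seq(1L, nchar(s), width),
              pmin(seq(width, nchar(s) + width - 1L, width), nchar(s)))
  }
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(header[i], wrap(records$sequence[i])), con, sep = "\n")
  }
  invisible(path)
}

#' Normalize a variant to its minimal allele representation
#'
#' Left-trims the common prefix of `ref`/`alt` (advancing `pos`), then
#' right-trims the common suffix, so that anchored-base VCF INDELs and
#' already-minimal representations become identical. Idempotent.
#'
#' @param chrom,pos,ref,alt Parallel vectors; `pos` is the 1-based position of
#'   the first reference base of `ref`.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `vtype`
#'   (`SNV`/`INS`/`DEL`). After normalization an insertion has `ref == ""`
#'   (inserted before `pos`) and a deletion has `alt == ""` (deleting
#'   `pos .. pos+nchar(ref)-1`).
#' @export
normalize_variants <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # left-trim shared prefix
    while (nchar(r) > 0L && nchar(a) > 0L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substring(r, 2L); a <- substring(a, 2L); p <- p + 1L
    }
    # right-trim shared suffix
    while (nchar(r) > 0L && nchar(a) > 0L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L); a <- substr(a, 1L, nchar(a) - 1L)
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  vtype <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
           ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  bad <- nchar(ref) == nchar(alt) & nchar(ref) != 1L
  if (any(bad))
    stop("unsupported multi-nucleotide substitution at ",
         chrom[bad][1L], ":", pos[bad][1L], call. = FALSE)
  same <- vtype == "SNV" & ref == alt
  if (any(same))
    stop("ref == alt after normalization at ", chrom[same][1L], ":",
         pos[same][1L], call. = FALSE)
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             vtype = vtype, stringsAsFactors = FALSE)
}

#' Read a coding-variant table
#'
#' Accepts a TSV with header columns `chrom`, `pos`, `ref`, `alt` (extra
#' columns such as `zygosity` are carried through). VCF-style anchored-base
#' INDEL encoding is accepted and normalized to the minimal representation.
#'
#' @param path TSV file.
#' @return data.frame of variants with inferred `vtype`.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("variant table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L)
    return(cbind(normalize_variants(character(), integer(), character(),
                                    character())))
  if (any(is.na(suppressWarnings(as.integer(tab$pos)))))
    stop("non-integer pos in variant table '", path, "'", call. = FALSE)
  if (any(grepl("[^ACGTacgt]", paste0(tab$ref, tab$alt))))
    stop("non-ACGT characters in ref/alt alleles of '", path, "'",
         call. = FALSE)
  out <- normalize_variants(tab$chrom, tab$pos, tab$ref, tab$alt)
  extra <- setdiff(names(tab), need)
  for (k in extra) out[[k]] <- tab[[k]]
  out
}

#' Read a peptide-spectrum-match table
#'
#' Expects a TSV with columns `spectrum_id`, `peptide`, `accessions`
#' (semicolon-joined protein accessions) and `score` (higher = better).
#' Peptides are uppercased and stripped of modification annotations to the
#' bare residue sequence. A PSM is flagged decoy only if *all* its accessions
#' carry the `rev_` prefix; mixed target/decoy hits count as target.
#'
#' @param path TSV file.
#' @param sample_id Sample identifier attached to every row.
#' @return data.frame with columns `spectrum_id`, `peptide`, `accessions`
#'   (semicolon-joined string), `score`, `is_decoy`, `sample_id`.
#' @export
read_psm_table <- function(path, sample_id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "peptide", "accessions", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("PSM table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) {
    warning("PSM table '", path, "' is empty")
    return(data.frame(spectrum_id = character(), peptide = character(),
                      accessions = character(), score = numeric(),
                      is_decoy = logical(), sample_id = character(),
                      stringsAsFactors = FALSE))
  }
  # strip modification annotations: bracketed groups, then residual symbols
  peptide <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", tab$peptide)
  peptide <- toupper(gsub("[^A-Za-z]", "", peptide))
  if (any(!nzchar(peptide)))
    stop("empty peptide sequence in '", path, "'", call. = FALSE)
  accs <- strsplit(as.character(tab$accessions), ";", fixed = TRUE)
  if (any(lengths(accs) == 0L))
    stop("PSM without protein accessions in '", path, "'", call. = FALSE)
  is_decoy <- vapply(accs, function(a) all(startsWith(a, "rev_")), TRUE)
  dup <- duplicated(tab$spectrum_id)
  if (any(dup))
    warning(sum(dup), " duplicated spectrum_id value(s) in '", path,
            "' (all rows retained)")
  data.frame(spectrum_id = as.character(tab$spectrum_id), peptide = peptide,
             accessions = as.character(tab$accessions),
             score = as.numeric(tab$score), is_decoy = is_decoy,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Read transcript models from the annotation TSV
#'
#' The annotation format is a TSV with columns `transcript_id`, `gene_symbol`,
#' `chrom`, `strand` and `cds_segments` (semicolon-joined `start-end` pairs,
#' 1-based inclusive genomic coordinates, sorted by genomic start). The
#' spliced coding sequence is reconstructed from the chromosome sequences.
#'
#' @param path Annotation TSV.
#' @param chrom_seqs Named character vector of chromosome sequences.
#' @return List of transcript models (see [transcript_model()]).
#' @export
read_transcript_models <- function(path, chrom_seqs) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_symbol", "chrom", "strand", "cds_segments")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    segs <- do.call(rbind, lapply(
      strsplit(tab$cds_segments[i], ";", fixed = TRUE)[[1L]],
      function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])))
    chrom <- tab$chrom[i]
    if (!chrom %in% names(chrom_seqs))
      stop("annotation references unknown chromosome '", chrom, "'",
           call. = FALSE)
    cds <- spliced_cds(chrom_seqs[[chrom]], segs, tab$strand[i])
    transcript_model(tab$transcript_id[i], tab$gene_symbol[i], chrom,
                     tab$strand[i], segs, cds)
  })
}

#' Write transcript models as the annotation TSV
#' @param models List of transcript models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_models <- function(models, path) {
  tab <- data.frame(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    gene_symbol = vapply(models, `[[`, "", "gene_symbol"),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    cds_segments = vapply(models, function(m)
      paste(paste0(m$cds_segments[, 1L], "-", m$cds_segments[, 2L]),
            collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}

# TSV writer used for every tabular output: tab-separated, no quoting, no
# row names, "\n" line endings regardless of platform (byte reproducibility).
write_tsv <- function(tab, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
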