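#' Construct a transcript model
#'
#' Links genomic coordinates to coding-sequence coordinates. `cds_segments`
#' are 1-based inclusive genomic intervals, non-overlapping and sorted by
#' genomic start; on the minus strand the transcript reads the segments in
#' reverse genomic order, reverse-complemented. `cds_sequence` is the spliced
#' coding sequence on the sense (transcript) strand, beginning with the start
#' codon and ending with a stop codon.
#'
#' @param transcript_id,gene_symbol,chrom,strand Identifiers; `strand` is
#'   `"+"` or `"-"`.
#' @param cds_segments Two-column integer matrix of (start, end) rows.
#' @param cds_sequence Spliced coding nucleotide string.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_symbol, chrom, strand,
                             cds_segments, cds_sequence) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds_segments <- matrix(as.integer(cds_segments), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  if (is.unsorted(cds_segments[, 1L], strictly = TRUE) &&
      nrow(cds_segments) > 1L)
    stop("cds_segments must be sorted by genomic start")
  if (any(cds_segments[, 2L] < cds_segments[, 1L]))
    stop("cds_segment end before start")
  if (nrow(cds_segments) > 1L &&
      any(cds_segments[-1L, 1L] <= cds_segments[-nrow(cds_segments), 2L]))
    stop("cds_segments overlap")
  seg_len <- sum(cds_segments[, 2L] - cds_segments[, 1L] + 1L)
  cds_sequence <- toupper(cds_sequence)
  if (seg_len != nchar(cds_sequence))
    stop("segment lengths (", seg_len, ") do not match cds_sequence length (",
         nchar(cds_sequence), ")")
  if (nchar(cds_sequence) %% 3L != 0L)
    stop("cds_sequence length not divisible by 3")
  structure(list(transcript_id = transcript_id, gene_symbol = gene_symbol,
                 chrom = chrom, strand = strand, cds_segments = cds_segments,
                 cds_sequence = cds_sequence),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$gene_symbol, ") ",
      x$chrom, x$strand, " ", nrow(x$cds_segments), " CDS segment(s), ",
      nchar(x$cds_sequence), " nt\n", sep = "")
  invisible(x)
}

# Splice the CDS out of a chromosome sequence for given segments and strand.
spliced_cds <- function(chrom_seq, segments, strand) {
  pieces <- substring(chrom_seq, segments[, 1L], segments[, 2L])
  s <- paste(pieces, collapse = "")
  if (strand == "-") s <- revcomp(s) else s
}

#' Reverse-complement a nucleotide string
#' @param s Nucleotide string over ACGTN.
#' @return The reverse complement.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate a nucleotide string with the standard code
#'
#' Trailing bases short of a codon are dropped; codons containing `N`
#' translate to `X`; stop codons translate to `*`.
#' @param s Nucleotide string over ACGTN.
#' @return Amino-acid string (possibly empty).
#' @export
translate_nt <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codon contains N
  paste(aa, collapse = "")
}

#' Map a genomic position into CDS coordinates
#'
#' @param model A `transcript_model`.
#' @param gpos 1-based genomic position.
#' @return 1-based position in `cds_sequence`, or `NA_integer_` if `gpos`
#'   falls outside every CDS segment.
#' @export
genomic_to_cds <- function(model, gpos) {
  segs <- model$cds_segments
  widths <- segs[, 2L] - segs[, 1L] + 1L
  hit <- which(gpos >= segs[, 1L] & gpos <= segs[, 2L])
  if (length(hit) == 0L) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    as.integer(before + (gpos - segs[hit, 1L] + 1L))
  } else {
    # transcript order is reverse genomic order
    n <- nrow(segs)
    after <- if (hit < n) sum(widths[seq(hit + 1L, n)]) else 0L
    as.integer(after + (segs[hit, 2L] - gpos + 1L))
  }
}

#' Map a CDS position back to genomic coordinates
#' @param model A `transcript_model`.
#' @param cpos 1-based position in `cds_sequence`.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(model, cpos) {
  segs <- model$cds_segments
  widths <- segs[, 2L] - segs[, 1L] + 1L
  if (cpos < 1L || cpos > sum(widths)) stop("cds position out of range")
  order_idx <- if (model$strand == "+") seq_len(nrow(segs)) else
    rev(seq_len(nrow(segs)))
  left <- cpos
  for (i in order_idx) {
    if (left <= widths[i]) {
      return(if (model$strand == "+") as.integer(segs[i, 1L] + left - 1L)
             else as.integer(segs[i, 2L] - left + 1L))
    }
    left <- left - widths[i]
  }
}

#' Translate the coding sequences of transcript models into proteins
#'
#' The terminal stop codon is removed; an error is raised if a model contains
#' an internal stop (annotation/sequence mismatch).
#'
#' @param models List of transcript models.
#' @return data.frame with `accession` (transcript id), `description`
#'   (gene symbol) and `sequence` columns — the wild-type protein database.
#' @export
wildtype_proteins <- function(models) {
  seqs <- vapply(models, function(m) {
    p <- translate_nt(m$cds_sequence)
    if (substr(p, nchar(p), nchar(p)) == "*") p <- substr(p, 1L, nchar(p) - 1L)
    if (grepl("*", p, fixed = TRUE))
      stop("internal stop codon in ", m$transcript_id)
    p
  }, "")
  data.frame(accession = vapply(models, `[[`, "", "transcript_id"),
             description = vapply(models, `[[`, "", "gene_symbol"),
             sequence = seqs, stringsAsFactors = FALSE)
}
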