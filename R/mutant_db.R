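#' Call the coding consequence of a variant on one transcript
#'
#' SNV positions are mapped through the CDS segments honoring strand
#' (minus-strand alleles are reverse-complemented) and the affected codon is
#' retranslated with the standard code. INDELs are classified frameshift when
#' the length change is not a multiple of 3. A variant outside every CDS
#' segment (or on another chromosome) is `noncoding`, not an error.
#'
#' @param variant One-row variant data.frame (normalized; see
#'   [normalize_variants()]).
#' @param model A `transcript_model`.
#' @return A list of class `consequence` with fields `kind` (`synonymous`,
#'   `missense`, `stop_gain`, `stop_loss`, `frameshift`, `inframe_indel` or
#'   `noncoding`), `cds_pos`, and for point changes `aa_pos`, `ref_aa`,
#'   `alt_aa`.
#' @export
call_consequence <- function(variant, model) {
  stopifnot(inherits(model, "transcript_model"))
  v <- as.list(variant[1L, c("chrom", "pos", "ref", "alt", "vtype")])
  v$pos <- as.integer(v$pos)
  mk <- function(kind, cds_pos = NA_integer_, aa_pos = NA_integer_,
                 ref_aa = NA_character_, alt_aa = NA_character_) {
    structure(list(variant = v, transcript_id = model$transcript_id,
                   kind = kind, cds_pos = cds_pos, aa_pos = aa_pos,
                   ref_aa = ref_aa, alt_aa = alt_aa), class = "consequence")
  }
  if (v$chrom != model$chrom) return(mk("noncoding"))

  if (v$vtype == "SNV") {
    cpos <- genomic_to_cds(model, v$pos)
    if (is.na(cpos)) return(mk("noncoding"))
    ref <- v$ref; alt <- v$alt
    if (model$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
    if (substr(model$cds_sequence, cpos, cpos) != ref)
      stop("reference mismatch for ", v$chrom, ":", v$pos, " on ",
           model$transcript_id, ": CDS has '",
           substr(model$cds_sequence, cpos, cpos), "', variant ref is '",
           ref, "'", call. = FALSE)
    aa_pos <- (cpos - 1L) %/% 3L + 1L
    cstart <- (aa_pos - 1L) * 3L + 1L
    codon <- substr(model$cds_sequence, cstart, cstart + 2L)
    off <- cpos - cstart + 1L
    mcodon <- codon
    substr(mcodon, off, off) <- alt
    ref_aa <- translate_nt(codon)
    alt_aa <- translate_nt(mcodon)
    kind <- if (ref_aa == alt_aa) "synonymous"
            else if (alt_aa == "*") "stop_gain"
            else if (ref_aa == "*") "stop_loss"
            else "missense"
    return(mk(kind, cpos, aa_pos, ref_aa, alt_aa))
  }

  # INDEL: coding if the affected position (deleted bases, or the insertion
  # point) touches a CDS segment
  if (v$vtype == "DEL") {
    span <- v$pos:(v$pos + nchar(v$ref) - 1L)
    cpos <- NA_integer_
    for (p in span) {
      cpos <- genomic_to_cds(model, p)
      if (!is.na(cpos)) break
    }
  } else {
    # insertion before v$pos: coding if either flanking base is in the CDS
    cpos <- genomic_to_cds(model, v$pos)
    if (is.na(cpos)) cpos <- genomic_to_cds(model, v$pos - 1L)
  }
  if (is.na(cpos)) return(mk("noncoding"))
  shift <- abs(nchar(v$alt) - nchar(v$ref))
  mk(if (shift %% 3L != 0L) "frameshift" else "inframe_indel", cpos)
}

#' Build a substitution mutant-database entry from a point consequence
#'
#' Missense consequences yield the full-length protein with the single
#' substitution; stop gains yield the protein truncated before the new stop;
#' stop losses append the alternate residue at the former stop position
#' (models carry no sequence beyond the stop codon to read through).
#' Synonymous or noncoding consequences yield `NULL`.
#'
#' @param consequence A `consequence`.
#' @param wildtype_protein Wild-type protein string of the same transcript
#'   (no terminal `*`).
#' @return Mutant protein string, or `NULL` when no entry is warranted.
#' @export
build_snv_entry <- function(consequence, wildtype_protein) {
  k <- consequence$kind
  if (!k %in% c("missense", "stop_gain", "stop_loss")) return(NULL)
  aa_pos <- consequence$aa_pos
  if (k == "stop_loss") {
    if (aa_pos != nchar(wildtype_protein) + 1L)
      stop("stop_loss consequence not at the stop position of the wild-type",
           call. = FALSE)
    return(paste0(wildtype_protein, consequence$alt_aa))
  }
  if (aa_pos > nchar(wildtype_protein))
    stop("aa_pos ", aa_pos, " outside wild-type protein of length ",
         nchar(wildtype_protein), " (annotation/sequence mismatch)",
         call. = FALSE)
  if (substr(wildtype_protein, aa_pos, aa_pos) != consequence$ref_aa)
    stop("wild-type residue mismatch at position ", aa_pos,
         " (annotation/sequence mismatch)", call. = FALSE)
  if (k == "stop_gain") return(substr(wildtype_protein, 1L, aa_pos - 1L))
  s <- wildtype_protein
  substr(s, aa_pos, aa_pos) <- consequence$alt_aa
  s
}

#' Extract the mutant-allele window around an INDEL
#'
#' Fetches up to `flank_nt` reference bases upstream of the variant, splices
#' in the alternate allele, and appends up to `flank_nt` reference bases
#' downstream; flanks are truncated at the sequence ends.
#'
#' @param chrom_sequence Reference sequence the variant is positioned on.
#' @param variant One-row normalized variant (INS or DEL).
#' @param flank_nt Flank length (>= 1).
#' @return The mutant nucleotide window.
#' @export
indel_window <- function(chrom_sequence, variant, flank_nt) {
  v <- as.list(variant[1L, ])
  v$pos <- as.integer(v$pos)
  stopifnot(v$vtype %in% c("INS", "DEL"), flank_nt >= 1L)
  L <- nchar(chrom_sequence)
  ref_len <- nchar(v$ref)
  if (ref_len > 0L &&
      substr(chrom_sequence, v$pos, v$pos + ref_len - 1L) != v$ref)
    stop("reference mismatch at ", v$chrom, ":", v$pos, ": sequence has '",
         substr(chrom_sequence, v$pos, v$pos + ref_len - 1L),
         "', variant ref is '", v$ref, "'", call. = FALSE)
  up_start <- max(1L, v$pos - as.integer(flank_nt))
  up <- if (v$pos > 1L) substr(chrom_sequence, up_start, v$pos - 1L) else ""
  down_from <- v$pos + ref_len
  down_to <- min(L, v$pos + ref_len - 1L + as.integer(flank_nt))
  down <- if (down_from <= down_to)
    substr(chrom_sequence, down_from, down_to) else ""
  paste0(up, v$alt, down)
}

#' Six-frame translation split at stop codons
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement with the standard code, splits each translation at stop codons,
#' and keeps fragments of at least `min_fragment_aa` residues. Codons
#' containing `N` translate to `X`.
#'
#' @param nt_sequence Nucleotide string over ACGTN.
#' @param min_fragment_aa Minimum fragment length retained.
#' @return Named list of six character vectors (`F1`,`F2`,`F3` forward;
#'   `R1`,`R2`,`R3` on the reverse complement), each the surviving fragments
#'   of that frame in order.
#' @export
six_frame_translate <- function(nt_sequence, min_fragment_aa = 7L) {
  rc <- revcomp(nt_sequence)
  one <- function(s, off) {
    aa <- translate_nt(substring(s, off))
    frag <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    frag[nchar(frag) >= min_fragment_aa]
  }
  list(F1 = one(nt_sequence, 1L), F2 = one(nt_sequence, 2L),
       F3 = one(nt_sequence, 3L),
       R1 = one(rc, 1L), R2 = one(rc, 2L), R3 = one(rc, 3L))
}

#' Generate reversed-sequence decoys
#'
#' @param records Sequence table (`accession`, `sequence`).
#' @return Sequence table of reversed sequences with `rev_`-prefixed
#'   accessions.
#' @export
make_decoys <- function(records) {
  rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                            collapse = "")
  data.frame(accession = paste0("rev_", records$accession),
             description = "decoy",
             sequence = vapply(records$sequence, rev1, "", USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Build the customized mutant protein database
#'
#' For every qualifying coding SNV and every overlapping transcript, emits a
#' full-length substitution entry; for every coding INDEL, emits one entry per
#' surviving six-frame window fragment. Decoys (reversed sequences, `rev_`
#' prefix) are generated for the combined wild-type + mutant database.
#'
#' @param variants Normalized variant table.
#' @param models List of transcript models.
#' @param chrom_seqs Named character vector of chromosome sequences.
#' @param config A `vesiprot_config` (uses `flank_nt`, `min_fragment_aa`).
#' @param continue_on_error Log and skip variants with reference mismatches
#'   instead of aborting.
#' @return List with `mutant` (data.frame: `accession`, `sequence`, `gene`,
#'   `transcript_id`, `chrom`, `pos`, `ref`, `alt`, `kind`, `frame`,
#'   `aa_pos`, `wt_accession`), and `decoy` (sequence table for wild-type +
#'   mutant entries).
#' @export
build_database <- function(variants, models, chrom_seqs,
                           config = vesiprot_config(),
                           continue_on_error = FALSE) {
  wt <- wildtype_proteins(models)
  rows <- list()
  errors <- character()
  model_chroms <- vapply(models, `[[`, "", "chrom")
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    overlapping <- models[model_chroms == v$chrom]
    res <- tryCatch(
      variant_entries(v, overlapping, chrom_seqs, wt, config),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      if (!continue_on_error) stop(res, call. = FALSE)
      errors <- c(errors, res)
      next
    }
    rows <- c(rows, res)
  }
  if (length(errors))
    warning("skipped ", length(errors), " variant(s): ",
            paste(errors, collapse = "; "))
  mutant <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), sequence = character(),
               gene = character(), transcript_id = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), kind = character(), frame = character(),
               aa_pos = integer(), wt_accession = character(),
               stringsAsFactors = FALSE)
  rownames(mutant) <- NULL
  target <- rbind(wt[, c("accession", "sequence")],
                  mutant[, c("accession", "sequence")])
  list(mutant = mutant, decoy = make_decoys(target))
}

# Entries for one variant across its overlapping transcripts.
variant_entries <- function(v, overlapping, chrom_seqs, wt, config) {
  rows <- list()
  vid <- sprintf("%s:%d:%s>%s", v$chrom, as.integer(v$pos),
                 ifelse(nzchar(v$ref), v$ref, "-"),
                 ifelse(nzchar(v$alt), v$alt, "-"))
  if (v$vtype == "SNV") {
    for (m in overlapping) {
      cons <- call_consequence(v, m)
      if (!cons$kind %in% c("missense", "stop_gain", "stop_loss")) next
      wt_seq <- wt$sequence[wt$accession == m$transcript_id]
      entry <- build_snv_entry(cons, wt_seq)
      if (is.null(entry) || !nzchar(entry)) next
      rows[[length(rows) + 1L]] <- data.frame(
        accession = paste("mut", m$gene_symbol, m$transcript_id, vid, "sub",
                          sep = "|"),
        sequence = entry, gene = m$gene_symbol,
        transcript_id = m$transcript_id, chrom = v$chrom,
        pos = as.integer(v$pos), ref = v$ref, alt = v$alt, kind = cons$kind,
        frame = "substitution", aa_pos = cons$aa_pos,
        wt_accession = m$transcript_id, stringsAsFactors = FALSE)
    }
    return(rows)
  }
  # INDEL: one entry per surviving window frame fragment (genomic window,
  # emitted once per variant; the first overlapping transcript with a coding
  # consequence lends gene/transcript labels to the accession)
  coding <- NULL
  for (m in overlapping) {
    cons <- call_consequence(v, m)
    if (cons$kind %in% c("frameshift", "inframe_indel")) { coding <- m; break }
  }
  if (is.null(coding)) return(rows)
  win <- indel_window(chrom_seqs[[v$chrom]], v, config$flank_nt)
  frames <- six_frame_translate(win, config$min_fragment_aa)
  kind <- call_consequence(v, coding)$kind
  for (fr in names(frames)) {
    frags <- frames[[fr]]
    for (j in seq_along(frags)) {
      rows[[length(rows) + 1L]] <- data.frame(
        accession = paste("mut", coding$gene_symbol, coding$transcript_id,
                          vid, paste0(fr, ".", j), sep = "|"),
        sequence = frags[j], gene = coding$gene_symbol,
        transcript_id = coding$transcript_id, chrom = v$chrom,
        pos = as.integer(v$pos), ref = v$ref, alt = v$alt, kind = kind,
        frame = fr, aa_pos = NA_integer_,
        wt_accession = coding$transcript_id, stringsAsFactors = FALSE)
    }
  }
  rows
}
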