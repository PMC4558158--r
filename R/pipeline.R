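#' Write a complete synthetic study bundle to disk
#'
#' Generates a toy reference transcriptome, spikes coding variants, builds
#' the mutant + decoy databases, plants abundances/fold changes/exclusive
#' proteins/secreted mutants, simulates per-compartment PSM streams, and
#' writes everything as the plain-text formats the pipeline consumes
#' (reference FASTA, annotation TSV, variant TSV, one PSM TSV per sample)
#' plus truth tables.
#'
#' @param outdir Output directory (created if needed).
#' @param n_transcripts Number of transcripts.
#' @param depth_per_sample Spectra per sample.
#' @param seed Integer seed driving every random stage.
#' @param config A `vesiprot_config`.
#' @param n_nonsyn_snv,n_syn_snv,n_indel Variant counts to spike.
#' @param decoy_fraction Incorrect-match fraction of the PSM streams.
#' @param n_diff,n_exclusive_each Differential and per-compartment exclusive
#'   protein planting (defaults scale with the reference size).
#' @return Invisibly, a list with the in-memory objects (`reference`,
#'   `variants`, `db`, `truth`, `psms`, `paths`).
#' @export
simulate_bundle <- function(outdir, n_transcripts = 50L,
                            depth_per_sample = 20000L, seed = 1L,
                            config = vesiprot_config(rng_seed = seed),
                            n_nonsyn_snv = 12L, n_syn_snv = 4L,
                            n_indel = 6L, decoy_fraction = 0.05,
                            n_diff = min(15L, max(1L, n_transcripts %/% 3L)),
                            n_exclusive_each = if (n_transcripts >= 20L) 2L
                                               else 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  reference <- generate_reference(n_transcripts, seed = seed)
  spiked <- spike_variants(reference, n_nonsyn_snv, n_syn_snv, n_indel,
                           seed = seed + 1L)
  db <- build_database(spiked$variants, reference$models,
                       reference$chrom_seqs, config)
  wt <- wildtype_proteins(reference$models)
  truth <- plant_truth(wt, db$mutant, n_diff = n_diff,
                       n_exclusive_each = n_exclusive_each, seed = seed + 2L)
  target <- rbind(wt[, c("accession", "sequence")],
                  db$mutant[, c("accession", "sequence")])
  psms <- simulate_psms(target, db$decoy, truth, depth_per_sample,
                        decoy_fraction, seed = seed + 3L)
  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    annotation = file.path(outdir, "annotation.tsv"),
    variants = file.path(outdir, "variants.tsv"),
    psms = stats::setNames(file.path(outdir,
                                     paste0("psms_", names(psms), ".tsv")),
                           names(psms)),
    truth_fold = file.path(outdir, "truth_fold.tsv"),
    truth_variants = file.path(outdir, "truth_variants.tsv"),
    truth_mutants = file.path(outdir, "truth_mutants.tsv"))
  write_fasta(data.frame(accession = names(reference$chrom_seqs),
                         sequence = unname(reference$chrom_seqs),
                         stringsAsFactors = FALSE), paths$genome)
  write_transcript_models(reference$models, paths$annotation)
  write_tsv(spiked$variants[, c("chrom", "pos", "ref", "alt")],
            paths$variants)
  for (smp in names(psms)) write_tsv(psms[[smp]], paths$psms[[smp]])
  write_tsv(data.frame(accession = names(truth$base_abundance),
                       base_abundance = unname(truth$base_abundance),
                       planted_log2_fold = unname(truth$planted_log2_fold),
                       exclusive_to = ifelse(
                         names(truth$base_abundance) %in%
                           names(truth$exclusive_proteins),
                         truth$exclusive_proteins[
                           names(truth$base_abundance)], "none"),
                       stringsAsFactors = FALSE), paths$truth_fold)
  write_tsv(spiked$truth, paths$truth_variants)
  write_tsv(data.frame(accession = names(truth$mutant_secretion),
                       compartments = vapply(truth$mutant_secretion,
                                             paste, "", collapse = ";"),
                       stringsAsFactors = FALSE), paths$truth_mutants)
  invisible(list(reference = reference, variants = spiked$variants,
                 variant_truth = spiked$truth, db = db, truth = truth,
                 psms = psms, paths = paths))
}

#' Run the full proteogenomic pipeline
#'
#' Stages: (1) load reference genome + transcript annotation; (2) build the
#' customized mutant + decoy databases and write them as FASTA; (3) per
#' sample, FDR-filter the PSMs and infer identified proteins; (4) call
#' mutant proteins and tabulate the exosome/ectosome Venn overlap; (5)
#' quantify exosome vs ectosome by RSc with fold-change and exclusivity
#' calls plus top-N tables; (6) chi-square category enrichment of the
#' compartment-exclusive proteins; (7) write a run manifest (config, input
#' checksums, seed, outputs). Re-running with identical inputs and seed
#' reproduces identical output bytes. Any stage failure aborts with the
#' stage name; files being written when a stage fails keep an
#' `.incomplete` suffix.
#'
#' @param config A `vesiprot_config`.
#' @param genome_path Reference FASTA (chromosome sequences).
#' @param annotation_path Transcript-model TSV.
#' @param variant_path Variant TSV.
#' @param psm_paths Named character vector sample_id -> PSM TSV. Must include
#'   `exosome` and `ectosome` for the comparative stages.
#' @param category_path Optional category gene-set TSV for enrichment.
#' @param outdir Output directory.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, genome_path, annotation_path, variant_path,
                         psm_paths, category_path = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name, writer = write_tsv) {
    final <- file.path(outdir, name)
    tmp <- paste0(final, ".incomplete")
    writer(obj, tmp)
    file.rename(tmp, final)
    outputs <<- c(outputs, name)
    final
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  res$reference <- stage("load_reference", {
    genome <- read_fasta(genome_path, type = "nt")
    chrom_seqs <- stats::setNames(genome$sequence, genome$accession)
    models <- read_transcript_models(annotation_path, chrom_seqs)
    list(chrom_seqs = chrom_seqs, models = models)
  })

  res$db <- stage("build_database", {
    variants <- read_variant_table(variant_path)
    db <- build_database(variants, res$reference$models,
                         res$reference$chrom_seqs, config)
    wt <- wildtype_proteins(res$reference$models)
    emit(db$mutant[, c("accession", "sequence")], "mutant_db.fasta",
         write_fasta)
    emit(db$decoy, "decoy_db.fasta", write_fasta)
    emit(wt, "wildtype_db.fasta", write_fasta)
    c(db, list(wt = wt, variants = variants))
  })

  res$identification <- stage("identification", {
    for (smp in names(psm_paths)) {
      if (!file.exists(psm_paths[[smp]]))
        stop("missing PSM file for sample '", smp, "': ", psm_paths[[smp]])
    }
    per_sample <- lapply(names(psm_paths), function(smp) {
      psms <- read_psm_table(psm_paths[[smp]], smp)
      filt <- peptide_fdr_filter(psms, config$peptide_fdr_max)
      ident <- infer_proteins(filt$psms, config$min_unique_peptides)
      list(psms = filt$psms, operating_point = filt$operating_point,
           curve = filt$curve, identified = ident,
           total = nrow(filt$psms))
    })
    names(per_sample) <- names(psm_paths)
    idtab <- do.call(rbind, lapply(per_sample, `[[`, "identified"))
    idtab$is_mutant <- idtab$accession %in% res$db$mutant$accession
    emit(idtab, "identified_proteins.tsv")
    emit(do.call(rbind, lapply(names(per_sample), function(s)
      cbind(sample_id = s, per_sample[[s]]$curve))), "fdr_curves.tsv")
    per_sample
  })

  res$mutants <- stage("mutant_calls", {
    calls <- lapply(names(res$identification), function(smp) {
      st <- res$identification[[smp]]
      call_mutants(st$identified, st$psms, res$db$mutant, res$db$wt)
    })
    names(calls) <- names(res$identification)
    tab <- do.call(rbind, calls)
    emit(tab, "mutant_calls.tsv")
    if (all(c("exosome", "ectosome") %in% names(calls))) {
      v <- venn_counts(calls$exosome$accession, calls$ectosome$accession)
      emit(data.frame(only_exosome = v$only_a, only_ectosome = v$only_b,
                      common = v$common, exclusive_total = v$exclusive_total),
           "mutant_venn.tsv")
    }
    calls
  })

  res$quantification <- stage("quantification", {
    idents <- lapply(res$identification, `[[`, "identified")
    totals <- vapply(res$identification, `[[`, 1L, "total")
    cm <- count_matrix(idents, totals)
    diff <- NULL
    if (all(c("exosome", "ectosome") %in% colnames(cm$counts))) {
      diff <- differential_calls(cm, "exosome", "ectosome", config)
      emit(diff, "differential_exosome_vs_ectosome.tsv")
      emit(attr(diff, "summary"), "differential_summary.json",
           function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE))
      for (smp in c("exosome", "ectosome")) {
        emit(top_n_table(cm, smp, min(50L, nrow(cm$counts))),
             paste0("top50_", smp, ".tsv"))
      }
    }
    list(count_matrix = cm, differential = diff)
  })

  skip_enrichment <- is.null(category_path) ||
    is.null(res$quantification$differential)
  res$enrichment <- if (skip_enrichment) NULL else stage("enrichment", {
    cats <- read_category_sets(category_path)
    gene_of <- accession_genes(rownames(res$quantification$count_matrix$counts),
                               res$reference$models, res$db$mutant)
    diff <- res$quantification$differential
    results <- list()
    for (side in c("x", "y")) {
      excl <- diff$accession[diff$call == paste0("exclusive_", side)]
      genes <- unique(stats::na.omit(gene_of[excl]))
      smp <- if (side == "x") "exosome" else "ectosome"
      if (length(genes) == 0L) next
      enr <- tryCatch(enrich_sets(genes, cats,
                                  alpha = config$enrichment_alpha),
                      error = function(e) NULL)
      if (is.null(enr)) next
      emit(enr, paste0("enrichment_", smp, ".tsv"))
      results[[smp]] <- enr
    }
    results
  })

  stage("manifest", {
    inputs <- c(genome = genome_path, annotation = annotation_path,
                variants = variant_path, psm_paths)
    if (!is.null(category_path)) inputs <- c(inputs, category = category_path)
    manifest <- c(
      paste0("config.", names(unclass(config)), "=",
             vapply(unclass(config), as.character, "")),
      paste0("input.", names(inputs), ".md5=",
             unname(tools::md5sum(unname(inputs)))),
      paste0("output=", sort(outputs)))
    emit(manifest, "manifest.txt", function(x, p) writeLines(x, p))
  })

  invisible(res)
}

# Map accessions (wild-type transcript ids or mut|gene|... entries) to gene
# symbols.
accession_genes <- function(accessions, models, mutant_db) {
  gene_by_tx <- stats::setNames(vapply(models, `[[`, "", "gene_symbol"),
                                vapply(models, `[[`, "", "transcript_id"))
  out <- stats::setNames(rep(NA_character_, length(accessions)), accessions)
  wt_hit <- accessions %in% names(gene_by_tx)
  out[wt_hit] <- gene_by_tx[accessions[wt_hit]]
  mut_hit <- accessions %in% mutant_db$accession
  out[mut_hit] <- mutant_db$gene[match(accessions[mut_hit],
                                       mutant_db$accession)]
  out
}
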