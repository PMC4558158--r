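#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with one
#' degree of freedom; the p-value comes from the chi-square survival
#' function. A zero row or column marginal leaves the test undefined and is
#' an error.
#'
#' @param a,b,c,d Cell counts: `a` = query in category, `b` = query outside,
#'   `c` = rest of the background in category, `d` = remainder.
#' @return Named list with `chi2` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) == 0) stop("empty table")
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal: chi-square test undefined", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Read category gene sets (two-column TSV: category, gene)
#' @param path TSV file with header columns `category` and `gene`.
#' @return data.frame with uppercased gene symbols.
#' @export
read_category_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("category", "gene")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("category file '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab$gene <- toupper(tab$gene)
  unique(tab[, need])
}

#' Chi-square enrichment of a gene set against categorized backgrounds
#'
#' For each category, builds the 2x2 table of query/background membership
#' over the background universe and applies the uncorrected Pearson
#' chi-square test. Decisions use the raw p-value at `alpha` and require
#' over-representation (query in-category rate above the background's);
#' Benjamini-Hochberg q-values are appended for reference. Categories whose
#' table has a zero marginal are reported with `NA` statistics.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param category_sets data.frame with `category` and `gene` columns.
#' @param universe Background universe of gene symbols (defaults to all genes
#'   of `category_sets`). Query symbols outside the universe are dropped
#'   with a message.
#' @param alpha Raw-p significance level.
#' @return data.frame with `category`, `a`, `b`, `c`, `d`, `chi2`, `p`, `q`,
#'   `enriched`.
#' @export
enrich_sets <- function(query_genes, category_sets,
                        universe = unique(category_sets$gene),
                        alpha = 0.05) {
  query <- unique(toupper(query_genes))
  universe <- unique(toupper(universe))
  dropped <- setdiff(query, universe)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (length(query) == 0L)
    stop("empty query after mapping to the universe", call. = FALSE)
  cats <- sort(unique(category_sets$category))
  rows <- lapply(cats, function(cat) {
    genes <- intersect(category_sets$gene[category_sets$category == cat],
                       universe)
    a <- length(intersect(query, genes))
    b <- length(query) - a
    cc <- length(genes) - a
    d <- length(universe) - length(query) - cc
    res <- tryCatch(chi_square_2x2(a, b, cc, d),
                    error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(category = cat, a = a, b = b, c = cc, d = d, chi2 = res$chi2,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  over <- out$a / (out$a + out$b) > out$c / (out$c + out$d)
  out$enriched <- !is.na(out$p) & out$p < alpha & over
  out
}

#' TPM-normalize an expression count matrix and rank genes per library
#'
#' @param counts Non-negative integer matrix, genes x libraries. Every
#'   library total must be positive.
#' @return List of class `expression_background`: `tpm` (each column sums to
#'   1e6), `rank` (dense rank per library, highest TPM = rank 1).
#' @export
tpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("all-zero library", call. = FALSE)
  tpm_m <- sweep(counts, 2L, totals, "/") * 1e6
  rank_m <- apply(tpm_m, 2L, function(x)
    match(x, sort(unique(x), decreasing = TRUE)))
  dimnames(rank_m) <- dimnames(tpm_m)
  structure(list(tpm = tpm_m, rank = rank_m),
            class = "expression_background")
}

#' Build category sets from an expression background by rank quantile
#'
#' Membership rule for expression-derived backgrounds: the top fraction of
#' genes per library by TPM rank forms that library's category.
#'
#' @param background An `expression_background`.
#' @param top_fraction Quantile of top-ranked genes kept per library.
#' @return data.frame with `category` (library) and `gene` columns.
#' @export
expression_category_sets <- function(background, top_fraction = 0.25) {
  stopifnot(inherits(background, "expression_background"),
            top_fraction > 0, top_fraction <= 1)
  rk <- background$rank
  n_keep <- max(1L, ceiling(nrow(rk) * top_fraction))
  do.call(rbind, lapply(colnames(rk), function(lib) {
    genes <- rownames(rk)[order(rk[, lib], rownames(rk))][seq_len(n_keep)]
    data.frame(category = lib, gene = toupper(genes),
               stringsAsFactors = FALSE)
  }))
}

#' Normalized spectral counts of enriched-category members per compartment
#'
#' For every enriched category, exports the normalized spectral count (s/T)
#' of each member protein in each compartment as a tidy table ready for box
#' plotting; proteins absent from a compartment contribute a zero row.
#'
#' @param enrichment_results Output of [enrich_sets()].
#' @param category_sets The category sets used for the enrichment.
#' @param cm A `count_matrix` whose rows can be mapped to genes.
#' @param gene_of Named character vector accession -> gene symbol.
#' @return data.frame with `category`, `compartment`, `accession`,
#'   `normalized_count`.
#' @export
abundance_by_category <- function(enrichment_results, category_sets, cm,
                                  gene_of) {
  stopifnot(inherits(cm, "count_matrix"))
  enr <- enrichment_results$category[enrichment_results$enriched]
  genes_by_acc <- toupper(gene_of[rownames(cm$counts)])
  norm <- sweep(cm$counts, 2L, cm$totals, "/")
  rows <- list()
  for (cat in enr) {
    members <- category_sets$gene[category_sets$category == cat]
    accs <- rownames(cm$counts)[genes_by_acc %in% members]
    for (smp in colnames(cm$counts)) {
      for (acc in accs) {
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, compartment = smp, accession = acc,
          normalized_count = norm[acc, smp], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(category = character(), compartment = character(),
                      accession = character(), normalized_count = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
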