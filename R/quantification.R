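#' Ratio of normalized spectral counts (RSc)
#'
#' For a protein with significant spectral counts `s_x`, `s_y` in two samples
#' whose total significant spectra are `t_x`, `t_y`, the raw ratio is
#'
#'   raw = (s_y + c) (t_x - s_x + c) / \[(s_x + c) (t_y - s_y + c)\]
#'
#' with additive correction factor `c` (default 1.25), which keeps the ratio
#' finite when a count is zero. Raw ratios below 1 are reported as the
#' negative inverse, so |signed| >= 1 always, a raw ratio of exactly 1 maps
#' to signed 1, and signed(x, y) = -signed(y, x) whenever raw != 1. Note the
#' direction of the printed formula: the numerator carries the *second*
#' sample's count, so raw < 1 (signed negative) means the protein is more
#' abundant in sample x.
#'
#' All arguments are vectorized.
#'
#' @param s_x,s_y Significant spectra of the protein in samples x and y.
#' @param t_x,t_y Total significant spectra of samples x and y.
#' @param c Correction factor (> 0).
#' @return data.frame with columns `raw_ratio` and `signed_ratio`.
#' @export
rsc <- function(s_x, t_x, s_y, t_y, c = 1.25) {
  if (any(c <= 0)) stop("correction factor c must be > 0")
  if (any(s_x < 0 | s_y < 0 | s_x > t_x | s_y > t_y))
    stop("spectral counts must satisfy 0 <= s <= t")
  raw <- (s_y + c) * (t_x - s_x + c) / ((s_x + c) * (t_y - s_y + c))
  signed <- ifelse(raw >= 1, raw, -1 / raw)
  data.frame(raw_ratio = raw, signed_ratio = signed)
}

#' Differential and exclusivity calls between two samples
#'
#' Exclusivity (identified in exactly one of the two samples, per the
#' post-filter identification output encoded as a zero count) takes
#' precedence over the fold-change classification; remaining proteins are
#' classified by |signed RSc| against `fold_change_min`. Under the default
#' `"as_printed"` orientation a signed ratio >= threshold is `up_in_y` and
#' <= -threshold is `up_in_x` (the formula's numerator carries sample y).
#'
#' @param cm A `count_matrix`.
#' @param sample_x,sample_y Sample identifiers (columns of `cm`).
#' @param config A `vesiprot_config`.
#' @return data.frame with one row per protein: `accession`, `s_x`, `t_x`,
#'   `s_y`, `t_y`, `raw_ratio`, `signed_ratio`, `call` in
#'   \{`up_in_x`, `up_in_y`, `unchanged`, `exclusive_x`, `exclusive_y`\}.
#'   The per-class tally is attached as attribute `"summary"`.
#' @export
differential_calls <- function(cm, sample_x, sample_y,
                               config = vesiprot_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  for (s in c(sample_x, sample_y)) {
    if (!s %in% colnames(cm$counts))
      stop("unknown sample id: ", s, call. = FALSE)
  }
  s_x <- cm$counts[, sample_x]
  s_y <- cm$counts[, sample_y]
  t_x <- cm$totals[[sample_x]]
  t_y <- cm$totals[[sample_y]]
  r <- rsc(s_x, t_x, s_y, t_y, config$spectral_correction_c)
  up_y <- r$signed_ratio >= config$fold_change_min
  up_x <- r$signed_ratio <= -config$fold_change_min
  if (config$ratio_orientation == "flipped") {
    tmp <- up_y; up_y <- up_x; up_x <- tmp
  }
  call <- ifelse(s_x > 0 & s_y == 0, "exclusive_x",
          ifelse(s_y > 0 & s_x == 0, "exclusive_y",
          ifelse(up_x, "up_in_x",
          ifelse(up_y, "up_in_y", "unchanged"))))
  out <- data.frame(accession = rownames(cm$counts), s_x = s_x, t_x = t_x,
                    s_y = s_y, t_y = t_y, raw_ratio = r$raw_ratio,
                    signed_ratio = r$signed_ratio, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  tally <- table(factor(out$call, levels = c("up_in_x", "up_in_y",
                                             "unchanged", "exclusive_x",
                                             "exclusive_y")))
  attr(out, "summary") <- as.list(tally)
  out
}

#' Top-N most abundant proteins of a sample
#'
#' Ranks proteins by normalized spectral count s/T within one sample, ties
#' broken lexicographically by accession.
#'
#' @param cm A `count_matrix`.
#' @param sample Sample identifier.
#' @param n Number of rows requested (>= 1); if more than available, all
#'   proteins are returned with a warning.
#' @return data.frame with `rank`, `accession`, `n_significant_spectra`,
#'   `normalized_count`.
#' @export
top_n_table <- function(cm, sample, n) {
  stopifnot(inherits(cm, "count_matrix"), n >= 1L)
  if (!sample %in% colnames(cm$counts))
    stop("unknown sample id: ", sample, call. = FALSE)
  s <- cm$counts[, sample]
  norm <- s / cm$totals[[sample]]
  ord <- order(-norm, rownames(cm$counts))
  if (n > length(ord)) {
    warning("requested ", n, " proteins but only ", length(ord),
            " available")
    n <- length(ord)
  }
  pick <- ord[seq_len(n)]
  data.frame(rank = seq_len(n), accession = rownames(cm$counts)[pick],
             n_significant_spectra = s[pick], normalized_count = norm[pick],
             row.names = NULL, stringsAsFactors = FALSE)
}
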