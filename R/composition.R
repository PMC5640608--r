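#' Residue fraction of a protein
#'
#' Percentage of a protein's residues that are the given amino acid.
#' Non-canonical letters (X, B, Z, U, O, J, stop `*`, gaps) are stripped
#' before counting, so they appear in neither numerator nor denominator.
#'
#' @param sequence amino-acid sequence (character scalar, or anything
#'   coercible via `as.character`, e.g. one element of an `AAStringSet`).
#' @param residue single amino-acid letter (default `"H"`, histidine).
#' @return Percentage in `[0, 100]`.
#' @examples
#' residue_fraction("HAAA", "H")  # 25
#' @export
residue_fraction <- function(sequence, residue = "H") {
  stopifnot(length(residue) == 1L, nchar(residue) == 1L)
  seq <- toupper(as.character(sequence))
  stopifnot(length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  seq <- gsub(sprintf("[^%s]", AA_CANONICAL), "", seq)
  if (!nzchar(seq)) stop("sequence has no canonical residues")
  n <- nchar(seq)
  hits <- n - nchar(gsub(toupper(residue), "", seq, fixed = TRUE))
  100 * hits / n
}

AA_CANONICAL <- "ACDEFGHIKLMNPQRSTVWY"

# Residue fractions (percent) for every protein in a set; vectorized.
proteome_fractions <- function(proteins, residue = "H") {
  ids <- names(proteins)
  seqs <- as.character(proteins)
  if (is.null(ids)) ids <- sprintf("protein_%d", seq_along(seqs))
  vapply(seqs, function(s) residue_fraction(s, residue), numeric(1),
         USE.NAMES = FALSE) -> pct
  data.frame(protein_id = ids,
             length = nchar(gsub(sprintf("[^%s]", AA_CANONICAL), "",
                                 toupper(seqs))),
             pct = pct, row.names = NULL, stringsAsFactors = FALSE)
}

#' Proteome-wide residue composition statistics
#'
#' Unweighted per-protein mean and population standard deviation of the
#' residue fraction, with an outlier threshold at `mean + k * SD` (the
#' screen the study ran for histidine: mean 1.4%, SD 1.1%, cut at two SD).
#'
#' @param proteins `AAStringSet` or named character vector of sequences
#'   (at least 2).
#' @param residue amino-acid letter (default `"H"`).
#' @param k SD multiplier for the threshold (default 2).
#' @return List of class `composition_stats`: `residue`, `n`, `mean_pct`,
#'   `sd_pct`, `k`, `threshold_pct`, and the per-protein `fractions` table.
#' @export
proteome_stats <- function(proteins, residue = "H", k = 2) {
  fr <- proteome_fractions(proteins, residue)
  if (nrow(fr) < 2L) stop("need at least 2 proteins")
  m <- mean(fr$pct)
  sdp <- sqrt(mean((fr$pct - m)^2))   # population SD, unweighted by length
  structure(list(residue = residue, n = nrow(fr), mean_pct = m, sd_pct = sdp,
                 k = k, threshold_pct = m + k * sdp, fractions = fr),
            class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("<composition_stats> residue %s over %d proteins\n",
              x$residue, x$n))
  cat(sprintf("  mean %.2f%%  SD %.2f%%  threshold (mean + %g SD) %.2f%%\n",
              x$mean_pct, x$sd_pct, x$k, x$threshold_pct))
  invisible(x)
}

#' Flag residue-composition outliers
#'
#' Proteins whose residue fraction is at least the threshold ("at least" is
#' inclusive: a protein exactly at the cut is flagged), sorted by descending
#' fraction. The default threshold is the rule-derived `mean + k * SD`; an
#' override reproduces a fixed published cut (the study used 3.5% for
#' histidine).
#'
#' @param proteins `AAStringSet` or character vector of sequences.
#' @param stats a `composition_stats` from [proteome_stats()]; computed from
#'   `proteins` if NULL.
#' @param threshold_override fixed threshold percentage, replacing the
#'   rule-derived one.
#' @param residue,k used when `stats` is NULL.
#' @return data.frame of flagged proteins: `protein_id`, `length`, `pct`,
#'   sorted by `pct` descending; the threshold used is attached as attribute
#'   `threshold_pct`.
#' @export
flag_outliers <- function(proteins, stats = NULL, threshold_override = NULL,
                          residue = "H", k = 2) {
  if (is.null(stats)) stats <- proteome_stats(proteins, residue, k)
  thr <- if (is.null(threshold_override)) stats$threshold_pct
         else threshold_override
  fr <- stats$fractions
  out <- fr[fr$pct >= thr, , drop = FALSE]
  out <- out[order(-out$pct, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold_pct") <- thr
  out
}

#' Run the composition screen end to end
#'
#' Convenience wrapper: compute proteome statistics for a residue and return
#' the per-protein table with outlier flags, plus the statistics header.
#'
#' @inheritParams proteome_stats
#' @param threshold_override optional fixed threshold percentage.
#' @return List with `stats` and `table` (protein_id, length, pct, flagged).
#' @export
aa_screen <- function(proteins, residue = "H", k = 2,
                      threshold_override = NULL) {
  stats <- proteome_stats(proteins, residue, k)
  thr <- if (is.null(threshold_override)) stats$threshold_pct
         else threshold_override
  tab <- stats$fractions
  tab$flagged <- tab$pct >= thr
  tab <- tab[order(-tab$pct, tab$protein_id), ]
  rownames(tab) <- NULL
  list(stats = stats, threshold_pct = thr, table = tab)
}
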