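## Translation efficiency and its relation to motif density.

#' Translation efficiency
#'
#' Translation efficiency of gene i is protein abundance divided by
#' transcription level (exact ratio).
#'
#' @param abundance nonnegative protein abundance(s).
#' @param transcription positive transcription level(s).
#' @return abundance / transcription.
#' @export
translation_efficiency <- function(abundance, transcription) {
  if (any(transcription <= 0)) stop("transcription level must be positive")
  if (any(abundance < 0)) stop("abundance must be nonnegative")
  abundance / transcription
}

#' Motif density per 100 residues
#'
#' @param length protein length(s) (> 0), named by protein id, or a proteome
#'   (named character vector of sequences).
#' @param motif_table motif table covering the proteins.
#' @return named numeric vector: 100 * motif count / length.
#' @export
motif_density <- function(length, motif_table) {
  if (is.character(length)) length <- nchar(length)
  if (any(length <= 0)) stop("protein length must be positive")
  counts <- setNames(numeric(base::length(length)), names(length))
  tb <- table(motif_table$protein_id)
  hit <- intersect(names(tb), names(counts))
  counts[hit] <- as.numeric(tb[hit])
  100 * counts / length
}

#' Correlate expression measures with motif density
#'
#' Spearman rank correlation (tie-corrected) between motif density and either
#' translation efficiency or protein abundance, over the genes present in
#' both inputs. A quartile-binned summary (mean density per expression
#' quartile) is attached for plotting.
#'
#' @param records data.frame with columns `gene_id`, `abundance`,
#'   `transcription`.
#' @param densities named numeric vector of motif densities (per protein).
#' @param measure `"TE"` or `"ABUNDANCE"`.
#' @return list with `rho`, `p_value`, `n`, `measure`, `quartiles`
#'   (data.frame), `flagged` (TRUE when an input is constant).
#' @export
correlate_expression_motifs <- function(records, densities,
                                        measure = c("TE", "ABUNDANCE")) {
  measure <- match.arg(measure)
  genes <- intersect(records$gene_id, names(densities))
  if (length(genes) < 3) stop("need at least 3 paired observations")
  rec <- records[match(genes, records$gene_id), ]
  x <- switch(measure,
              TE = translation_efficiency(rec$abundance, rec$transcription),
              ABUNDANCE = rec$abundance)
  y <- unname(densities[genes])
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(genes),
                measure = measure, quartiles = NULL, flagged = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  qs <- stats::quantile(x, probs = seq(0, 1, 0.25))
  bin <- cut(x, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  quart <- data.frame(quartile = sort(unique(bin)),
                      mean_density = tapply(y, bin, mean),
                      n = as.integer(table(bin)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(genes),
       measure = measure, quartiles = quart, flagged = FALSE)
}

#' Concordance of predicted strengths with ribosome-profiling stall scores
#'
#' Fraction of genes whose stall (asymmetry) score is at or above `threshold`
#' that possess at least one MEDIUM or STRONG motif. Genes absent from the
#' motif table count as lacking motifs.
#'
#' @param stall_scores named numeric vector (gene -> asymmetry ratio).
#' @param motif_table motif table with strengths.
#' @param threshold score threshold (> 0), default 2.
#' @return list with `fraction`, `n_above`, `n_with_motif`, `threshold`,
#'   `flagged` (TRUE when no gene reaches the threshold).
#' @export
profiling_concordance <- function(stall_scores, motif_table, threshold = 2) {
  stopifnot(threshold > 0)
  above <- names(stall_scores)[stall_scores >= threshold]
  if (length(above) == 0)
    return(list(fraction = NA_real_, n_above = 0L, n_with_motif = 0L,
                threshold = threshold, flagged = TRUE))
  strong <- motif_table$protein_id[motif_table$strength %in%
                                     c("MEDIUM", "STRONG")]
  hit <- above %in% strong
  list(fraction = mean(hit), n_above = length(above),
       n_with_motif = sum(hit), threshold = threshold, flagged = FALSE)
}
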