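## Polyproline motif detection and strength classification.
##
## A polyproline motif is a maximal run of n >= 2 consecutive prolines with
## its flanking context X(-2)X(-1)-nP-X(+1). Coordinates are 1-based
## inclusive; `start` is the first proline of the run, which is also the
## anchor used by all positional analyses.

#' Scan a protein sequence for polyproline motifs
#'
#' Finds every maximal run of two or more consecutive 'P' residues,
#' left-to-right, and records its flanking residues. Flanks outside the
#' sequence (motif at a terminus) are reported as `NA`.
#'
#' @param sequence upper-case amino-acid string; letters outside the 20
#'   standard amino acids are permitted (they render a motif unclassifiable
#'   but not undetectable).
#' @param protein_id identifier carried into the output.
#' @return a data.frame with columns `protein_id`, `start`, `n`, `x_m2`,
#'   `x_m1`, `x_p1`, `strength` (NA; fill with [classify_motifs()]).
#' @export
scan_motifs <- function(sequence, protein_id = "seq1") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      nchar(sequence) == 0)
    stop("sequence must be a single non-empty string")
  chars <- seq_chars(sequence)
  runs <- rle(chars == "P")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= 2L
  if (!any(keep)) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      n = integer(0), x_m2 = character(0),
                      x_m1 = character(0), x_p1 = character(0),
                      strength = character(0), stringsAsFactors = FALSE))
  }
  s <- starts[keep]
  n <- runs$lengths[keep]
  L <- length(chars)
  at <- function(i) ifelse(i >= 1L & i <= L, chars[pmax(pmin(i, L), 1L)],
                           NA_character_)
  data.frame(protein_id = protein_id, start = s, n = n,
             x_m2 = at(s - 2L), x_m1 = at(s - 1L), x_p1 = at(s + n),
             strength = NA_character_, stringsAsFactors = FALSE)
}

## Look up effect classes for a vector of flank letters at one position.
## NA letters (sequence boundary) get `missing_eff`; non-standard letters NA.
flank_effects <- function(letters, fe_map, missing_eff) {
  out <- unname(fe_map[letters])
  out[is.na(letters)] <- missing_eff
  out
}

#' Classify polyproline motifs by predicted stalling strength
#'
#' Applies the rule table to each motif row: flank residues are mapped to
#' effect classes per position and combined through the rule grid keyed by the
#' proline run-length category (2 vs 3+). Motifs whose present flanks include
#' a non-standard letter are labelled `"UNCLASSIFIED"` and are excluded from
#' all strength-stratified analyses downstream (they still count as raw motif
#' occurrences). Missing flanks at a sequence terminus are by default treated
#' as neutral context: weak-effect at X(-1)/X(+1), no modulation at X(-2);
#' with `missing_policy = "exclude"` such motifs are labelled
#' `"UNCLASSIFIED"` instead.
#'
#' @param motifs data.frame from [scan_motifs()]/[scan_proteome()].
#' @param rules a validated `strength_rule_table`.
#' @param missing_policy `"neutral"` (default) or `"exclude"`.
#' @return `motifs` with the `strength` column filled.
#' @export
classify_motifs <- function(motifs, rules = default_rule_table(),
                            missing_policy = c("neutral", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  if (!isTRUE(attr(rules, "validated")))
    stop("rule table has not been validated; run validate_rule_table()")
  if (nrow(motifs) == 0) return(motifs)
  e_m2 <- flank_effects(motifs$x_m2, rules$flank_effect$x_m2, "MEDIUM_EFF")
  e_m1 <- flank_effects(motifs$x_m1, rules$flank_effect$x_m1, "WEAK_EFF")
  e_p1 <- flank_effects(motifs$x_p1, rules$flank_effect$x_p1, "WEAK_EFF")
  n_cat <- ifelse(motifs$n >= 3L, "3+", "2")
  cr <- rules$combination_rules
  lut <- setNames(cr$strength, rule_key(cr$n_cat, cr$e_m2, cr$e_m1, cr$e_p1))
  strength <- unname(lut[rule_key(n_cat, e_m2, e_m1, e_p1)])
  ambiguous <- is.na(e_m2) | is.na(e_m1) | is.na(e_p1)
  strength[ambiguous] <- "UNCLASSIFIED"
  if (missing_policy == "exclude") {
    terminal <- is.na(motifs$x_m2) | is.na(motifs$x_m1) | is.na(motifs$x_p1)
    strength[terminal] <- "UNCLASSIFIED"
  }
  motifs$strength <- strength
  motifs
}

#' Classify a single motif
#'
#' @param motif one-row data.frame as produced by [scan_motifs()].
#' @inheritParams classify_motifs
#' @return a strength label: `"WEAK"`, `"MEDIUM"`, `"STRONG"` or
#'   `"UNCLASSIFIED"`.
#' @export
classify_motif <- function(motif, rules = default_rule_table(),
                           missing_policy = "neutral") {
  classify_motifs(motif[1, , drop = FALSE], rules, missing_policy)$strength
}

#' Scan a whole proteome and classify all motifs
#'
#' @param proteome named character vector of protein sequences (unique ids).
#' @inheritParams classify_motifs
#' @return a `motif_table`: data.frame of all motifs sorted by
#'   (protein_id, start) with strengths filled; attribute `protein_counts` is
#'   a named integer vector covering every protein (zeros included).
#' @export
scan_proteome <- function(proteome, rules = default_rule_table(),
                          missing_policy = "neutral") {
  check_proteome(proteome)
  ids <- names(proteome)
  tabs <- lapply(seq_along(proteome), function(i)
    scan_motifs(proteome[[i]], ids[i]))
  tab <- if (length(tabs))
    do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  else scan_motifs("A", "x") # no-motif scan yields the empty frame
  tab <- classify_motifs(tab, rules, missing_policy)
  tab <- tab[order(tab$protein_id, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  counts <- setNames(integer(length(ids)), ids)
  if (nrow(tab)) {
    tb <- table(tab$protein_id)
    counts[names(tb)] <- as.integer(tb)
  }
  attr(tab, "protein_counts") <- counts
  class(tab) <- c("motif_table", "data.frame")
  tab
}

#' Per-protein motif counts
#'
#' @param motif_table a `motif_table` from [scan_proteome()].
#' @return named integer vector, one entry per protein, zeros included.
#' @export
motif_counts <- function(motif_table) {
  counts <- attr(motif_table, "protein_counts")
  if (is.null(counts)) {
    tb <- table(motif_table$protein_id)
    counts <- setNames(as.integer(tb), names(tb))
  }
  counts
}
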