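## Positional analyses of motif occurrence: N-terminal ramp, domain/linker
## enrichment, boundary profiles and TMH-relative site analysis.
##
## All coordinates are 1-based inclusive. A motif's position ("anchor") is
## the first proline of its stretch.

## ---- annotation tracks ----------------------------------------------------

#' Validate an annotation track
#'
#' @param track data.frame with columns `protein_id`, `start`, `end` (1-based
#'   inclusive) and optionally `kind`.
#' @param proteome named character vector used to bound-check intervals.
#' @return the track, sorted by (protein_id, start).
#' @export
validate_track <- function(track, proteome = NULL) {
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(track)))
    stop("track must have columns ", paste(need, collapse = ", "))
  if (any(track$start < 1) || any(track$end < track$start))
    stop("intervals must satisfy 1 <= start <= end")
  if (!is.null(proteome)) {
    lens <- nchar(proteome)[track$protein_id]
    if (anyNA(lens)) stop("track refers to unknown proteins")
    if (any(track$end > lens)) stop("interval beyond protein length")
  }
  track <- track[order(track$protein_id, track$start), , drop = FALSE]
  for (pid in unique(track$protein_id)) {
    sub <- track[track$protein_id == pid, ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      stop("overlapping intervals for protein ", pid)
  }
  rownames(track) <- NULL
  track
}

## ---- N-terminal ramp ------------------------------------------------------

#' N-terminal ramp test
#'
#' Cuts every protein into its first `split` residues and the remainder; a
#' motif belongs to the segment containing its anchor. Each segment
#' population is shuffle-normalised independently (segments shuffled within
#' themselves, preserving their own composition) and the two ratio vectors
#' are compared by the rank-sum test.
#'
#' @param proteome named character vector.
#' @param split boundary (default 50 residues).
#' @param replicates,seed shuffle-null parameters.
#' @return list with `nterm` and `rest` (`fold_change_result`s), `p_value`
#'   (rank-sum on the ratio vectors), `n_nterm`, `n_rest`.
#' @export
nterminal_ramp_test <- function(proteome, split = 50, replicates = 1000,
                                seed = 1) {
  stopifnot(split >= 1)
  check_proteome(proteome)
  nterm <- substr(proteome, 1, split)
  rest <- substr(proteome, split + 1, nchar(proteome))
  rest <- rest[nchar(rest) > 0]
  fc_n <- shuffle_fold_change(nterm, count_motifs, replicates,
                              derive_seed(seed, 1, 0))
  if (length(rest) == 0) { # every protein shorter than the split
    return(list(nterm = fc_n, rest = NULL, p_value = NA_real_,
                n_nterm = fc_n$n_obs, n_rest = 0L))
  }
  fc_r <- shuffle_fold_change(rest, count_motifs, replicates,
                              derive_seed(seed, 2, 0))
  list(nterm = fc_n, rest = fc_r,
       p_value = compare_fold_change_vectors(fc_n$ratios, fc_r$ratios),
       n_nterm = fc_n$n_obs, n_rest = fc_r$n_obs)
}

## ---- linkers --------------------------------------------------------------

#' Inter-domain linkers
#'
#' The linker between consecutive domains ending at e and starting at s is
#' [e+1, s-1]; a span shorter than 5 residues is extended downstream (into
#' the next domain) to length 5, clipped at the protein end.
#'
#' @param domains data.frame of domain intervals for ONE protein (columns
#'   `start`, `end`), non-overlapping.
#' @param protein_length length of the protein.
#' @param min_length minimum linker length (default 5).
#' @return data.frame with columns `start`, `end`, one row per linker.
#' @export
define_linkers <- function(domains, protein_length, min_length = 5) {
  domains <- domains[order(domains$start), , drop = FALSE]
  if (nrow(domains) < 2) stop("need at least 2 domains")
  if (any(domains$start[-1] <= domains$end[-nrow(domains)]))
    stop("overlapping domains")
  out <- lapply(seq_len(nrow(domains) - 1), function(i) {
    s <- domains$end[i] + 1
    e <- domains$start[i + 1] - 1
    if (e - s + 1 < min_length) e <- s + min_length - 1
    e <- min(e, protein_length)
    data.frame(start = s, end = e)
  })
  do.call(rbind, out)
}

## Extract subsequences for a set of intervals (list of data.frames keyed by
## protein, or a track data.frame). Returns a character vector of segments.
extract_segments <- function(proteome, track) {
  vapply(seq_len(nrow(track)), function(i)
    substr(proteome[[track$protein_id[i]]], track$start[i], track$end[i]),
    character(1))
}

## ---- Markov region enrichment ---------------------------------------------

#' Enrichment/depletion of diproline words in a set of sequence segments
#'
#' The observed statistic is the overlapping PP word count inside the
#' segments; the expectation and variance follow from the M0 null (letter
#' frequencies estimated from the segment set itself unless a null is
#' supplied), and the p-value from [markov_word_test()].
#'
#' @param segments character vector of sequence segments.
#' @param null optional `markov_null`; default: estimated from `segments`.
#' @param word proline-run word (default "PP").
#' @param exact_threshold passed to [markov_word_test()].
#' @return a `fold_change_result` with `null_kind = "MARKOV_M0"`.
#' @export
region_enrichment <- function(segments, null = NULL, word = "PP",
                              exact_threshold = 2000) {
  segments <- segments[nchar(segments) >= nchar(word)]
  if (length(segments) == 0) stop("empty segment set")
  if (is.null(null)) null <- markov_null(segments, source = "segments")
  n_obs <- count_pp_words(segments)
  lens <- nchar(segments)
  tst <- markov_word_test(n_obs, lens, null, word, exact_threshold)
  degenerate <- tst$expectation == 0
  structure(list(
    n_obs = n_obs, n_exp = tst$expectation,
    fold_change = if (degenerate) NA_real_ else n_obs / tst$expectation,
    variance = tst$variance, z = tst$z,
    p_deplete = tst$p_deplete, p_enrich = tst$p_enrich,
    p_value = tst$p_value, branch = tst$branch,
    null_kind = "MARKOV_M0", degenerate = degenerate),
    class = "fold_change_result")
}

## ---- boundary profiles ----------------------------------------------------

#' Positional profile of motif anchors around annotation boundaries
#'
#' For each anchor instance (protein start, domain start/end or TMH start),
#' every motif anchor in the same protein contributes one count at
#' offset = motif anchor - anchor position (offset 0 is the anchor residue;
#' negative offsets are upstream). Frequencies are normalised by the number
#' of anchor instances whose protein covers each offset, then smoothed over a
#' three-residue window (edges average the available points).
#'
#' @param proteome named character vector.
#' @param motif_table motif table for the proteome.
#' @param track annotation track (ignored for `anchor_kind =
#'   "PROTEIN_START"`).
#' @param anchor_kind one of `"PROTEIN_START"`, `"DOMAIN_START"`,
#'   `"DOMAIN_END"`, `"TMH_START"`.
#' @param offsets integer window, e.g. `-25:25`.
#' @return a `positional_profile`: data.frame with columns `offset`,
#'   `raw_count`, `n_contributing`, `frequency`, `smoothed`.
#' @export
boundary_profile <- function(proteome, motif_table, track = NULL,
                             anchor_kind = c("PROTEIN_START", "DOMAIN_START",
                                             "DOMAIN_END", "TMH_START"),
                             offsets = -25:25) {
  anchor_kind <- match.arg(anchor_kind)
  anchors <- switch(anchor_kind,
    PROTEIN_START = data.frame(protein_id = names(proteome), pos = 1L),
    DOMAIN_START = data.frame(protein_id = track$protein_id,
                              pos = track$start),
    DOMAIN_END = data.frame(protein_id = track$protein_id, pos = track$end),
    TMH_START = data.frame(protein_id = track$protein_id, pos = track$start))
  lens <- nchar(proteome)
  raw <- setNames(numeric(length(offsets)), offsets)
  ncontrib <- setNames(numeric(length(offsets)), offsets)
  anchor_by_prot <- split(anchors$pos, anchors$protein_id)
  motif_by_prot <- split(motif_table$start, motif_table$protein_id)
  for (pid in names(anchor_by_prot)) {
    L <- lens[[pid]]
    for (apos in anchor_by_prot[[pid]]) {
      abs_pos <- apos + offsets
      covered <- abs_pos >= 1 & abs_pos <= L
      ncontrib <- ncontrib + covered
      mpos <- motif_by_prot[[pid]]
      if (!is.null(mpos)) {
        off <- mpos - apos
        off <- off[off >= min(offsets) & off <= max(offsets)]
        if (length(off))
          raw <- raw + tabulate(off - min(offsets) + 1L,
                                nbins = length(offsets))
      }
    }
  }
  freq <- ifelse(ncontrib > 0, raw / ncontrib, 0)
  smoothed <- smooth3(freq)
  out <- data.frame(offset = offsets, raw_count = as.numeric(raw),
                    n_contributing = as.numeric(ncontrib),
                    frequency = freq, smoothed = smoothed)
  rownames(out) <- NULL
  class(out) <- c("positional_profile", "data.frame")
  attr(out, "anchor_kind") <- anchor_kind
  out
}

## 3-point moving average; edges average the available points.
smooth3 <- function(x) {
  n <- length(x)
  if (n == 0) return(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - 1):min(n, i + 1)
    mean(x[idx])
  }, numeric(1))
}

#' Enrichment in boundary windows
#'
#' Extracts the window `rel_window` (offsets relative to each anchor
#' instance, same convention as [boundary_profile()]) for every anchor whose
#' window lies fully inside the protein, and runs [region_enrichment()] on
#' the extracted segments.
#'
#' @inheritParams boundary_profile
#' @param rel_window integer c(lo, hi) offsets, e.g. c(-12, -2) relative to
#'   domain starts.
#' @return a `fold_change_result`.
#' @export
boundary_window_enrichment <- function(proteome, track,
                                       anchor_kind = "DOMAIN_START",
                                       rel_window = c(-12, -2)) {
  pos <- if (anchor_kind == "DOMAIN_END") track$end else track$start
  win <- data.frame(protein_id = track$protein_id,
                    start = pos + rel_window[1], end = pos + rel_window[2])
  lens <- nchar(proteome)[win$protein_id]
  win <- win[win$start >= 1 & win$end <= lens, , drop = FALSE]
  if (nrow(win) == 0) stop("no complete windows")
  region_enrichment(extract_segments(proteome, win))
}

## ---- TMH sites ------------------------------------------------------------

## Default site definitions, offsets relative to the TMH start:
## positive offsets are 1-based positions counted from the TMH
## start (+1 = the start residue itself), negative offsets upstream (-1 = the
## residue immediately before the start). There is no offset 0.
TMH_SITES <- list(I = c(-17, -1), II = c(23, 32), III = c(49, 59),
                  IV = c(77, 87))

site_absolute <- function(tmh_start, site) {
  lo <- if (site[1] > 0) tmh_start + site[1] - 1L else tmh_start + site[1]
  hi <- if (site[2] > 0) tmh_start + site[2] - 1L else tmh_start + site[2]
  c(lo, hi)
}

#' TMH-relative site analysis
#'
#' For every TMH instance and every site (default: site I = -17..-1, II =
#' 23..32, III = 49..59, IV = 77..87 relative to the TMH start), the site's
#' absolute interval is computed; instances extending beyond the protein are
#' dropped. Each instance is labelled `TMH` if its midpoint residue lies
#' inside any annotated TMH of that protein, else `non-TMH`, and
#' [region_enrichment()] is run per (site, label) group.
#'
#' @param proteome named character vector.
#' @param tmh_track annotation track of TMH intervals.
#' @param sites named list of c(lo, hi) offset pairs.
#' @param exact_threshold passed to [region_enrichment()].
#' @return data.frame with one row per (site, location): instance counts,
#'   observed and expected counts, fold change and p-value.
#' @export
tmh_site_analysis <- function(proteome, tmh_track, sites = TMH_SITES,
                              exact_threshold = 2000) {
  if (nrow(tmh_track) == 0) stop("TMH track is empty")
  lens <- nchar(proteome)
  inst <- list()
  for (si in names(sites)) {
    ab <- t(vapply(tmh_track$start, site_absolute, numeric(2),
                   site = sites[[si]]))
    df <- data.frame(protein_id = tmh_track$protein_id, site = si,
                     start = ab[, 1], end = ab[, 2],
                     stringsAsFactors = FALSE)
    df <- df[df$start >= 1 & df$end <= lens[df$protein_id], , drop = FALSE]
    if (nrow(df) == 0) next
    mid <- floor((df$start + df$end) / 2)
    in_tmh <- vapply(seq_len(nrow(df)), function(i) {
      tm <- tmh_track[tmh_track$protein_id == df$protein_id[i], ]
      any(mid[i] >= tm$start & mid[i] <= tm$end)
    }, logical(1))
    df$location <- ifelse(in_tmh, "TMH", "non-TMH")
    inst[[si]] <- df
  }
  inst <- do.call(rbind, c(inst, list(make.row.names = FALSE)))
  rows <- list()
  for (si in unique(inst$site)) for (loc in c("TMH", "non-TMH")) {
    sub <- inst[inst$site == si & inst$location == loc, , drop = FALSE]
    if (nrow(sub) == 0) next
    fc <- region_enrichment(extract_segments(proteome, sub),
                            exact_threshold = exact_threshold)
    rows[[length(rows) + 1]] <- data.frame(
      site = si, location = loc, n_instances = nrow(sub),
      n_obs = fc$n_obs, n_exp = fc$n_exp, fold_change = fc$fold_change,
      p_enrich = fc$p_enrich, p_deplete = fc$p_deplete,
      p_value = fc$p_value, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Motif-bearing proportion: transmembrane vs soluble proteins
#'
#' 2x2 contingency (harbors >= 1 motif yes/no, TP vs soluble) tested by the
#' chi-squared test without continuity correction.
#'
#' @param tp_ids,soluble_ids disjoint character vectors of protein ids.
#' @param motif_table motif table covering both sets.
#' @return list with `prop_tp`, `prop_soluble`, `table`, `p_value`.
#' @export
tp_proportion_test <- function(tp_ids, soluble_ids, motif_table) {
  if (length(tp_ids) == 0 || length(soluble_ids) == 0)
    stop("both id sets must be non-empty")
  if (length(intersect(tp_ids, soluble_ids)))
    stop("id sets must be disjoint")
  has_motif <- unique(motif_table$protein_id)
  tab <- rbind(TP = c(sum(tp_ids %in% has_motif),
                      sum(!tp_ids %in% has_motif)),
               soluble = c(sum(soluble_ids %in% has_motif),
                           sum(!soluble_ids %in% has_motif)))
  colnames(tab) <- c("with_motif", "without_motif")
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(prop_tp = tab["TP", 1] / length(tp_ids),
       prop_soluble = tab["soluble", 1] / length(soluble_ids),
       table = tab, p_value = p)
}
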