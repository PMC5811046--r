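## Enrichment/depletion nulls.
##
## Two nulls are implemented. (i) Composition-preserving shuffling: each
## sequence is permuted uniformly at random; the observed motif count is
## divided by the mean count over R shuffled replicates (fold change =
## N_obs / N_exp), and the vector of per-replicate ratios supports rank-sum
## comparisons between sequence populations. (ii) A zero-order Markov model
## (M0): the expected number of overlapping occurrences of the diproline word
## PP in i.i.d. letters follows in closed form from the proline frequency;
## p-values come from an exact dynamic program over the count distribution or
## a Gaussian approximation with continuity correction.

## ---- counting helpers -----------------------------------------------------

## Sequences are handled internally as lists of single-letter vectors.
as_char_list <- function(sequences) {
  if (is.list(sequences)) return(sequences)
  strsplit(unname(sequences), "", fixed = TRUE)
}

## Number of maximal P-runs of length >= 2 in one letter vector.
count_stretches_chars <- function(chars) {
  r <- rle(chars == "P")
  sum(r$values & r$lengths >= 2L)
}

#' Count polyproline motifs (maximal P-runs of length >= 2)
#'
#' @param sequences character vector of sequences, or list of letter vectors.
#' @return total motif count over all sequences.
#' @export
count_motifs <- function(sequences) {
  sum(vapply(as_char_list(sequences), count_stretches_chars, integer(1)))
}

#' Count overlapping occurrences of the diproline word PP
#'
#' A run of m prolines contains m - 1 overlapping PP words; this is the word
#' statistic the Markov M0 test operates on (in contrast to the
#' maximal-stretch motif count used by the shuffle null).
#'
#' @inheritParams count_motifs
#' @return total overlapping PP count over all sequences.
#' @export
count_pp_words <- function(sequences) {
  sum(vapply(as_char_list(sequences), function(chars) {
    if (length(chars) < 2L) return(0L)
    p <- chars == "P"
    sum(p[-length(p)] & p[-1L])
  }, integer(1)))
}

## Counter factory: motifs of one strength class (or "ALL" raw motifs).
## Used for strength-stratified shuffle normalisation.
strength_counter <- function(class = "ALL", rules = default_rule_table()) {
  force(rules)
  if (identical(class, "ALL")) return(count_motifs)
  stopifnot(class %in% c("WEAK", "MEDIUM", "STRONG"))
  function(sequences) {
    chl <- as_char_list(sequences)
    total <- 0L
    for (chars in chl) {
      m <- scan_motifs(paste(chars, collapse = ""), "x")
      if (nrow(m) == 0) next
      m <- classify_motifs(m, rules)
      total <- total + sum(m$strength == class)
    }
    total
  }
}

## ---- shuffle null ---------------------------------------------------------

#' Composition-preserving sequence shuffle
#'
#' Uniformly random permutation of the letters of a sequence (Fisher-Yates
#' contract via `sample.int`), reproducible given `seed`. The letter multiset
#' is preserved exactly.
#'
#' @param sequence a single sequence string.
#' @param seed integer seed.
#' @return the shuffled sequence string.
#' @export
shuffle_sequence <- function(sequence, seed) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  chars <- seq_chars(sequence)
  with_seed(seed, paste(chars[sample.int(length(chars))], collapse = ""))
}

#' Fold change of motif occurrence under the shuffle null
#'
#' Shuffles every sequence `replicates` times (replicate r of sequence i uses
#' the seed derived from `(seed, r, i)`), counts motifs with `motif_counter`
#' summed over all sequences within each replicate, and forms
#' fold change = N_obs / mean(replicate counts). Empirical tail p-values use
#' the pseudocount form (1 + k) / (R + 1).
#'
#' @param sequences character vector of sequences.
#' @param motif_counter function(list of letter vectors) -> count; default
#'   counts maximal polyproline stretches.
#' @param replicates number of shuffle replicates R (default 1000).
#' @param seed root seed.
#' @return a `fold_change_result`: list with `n_obs`, `n_exp`,
#'   `fold_change`, `replicate_counts`, `ratios` (N_obs / replicate count,
#'   NA where a replicate count is zero), `p_deplete`, `p_enrich`, `p_value`
#'   (two-sided), `null_kind = "SHUFFLE"`, `degenerate` flag.
#' @export
shuffle_fold_change <- function(sequences, motif_counter = count_motifs,
                                replicates = 1000, seed = 1) {
  stopifnot(replicates >= 1)
  chl <- as_char_list(sequences)
  if (length(chl) == 0) stop("no sequences")
  n_obs <- motif_counter(chl)
  lens <- lengths(chl)
  counts <- numeric(replicates)
  for (r in seq_len(replicates)) {
    shuffled <- vector("list", length(chl))
    for (i in seq_along(chl)) {
      s <- derive_seed(seed, r, i)
      shuffled[[i]] <- with_seed(s, chl[[i]][sample.int(lens[i])])
    }
    counts[r] <- motif_counter(shuffled)
  }
  n_exp <- mean(counts)
  degenerate <- n_exp == 0
  ratios <- ifelse(counts > 0, n_obs / counts, NA_real_)
  p_dep <- (1 + sum(counts <= n_obs)) / (replicates + 1)
  p_enr <- (1 + sum(counts >= n_obs)) / (replicates + 1)
  structure(list(
    n_obs = n_obs, n_exp = n_exp,
    fold_change = if (degenerate) NA_real_ else n_obs / n_exp,
    replicate_counts = counts, ratios = ratios,
    p_deplete = p_dep, p_enrich = p_enr,
    p_value = min(1, 2 * min(p_dep, p_enr)),
    null_kind = "SHUFFLE", replicates = replicates, seed = seed,
    degenerate = degenerate), class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf(
    "fold change %s: n_obs=%s n_exp=%.3f fc=%.4f p=%.3g (deplete %.3g / enrich %.3g)\n",
    x$null_kind, format(x$n_obs), x$n_exp,
    ifelse(is.na(x$fold_change), NaN, x$fold_change),
    x$p_value, x$p_deplete, x$p_enrich))
  invisible(x)
}

## ---- Markov M0 null -------------------------------------------------------

#' Zero-order Markov null model
#'
#' Letter frequencies estimated from the sequence set under test (or supplied
#' directly), defining an i.i.d. null for word-count statistics.
#'
#' @param sequences sequences to estimate frequencies from (ignored if
#'   `freqs` given).
#' @param freqs optional named probability vector over the alphabet.
#' @param source free-text note on where the frequencies come from.
#' @return a `markov_null` object (order 0).
#' @export
markov_null <- function(sequences = NULL, freqs = NULL, source = "sequences") {
  if (is.null(freqs)) {
    if (is.null(sequences)) stop("supply sequences or freqs")
    chars <- unlist(as_char_list(sequences), use.names = FALSE)
    tb <- table(chars)
    freqs <- as.numeric(tb) / sum(tb)
    names(freqs) <- names(tb)
  }
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("frequencies must be nonnegative and sum to 1")
  structure(list(order = 0L, letter_freqs = freqs, source = source),
            class = "markov_null")
}

## Word must be a homopolymer proline run "PP", "PPP", ...; returns run length.
check_word <- function(word) {
  k <- nchar(word)
  if (k < 2 || !all(seq_chars(word) == "P"))
    stop("unsupported pattern: only homopolymer proline-run words (e.g. \"PP\") are supported")
  k
}

#' Expected overlapping word count under the M0 null
#'
#' For a homopolymer word of length k and letter frequency p in one sequence
#' of length L there are L - k + 1 overlapping windows, each matching with
#' probability p^k; the expectation is (L - k + 1) p^k. The variance accounts
#' for self-overlap: windows at lag d < k share letters, with
#' E[I_i I_(i+d)] = p^(k + d). Totals sum over sequences.
#'
#' @param lengths integer vector of sequence lengths (each >= nchar(word)).
#' @param null a `markov_null`.
#' @param word the proline-run word (default "PP").
#' @return list with `expectation` and `variance` of the total count.
#' @export
markov_expected_count <- function(lengths, null, word = "PP") {
  k <- check_word(word)
  if (any(lengths < k)) stop("all lengths must be >= word length")
  p <- unname(null$letter_freqs["P"])
  if (is.na(p)) p <- 0
  expectation <- sum(lengths - k + 1) * p^k
  variance <- 0
  for (L in lengths) {
    W <- L - k + 1
    v <- W * p^k * (1 - p^k)
    if (W > 1) {
      d <- seq_len(min(k - 1, W - 1))
      v <- v + 2 * sum((W - d) * (p^(k + d) - p^(2 * k)))
    }
    variance <- variance + v
  }
  list(expectation = expectation, variance = variance)
}

#' Exact distribution of the overlapping proline-word count
#'
#' Dynamic program over positions with state (current count, trailing P-run
#' length) for i.i.d. letters; distributions of independent sequences are
#' convolved. Exact up to the support cap `kmax`.
#'
#' @inheritParams markov_expected_count
#' @param kmax cap on the count support (default: full support).
#' @return numeric vector `prob` where `prob[j + 1] = P(count = j)`.
#' @export
markov_count_distribution <- function(lengths, null, word = "PP",
                                      kmax = NULL) {
  k <- check_word(word)
  p <- unname(null$letter_freqs["P"])
  if (is.na(p)) p <- 0
  max_count <- sum(pmax(lengths - k + 1, 0))
  if (is.null(kmax)) kmax <- max_count
  kmax <- min(kmax, max_count)
  total <- 1 # distribution of the running total, starts at P(0) = 1
  for (L in lengths) {
    ## state matrix: rows = count 0..kmax, cols = trailing run 0..k (capped)
    st <- matrix(0, nrow = kmax + 1, ncol = k + 1)
    st[1, 1] <- 1
    for (pos in seq_len(L)) {
      nxt <- matrix(0, nrow = kmax + 1, ncol = k + 1)
      ## non-P letter: run resets, count unchanged
      nxt[, 1] <- rowSums(st) * (1 - p)
      ## P letter
      for (r in 0:(k - 1)) {
        col <- r + 1
        if (r + 1 < k) {
          nxt[, r + 2] <- nxt[, r + 2] + st[, col] * p
        } else {
          ## completes the word: count + 1, run enters the saturated state
          if (kmax >= 1)
            nxt[2:(kmax + 1), k + 1] <- nxt[2:(kmax + 1), k + 1] +
              st[1:kmax, col] * p
        }
      }
      ## saturated run: each further P adds one occurrence
      if (kmax >= 1)
        nxt[2:(kmax + 1), k + 1] <- nxt[2:(kmax + 1), k + 1] +
          st[1:kmax, k + 1] * p
      st <- nxt
    }
    dist_one <- rowSums(st)
    ## convolve with the running total
    new_total <- numeric(kmax + 1)
    for (j in seq_along(total)) {
      jj <- j:(kmax + 1)
      new_total[jj] <- new_total[jj] + total[j] * dist_one[seq_along(jj)]
    }
    total <- new_total
  }
  total
}

#' Significance of word-count enrichment or depletion under M0
#'
#' Below `exact_threshold` total residues, p-values come from the exact
#' dynamic-programming count distribution; above it, from a Gaussian
#' approximation with continuity correction. The branch used is reported.
#'
#' @param n_obs observed overlapping word count.
#' @param lengths sequence lengths.
#' @param null a `markov_null`.
#' @param word proline-run word (default "PP").
#' @param exact_threshold total-length cutoff for the exact branch.
#' @return list with `z`, `p_enrich`, `p_deplete`, `p_value` (two-sided,
#'   capped at 1), `branch` ("exact" or "gaussian"), `expectation`,
#'   `variance`.
#' @export
markov_word_test <- function(n_obs, lengths, null, word = "PP",
                             exact_threshold = 2000) {
  ev <- markov_expected_count(lengths, null, word)
  if (sum(lengths) <= exact_threshold) {
    prob <- markov_count_distribution(lengths, null, word)
    idx <- n_obs + 1
    p_enr <- if (idx <= length(prob)) sum(prob[idx:length(prob)]) else 0
    p_dep <- if (idx >= 1) sum(prob[seq_len(min(idx, length(prob)))]) else 0
    z <- if (ev$variance > 0) (n_obs - ev$expectation) / sqrt(ev$variance)
         else NA_real_
    branch <- "exact"
  } else {
    if (ev$variance <= 0) stop("variance must be positive for the Gaussian branch")
    sd <- sqrt(ev$variance)
    z <- (n_obs - ev$expectation) / sd
    p_enr <- stats::pnorm((n_obs - 0.5 - ev$expectation) / sd,
                          lower.tail = FALSE)
    p_dep <- stats::pnorm((n_obs + 0.5 - ev$expectation) / sd)
    branch <- "gaussian"
  }
  list(z = z, p_enrich = p_enr, p_deplete = p_dep,
       p_value = min(1, 2 * min(p_enr, p_dep)), branch = branch,
       expectation = ev$expectation, variance = ev$variance)
}

## ---- dimer ratios ---------------------------------------------------------

#' Observed/expected frequency ratios for amino-acid dimers
#'
#' Observed dimer frequencies are computed from overlapping windows within
#' each sequence (no dimers across sequence boundaries); the expected
#' frequency of dimer ab is the product of the observed single-letter
#' frequencies f_a f_b.
#'
#' @param proteome named character vector of sequences.
#' @return data.frame with columns `a`, `b`, `dimer`, `obs_freq`, `exp_freq`,
#'   `ratio`, one row per ordered letter pair over the observed alphabet.
#' @export
dimer_ratio_table <- function(proteome) {
  if (length(proteome) == 0) stop("non-empty proteome required")
  chl <- as_char_list(proteome)
  letters1 <- unlist(chl, use.names = FALSE)
  tb1 <- table(letters1)
  f1 <- setNames(as.numeric(tb1) / sum(tb1), names(tb1))
  firsts <- unlist(lapply(chl, function(x) x[-length(x)]), use.names = FALSE)
  seconds <- unlist(lapply(chl, function(x) x[-1L]), use.names = FALSE)
  alph <- sort(names(f1))
  tb <- table(factor(firsts, levels = alph), factor(seconds, levels = alph))
  obs <- as.numeric(tb) / sum(tb)
  grid <- expand.grid(a = alph, b = alph, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  ## table() fills column-major over (first, second); expand.grid varies `a`
  ## fastest, matching rows to tb entries
  exp_freq <- f1[grid$a] * f1[grid$b]
  data.frame(a = grid$a, b = grid$b, dimer = paste0(grid$a, grid$b),
             obs_freq = obs, exp_freq = unname(exp_freq),
             ratio = ifelse(exp_freq > 0, obs / exp_freq, NA_real_),
             stringsAsFactors = FALSE)
}

#' Compare two fold-change ratio vectors
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test with tie correction (normal
#' approximation), symmetric in its arguments. Degenerate all-tied input
#' returns p = 1.
#'
#' @param ratios_a,ratios_b numeric vectors (NAs dropped).
#' @return two-sided p-value.
#' @export
compare_fold_change_vectors <- function(ratios_a, ratios_b) {
  a <- ratios_a[!is.na(ratios_a)]
  b <- ratios_b[!is.na(ratios_b)]
  if (length(a) < 1 || length(b) < 1) stop("both vectors must be non-empty")
  if (length(unique(c(a, b))) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
}
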