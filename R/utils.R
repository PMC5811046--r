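#' @keywords internal
"_PACKAGE"

## Canonical order of stalling states; rank 0..3 follows position in this vector.
STRENGTH_LEVELS <- c("NONE", "WEAK", "MEDIUM", "STRONG")

#' Rank of a stalling strength class
#'
#' Total order NONE (0) < WEAK (1) < MEDIUM (2) < STRONG (3). All comparisons
#' between classes in this package go through ranks.
#'
#' @param x character vector of class labels.
#' @return integer vector of ranks in 0..3; NA for unknown labels
#'   (e.g. "UNCLASSIFIED").
#' @export
strength_rank <- function(x) {
  r <- match(x, STRENGTH_LEVELS) - 1L
  r
}

## The 20 standard amino-acid letters.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Amino-acid composition of the E. coli K-12 proteome (UniProt-style
## background frequencies, renormalised). Used as the generator default.
ECOLI_AA_FREQS <- c(
  A = 0.0950, C = 0.0117, D = 0.0515, E = 0.0576, F = 0.0390,
  G = 0.0737, H = 0.0227, I = 0.0601, K = 0.0441, L = 0.1066,
  M = 0.0282, N = 0.0395, P = 0.0442, Q = 0.0444, R = 0.0553,
  S = 0.0580, T = 0.0540, V = 0.0707, W = 0.0153, Y = 0.0284)
ECOLI_AA_FREQS <- ECOLI_AA_FREQS / sum(ECOLI_AA_FREQS)

#' Deterministic seed derivation
#'
#' Derives a child seed from a root seed and up to two stream indices, so that
#' every replicate/sequence combination has its own reproducible RNG stream.
#' Pure integer arithmetic on doubles (exact below 2^53); result in
#' 1..2^31-2.
#'
#' @param root integer root seed.
#' @param a,b nonnegative integer stream indices.
#' @return a single integer seed.
#' @export
derive_seed <- function(root, a = 0L, b = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(root) %% m) * 48271 %% m
  x <- (x + as.numeric(a) * 1299709 + as.numeric(b) * 15485863) %% m
  as.integer(x %% (m - 1) + 1)
}

## Evaluate expr under a local RNG seed, restoring the global RNG state.
with_seed <- function(seed, expr) {
  force(seed) # must precede the state save: the argument may draw from the RNG
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Split a sequence string into a character vector of single letters.
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

## Validate a proteome: named character vector, unique non-empty ids.
check_proteome <- function(proteome) {
  if (length(proteome) == 0) return(invisible(proteome))
  ids <- names(proteome)
  if (is.null(ids) || any(ids == "" | is.na(ids)))
    stop("proteome must be a named character vector of sequences")
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(proteome)
}
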