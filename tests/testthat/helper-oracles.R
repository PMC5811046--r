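## Independent oracles and small fixture generators used across the suite.
## These deliberately use different machinery than the package internals
## (regex instead of rle scanning; exhaustive enumeration instead of pruning
## or dynamic programming).

STATES4 <- c("NONE", "WEAK", "MEDIUM", "STRONG")

## i.i.d. amino-acid sequences with a controlled proline frequency.
random_aa_seqs <- function(n, len, f_p = 0.05, seed = 1) {
  alphabet <- c("P", "A", "G", "L", "K", "V", "D", "S")
  probs <- c(f_p, rep((1 - f_p) / 7, 7))
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(alphabet, len, replace = TRUE, prob = probs),
            collapse = ""),
      character(1))
  })
}

## Regex oracle for maximal polyproline stretches: starts and lengths of
## every match of P{2,} (regex matches are maximal by construction).
regex_scan_oracle <- function(sequence) {
  m <- gregexpr("P{2,}", sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), n = integer(0)))
  data.frame(start = as.integer(m), n = attr(m, "match.length"))
}

## Exhaustive distribution of the overlapping PP count over {P, A}^L with
## P(P) = p: enumerates all 2^L sequences.
enum_pp_dist <- function(L, p) {
  counts <- integer(2^L)
  probs <- numeric(2^L)
  for (idx in 0:(2^L - 1)) {
    bits <- as.integer(intToBits(idx))[seq_len(L)] # 1 = P
    cnt <- if (L >= 2) sum(bits[-L] & bits[-1]) else 0L
    counts[idx + 1] <- cnt
    probs[idx + 1] <- prod(ifelse(bits == 1, p, 1 - p))
  }
  kmax <- max(counts)
  vapply(0:kmax, function(k) sum(probs[counts == k]), numeric(1))
}

## Symmetric Mk transition matrix (closed form), duplicated here on purpose.
oracle_pmat <- function(alpha, t) {
  e <- exp(-4 * alpha * t)
  m <- matrix(0.25 - 0.25 * e, 4, 4)
  diag(m) <- 0.25 + 0.75 * e
  m
}

## Brute-force joint enumeration over all internal-node states: returns the
## log-likelihood and the marginal posterior matrix for internal nodes.
brute_force_mk <- function(tree, leaf_states, alpha) {
  ntip <- ape::Ntip(tree); nn <- tree$Nnode
  ranks <- match(leaf_states[tree$tip.label], STATES4)
  combs <- as.matrix(expand.grid(rep(list(1:4), nn)))
  liks <- numeric(nrow(combs))
  for (r in seq_len(nrow(combs))) {
    st <- c(ranks, combs[r, ])
    lik <- 0.25
    for (e in seq_len(nrow(tree$edge))) {
      P <- oracle_pmat(alpha, tree$edge.length[e])
      lik <- lik * P[st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    liks[r] <- lik
  }
  post <- matrix(0, nn, 4)
  for (j in seq_len(nn)) for (s in 1:4)
    post[j, s] <- sum(liks[combs[, j] == s])
  list(loglik = log(sum(liks)), posteriors = post / sum(liks))
}

## Random leaf-state assignment.
random_states <- function(tips, seed = 1) {
  withr::with_seed(seed,
    setNames(sample(STATES4, length(tips), replace = TRUE), tips))
}
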