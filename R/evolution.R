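## Evolution of ribosome-stalling states on phylogenies.
##
## Motif-bearing aligned regions are extracted from per-group multiple
## alignments; each leaf carries one of the four stalling states
## NONE < WEAK < MEDIUM < STRONG. Ancestral states are reconstructed by
## maximum likelihood under a symmetric 4-state Mk model with a single rate
## alpha (transition probability to the same state over branch length t is
## 1/4 + 3/4 exp(-4 alpha t)); each internal node receives the state with
## maximal marginal posterior under a uniform root prior, ties broken toward
## the weaker state. Branches whose endpoint states differ carry a gain
## (child ranks higher) or loss (child ranks lower) event, and the propensity
## of stalling effect change is
##   PSEC = sum(B_g)/sum(B_cg) - sum(B_l)/sum(B_cl),
## where B_g/B_l are branch lengths carrying gains/losses and B_cg/B_cl are
## branch lengths on which a gain (parent not STRONG) or loss (parent not
## NONE) was possible.

## ---- aligned regions ------------------------------------------------------

#' Map motifs to alignment columns and build motif-bearing regions
#'
#' Each motif's proline stretch is mapped through its sequence's gap structure
#' to alignment columns; column intervals overlapping across sequences are
#' merged transitively into regions. A leaf's state in a region is the
#' highest-ranking strength among its motifs overlapping the region (>= 1
#' shared column), else `"NONE"`. Motifs labelled `"UNCLASSIFIED"` do not
#' contribute states.
#'
#' @param msa named character vector of aligned sequences (gap character
#'   `"-"`), all the same width.
#' @param motif_table motif table for the de-gapped sequences (coordinates in
#'   residue space).
#' @param og_id group identifier carried into the output.
#' @param proteome optional named character vector to check that each aligned
#'   sequence de-gaps to its proteome sequence.
#' @return list of `aligned_region` objects: `og_id`, `columns`
#'   (c(start, end), 1-based inclusive), `leaf_states` (named vector over all
#'   alignment sequences), `fragmented` (TRUE when a gap splits a stretch
#'   across non-adjacent columns).
#' @export
map_motifs_to_alignment <- function(msa, motif_table, og_id = "og",
                                    proteome = NULL) {
  if (length(unique(nchar(msa))) != 1)
    stop("aligned sequences must all have the same width")
  width <- nchar(msa[[1]])
  ids <- names(msa)
  col_maps <- lapply(msa, function(s) which(seq_chars(s) != "-"))
  if (!is.null(proteome)) {
    for (id in ids) {
      degapped <- gsub("-", "", msa[[id]], fixed = TRUE)
      if (!identical(degapped, unname(proteome[[id]])))
        stop("de-gapped alignment sequence does not match proteome: ", id)
    }
  }
  mt <- motif_table[motif_table$protein_id %in% ids, , drop = FALSE]
  if (nrow(mt) == 0) return(list())
  iv <- lapply(seq_len(nrow(mt)), function(i) {
    cols <- col_maps[[mt$protein_id[i]]]
    res <- mt$start[i]:(mt$start[i] + mt$n[i] - 1L)
    if (max(res) > length(cols))
      stop("motif outside de-gapped sequence length: ", mt$protein_id[i])
    cc <- cols[res]
    c(min(cc), max(cc), span = max(cc) - min(cc) + 1L > mt$n[i])
  })
  iv <- do.call(rbind, iv)
  ## transitive merge of overlapping column intervals
  ord <- order(iv[, 1], iv[, 2])
  iv <- iv[ord, , drop = FALSE]
  mt <- mt[ord, , drop = FALSE]
  group <- integer(nrow(iv))
  g <- 0L; cur_end <- -1L
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 1] > cur_end) { g <- g + 1L; cur_end <- iv[i, 2] }
    else cur_end <- max(cur_end, iv[i, 2])
    group[i] <- g
  }
  regions <- lapply(split(seq_len(nrow(iv)), group), function(idx) {
    cols <- c(min(iv[idx, 1]), max(iv[idx, 2]))
    states <- setNames(rep("NONE", length(ids)), ids)
    sub <- mt[idx, , drop = FALSE]
    sub <- sub[!is.na(sub$strength) & sub$strength != "UNCLASSIFIED", ,
               drop = FALSE]
    if (nrow(sub)) {
      for (pid in unique(sub$protein_id)) {
        cls <- sub$strength[sub$protein_id == pid]
        states[pid] <- STRENGTH_LEVELS[max(strength_rank(cls)) + 1L]
      }
    }
    structure(list(og_id = og_id, columns = cols, leaf_states = states,
                   fragmented = any(iv[idx, 3] == 1)),
              class = "aligned_region")
  })
  names(regions) <- NULL
  regions
}

## ---- midpoint rooting -----------------------------------------------------

#' Midpoint rooting
#'
#' Roots an (un)rooted tree at the midpoint of the longest leaf-to-leaf path.
#' Ties on the longest path are broken deterministically toward the
#' lexicographically smallest (sorted) leaf-name pair. Pairwise leaf path
#' lengths are preserved. When every branch length is zero the tree is rooted
#' at the lexicographically smallest leaf's attachment and flagged with
#' attribute `degenerate_root`.
#'
#' @param tree an `ape::phylo` with branch lengths >= 0 and >= 2 leaves.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (ape::Ntip(tree) < 2) stop("need at least 2 leaves")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (ape::Ntip(tree) == 2) {
    len <- sum(tree$edge.length)
    lab <- sort(tree$tip.label)
    out <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", lab[1], len / 2,
                                         lab[2], len / 2))
    return(out)
  }
  dn <- ape::dist.nodes(tree)
  ntip <- ape::Ntip(tree)
  dt <- dn[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dmax <- max(dt)
  if (dmax == 0) {
    tip <- which(tree$tip.label == sort(tree$tip.label)[1])
    out <- ape::root(tree, outgroup = tip, resolve.root = TRUE)
    attr(out, "degenerate_root") <- TRUE
    return(out)
  }
  cand <- which(dt == dmax, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  pair_names <- apply(cand, 1, function(rw)
    paste(sort(tree$tip.label[rw]), collapse = "\r"))
  pick <- cand[order(pair_names)[1], ]
  path <- ape::nodepath(tree, pick[1], pick[2])
  half <- dmax / 2
  cum <- c(0, cumsum(dn[cbind(path[-length(path)], path[-1])]))
  t_idx <- which(cum >= half - 1e-12)[1]
  lo <- path[t_idx - 1]; hi <- path[t_idx]
  ## the new root lies on edge (lo, hi), at distance cum[t_idx] - half from hi
  edge_child <- if (any(tree$edge[, 1] == lo & tree$edge[, 2] == hi)) hi else lo
  pos_from_child <- if (edge_child == hi) cum[t_idx] - half
                    else half - cum[t_idx - 1]
  elen <- tree$edge.length[tree$edge[, 2] == edge_child]
  pos_from_child <- min(max(pos_from_child, 0), elen)
  ## phytools::reroot measures `position` from the parent end of the edge
  out <- phytools::reroot(tree, node.number = edge_child,
                          position = elen - pos_from_child)
  out
}

## ---- Mk likelihood and marginal reconstruction ----------------------------

## Transition probability matrix of the symmetric 4-state Mk model.
mk_pmat <- function(alpha, t) {
  e <- exp(-4 * alpha * t)
  same <- 0.25 + 0.75 * e
  diff <- 0.25 - 0.25 * e
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

## Post-order partial likelihoods D[node, state] = P(data below node | state).
mk_down <- function(tree, leaf_states, alpha) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  D <- matrix(0, ntip + nnode, 4)
  ranks <- strength_rank(leaf_states[tree$tip.label]) + 1L
  if (anyNA(ranks)) stop("leaf with missing or invalid state")
  D[cbind(seq_len(ntip), ranks)] <- 1
  reord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(reord$edge))) {
    parent <- reord$edge[i, 1]; child <- reord$edge[i, 2]
    P <- mk_pmat(alpha, reord$edge.length[i])
    msg <- as.numeric(P %*% D[child, ])
    if (all(D[parent, ] == 0)) D[parent, ] <- msg
    else D[parent, ] <- D[parent, ] * msg
  }
  D
}

## Careful: a parent's row starts as all-zero sentinel; internal nodes with a
## single processed child multiply correctly because postorder visits all
## children before the parent's own edge.

mk_loglik <- function(tree, leaf_states, alpha) {
  D <- mk_down(tree, leaf_states, alpha)
  root <- ape::Ntip(tree) + 1L
  log(sum(0.25 * D[root, ]))
}

#' Maximum likelihood ancestral reconstruction of stalling states
#'
#' Felsenstein pruning under the symmetric 4-state Mk model with uniform root
#' prior. The rate alpha is optimised by bounded one-dimensional likelihood
#' maximisation unless supplied. Every internal node is assigned the state
#' with maximal marginal posterior; ties (within 1e-12 relative) are broken
#' toward the weaker state.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param leaf_states named character vector (one of NONE/WEAK/MEDIUM/STRONG
#'   per tip label).
#' @param rate fixed alpha, or NULL to optimise.
#' @param rate_bounds optimisation bounds for alpha.
#' @return a `state_tree`: list with `tree`, `node_states` (length
#'   Ntip + Nnode, tips first), `posteriors` (matrix, internal nodes), `rate`,
#'   `loglik`.
#' @export
reconstruct_ancestral_states <- function(tree, leaf_states, rate = NULL,
                                         rate_bounds = c(1e-6, 100)) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!all(tree$tip.label %in% names(leaf_states)))
    stop("leaf_states must cover all leaves; missing: ",
         paste(setdiff(tree$tip.label, names(leaf_states)), collapse = ", "))
  if (is.null(rate)) {
    if (length(unique(leaf_states[tree$tip.label])) == 1) {
      rate <- rate_bounds[1] # invariant data: likelihood is flat-decreasing
    } else {
      ## optimise over log(alpha): the likelihood plateaus at high rates and
      ## golden-section search on the linear scale can stall on the plateau
      opt <- stats::optimize(function(la)
        mk_loglik(tree, leaf_states, exp(la)),
        interval = log(rate_bounds), maximum = TRUE)
      rate <- exp(opt$maximum)
    }
  }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  D <- mk_down(tree, leaf_states, rate)
  ## pre-order up-pass: U[node, state] = P(data elsewhere, state at node)
  U <- matrix(0, ntip + nnode, 4)
  root <- ntip + 1L
  U[root, ] <- 0.25
  reord <- ape::reorder.phylo(tree, "postorder")
  edges <- reord$edge[rev(seq_len(nrow(reord$edge))), , drop = FALSE]
  elens <- reord$edge.length[rev(seq_len(nrow(reord$edge)))]
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]; child <- edges[i, 2]
    ## contribution of the parent's other children
    sibs <- reord$edge[, 1] == parent & reord$edge[, 2] != child
    contrib <- U[parent, ]
    if (any(sibs)) {
      for (j in which(sibs)) {
        Pj <- mk_pmat(rate, reord$edge.length[j])
        contrib <- contrib * as.numeric(Pj %*% D[reord$edge[j, 2], ])
      }
    }
    P <- mk_pmat(rate, elens[i])
    U[child, ] <- as.numeric(t(P) %*% contrib)
  }
  post <- U * D
  post <- post / rowSums(post)
  node_states <- character(ntip + nnode)
  node_states[seq_len(ntip)] <- leaf_states[tree$tip.label]
  for (nd in (ntip + 1L):(ntip + nnode)) {
    pr <- post[nd, ]
    best <- which(pr >= max(pr) * (1 - 1e-12))
    node_states[nd] <- STRENGTH_LEVELS[min(best)]
  }
  structure(list(tree = tree, node_states = node_states,
                 posteriors = post[(ntip + 1L):(ntip + nnode), , drop = FALSE],
                 rate = rate,
                 loglik = log(sum(0.25 * D[root, ]))),
            class = "state_tree")
}

#' Gain and loss events on a reconstructed state tree
#'
#' For every branch (parent to child, terminal branches included): the child
#' ranking above its parent is a gain of the stalling effect, below is a
#' loss, equal is no event.
#'
#' @param state_tree a `state_tree` from [reconstruct_ancestral_states()].
#' @return data.frame with columns `parent`, `child` (node indices),
#'   `parent_state`, `child_state`, `branch_length`,
#'   `event` (`"GAIN"`, `"LOSS"` or NA).
#' @export
count_events <- function(state_tree) {
  tree <- state_tree$tree
  st <- state_tree$node_states
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  pr <- strength_rank(st[parent]); cr <- strength_rank(st[child])
  event <- rep(NA_character_, length(parent))
  event[cr > pr] <- "GAIN"
  event[cr < pr] <- "LOSS"
  data.frame(parent = parent, child = child,
             parent_state = st[parent], child_state = st[child],
             branch_length = tree$edge.length, event = event,
             stringsAsFactors = FALSE)
}

#' Propensity of stalling effect change (PSEC)
#'
#' PSEC = sum(B_g)/sum(B_cg) - sum(B_l)/sum(B_cl). A branch admits a gain iff
#' its parent is not already STRONG and a loss iff its parent is not NONE (a
#' branch may be counted in both denominators). A ratio with zero denominator
#' contributes 0. PSEC lies in [-1, 1]; negative values indicate evolutionary
#' loss of the stalling effect.
#'
#' @param state_tree a `state_tree`.
#' @param events optional event table from [count_events()] on the same tree.
#' @return a `psec_result`: list with `b_g`, `b_l`, `b_cg`, `b_cl`, `gains`,
#'   `losses`, `psec`.
#' @export
compute_psec <- function(state_tree, events = count_events(state_tree)) {
  pr <- strength_rank(events$parent_state)
  bl <- events$branch_length
  b_g <- sum(bl[events$event %in% "GAIN"])
  b_l <- sum(bl[events$event %in% "LOSS"])
  b_cg <- sum(bl[pr < 3])
  b_cl <- sum(bl[pr > 0])
  ratio <- function(num, den) if (den > 0) num / den else 0
  structure(list(b_g = b_g, b_l = b_l, b_cg = b_cg, b_cl = b_cl,
                 gains = sum(events$event %in% "GAIN"),
                 losses = sum(events$event %in% "LOSS"),
                 psec = ratio(b_g, b_cg) - ratio(b_l, b_cl)),
            class = "psec_result")
}

#' @export
print.psec_result <- function(x, ...) {
  cat(sprintf("PSEC = %.4f (gains %d on %.3f/%.3f; losses %d on %.3f/%.3f)\n",
              x$psec, x$gains, x$b_g, x$b_cg, x$losses, x$b_l, x$b_cl))
  invisible(x)
}

#' Per-region PSEC for one orthologous group
#'
#' Convenience wrapper: extracts motif-bearing aligned regions, midpoint-roots
#' the group tree if unrooted, reconstructs ancestral states per region and
#' computes PSEC.
#'
#' @param msa named aligned sequences; @param tree `phylo` for the group;
#' @param motif_table motif table for the de-gapped sequences;
#' @param og_id group id; @param rate,rate_bounds passed to reconstruction.
#' @return data.frame with one row per region: `og_id`, `col_start`,
#'   `col_end`, `gains`, `losses`, `b_g`, `b_l`, `b_cg`, `b_cl`, `psec`.
#' @export
og_psec <- function(msa, tree, motif_table, og_id = "og", rate = NULL,
                    rate_bounds = c(1e-6, 100)) {
  regions <- map_motifs_to_alignment(msa, motif_table, og_id)
  if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  rows <- lapply(regions, function(rg) {
    st <- reconstruct_ancestral_states(tree, rg$leaf_states, rate, rate_bounds)
    ps <- compute_psec(st)
    data.frame(og_id = og_id, col_start = rg$columns[1],
               col_end = rg$columns[2], gains = ps$gains, losses = ps$losses,
               b_g = ps$b_g, b_l = ps$b_l, b_cg = ps$b_cg, b_cl = ps$b_cl,
               psec = ps$psec, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cohort summary of PSEC signs
#'
#' Counts regions with positive, negative and zero PSEC and tests the
#' positive/negative split against 50:50 with a chi-squared test.
#'
#' @param psec numeric vector of per-region PSEC values.
#' @return list with `n_positive`, `n_negative`, `n_zero`, `frac_positive`,
#'   `frac_negative` (fractions among nonzero), `p_value`.
#' @export
psec_cohort_summary <- function(psec) {
  np <- sum(psec > 0); nn <- sum(psec < 0); nz <- sum(psec == 0)
  p <- if (np + nn > 0)
    suppressWarnings(stats::chisq.test(c(np, nn), p = c(0.5, 0.5))$p.value)
  else NA_real_
  list(n_positive = np, n_negative = nn, n_zero = nz,
       frac_positive = if (np + nn) np / (np + nn) else NA_real_,
       frac_negative = if (np + nn) nn / (np + nn) else NA_real_,
       p_value = p)
}
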