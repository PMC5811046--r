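## Synthetic-data generators.
##
## These generators emulate the statistical structure of the real inputs
## (bacterial proteomes with OMA-style orthologous groups, Gene3D-style
## domain tracks, UniProt-style TMH tracks, expression tables) with recorded
## ground truth, so that every analysis stage is testable without downloads.
## A given seed fully determines every output.

## Flank/run recipes that realise a requested strength class under the
## default rule table (neutral X(-2), class set by X(-1)/X(+1)).
PLANT_RECIPES <- list(
  STRONG = list(x_m2 = "A", x_m1 = "A", run = 2L, x_p1 = "K"),
  MEDIUM = list(x_m2 = "A", x_m1 = "V", run = 2L, x_p1 = "K"),
  WEAK   = list(x_m2 = "A", x_m1 = "L", run = 2L, x_p1 = "L"))

## Overwrite one motif into a letter vector at anchor `start` (first proline).
plant_motif_chars <- function(chars, start, class) {
  rec <- PLANT_RECIPES[[class]]
  idx <- (start - 2L):(start + rec$run)
  stopifnot(idx[1] >= 1, idx[length(idx)] <= length(chars))
  chars[idx] <- c(rec$x_m2, rec$x_m1, rep("P", rec$run), rec$x_p1)
  chars
}

#' Generate a synthetic proteome with planted motifs
#'
#' Sequences are drawn i.i.d. from `aa_freqs` with lognormal lengths; planted
#' motifs overwrite letters (lengths and length distribution stay intact) at
#' non-overlapping positions, with flanks chosen to realise the requested
#' strength class under the default rule table. Ground truth is the full
#' motif table of the final sequences (planted plus incidental stretches).
#'
#' @param n_proteins number of proteins (default 4500, a typical bacterial
#'   proteome).
#' @param length_meanlog,length_sdlog lognormal length parameters (default
#'   median 300 residues).
#' @param min_length minimum protein length.
#' @param aa_freqs letter frequencies (default: E. coli K-12 composition).
#' @param plant data.frame with columns `class` (WEAK/MEDIUM/STRONG) and
#'   `density` (expected planted motifs per 100 residues), or NULL.
#' @param rules rule table used for the ground-truth classification.
#' @param seed integer seed.
#' @return list with `proteome` (named character vector), `motif_table`
#'   (ground truth from [scan_proteome()]), `planted` (data.frame of planted
#'   motifs: `protein_id`, `start`, `n`, `class`).
#' @export
generate_proteome <- function(n_proteins = 4500,
                              length_meanlog = log(300),
                              length_sdlog = 0.35, min_length = 60,
                              aa_freqs = ECOLI_AA_FREQS, plant = NULL,
                              rules = default_rule_table(), seed = 1) {
  with_seed(seed, {
    lens <- pmax(round(stats::rlnorm(n_proteins, length_meanlog,
                                     length_sdlog)), min_length)
    ids <- sprintf("prot%05d", seq_len(n_proteins))
    letters_pool <- names(aa_freqs)
    planted <- list()
    seqs <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      L <- lens[i]
      chars <- sample(letters_pool, L, replace = TRUE, prob = aa_freqs)
      if (!is.null(plant) && nrow(plant)) {
        taken <- integer(0) # planted anchors across ALL classes
        for (k in seq_len(nrow(plant))) {
          cls <- plant$class[k]
          n_want <- stats::rpois(1, plant$density[k] * L / 100)
          if (n_want == 0) next
          run <- PLANT_RECIPES[[cls]]$run
          lo <- 3L; hi <- L - run - 1L
          if (hi < lo) next
          cand <- sample(lo:hi, min(n_want * 4L, hi - lo + 1L))
          chosen <- integer(0)
          for (s in cand) {
            if (length(chosen) >= n_want) break
            if (all(abs(s - c(chosen, taken)) >= run + 4L))
              chosen <- c(chosen, s)
          }
          taken <- c(taken, chosen)
          for (s in chosen) {
            chars <- plant_motif_chars(chars, s, cls)
            planted[[length(planted) + 1]] <-
              data.frame(protein_id = ids[i], start = s, n = run,
                         class = cls, stringsAsFactors = FALSE)
          }
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    proteome <- setNames(seqs, ids)
    planted <- if (length(planted))
      do.call(rbind, c(planted, list(make.row.names = FALSE)))
    else data.frame(protein_id = character(0), start = integer(0),
                    n = integer(0), class = character(0))
    ## planted motifs may collide with incidental prolines extending a run;
    ## ground truth is whatever the final sequences contain
    list(proteome = proteome,
         motif_table = scan_proteome(proteome, rules),
         planted = planted)
  })
}

#' Thin polyproline stretches from a proteome
#'
#' Disrupts a fraction `q` of maximal P-stretches, chosen at random, by
#' overwriting one proline of each selected stretch with a residue drawn from
#' the proteome's non-proline composition. Used to plant known depletion.
#'
#' @param proteome named character vector.
#' @param q fraction of stretches to disrupt (0..1).
#' @param seed integer seed.
#' @return list with `proteome` (modified), `n_removed`, `n_original`.
#' @export
thin_motifs <- function(proteome, q, seed = 1) {
  stopifnot(q >= 0, q <= 1)
  with_seed(seed, {
    mt <- scan_proteome(proteome)
    if (nrow(mt) == 0)
      return(list(proteome = proteome, n_removed = 0L, n_original = 0L))
    pick <- which(stats::runif(nrow(mt)) < q)
    chars_all <- unlist(strsplit(unname(proteome), ""), use.names = FALSE)
    freq <- table(chars_all[chars_all != "P"])
    pool <- names(freq); pr <- as.numeric(freq) / sum(freq)
    chl <- strsplit(proteome, "")
    for (i in pick) {
      pid <- mt$protein_id[i]
      pos <- mt$start[i] + sample.int(mt$n[i], 1) - 1L
      chl[[pid]][pos] <- sample(pool, 1, prob = pr)
    }
    out <- vapply(chl, paste, character(1), collapse = "")
    list(proteome = setNames(out, names(proteome)),
         n_removed = length(pick), n_original = nrow(mt))
  })
}

#' Generate a synthetic pan-genome
#'
#' Core groups get one member per strain; accessory groups are present in a
#' random strain subset (each non-seed strain included with probability
#' `accessory_sharing`). Members are generated independently per strain.
#' Motifs are planted at `plant_density` in every protein; in core-group
#' members each planted stretch is then retained only with probability
#' `core_density_factor`, emulating evolutionary loss of stalling motifs from
#' conserved proteins while leaving the amino-acid composition nearly
#' unchanged (a disrupted stretch keeps one proline). A fraction of each
#' strain's proteins is left unassigned to any group (these are accessory by
#' definition).
#'
#' @param n_strains number of strains (default 43).
#' @param n_groups number of orthologous groups.
#' @param core_fraction fraction of groups present in every strain.
#' @param accessory_sharing inclusion probability per strain for accessory
#'   groups.
#' @param unassigned_per_strain proteins per strain outside any group.
#' @param plant_density baseline planted motif density (motifs/100 aa,
#'   class WEAK) for accessory proteins; 0 disables planting.
#' @param core_density_factor multiplier on `plant_density` for core
#'   proteins.
#' @param length_meanlog,length_sdlog,min_length,aa_freqs sequence model.
#' @param seed integer seed.
#' @return list with `proteomes` (named list strain -> named character
#'   vector), `og_table` (data.frame og_id/strain/protein_id), `truth`
#'   (data.frame og_id/label), `strains`.
#' @export
generate_pangenome <- function(n_strains = 43, n_groups = 200,
                               core_fraction = 0.5, accessory_sharing = 0.5,
                               unassigned_per_strain = 10,
                               plant_density = 0, core_density_factor = 1,
                               length_meanlog = log(300),
                               length_sdlog = 0.35, min_length = 60,
                               aa_freqs = ECOLI_AA_FREQS, seed = 1) {
  stopifnot(n_strains >= 2)
  with_seed(seed, {
    strains <- sprintf("strain%02d", seq_len(n_strains))
    n_core <- round(n_groups * core_fraction)
    labels <- c(rep("CORE", n_core), rep("ACCESSORY", n_groups - n_core))
    og_ids <- sprintf("OG%04d", seq_len(n_groups))
    gen_seq <- function() {
      L <- max(round(stats::rlnorm(1, length_meanlog, length_sdlog)),
               min_length)
      chars <- sample(names(aa_freqs), L, replace = TRUE, prob = aa_freqs)
      paste(chars, collapse = "")
    }
    plant_into <- function(s, density, retain = 1) {
      if (density <= 0) return(s)
      chars <- seq_chars(s)
      L <- length(chars)
      n_want <- stats::rpois(1, density * L / 100)
      if (n_want == 0 || L < 8) return(s)
      cand <- sample(3:(L - 3), min(n_want * 4L, L - 5))
      chosen <- integer(0)
      for (p in cand) {
        if (length(chosen) >= n_want) break
        if (all(abs(p - chosen) >= 6L)) chosen <- c(chosen, p)
      }
      for (p in chosen) {
        chars <- plant_motif_chars(chars, p, "WEAK")
        if (stats::runif(1) > retain) chars[p + 1] <- "G" # stretch disrupted
      }
      paste(chars, collapse = "")
    }
    proteomes <- setNames(vector("list", n_strains), strains)
    for (s in strains) proteomes[[s]] <- character(0)
    og_rows <- list()
    counter <- setNames(rep(0L, n_strains), strains)
    for (g in seq_len(n_groups)) {
      present <- if (labels[g] == "CORE") strains
      else {
        keep <- strains[stats::runif(n_strains) < accessory_sharing]
        if (length(keep) == 0) keep <- sample(strains, 1)
        keep
      }
      retain <- if (labels[g] == "CORE") core_density_factor else 1
      for (s in present) {
        counter[s] <- counter[s] + 1L
        pid <- sprintf("%s_p%05d", s, counter[s])
        sq <- plant_into(gen_seq(), plant_density, retain)
        proteomes[[s]] <- c(proteomes[[s]], setNames(sq, pid))
        og_rows[[length(og_rows) + 1]] <-
          data.frame(og_id = og_ids[g], strain = s, protein_id = pid,
                     stringsAsFactors = FALSE)
      }
    }
    for (s in strains) {
      for (u in seq_len(unassigned_per_strain)) {
        counter[s] <- counter[s] + 1L
        pid <- sprintf("%s_p%05d", s, counter[s])
        sq <- plant_into(gen_seq(), plant_density)
        proteomes[[s]] <- c(proteomes[[s]], setNames(sq, pid))
      }
    }
    list(proteomes = proteomes,
         og_table = do.call(rbind, c(og_rows, list(make.row.names = FALSE))),
         truth = data.frame(og_id = og_ids, label = labels,
                            stringsAsFactors = FALSE),
         strains = strains)
  })
}

## ---- state evolution ------------------------------------------------------

## Rate matrix of the (possibly biased) 4-state process: base symmetric rate
## alpha; upward transitions (toward stronger stalling) scaled by gain_bias,
## downward by loss_bias.
state_rate_matrix <- function(alpha, gain_bias = 1, loss_bias = 1) {
  Q <- matrix(alpha, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (j > i) Q[i, j] <- alpha * gain_bias
    if (j < i) Q[i, j] <- alpha * loss_bias
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Simulate stalling-state evolution on a random tree
#'
#' Grows a pure-birth (Yule) tree and evolves the 4-state stalling character
#' from the root down every branch as a continuous-time Markov jump process.
#' Optional directional bias scales the rates of gains (toward stronger
#' states) and losses independently; `gain_bias = loss_bias = 1` is the
#' unbiased symmetric process. Every transition is recorded with its branch.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param birth Yule birth rate.
#' @param alpha base transition rate.
#' @param root_state state at the root, or NULL to sample uniformly.
#' @param gain_bias,loss_bias rate multipliers for upward/downward moves.
#' @param scale multiplier applied to all branch lengths.
#' @param seed integer seed.
#' @return list with `tree` (rooted `phylo`), `leaf_states`, `node_states`
#'   (truth for all nodes, tips first), `transitions` (data.frame: edge
#'   index, from, to, direction), `params`.
#' @export
simulate_state_evolution <- function(n_leaves = 10, birth = 1, alpha = 0.5,
                                     root_state = NULL, gain_bias = 1,
                                     loss_bias = 1, scale = 1, seed = 1) {
  stopifnot(n_leaves >= 3)
  with_seed(seed, {
    tree <- ape::rphylo(n_leaves, birth, 0)
    tree$edge.length <- tree$edge.length * scale
    Q <- state_rate_matrix(alpha, gain_bias, loss_bias)
    ntot <- ape::Ntip(tree) + tree$Nnode
    states <- integer(ntot) # 1..4 = NONE..STRONG
    root <- ape::Ntip(tree) + 1L
    states[root] <- if (is.null(root_state)) sample.int(4, 1)
                    else strength_rank(root_state) + 1L
    trans <- list()
    ## traverse edges parents-first (reverse postorder)
    reord <- ape::reorder.phylo(tree, "postorder")
    for (i in rev(seq_len(nrow(reord$edge)))) {
      parent <- reord$edge[i, 1]; child <- reord$edge[i, 2]
      t_rem <- reord$edge.length[i]
      st <- states[parent]
      repeat {
        out_rate <- -Q[st, st]
        if (out_rate <= 0) break
        w <- stats::rexp(1, out_rate)
        if (w > t_rem) break
        t_rem <- t_rem - w
        others <- setdiff(1:4, st)
        nxt <- others[sample.int(3, 1, prob = Q[st, others] / out_rate)]
        trans[[length(trans) + 1]] <- data.frame(
          parent = parent, child = child,
          from = STRENGTH_LEVELS[st], to = STRENGTH_LEVELS[nxt],
          direction = if (nxt > st) "GAIN" else "LOSS",
          stringsAsFactors = FALSE)
        st <- nxt
      }
      states[child] <- st
    }
    node_states <- STRENGTH_LEVELS[states]
    leaf_states <- setNames(node_states[seq_len(ape::Ntip(tree))],
                            tree$tip.label)
    transitions <- if (length(trans))
      do.call(rbind, c(trans, list(make.row.names = FALSE)))
    else data.frame(parent = integer(0), child = integer(0),
                    from = character(0), to = character(0),
                    direction = character(0))
    list(tree = tree, leaf_states = leaf_states, node_states = node_states,
         transitions = transitions,
         params = list(n_leaves = n_leaves, birth = birth, alpha = alpha,
                       gain_bias = gain_bias, loss_bias = loss_bias,
                       scale = scale, seed = seed))
  })
}

## ---- annotations ----------------------------------------------------------

#' Generate synthetic domain and TMH annotation tracks
#'
#' Places non-overlapping structural-domain intervals (two per sufficiently
#' long protein) and, on a configurable fraction of proteins, TMH intervals
#' with lengths centred at 21 residues. Optionally plants extra motifs at
#' domain-boundary windows (offsets `boundary_window` relative to the second
#' domain's start) or inside non-TMH site III instances, overwriting letters
#' in the returned (modified) proteome.
#'
#' @param proteome named character vector (will be modified when planting).
#' @param tmh_fraction fraction of proteins given TMH annotations.
#' @param plant_boundary_prob per-anchor probability of planting one motif in
#'   the boundary window upstream of the second domain's start.
#' @param boundary_window c(lo, hi) offsets relative to the domain start
#'   (offset 0 = the start residue).
#' @param plant_site3_prob per-TMH probability of planting one motif inside
#'   the (non-TMH) site III instance.
#' @param plant_class strength class of planted motifs.
#' @param seed integer seed.
#' @return list with `proteome` (possibly modified), `domains`, `tmh`
#'   (annotation tracks), `planted` (data.frame of planted motif anchors).
#' @export
generate_annotations <- function(proteome, tmh_fraction = 0.2,
                                 plant_boundary_prob = 0,
                                 boundary_window = c(-12, -2),
                                 plant_site3_prob = 0,
                                 plant_class = "MEDIUM", seed = 1) {
  with_seed(seed, {
    chl <- strsplit(unname(proteome), "")
    names(chl) <- names(proteome)
    lens <- lengths(chl)
    dom_rows <- list(); tmh_rows <- list(); planted <- list()
    is_tp <- stats::runif(length(proteome)) < tmh_fraction
    for (i in seq_along(proteome)) {
      pid <- names(proteome)[i]; L <- lens[i]
      if (L >= 220) {
        d1_len <- sample(80:110, 1); d2_len <- sample(80:110, 1)
        d1_start <- sample(3:10, 1)
        gap <- sample(3:25, 1)
        d1_end <- d1_start + d1_len - 1
        d2_start <- d1_end + gap + 1
        d2_end <- min(d2_start + d2_len - 1, L - 2)
        if (d2_end > d2_start) {
          dom_rows[[length(dom_rows) + 1]] <- data.frame(
            protein_id = pid, kind = "DOMAIN",
            start = c(d1_start, d2_start), end = c(d1_end, d2_end),
            stringsAsFactors = FALSE)
          if (plant_boundary_prob > 0 &&
              stats::runif(1) < plant_boundary_prob) {
            off <- sample(boundary_window[1]:boundary_window[2], 1)
            anchor <- d2_start + off
            if (anchor >= 3 && anchor + 3 <= L) {
              chl[[pid]] <- plant_motif_chars(chl[[pid]], anchor, plant_class)
              planted[[length(planted) + 1]] <- data.frame(
                protein_id = pid, start = anchor, target = "boundary",
                stringsAsFactors = FALSE)
            }
          }
        }
      }
      if (is_tp[i] && L >= 160) {
        n_tmh <- min(sample(1:3, 1), floor(L / 140))
        pos <- 20
        for (k in seq_len(max(n_tmh, 1))) {
          tlen <- sample(19:23, 1, prob = c(0.1, 0.15, 0.5, 0.15, 0.1))
          t_start <- pos
          t_end <- t_start + tlen - 1
          if (t_end > L - 5) break
          tmh_rows[[length(tmh_rows) + 1]] <- data.frame(
            protein_id = pid, kind = "TMH", start = t_start, end = t_end,
            stringsAsFactors = FALSE)
          if (plant_site3_prob > 0 && stats::runif(1) < plant_site3_prob) {
            site <- site_absolute(t_start, TMH_SITES$III)
            if (site[2] + 2 <= L) {
              anchor <- sample((site[1] + 2):(site[2] - 2), 1)
              chl[[pid]] <- plant_motif_chars(chl[[pid]], anchor, plant_class)
              planted[[length(planted) + 1]] <- data.frame(
                protein_id = pid, start = anchor, target = "site3",
                stringsAsFactors = FALSE)
            }
          }
          pos <- t_end + sample(100:130, 1) # leaves site III outside TMHs
        }
      }
    }
    out_proteome <- setNames(
      vapply(chl, paste, character(1), collapse = ""), names(proteome))
    bind <- function(rows, kind) {
      if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
      else data.frame(protein_id = character(0), kind = character(0),
                      start = integer(0), end = integer(0))
    }
    list(proteome = out_proteome,
         domains = bind(dom_rows), tmh = bind(tmh_rows),
         planted = if (length(planted))
           do.call(rbind, c(planted, list(make.row.names = FALSE)))
         else data.frame(protein_id = character(0), start = integer(0),
                         target = character(0)))
  })
}

## ---- expression -----------------------------------------------------------

#' Generate synthetic expression and ribosome-profiling tables
#'
#' Translation efficiency is drawn through a Gaussian copula with a target
#' Spearman correlation to motif density (normal scores of the density ranks,
#' Pearson parameter r = 2 sin(pi * rho / 6)); transcription levels are
#' lognormal and abundance = TE * transcription, so the efficiency ratio is
#' exact. Profiling asymmetry scores carry a planted positive association
#' with the protein's maximal motif strength rank.
#'
#' @param proteome named character vector.
#' @param motif_table motif table for the proteome.
#' @param target_rho target Spearman correlation between motif density and
#'   translation efficiency (default -0.105).
#' @param score_slope increase of the log asymmetry score per strength rank.
#' @param seed integer seed.
#' @return list with `expression` (data.frame gene_id/abundance/
#'   transcription), `profiling` (data.frame gene_id/score), `densities`.
#' @export
generate_expression <- function(proteome, motif_table, target_rho = -0.105,
                                score_slope = 0.8, seed = 1) {
  with_seed(seed, {
    n <- length(proteome)
    dens <- motif_density(proteome, motif_table)
    rk <- rank(dens, ties.method = "average")
    z_d <- stats::qnorm((rk - 0.5) / n)
    sdz <- stats::sd(z_d)
    z_d <- if (sdz > 0) z_d / sdz else stats::rnorm(n)
    r <- 2 * sin(pi * target_rho / 6)
    z_e <- r * z_d + sqrt(1 - r^2) * stats::rnorm(n)
    te <- exp(1.5 + 0.9 * z_e)
    transcription <- stats::rlnorm(n, meanlog = 3, sdlog = 0.8)
    abundance <- te * transcription
    max_rank <- setNames(rep(0L, n), names(proteome))
    cls <- motif_table[!motif_table$strength %in% "UNCLASSIFIED", ,
                       drop = FALSE]
    if (nrow(cls)) {
      mx <- tapply(strength_rank(cls$strength), cls$protein_id, max)
      max_rank[names(mx)] <- as.integer(mx)
    }
    score <- exp(stats::rnorm(n, mean = -0.3 + score_slope * max_rank,
                              sd = 0.7))
    list(expression = data.frame(gene_id = names(proteome),
                                 abundance = abundance,
                                 transcription = transcription,
                                 stringsAsFactors = FALSE),
         profiling = data.frame(gene_id = names(proteome), score = score,
                                stringsAsFactors = FALSE),
         densities = dens)
  })
}
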