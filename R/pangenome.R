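## Core/accessory pan-proteome partition and motif-occurrence comparison.

#' Partition proteins into core and accessory sets
#'
#' An orthologous group belongs to the core iff it has at least one member in
#' every strain of `strain_set` (paralog counts are irrelevant). Proteins of
#' core groups are labelled CORE; members of other groups and proteins not
#' assigned to any group are ACCESSORY.
#'
#' @param og_table data.frame with columns `og_id`, `strain`, `protein_id`
#'   (one row per membership; a protein belongs to at most one group).
#' @param strain_set character vector of strain names (non-empty).
#' @param proteomes named list (strain -> named character vector of
#'   sequences) covering every strain in `strain_set`.
#' @return a `core_accessory_assignment`: data.frame with columns `strain`,
#'   `protein_id`, `label`; attribute `strain_summary` counts per strain.
#' @export
partition_core_accessory <- function(og_table, strain_set, proteomes) {
  if (length(strain_set) == 0) stop("strain_set must be non-empty")
  need <- c("og_id", "strain", "protein_id")
  if (!all(need %in% names(og_table)))
    stop("og_table must have columns og_id, strain, protein_id")
  if (anyDuplicated(og_table$protein_id))
    stop("protein assigned to more than one orthologous group: ",
         paste(unique(og_table$protein_id[duplicated(og_table$protein_id)]),
               collapse = ", "))
  for (s in strain_set) {
    members <- og_table$protein_id[og_table$strain == s]
    absent <- setdiff(members, names(proteomes[[s]]))
    if (length(absent))
      stop("member protein absent from proteome of strain ", s, ": ",
           paste(absent, collapse = ", "))
  }
  og_sub <- og_table[og_table$strain %in% strain_set, , drop = FALSE]
  strains_per_group <- tapply(og_sub$strain, og_sub$og_id,
                              function(x) length(unique(x)))
  core_groups <- names(strains_per_group)[strains_per_group ==
                                            length(strain_set)]
  rows <- lapply(strain_set, function(s) {
    ids <- names(proteomes[[s]])
    lab <- rep("ACCESSORY", length(ids))
    core_ids <- og_sub$protein_id[og_sub$strain == s &
                                    og_sub$og_id %in% core_groups]
    lab[ids %in% core_ids] <- "CORE"
    data.frame(strain = s, protein_id = ids, label = lab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summ <- do.call(rbind, lapply(strain_set, function(s) {
    sub <- out[out$strain == s, ]
    data.frame(strain = s, n_core = sum(sub$label == "CORE"),
               n_accessory = sum(sub$label == "ACCESSORY"),
               stringsAsFactors = FALSE)
  }))
  attr(out, "strain_summary") <- summ
  class(out) <- c("core_accessory_assignment", "data.frame")
  out
}

#' Compare motif occurrence between core and accessory proteomes
#'
#' Per strain and per strength stratum, computes shuffle-normalised
#' fold-change ratio vectors for the CORE and ACCESSORY protein subsets and
#' compares them with the rank-sum test. The stratum `"ALL"` counts raw
#' motifs regardless of strength.
#'
#' @param assignment output of [partition_core_accessory()].
#' @param proteomes named list (strain -> named character vector).
#' @param strata character vector of strata among
#'   `c("ALL", "WEAK", "MEDIUM", "STRONG")`.
#' @param rules rule table for strength-stratified counting.
#' @param replicates,seed shuffle-null parameters.
#' @return data.frame with one row per (strain, stratum): observed counts,
#'   fold changes for both subsets and the rank-sum `p_value`; rows for empty
#'   strata are flagged `skipped`.
#' @export
compare_core_accessory_occurrence <- function(assignment, proteomes,
                                              strata = "ALL",
                                              rules = default_rule_table(),
                                              replicates = 1000, seed = 1) {
  strains <- unique(assignment$strain)
  rows <- list()
  for (s in strains) {
    sub <- assignment[assignment$strain == s, ]
    core_seqs <- proteomes[[s]][sub$protein_id[sub$label == "CORE"]]
    acc_seqs <- proteomes[[s]][sub$protein_id[sub$label == "ACCESSORY"]]
    for (st in strata) {
      counter <- strength_counter(st, rules)
      if (length(core_seqs) == 0 || length(acc_seqs) == 0 ||
          counter(core_seqs) == 0 || counter(acc_seqs) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          strain = s, stratum = st, n_core = NA, n_accessory = NA,
          fc_core = NA_real_, fc_accessory = NA_real_, p_value = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      fc_core <- shuffle_fold_change(core_seqs, counter, replicates,
                                     derive_seed(seed, 1, match(s, strains)))
      fc_acc <- shuffle_fold_change(acc_seqs, counter, replicates,
                                    derive_seed(seed, 2, match(s, strains)))
      rows[[length(rows) + 1]] <- data.frame(
        strain = s, stratum = st, n_core = fc_core$n_obs,
        n_accessory = fc_acc$n_obs, fc_core = fc_core$fold_change,
        fc_accessory = fc_acc$fold_change,
        p_value = compare_fold_change_vectors(fc_core$ratios, fc_acc$ratios),
        skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
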