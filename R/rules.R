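## Stalling-strength rule tables: flank-residue effect classes at positions
## X(-2), X(-1), X(+1) and the combination rules mapping (run-length category,
## effect triple) -> strength class.

EFFECT_LEVELS <- c("WEAK_EFF", "MEDIUM_EFF", "STRONG_EFF")

effect_rank <- function(x) match(x, EFFECT_LEVELS) # 1..3

#' Default stalling-strength rule table
#'
#' Builds the packaged rule table for classifying polyproline motifs
#' X(-2)X(-1)-nP-X(+1). Flank residues are binned into weak/medium/strong
#' effect classes per position, anchored on the experimentally established
#' contexts: strong arrest for PPP and for A, D, G upstream (X(-1)) or
#' D, G, N, W downstream (X(+1)) of the diproline; weak arrest for C, H, L at
#' X(-1) and L at X(+1). At X(-2), H, K, Q, R, W pronounce the arrest and
#' C, G, L, S, T attenuate it; all remaining residues are neutral
#' (medium-effect). Combination rules: a run of three or more prolines is
#' always STRONG; for a diproline the base class is the strongest effect among
#' X(-1) and X(+1), promoted one rank by a strong-effect X(-2) and demoted one
#' rank by a weak-effect X(-2), clamped to [WEAK, STRONG].
#'
#' @return a `strength_rule_table` object (validated).
#' @export
default_rule_table <- function() {
  eff <- function(strong, weak) {
    out <- setNames(rep("MEDIUM_EFF", length(AA_STANDARD)), AA_STANDARD)
    out[strong] <- "STRONG_EFF"
    out[weak] <- "WEAK_EFF"
    out
  }
  flank_effect <- list(
    x_m2 = eff(strong = c("H", "K", "Q", "R", "W"),
               weak   = c("C", "G", "L", "S", "T")),
    x_m1 = eff(strong = c("A", "D", "G", "P"),
               weak   = c("C", "H", "L")),
    x_p1 = eff(strong = c("D", "G", "N", "P", "W"),
               weak   = c("L")))

  ## Enumerate the full (n-category x effect triple) grid.
  grid <- expand.grid(n_cat = c("2", "3+"),
                      e_m2 = EFFECT_LEVELS, e_m1 = EFFECT_LEVELS,
                      e_p1 = EFFECT_LEVELS, stringsAsFactors = FALSE)
  grid$strength <- apply(grid, 1L, function(row) {
    if (row[["n_cat"]] == "3+") return("STRONG")
    base <- max(effect_rank(row[["e_m1"]]), effect_rank(row[["e_p1"]]))
    mod <- switch(row[["e_m2"]], STRONG_EFF = 1L, WEAK_EFF = -1L, 0L)
    STRENGTH_LEVELS[min(max(base + mod, 1L), 3L) + 1L]
  })
  rules <- structure(
    list(flank_effect = flank_effect,
         combination_rules = grid,
         provenance = paste(
           "Constructed from published arrest-context experiments",
           "(strong: PPP, D/PP/D, PPW, APP, G/PP/G, PPN; weak: L/PP/L, CPP,",
           "HPP; X(-2) promoters H,K,Q,R,W; attenuators C,G,L,S,T), with the",
           "package's default combination rule over effect classes.")),
    class = "strength_rule_table")
  validate_rule_table(rules)
}

rule_key <- function(n_cat, e_m2, e_m1, e_p1) {
  paste(n_cat, e_m2, e_m1, e_p1, sep = "|")
}

#' Validate a stalling-strength rule table
#'
#' Checks that every standard amino acid has an effect class at each of the
#' three flank positions and that the combination rules are total over their
#' key domain. On success, marks the table validated (classification refuses
#' unvalidated tables).
#'
#' @param rules a `strength_rule_table`.
#' @return the validated table, invisibly usable downstream.
#' @export
validate_rule_table <- function(rules) {
  if (!inherits(rules, "strength_rule_table"))
    stop("not a strength_rule_table")
  gaps <- character(0)
  for (pos in c("x_m2", "x_m1", "x_p1")) {
    have <- names(rules$flank_effect[[pos]])
    missing <- setdiff(AA_STANDARD, have)
    if (length(missing))
      gaps <- c(gaps, paste0(pos, ": missing letters ",
                             paste(missing, collapse = ",")))
    bad <- !rules$flank_effect[[pos]] %in% EFFECT_LEVELS
    if (any(bad))
      gaps <- c(gaps, paste0(pos, ": invalid effect class for ",
                             paste(have[bad], collapse = ",")))
  }
  cr <- rules$combination_rules
  need <- c("n_cat", "e_m2", "e_m1", "e_p1", "strength")
  if (!all(need %in% names(cr))) {
    gaps <- c(gaps, paste("combination_rules: missing columns",
                          paste(setdiff(need, names(cr)), collapse = ",")))
  } else {
    full <- expand.grid(n_cat = c("2", "3+"), e_m2 = EFFECT_LEVELS,
                        e_m1 = EFFECT_LEVELS, e_p1 = EFFECT_LEVELS,
                        stringsAsFactors = FALSE)
    want <- rule_key(full$n_cat, full$e_m2, full$e_m1, full$e_p1)
    have <- rule_key(cr$n_cat, cr$e_m2, cr$e_m1, cr$e_p1)
    missing <- setdiff(want, have)
    if (length(missing))
      gaps <- c(gaps, paste("combination_rules: missing keys",
                            paste(missing, collapse = "; ")))
    bad <- !cr$strength %in% c("WEAK", "MEDIUM", "STRONG")
    if (any(bad))
      gaps <- c(gaps, "combination_rules: strengths must be WEAK/MEDIUM/STRONG")
  }
  if (length(gaps))
    stop("invalid rule table:\n  ", paste(gaps, collapse = "\n  "))
  attr(rules, "validated") <- TRUE
  rules
}

#' Write a rule table to a YAML file
#'
#' @param rules a validated `strength_rule_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(rules, path) {
  rules <- validate_rule_table(rules)
  cr <- rules$combination_rules
  obj <- list(
    provenance = rules$provenance,
    flank_effect = lapply(rules$flank_effect, as.list),
    combination_rules = lapply(seq_len(nrow(cr)), function(i)
      list(n_cat = cr$n_cat[i], e_m2 = cr$e_m2[i], e_m1 = cr$e_m1[i],
           e_p1 = cr$e_p1[i], strength = cr$strength[i])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a rule table from a YAML file
#'
#' Reads and validates a stalling-strength rule table. The packaged default
#' lives at `system.file("extdata", "stalling_rules.yaml", package =
#' "ppstall")`.
#'
#' @param path path to a rule-table YAML file.
#' @return a validated `strength_rule_table`.
#' @export
load_rule_table <- function(path) {
  if (!file.exists(path)) stop("rule table file not found: ", path)
  obj <- yaml::read_yaml(path)
  cr <- do.call(rbind, lapply(obj$combination_rules, function(x)
    data.frame(n_cat = x$n_cat, e_m2 = x$e_m2, e_m1 = x$e_m1,
               e_p1 = x$e_p1, strength = x$strength,
               stringsAsFactors = FALSE)))
  rules <- structure(
    list(flank_effect = lapply(obj$flank_effect, unlist),
         combination_rules = cr,
         provenance = obj$provenance %||% ""),
    class = "strength_rule_table")
  validate_rule_table(rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strength_rule_table <- function(x, ...) {
  cat("Stalling-strength rule table\n")
  for (pos in names(x$flank_effect)) {
    fe <- x$flank_effect[[pos]]
    cat(sprintf("  %s: strong={%s} weak={%s}\n", pos,
                paste(names(fe)[fe == "STRONG_EFF"], collapse = ""),
                paste(names(fe)[fe == "WEAK_EFF"], collapse = "")))
  }
  cat("  combination rules:", nrow(x$combination_rules), "keys\n")
  invisible(x)
}
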