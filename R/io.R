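## Readers and writers for the formats the pipeline consumes and emits.
## All external TSVs use 1-based inclusive coordinates; sequence letters are
## upper-cased on read; duplicate ids are rejected. Output tables are written
## sorted so files are diffable across runs.

#' Read a protein FASTA file
#'
#' Headers of the form `"strain|protein_id"` keep the full string as the id;
#' description text after whitespace is dropped.
#'
#' @param path FASTA file path.
#' @return named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write a protein FASTA file
#'
#' @param proteome named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  check_proteome(proteome)
  set <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but requires all sequences to share one width and
#' permits the gap character `-`.
#'
#' @param path aligned FASTA path.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  msa <- read_fasta(path)
  if (length(unique(nchar(msa))) > 1)
    stop("alignment sequences have unequal widths in ", path)
  msa
}

#' Read / write Newick trees
#'
#' Thin wrappers over `ape::read.tree` / `ape::write.tree` with existence
#' checks.
#'
#' @param path Newick file path.
#' @return a `phylo` (read) or `path` invisibly (write).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  tree
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree, path, digits = 15) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

## Generic column-checked TSV reader.
read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (cc in numeric_cols) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(df[[cc]]))
      stop("non-numeric values in column ", cc, " of ", path)
  }
  df
}

#' Read an annotation track TSV
#'
#' Expects columns `protein_id`, `kind`, `start`, `end` with 1-based
#' inclusive coordinates.
#'
#' @param path TSV path.
#' @param proteome optional proteome for bound checks.
#' @return validated track data.frame.
#' @export
read_annotation_tsv <- function(path, proteome = NULL) {
  df <- read_tsv_checked(path, c("protein_id", "kind", "start", "end"),
                         c("start", "end"))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  validate_track(df, proteome)
}

#' Read an orthologous-group membership TSV
#'
#' Expects columns `og_id`, `strain`, `protein_id` (one row per membership).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_orthology_tsv <- function(path) {
  read_tsv_checked(path, c("og_id", "strain", "protein_id"))
}

#' Read an expression TSV
#'
#' Expects columns `gene_id`, `abundance`, `transcription`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "abundance", "transcription"),
                         c("abundance", "transcription"))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  df
}

#' Write a motif table as TSV
#'
#' Columns `protein_id`, `start`, `n`, `x_m2`, `x_m1`, `x_p1`, `strength`;
#' 1-based inclusive coordinates; rows sorted by (protein_id, start).
#'
#' @param motif_table a `motif_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(motif_table, path) {
  df <- as.data.frame(motif_table)
  df <- df[order(df$protein_id, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif table TSV
#'
#' @param path TSV path written by [write_motif_table()].
#' @return a `motif_table` data.frame.
#' @export
read_motif_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "start", "n"), c("start", "n"))
  df$start <- as.integer(df$start); df$n <- as.integer(df$n)
  class(df) <- c("motif_table", "data.frame")
  df
}

#' Write a generic results table
#'
#' Tab-separated, no quoting, deterministic row order is the caller's
#' responsibility.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
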