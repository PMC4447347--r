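#' Construct a gene catalog
#'
#' A gene catalog is the tabular container used throughout the package: one
#' row per gene, with a unique `record_id` and a residue `sequence` (peptide
#' or nucleotide; the algorithm is alphabet-blind). Input order is preserved
#' and meaningful: collision suffixes are numbered in catalog order.
#'
#' @param record_id Character vector of unique, non-empty gene identifiers.
#' @param sequence Character vector of residue sequences, same length.
#' @param ... Further columns carried along (e.g. `protein_accession`).
#'
#' @return A tibble with at least columns `record_id` and `sequence`.
#' @export
#' @examples
#' gene_catalog(c("g1", "g2"), c("ACDEF", "CDEFG"))
gene_catalog <- function(record_id, sequence, ...) {
  cat <- tibble(record_id = as.character(record_id),
                sequence = as.character(sequence), ...)
  validate_catalog(cat)
}

validate_catalog <- function(catalog, allow_empty = TRUE) {
  if (!is.data.frame(catalog) ||
      !all(c("record_id", "sequence") %in% names(catalog))) {
    abort_kmertag(
      "A gene catalog must be a data frame with columns `record_id` and `sequence`.",
      "invalid_input")
  }
  catalog <- as_tibble(catalog)
  if (!allow_empty && nrow(catalog) == 0L) {
    abort_kmertag("The gene catalog is empty.", "invalid_input")
  }
  if (anyDuplicated(catalog$record_id)) {
    dup <- unique(catalog$record_id[duplicated(catalog$record_id)])
    abort_kmertag(
      paste0("Duplicate record_id in catalog: ",
             paste(head(dup, 3L), collapse = ", ")),
      "duplicate_record")
  }
  catalog
}

#' Normalize a residue sequence
#'
#' Uppercases, strips all whitespace, and removes a single trailing stop
#' symbol `*` (so a translated CDS that carries its terminal stop tags
#' identically to one that does not). Internal `*`, `X`, `U` and other
#' ambiguity letters are kept as ordinary symbols: the tagging scheme is
#' alphabet-blind.
#'
#' @param x Character vector of residue strings.
#' @return Character vector of normalized residue strings.
#' @export
#' @examples
#' normalize_sequence("mkvl abc*")
normalize_sequence <- function(x) {
  x <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  sub("\\*$", "", x)
}

# Single normalized, non-empty sequence or error.
check_sequence <- function(x) {
  if (length(x) != 1L || is.na(x)) {
    abort_kmertag("`sequence` must be a single non-missing string.", "invalid_input")
  }
  s <- normalize_sequence(x)
  if (!nzchar(s)) {
    abort_kmertag("Sequence is empty after normalization.", "invalid_input")
  }
  s
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 ||
      k != as.integer(k)) {
    abort_kmertag("`k` must be a single integer >= 1.", "invalid_parameter")
  }
  as.integer(k)
}
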