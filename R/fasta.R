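#' Read a FASTA file into a record table
#'
#' Wraps [Biostrings::readBStringSet()] and returns a tibble. The record id
#' is the first whitespace-delimited header token; the rest of the header is
#' kept as `description`. Wrapped sequence lines are concatenated verbatim
#' (no normalization happens at read time). Gzip input is handled
#' transparently.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#'
#' @return A tibble with columns `record_id`, `description`, `sequence`, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_kmertag(paste0("File not found: ", path), "io")
  }
  check_fasta_leadin(path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  record_id <- sub("[[:space:]].*$", "", headers)
  description <- ifelse(grepl("[[:space:]]", headers),
                        sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (any(!nzchar(record_id))) {
    abort_kmertag(paste0("Record with empty id in ", path), "malformed_fasta")
  }
  if (anyDuplicated(record_id)) {
    dup <- unique(record_id[duplicated(record_id)])
    abort_kmertag(
      paste0("Duplicate FASTA record id(s) in ", path, ": ",
             paste(head(dup, 3L), collapse = ", ")),
      "duplicate_record")
  }
  tibble(record_id = record_id, description = description,
         sequence = unname(as.character(set)))
}

# The first non-blank character of a FASTA file must be ">"; report the
# offending line if not.
check_fasta_leadin <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  line_no <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) {
      abort_kmertag(paste0("No FASTA records in ", path), "malformed_fasta")
    }
    line_no <- line_no + 1L
    if (grepl("[^[:space:]]", line)) {
      if (!startsWith(trimws(line), ">")) {
        abort_kmertag(
          paste0("Malformed FASTA: line ", line_no, " of ", path,
                 " does not start with '>': ", substr(line, 1L, 40L)),
          "malformed_fasta")
      }
      return(invisible(TRUE))
    }
  }
}

#' Write a catalog or record table as FASTA
#'
#' Headers are `record_id` followed, when a non-empty `description` column is
#' present, by a space and the description. Round-trips with [read_fasta()]
#' on `(record_id, sequence)`.
#'
#' @param records A data frame with `record_id` and `sequence` columns
#'   (optionally `description`).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#'
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- validate_catalog(records)
  headers <- records$record_id
  if ("description" %in% names(records)) {
    has_desc <- nzchar(records$description) & !is.na(records$description)
    headers <- ifelse(has_desc, paste(headers, records$description), headers)
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract the gene accession from an Ensembl-style peptide header
#'
#' Ensembl peptide FASTA descriptions carry `key:value` tokens; the only one
#' needed here is `gene:`, e.g.
#' `>ENSP00000388547.1 pep gene:ENSG00000187634.6 transcript:...`.
#' Unrecognized tokens are ignored.
#'
#' @param description Character vector of FASTA description strings.
#' @return Character vector of gene accessions, `NA` where no `gene:` token
#'   is present.
#' @export
parse_gene_accession <- function(description) {
  m <- stringr::str_match(as.character(description),
                          "(?:^|\\s)gene:(\\S+)")[, 2L]
  as.character(m)
}

#' Select one representative protein per gene
#'
#' Reduces a multi-protein-per-gene peptide record table to a gene catalog
#' with exactly one sequence per gene: the record whose protein accession
#' (the FASTA record id) is smallest under bytewise lexicographic
#' comparison. For fixed-width zero-padded accessions (ENSP-style) this
#' coincides with numeric order. Records without a parseable `gene:` token
#' are skipped with a warning. The catalog is ordered by first appearance of
#' each gene in the input, so the result is invariant to shuffling proteins
#' within a gene.
#'
#' @param records A record tibble from [read_fasta()].
#'
#' @return A gene catalog tibble: `record_id` (the gene accession),
#'   `protein_accession`, `description`, `sequence`.
#' @export
select_representative_per_gene <- function(records) {
  records <- as_tibble(records)
  gene <- parse_gene_accession(records$description)
  skipped <- sum(is.na(gene))
  if (skipped > 0L) {
    warn(paste0(skipped, " record(s) lack a 'gene:' header token and were skipped."),
         class = "kmertag_warning_missing_gene")
  }
  kept <- records[!is.na(gene), , drop = FALSE]
  kept$gene_accession <- gene[!is.na(gene)]
  if (nrow(kept) == 0L) {
    abort_kmertag("No records with a parseable 'gene:' token.", "empty_catalog")
  }
  kept |>
    mutate(.order = row_number()) |>
    mutate(.first = min(.data$.order),
           .min_acc = sort_c(.data$record_id)[1L],
           .by = "gene_accession") |>
    filter(.data$record_id == .data$.min_acc) |>
    arrange(.data$.first) |>
    mutate(protein_accession = .data$record_id,
           record_id = .data$gene_accession) |>
    select(all_of(c("record_id", "protein_accession", "description",
                    "sequence")))
}

#' Write a tag-assignment table
#'
#' One tab-separated line per assignment — `record_id`, `gene_accession`
#' (falling back to the record id when no separate gene accession is known),
#' `identifier` — under a `#`-prefixed header line. Round-trips bit-exactly
#' with [read_assignments()].
#'
#' @param assignments An assignment tibble from [assign_uniqtags()].
#' @param path Output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  assignments <- as_tibble(assignments)
  gene <- if ("gene_accession" %in% names(assignments)) {
    assignments$gene_accession
  } else {
    assignments$record_id
  }
  lines <- c("#record_id\tgene_accession\tidentifier",
             if (nrow(assignments)) {
               paste(assignments$record_id, gene, assignments$identifier,
                     sep = "\t")
             })
  con <- if (identical(path, "")) stdout() else file(path, "wb")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a tag-assignment table
#'
#' @param path Path to a TSV written by [write_assignments()].
#' @return A tibble with `record_id`, `gene_accession`, `identifier`, plus
#'   `kmer` and `suffix` split back out of the identifier.
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) {
    abort_kmertag(paste0("File not found: ", path), "io")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(record_id = character(), gene_accession = character(),
                  identifier = character(), kmer = character(),
                  suffix = integer()))
  }
  parts <- stringr::str_split_fixed(lines, "\t", 3L)
  if (any(!nzchar(parts[, 3L]))) {
    abort_kmertag(
      paste0("Malformed assignment TSV (expected 3 tab-separated columns): ",
             path),
      "malformed_tsv")
  }
  tibble(record_id = parts[, 1L],
         gene_accession = parts[, 2L],
         identifier = parts[, 3L]) |>
    mutate(kmer = sub("-[0-9]+$", "", .data$identifier),
           suffix = as.integer(sub("^.*-", "", .data$identifier)))
}
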