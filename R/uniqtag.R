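#' Candidate k-mers of a sequence
#'
#' Enumerates the distinct length-`k` substrings of a sequence, in order of
#' first occurrence. A sequence shorter than `k` has no k-mers in the strict
#' sense; such a sequence contributes its whole residue string as its single
#' candidate, so that every gene receives a tag.
#'
#' @param sequence A single residue string (normalized internally, see
#'   [normalize_sequence()]).
#' @param k Tag length, a single integer >= 1.
#'
#' @return Character vector of distinct candidate k-mers.
#' @export
#' @examples
#' candidate_kmers("MAGICHAT", 3)
#' candidate_kmers("ACD", 5) # whole sequence when shorter than k
candidate_kmers <- function(sequence, k) {
  k <- check_k(k)
  s <- check_sequence(sequence)
  kmers_of(s, k)
}

# Internal: `s` already normalized and non-empty.
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, seq_len(n - k + 1L), k:n))
}

#' Build the catalog-wide k-mer frequency index
#'
#' For a catalog \eqn{S} the index records \eqn{f(t, S)}: the number of
#' catalog sequences whose candidate k-mer set contains \eqn{t}. This is a
#' presence count, not an occurrence count — a k-mer repeated within one
#' sequence contributes once.
#'
#' @param catalog A gene catalog (see [gene_catalog()]); must be non-empty.
#' @inheritParams candidate_kmers
#'
#' @return An object of class `kmer_index`: a list with `k` and a named
#'   integer vector `counts`.
#' @export
#' @examples
#' idx <- build_kmer_index(gene_catalog(c("a", "b"), c("ACDEF", "CDEFG")), 3)
#' idx$counts
build_kmer_index <- function(catalog, k) {
  k <- check_k(k)
  catalog <- validate_catalog(catalog, allow_empty = FALSE)
  seqs <- vapply(catalog$sequence, check_sequence, character(1L),
                 USE.NAMES = FALSE)
  sets <- lapply(seqs, kmers_of, k = k)
  tab <- table(unlist(sets, use.names = FALSE))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(k = k, counts = counts), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "|", length(x$counts),
      "candidate k-mers, max presence count", max(x$counts), "\n")
  invisible(x)
}

#' Select a sequence's UniqTag k-mer
#'
#' The UniqTag k-mer \eqn{u_k(s, S)} is the lexicographically minimal k-mer
#' among those k-mers of the sequence that are least frequent in the catalog
#' the index was built from. Ties in frequency are broken by bytewise
#' (C-locale, uppercase) order. Typically this is the first, in sorted order,
#' of the k-mers unique to that gene.
#'
#' @inheritParams candidate_kmers
#' @param index A `kmer_index` built from a catalog containing `sequence`.
#'
#' @return A single candidate k-mer string.
#' @export
#' @examples
#' cat <- gene_catalog(c("a", "b"), c("ACDEF", "CDEFG"))
#' idx <- build_kmer_index(cat, 3)
#' uniqtag_kmer("ACDEF", idx) # "ACD": its only catalog-unique 3-mer
uniqtag_kmer <- function(sequence, index) {
  if (!inherits(index, "kmer_index")) {
    abort_kmertag("`index` must be a kmer_index from build_kmer_index().",
                  "invalid_parameter")
  }
  kmers <- candidate_kmers(sequence, index$k)
  counts <- index$counts[kmers]
  if (anyNA(counts)) {
    missing <- kmers[is.na(counts)]
    abort_kmertag(
      paste0("Candidate k-mer(s) absent from index (was it built from a ",
             "catalog containing this sequence?): ",
             paste(head(missing, 3L), collapse = ", ")),
      "inconsistent_index")
  }
  least <- kmers[counts == min(counts)]
  sort_c(least)[1L]
}

#' Assign UniqTag identifiers to every gene of a catalog
#'
#' Computes each gene's UniqTag k-mer against the whole-catalog frequency
#' index, then appends the collision suffix: genes sharing a chosen k-mer are
#' numbered `-1`, `-2`, ... in catalog order, and the suffix is always
#' emitted, including `-1` for k-mers chosen by a single gene (so a complete
#' identifier looks like `ARNDCEQGH-1`).
#'
#' Identifier components depend only on sequence content and the catalog's
#' k-mer composition: renaming records or permuting catalog order never
#' changes a gene's k-mer component (only suffix numbering can shift among
#' colliding genes).
#'
#' @param catalog A gene catalog. An empty catalog yields an empty
#'   assignment; any empty sequence is an error (the command-line interface
#'   skips such records instead, with a warning).
#' @param k Tag length; the default of 9 residues suits peptide catalogs,
#'   where a 9-mer over the 20-letter alphabet is almost always unique to
#'   its gene.
#'
#' @return A tibble with one row per gene in catalog order: `record_id`,
#'   `kmer`, `suffix`, `identifier`, plus any extra catalog columns
#'   (e.g. `protein_accession`).
#' @export
#' @examples
#' assign_uniqtags(gene_catalog(c("a", "b"), c("ACDEF", "CDEFG")), k = 3)
assign_uniqtags <- function(catalog, k = 9L) {
  k <- check_k(k)
  catalog <- validate_catalog(catalog)
  extra <- setdiff(names(catalog), c("record_id", "sequence"))
  if (nrow(catalog) == 0L) {
    return(tibble(record_id = character(), kmer = character(),
                  suffix = integer(), identifier = character()))
  }
  seqs <- vapply(catalog$sequence, check_sequence, character(1L),
                 USE.NAMES = FALSE)
  sets <- lapply(seqs, kmers_of, k = k)

  # Presence counts over candidate sets, then the per-gene argmin.
  all_kmers <- unlist(sets, use.names = FALSE)
  lev <- factor(all_kmers)
  freq <- tabulate(lev, nbins = nlevels(lev))
  per_kmer_count <- freq[as.integer(lev)]
  gene_of <- factor(rep.int(seq_along(sets), lengths(sets)),
                    levels = seq_along(sets))
  kmer_by_gene <- split(all_kmers, gene_of)
  count_by_gene <- split(per_kmer_count, gene_of)
  chosen <- mapply(function(km, ct) sort_c(km[ct == min(ct)])[1L],
                   kmer_by_gene, count_by_gene, USE.NAMES = FALSE)

  out <- tibble(record_id = catalog$record_id, kmer = chosen)
  if (length(extra)) out <- dplyr::bind_cols(out, catalog[extra])
  out |>
    mutate(suffix = row_number(), .by = "kmer") |>
    mutate(identifier = paste0(.data$kmer, "-", .data$suffix)) |>
    select(all_of(c("record_id", "kmer", "suffix", "identifier")),
           all_of(extra))
}
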