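#' Count common UniqTag identifiers between two assignments
#'
#' Cardinality of the intersection of the two identifier sets. By default
#' the full identifier is compared, collision suffix included, since that is
#' what the emitted identifier always carries; `kmer_only = TRUE` compares
#' the k-mer components alone.
#'
#' @param a,b Assignment tibbles (from [assign_uniqtags()] or
#'   [read_assignments()]).
#' @param kmer_only Compare only k-mer components, ignoring suffixes.
#' @return An integer count.
#' @export
common_identifiers <- function(a, b, kmer_only = FALSE) {
  if (kmer_only) {
    length(intersect(unique(a$kmer), unique(b$kmer)))
  } else {
    length(intersect(unique(a$identifier), unique(b$identifier)))
  }
}

#' Count common accessions between two builds
#'
#' Intersection cardinality of two accession sets, with `.N` version
#' suffixes stripped by default (stable accessions persist across builds
#' while their versions increment).
#'
#' @param ids_a,ids_b Character vectors of accessions.
#' @param strip_versions Drop a trailing `.<digits>` before comparing.
#' @return An integer count.
#' @export
common_accessions <- function(ids_a, ids_b, strip_versions = TRUE) {
  if (strip_versions) {
    ids_a <- sub("\\.[0-9]+$", "", ids_a)
    ids_b <- sub("\\.[0-9]+$", "", ids_b)
  }
  length(intersect(unique(ids_a), unique(ids_b)))
}

#' Count genes with identical representative sequences between builds
#'
#' Counted per gene of the compared (non-reference) catalog: the number of
#' its genes whose normalized representative sequence occurs among the
#' reference catalog's representative sequences. Two compared-build genes
#' sharing one sequence present in the reference both count.
#'
#' @param cat_ref,cat_other Representative-per-gene catalogs.
#' @return An integer count.
#' @export
identical_sequence_count <- function(cat_ref, cat_other) {
  cat_ref <- validate_catalog(cat_ref)
  cat_other <- validate_catalog(cat_other)
  sum(normalize_sequence(cat_other$sequence) %in%
        normalize_sequence(cat_ref$sequence))
}

#' Compare two annotation builds
#'
#' The build-vs-build stability report: UniqTags are assigned to each
#' catalog independently (no knowledge of the other build is used in
#' tagging) and the report counts common UniqTag identifiers, common gene
#' accessions, common protein accessions (when a `protein_accession` column
#' is present in both catalogs), and identical representative sequences.
#' All fractions are relative to the gene count of the non-reference build.
#'
#' @param cat_ref Reference-build catalog.
#' @param cat_other Compared-build catalog.
#' @param k Tag length (default 9, suited to peptides).
#' @param reference_label,other_label Labels used in the report and plots.
#' @param kmer_only Passed to [common_identifiers()].
#' @param strip_versions Passed to [common_accessions()].
#'
#' @return A one-row tibble of class `build_stability` with counts and
#'   fractions.
#' @export
#' @examples
#' cat <- gene_catalog(c("g1", "g2"), c("ACDEF", "CDEFG"))
#' compare_builds(cat, cat, k = 3)
compare_builds <- function(cat_ref, cat_other, k = 9L,
                           reference_label = "reference",
                           other_label = "other",
                           kmer_only = FALSE, strip_versions = TRUE) {
  cat_ref <- validate_catalog(cat_ref, allow_empty = FALSE)
  cat_other <- validate_catalog(cat_other, allow_empty = FALSE)
  tags_ref <- assign_uniqtags(cat_ref, k)
  tags_other <- assign_uniqtags(cat_other, k)
  n_other <- nrow(cat_other)
  cu <- common_identifiers(tags_ref, tags_other, kmer_only = kmer_only)
  cg <- common_accessions(cat_ref$record_id, cat_other$record_id,
                          strip_versions = strip_versions)
  cp <- if (all(c("protein_accession" %in% names(cat_ref),
                  "protein_accession" %in% names(cat_other)))) {
    common_accessions(cat_ref$protein_accession, cat_other$protein_accession,
                      strip_versions = strip_versions)
  } else {
    NA_integer_
  }
  is_ <- identical_sequence_count(cat_ref, cat_other)
  out <- tibble(
    reference_label = reference_label,
    other_label = other_label,
    k = as.integer(k),
    n_genes_other = n_other,
    common_uniqtags = cu,
    common_gene_accessions = cg,
    common_protein_accessions = cp,
    identical_sequences = is_,
    frac_common_uniqtags = cu / n_other,
    frac_common_gene_accessions = cg / n_other,
    frac_common_protein_accessions = cp / n_other,
    frac_identical_sequences = is_ / n_other
  )
  class(out) <- c("build_stability", class(out))
  out
}

#' Common-identifier counts across a range of k
#'
#' Re-assigns UniqTags to both catalogs at each `k` and records the common
#' full-identifier count — the k-sweep behind the observation that tag
#' stability is insensitive to k over a wide range.
#'
#' @inheritParams compare_builds
#' @param k_values Integer vector of tag lengths (deduplicated, sorted
#'   increasing).
#'
#' @return A tibble of class `k_sweep`: columns `k`, `build`,
#'   `common_uniqtags`, `n_genes_other`, `frac_common_uniqtags`.
#' @export
k_sweep <- function(cat_ref, cat_other, k_values = 8:50,
                    other_label = "other", kmer_only = FALSE) {
  cat_ref <- validate_catalog(cat_ref, allow_empty = FALSE)
  cat_other <- validate_catalog(cat_other, allow_empty = FALSE)
  k_values <- sort(unique(vapply(k_values, check_k, integer(1L))))
  n_other <- nrow(cat_other)
  counts <- vapply(k_values, function(k) {
    common_identifiers(assign_uniqtags(cat_ref, k),
                       assign_uniqtags(cat_other, k),
                       kmer_only = kmer_only)
  }, integer(1L))
  out <- tibble(k = k_values, build = other_label,
                common_uniqtags = counts, n_genes_other = n_other,
                frac_common_uniqtags = counts / n_other)
  class(out) <- c("k_sweep", class(out))
  out
}

#' @export
tidy.build_stability <- function(x, ...) {
  counts <- x |>
    select(all_of(c("other_label", "common_uniqtags",
                    "common_gene_accessions", "common_protein_accessions",
                    "identical_sequences"))) |>
    tidyr::pivot_longer(-all_of("other_label"), names_to = "metric",
                        values_to = "count")
  fracs <- x |>
    select(all_of(c("other_label", "frac_common_uniqtags",
                    "frac_common_gene_accessions",
                    "frac_common_protein_accessions",
                    "frac_identical_sequences"))) |>
    tidyr::pivot_longer(-all_of("other_label"), names_to = "metric",
                        values_to = "fraction") |>
    mutate(metric = sub("^frac_", "", .data$metric))
  left_join(counts, fracs, by = c("other_label", "metric"))
}

#' @export
glance.build_stability <- function(x, ...) {
  as_tibble(unclass(x))[, c("reference_label", "other_label", "k",
                            "n_genes_other", "frac_common_uniqtags",
                            "frac_identical_sequences")]
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Plot a stability report
#'
#' Bar chart of the per-metric stability fractions of one or more build
#' comparisons (rows of `build_stability` reports bound together compare
#' several builds against the reference, mirroring the classic
#' common-identifier figure).
#'
#' @param object A `build_stability` tibble (one or more rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.build_stability <- function(object, ...) {
  long <- tidy.build_stability(object) |>
    filter(!is.na(.data$fraction))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$other_label,
                                     y = .data$fraction,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "compared build", y = "fraction of compared-build genes",
                  fill = NULL,
                  title = "Identifier stability between annotation builds") +
    ggplot2::theme_minimal()
}

#' Plot a k-sweep
#'
#' @param object A `k_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k,
                                       y = .data$common_uniqtags,
                                       colour = .data$build)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "k-mer size", y = "common UniqTag identifiers",
                  colour = "build",
                  title = "UniqTag stability across k") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' @rdname autoplot.build_stability
#' @param report A `build_stability` tibble.
#' @export
plot_stability <- function(report, ...) autoplot.build_stability(report, ...)

#' @rdname autoplot.k_sweep
#' @param sweep A `k_sweep` tibble.
#' @export
plot_k_sweep <- function(sweep, ...) autoplot.k_sweep(sweep, ...)

#' Within-build tagging summary
#'
#' Per-build statistics of a representative-per-gene catalog: gene count,
#' the number (and fraction) of distinct normalized peptide sequences, and
#' the number of UniqTag collisions among those distinct sequences — the
#' count of distinct sequences that are not separable by their chosen
#' k-mer, i.e. distinct-sequence count minus distinct chosen-k-mer count.
#' Genes sharing an identical sequence are expected to collide and are not
#' counted here; a collision among distinct sequences means two different
#' peptides had no distinguishing least-frequent k-mer.
#'
#' @param catalog A representative-per-gene catalog.
#' @param k Tag length (default 9).
#'
#' @return A one-row tibble: `n_genes`, `n_distinct_sequences`,
#'   `frac_distinct_sequences`, `n_tag_collisions`, `frac_tag_collisions`
#'   (relative to distinct sequences).
#' @export
catalog_summary <- function(catalog, k = 9L) {
  catalog <- validate_catalog(catalog, allow_empty = FALSE)
  n_genes <- nrow(catalog)
  norm <- normalize_sequence(catalog$sequence)
  keep <- !duplicated(norm)
  distinct_cat <- tibble(record_id = catalog$record_id[keep],
                         sequence = norm[keep])
  tags <- assign_uniqtags(distinct_cat, k = k)
  n_distinct <- nrow(distinct_cat)
  n_coll <- n_distinct - length(unique(tags$kmer))
  tibble(n_genes = n_genes,
         n_distinct_sequences = n_distinct,
         frac_distinct_sequences = n_distinct / n_genes,
         n_tag_collisions = n_coll,
         frac_tag_collisions = n_coll / n_distinct)
}
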