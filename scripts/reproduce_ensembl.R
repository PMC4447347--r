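#!/usr/bin/env Rscript
# OPTIONAL reproduction of the published Ensembl human evaluation.
#
# Requires network access to download two archived Ensembl peptide FASTA
# files (~30 MB total); nothing in the package or its test suite depends on
# this script. Once the files are present the computation is deterministic
# (< 15 min on one CPU).
#
# usage: Rscript scripts/reproduce_ensembl.R [download_dir]
#
# Published values this should approach, on the matching variant:
#   release 75: 23,393 genes; 21,783 (93.1%) distinct peptides;
#               54 (0.25%) tag collisions among distinct sequences
#   release 76: 22,469 genes; 20,376 (90.7%) common UniqTags vs 75;
#               21,097 (93.9%) common gene accessions
# The archives do not state which gene-biotype filter was applied, so both
# the all-genes and the protein_coding-only variants are reported, along
# with both identical-sequence count semantics.

suppressMessages(library(kmertag))

dir <- commandArgs(trailingOnly = TRUE)
dir <- if (length(dir)) dir[1] else "scratch/ensembl"
dir.create(dir, showWarnings = FALSE, recursive = TRUE)

urls <- c(
  r75 = "https://ftp.ensembl.org/pub/release-75/fasta/homo_sapiens/pep/Homo_sapiens.GRCh37.75.pep.all.fa.gz",
  r76 = "https://ftp.ensembl.org/pub/release-76/fasta/homo_sapiens/pep/Homo_sapiens.GRCh38.76.pep.all.fa.gz")
paths <- file.path(dir, basename(urls))
names(paths) <- names(urls)
for (i in seq_along(urls)) {
  if (!file.exists(paths[i])) {
    message("downloading ", urls[i])
    utils::download.file(urls[i], paths[i], mode = "wb")
  }
}

biotype_of <- function(description) {
  m <- stringr::str_match(description, "(?:^|\\s)gene_biotype:(\\S+)")[, 2]
  m
}

report_variant <- function(rec75, rec76, label) {
  cat75 <- suppressWarnings(select_representative_per_gene(rec75))
  cat76 <- suppressWarnings(select_representative_per_gene(rec76))
  t75 <- assign_uniqtags(cat75, 9)
  t76 <- assign_uniqtags(cat76, 9)
  s75 <- catalog_summary(cat75, 9)
  cu <- common_identifiers(t75, t76)
  cg <- common_accessions(cat75$record_id, cat76$record_id)
  cp <- common_accessions(cat75$protein_accession, cat76$protein_accession)
  # identical sequences, both semantics
  is_gene <- identical_sequence_count(cat75, cat76)
  is_distinct <- length(intersect(unique(normalize_sequence(cat75$sequence)),
                                  unique(normalize_sequence(cat76$sequence))))
  n76 <- nrow(cat76)
  cat(sprintf("\n== %s ==\n", label))
  cat(sprintf("release 75: %d genes, %d distinct peptides (%.1f%%), %d tag collisions (%.2f%%)\n",
              s75$n_genes, s75$n_distinct_sequences,
              100 * s75$frac_distinct_sequences, s75$n_tag_collisions,
              100 * s75$frac_tag_collisions))
  cat(sprintf("release 76: %d genes\n", n76))
  cat(sprintf("common UniqTags 75-76:        %d (%.1f%%)\n", cu, 100 * cu / n76))
  cat(sprintf("common gene accessions:       %d (%.1f%%)\n", cg, 100 * cg / n76))
  cat(sprintf("common protein accessions:    %d (%.1f%%)\n", cp, 100 * cp / n76))
  cat(sprintf("identical sequences (per-gene / distinct-set): %d (%.1f%%) / %d\n",
              is_gene, 100 * is_gene / n76, is_distinct))
}

rec75 <- read_fasta(paths["r75"])
rec76 <- read_fasta(paths["r76"])
report_variant(rec75, rec76, "all genes in peptide FASTA")

keep75 <- biotype_of(rec75$description) %in% "protein_coding"
keep76 <- biotype_of(rec76$description) %in% "protein_coding"
report_variant(rec75[keep75, ], rec76[keep76, ], "protein_coding genes only")
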