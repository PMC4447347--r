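#' Configuration for mutating a catalog into a successor build
#'
#' Bundles the per-residue and per-gene event rates used by
#' [mutate_build()], which emulates what happens to a gene catalog between
#' two builds of an ongoing assembly-and-annotation project: small sequence
#' corrections (substitutions and short indels), genes gained and lost, and
#' gene-model merges and splits. The default rates are gentle — roughly 90%
#' of genes keep an identical sequence per step — loosely mirroring
#' adjacent-build behaviour of a mature annotation project; they are a
#' modelling choice, not an estimate.
#'
#' @param substitution_rate Per-residue substitution probability; a hit is
#'   always resampled to a *different* symbol.
#' @param indel_rate Per-residue probability of starting an indel.
#' @param indel_length Geometric success probability; event length is
#'   `1 + rgeom(indel_length)` residues.
#' @param p_gene_loss,p_gene_gain Per-gene loss probability / expected gain
#'   rate (gains are Binomial(n, p) new random genes).
#' @param p_merge,p_split Per-gene probabilities of being drawn into a
#'   merge (marked genes are concatenated pairwise, no linker) or split at a
#'   uniform interior point.
#' @param alphabet Residue alphabet used for gained genes, insertions and
#'   substitution resampling.
#' @param seed Integer seed; identical catalog + config give bit-identical
#'   output.
#'
#' @return An object of class `build_mutation_config`.
#' @export
build_mutation_config <- function(substitution_rate = 0.002,
                                  indel_rate = 0.0005,
                                  indel_length = 0.5,
                                  p_gene_loss = 0.01,
                                  p_gene_gain = 0.01,
                                  p_merge = 0.005,
                                  p_split = 0.005,
                                  alphabet = amino_acids(),
                                  seed = 1L) {
  probs <- c(substitution_rate = substitution_rate, indel_rate = indel_rate,
             indel_length = indel_length, p_gene_loss = p_gene_loss,
             p_gene_gain = p_gene_gain, p_merge = p_merge, p_split = p_split)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_kmertag("All rates must be probabilities in [0, 1].",
                  "invalid_parameter")
  }
  if (substitution_rate + indel_rate > 1) {
    abort_kmertag("Per-residue rates must jointly be <= 1.",
                  "invalid_parameter")
  }
  if (length(alphabet) < 2L) {
    abort_kmertag("`alphabet` needs at least 2 symbols.", "invalid_parameter")
  }
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate, indel_length = indel_length,
                 p_gene_loss = p_gene_loss, p_gene_gain = p_gene_gain,
                 p_merge = p_merge, p_split = p_split,
                 alphabet = as.character(alphabet),
                 seed = as.integer(seed)),
            class = "build_mutation_config")
}

random_string <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a random gene catalog
#'
#' Genes have i.i.d. uniform residues over `alphabet`; lengths are drawn
#' from a normal distribution truncated below at 1. The defaults (300 +/- 75
#' residues over the 20-letter amino-acid alphabet) imitate a typical
#' eukaryotic representative-peptide catalog.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_mean,length_sd Mean and standard deviation of sequence
#'   length (residues).
#' @param alphabet Residue alphabet.
#' @param seed Integer seed; the same seed reproduces the catalog exactly.
#' @param id_prefix Prefix for the zero-padded synthetic gene accessions.
#'
#' @return A gene catalog tibble with a `protein_accession` column (a
#'   parallel synthetic accession, so accession-based comparisons are
#'   exercised too).
#' @export
#' @examples
#' random_catalog(3, length_mean = 20, length_sd = 3, seed = 7)
random_catalog <- function(n_genes, length_mean = 300, length_sd = 75,
                           alphabet = amino_acids(), seed = 1L,
                           id_prefix = "SYNG") {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    abort_kmertag("`n_genes` must be a single integer >= 1.",
                  "invalid_parameter")
  }
  if (length_mean < 1) {
    abort_kmertag("`length_mean` must be >= 1.", "invalid_parameter")
  }
  n_genes <- as.integer(n_genes)
  withr::with_seed(as.integer(seed), {
    lens <- pmax(1L, as.integer(round(rnorm(n_genes, length_mean, length_sd))))
    seqs <- vapply(lens, random_string, character(1L), alphabet = alphabet)
  })
  gene_catalog(
    record_id = sprintf("%s%07d", id_prefix, seq_len(n_genes)),
    sequence = seqs,
    protein_accession = sprintf("%sP%07d", id_prefix, seq_len(n_genes))
  )
}

new_event <- function(event, record_id, partner_id = NA_character_,
                      position = NA_integer_, length = NA_integer_) {
  tibble(event = event, record_id = record_id, partner_id = partner_id,
         position = as.integer(position), length = as.integer(length))
}

#' Mutate a catalog into the next annotation build
#'
#' Applies, in a fixed documented order — gene loss, gene gain, merges,
#' splits, then per-residue substitutions and indels — all drawn from one
#' RNG stream seeded by `config$seed`. Merges concatenate two marked genes
#' with no linker (the merged gene keeps the first partner's accession);
#' splits cut at a uniform interior point (the left part keeps the
#' accession). The returned event log records every event with gene ids and
#' positions, so tests can condition on whether a mutation touched a tag's
#' locus.
#'
#' @param catalog A gene catalog.
#' @param config A [build_mutation_config()].
#'
#' @return A list with elements `catalog` (the successor build) and
#'   `events` (a tibble: `event`, `record_id`, `partner_id`, `position`,
#'   `length`).
#' @export
#' @examples
#' cat <- random_catalog(5, length_mean = 40, length_sd = 5, seed = 1)
#' nxt <- mutate_build(cat, build_mutation_config(seed = 2))
#' nxt$events
mutate_build <- function(catalog, config) {
  catalog <- validate_catalog(catalog, allow_empty = FALSE)
  if (!inherits(config, "build_mutation_config")) {
    abort_kmertag("`config` must come from build_mutation_config().",
                  "invalid_parameter")
  }
  ids <- catalog$record_id
  seqs <- catalog$sequence
  events <- list()
  withr::with_seed(config$seed, {
    ## 1. gene loss
    lost <- runif(length(ids)) < config$p_gene_loss
    if (any(lost)) {
      events <- c(events, list(new_event("loss", ids[lost])))
      ids <- ids[!lost]
      seqs <- seqs[!lost]
    }

    ## 2. gene gain: new random genes, lengths resampled from the catalog
    n_gain <- rbinom(1L, nrow(catalog), config$p_gene_gain)
    if (n_gain > 0L) {
      gain_lens <- sample(pmax(1L, nchar(catalog$sequence)), n_gain,
                          replace = TRUE)
      gain_seqs <- vapply(gain_lens, random_string, character(1L),
                          alphabet = config$alphabet)
      gain_ids <- sprintf("GAIN%04d_%07d", config$seed %% 10000L,
                          seq_len(n_gain))
      while (any(gain_ids %in% ids)) gain_ids <- paste0(gain_ids, "g")
      events <- c(events, list(new_event("gain", gain_ids,
                                         length = gain_lens)))
      ids <- c(ids, gain_ids)
      seqs <- c(seqs, gain_seqs)
    }

    ## 3. merges: marked genes are paired in catalog order and concatenated
    marked <- which(runif(length(ids)) < config$p_merge)
    if (length(marked) >= 2L) {
      pairs <- matrix(marked[seq_len(2L * (length(marked) %/% 2L))],
                      ncol = 2L, byrow = TRUE)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        events <- c(events, list(new_event(
          "merge", ids[i], partner_id = ids[j],
          position = nchar(seqs[i]))))
        seqs[i] <- paste0(seqs[i], seqs[j])
      }
      drop <- pairs[, 2L]
      ids <- ids[-drop]
      seqs <- seqs[-drop]
    }

    ## 4. splits: cut at a uniform interior point; right part gets a new id
    splittable <- which(runif(length(ids)) < config$p_split & nchar(seqs) >= 2L)
    if (length(splittable)) {
      new_ids <- character(0)
      new_seqs <- character(0)
      for (i in splittable) {
        pos <- sample.int(nchar(seqs[i]) - 1L, 1L)
        right_id <- paste0(ids[i], "_s2")
        while (right_id %in% c(ids, new_ids)) right_id <- paste0(right_id, "b")
        events <- c(events, list(new_event("split", ids[i],
                                           partner_id = right_id,
                                           position = pos)))
        new_ids <- c(new_ids, right_id)
        new_seqs <- c(new_seqs, substr(seqs[i], pos + 1L, nchar(seqs[i])))
        seqs[i] <- substr(seqs[i], 1L, pos)
      }
      ids <- c(ids, new_ids)
      seqs <- c(seqs, new_seqs)
    }

    ## 5. per-residue substitutions (always to a different symbol)
    if (config$substitution_rate > 0) {
      for (i in seq_along(seqs)) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        hits <- which(runif(length(chars)) < config$substitution_rate)
        for (p in hits) {
          alt <- setdiff(config$alphabet, chars[p])
          chars[p] <- if (length(alt)) sample(alt, 1L) else chars[p]
          events <- c(events, list(new_event("substitution", ids[i],
                                             position = p, length = 1L)))
        }
        if (length(hits)) seqs[i] <- paste(chars, collapse = "")
      }
    }

    ## 6. indels, applied right-to-left so logged positions stay valid
    if (config$indel_rate > 0) {
      for (i in seq_along(seqs)) {
        len0 <- nchar(seqs[i])
        starts <- sort(which(runif(len0) < config$indel_rate),
                       decreasing = TRUE)
        for (p in starts) {
          ev_len <- 1L + rgeom(1L, config$indel_length)
          if (runif(1L) < 0.5) { # deletion, never emptying the gene
            end <- min(p + ev_len - 1L, nchar(seqs[i]))
            if (end - (p - 1L) >= nchar(seqs[i])) next
            seqs[i] <- paste0(substr(seqs[i], 1L, p - 1L),
                              substr(seqs[i], end + 1L, nchar(seqs[i])))
            events <- c(events, list(new_event("deletion", ids[i],
                                               position = p,
                                               length = end - p + 1L)))
          } else {
            ins <- random_string(ev_len, config$alphabet)
            seqs[i] <- paste0(substr(seqs[i], 1L, p), ins,
                              substr(seqs[i], p + 1L, nchar(seqs[i])))
            events <- c(events, list(new_event("insertion", ids[i],
                                               position = p,
                                               length = ev_len)))
          }
        }
      }
    }
  })
  out <- tibble(record_id = ids, sequence = seqs)
  if ("protein_accession" %in% names(catalog)) {
    out <- out |>
      left_join(catalog[c("record_id", "protein_accession")],
                by = "record_id") |>
      mutate(protein_accession = ifelse(is.na(.data$protein_accession),
                                        paste0(.data$record_id, "_P"),
                                        .data$protein_accession))
  }
  ev <- if (length(events)) bind_rows(events) else new_event(character(0), character(0))[0, ]
  list(catalog = validate_catalog(out), events = ev)
}

#' Write a mutation event log as TSV
#'
#' @param events The `events` tibble from [mutate_build()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
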