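# Brute-force reference implementation of UniqTag assignment, written
# independently of the package internals: explicit loops for k-mer
# enumeration and presence counting, and codepoint-string padding for the
# bytewise lexicographic minimum.

oracle_norm <- function(s) sub("\\*$", "", toupper(gsub("[[:space:]]", "", s)))

oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(s)
  out <- character(0)
  for (i in 1:(n - k + 1)) {
    km <- substr(s, i, i + k - 1)
    if (!(km %in% out)) out <- c(out, km)
  }
  out
}

# bytewise order via zero-padded codepoint strings (ASCII-safe)
oracle_lexi_key <- function(x) {
  vapply(x, function(s) {
    paste(sprintf("%03d", utf8ToInt(s)), collapse = "")
  }, character(1))
}

oracle_assign <- function(sequences, k) {
  seqs <- vapply(sequences, oracle_norm, character(1), USE.NAMES = FALSE)
  sets <- lapply(seqs, oracle_kmers, k = k)
  chosen <- character(length(seqs))
  for (i in seq_along(seqs)) {
    cands <- sets[[i]]
    freq <- integer(length(cands))
    for (j in seq_along(cands)) {
      cnt <- 0L
      for (set in sets) if (cands[j] %in% set) cnt <- cnt + 1L
      freq[j] <- cnt
    }
    least <- cands[freq == min(freq)]
    chosen[i] <- least[order(oracle_lexi_key(least))][1]
  }
  suffix <- stats::ave(seq_along(chosen), chosen, FUN = seq_along)
  data.frame(kmer = chosen, suffix = suffix,
             identifier = paste0(chosen, "-", suffix),
             stringsAsFactors = FALSE)
}

random_seqs <- function(n, max_len, alphabet) {
  vapply(seq_len(n), function(i) {
    len <- sample.int(max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}
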