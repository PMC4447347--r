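test_that("random_catalog is deterministic under a seed and respects its alphabet", {
  a <- random_catalog(5, length_mean = 100, length_sd = 10, seed = 7)
  b <- random_catalog(5, length_mean = 100, length_sd = 10, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, random_catalog(5, 100, 10, seed = 8)))

  one <- random_catalog(1, length_mean = 10, length_sd = 1, seed = 1)
  expect_equal(nrow(one), 1L)

  dna <- random_catalog(4, length_mean = 50, length_sd = 5,
                        alphabet = dna_bases(), seed = 2)
  expect_true(all(strsplit(paste(dna$sequence, collapse = ""), "")[[1]] %in%
                    dna_bases()))

  expect_error(random_catalog(0, 10, 1), class = "kmertag_error_invalid_parameter")
})

test_that("mutate_build with all-zero rates is the identity", {
  cat0 <- random_catalog(10, length_mean = 50, length_sd = 5, seed = 1)
  cfg <- build_mutation_config(substitution_rate = 0, indel_rate = 0,
                               p_gene_loss = 0, p_gene_gain = 0,
                               p_merge = 0, p_split = 0, seed = 3)
  res <- mutate_build(cat0, cfg)
  expect_equal(res$catalog$record_id, cat0$record_id)
  expect_equal(res$catalog$sequence, cat0$sequence)
  expect_equal(nrow(res$events), 0L)
})

test_that("mutate_build is bit-identical under the same catalog and config", {
  cat0 <- random_catalog(30, length_mean = 80, length_sd = 10, seed = 4)
  cfg <- build_mutation_config(substitution_rate = 0.01, indel_rate = 0.002,
                               p_gene_loss = 0.05, p_gene_gain = 0.05,
                               p_merge = 0.05, p_split = 0.05, seed = 11)
  r1 <- mutate_build(cat0, cfg)
  r2 <- mutate_build(cat0, cfg)
  expect_identical(r1$catalog, r2$catalog)
  expect_identical(r1$events, r2$events)
})

test_that("a forced split exactly partitions the gene", {
  cat0 <- gene_catalog("g1", "MK")
  cfg <- build_mutation_config(substitution_rate = 0, indel_rate = 0,
                               p_gene_loss = 0, p_gene_gain = 0,
                               p_merge = 0, p_split = 1, seed = 5)
  res <- mutate_build(cat0, cfg)
  expect_equal(nrow(res$catalog), 2L)
  expect_equal(paste(res$catalog$sequence, collapse = ""), "MK")
  ev <- res$events[res$events$event == "split", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$position, 1L)
})

test_that("certain substitution leaves no identical sequence", {
  cat0 <- random_catalog(10, length_mean = 30, length_sd = 3, seed = 6)
  cfg <- build_mutation_config(substitution_rate = 1, indel_rate = 0,
                               p_gene_loss = 0, p_gene_gain = 0,
                               p_merge = 0, p_split = 0, seed = 7)
  res <- mutate_build(cat0, cfg)
  expect_equal(identical_sequence_count(cat0, res$catalog), 0L)
  # same lengths, same ids: only residues changed
  expect_equal(nchar(res$catalog$sequence), nchar(cat0$sequence))
})

test_that("every output gene is traceable to survival, gain, merge or split", {
  cat0 <- random_catalog(40, length_mean = 60, length_sd = 10, seed = 8)
  cfg <- build_mutation_config(substitution_rate = 0.01, indel_rate = 0.005,
                               p_gene_loss = 0.1, p_gene_gain = 0.1,
                               p_merge = 0.1, p_split = 0.1, seed = 9)
  res <- mutate_build(cat0, cfg)
  known <- c(cat0$record_id,
             res$events$record_id[res$events$event == "gain"],
             res$events$partner_id[res$events$event == "split"])
  expect_true(all(res$catalog$record_id %in% known))
  lost <- res$events$record_id[res$events$event == "loss"]
  expect_false(any(lost %in% res$catalog$record_id))
})

test_that("merged genes concatenate their partners' residues with no linker", {
  cat0 <- gene_catalog(c("g1", "g2"), c("AAAAA", "CCCCC"))
  cfg <- build_mutation_config(substitution_rate = 0, indel_rate = 0,
                               p_gene_loss = 0, p_gene_gain = 0,
                               p_merge = 1, p_split = 0, seed = 10)
  res <- mutate_build(cat0, cfg)
  expect_equal(res$catalog$sequence, "AAAAACCCCC")
  expect_equal(res$catalog$record_id, "g1")
  ev <- res$events[res$events$event == "merge", ]
  expect_equal(ev$partner_id, "g2")
  expect_equal(ev$position, 5L)
})

test_that("config validation rejects out-of-range rates", {
  expect_error(build_mutation_config(substitution_rate = 1.5),
               class = "kmertag_error_invalid_parameter")
  expect_error(build_mutation_config(p_merge = -0.1),
               class = "kmertag_error_invalid_parameter")
  expect_error(build_mutation_config(alphabet = "A"),
               class = "kmertag_error_invalid_parameter")
})

test_that("gentle default rates keep tags more stable than raw sequences", {
  cat0 <- random_catalog(80, length_mean = 200, length_sd = 40, seed = 12)
  res <- mutate_build(cat0, build_mutation_config(seed = 13))
  rep <- compare_builds(cat0, res$catalog, k = 9)
  expect_gte(rep$common_uniqtags, rep$identical_sequences)
  # a 200-residue gene escapes all per-residue events with
  # probability (1 - 0.002 - 0.0005)^200 ~ 0.6; allow sampling noise
  expect_gt(rep$frac_identical_sequences, 0.4)
  expect_gt(rep$frac_common_uniqtags, 0.7)
})
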