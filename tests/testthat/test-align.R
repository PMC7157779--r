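test_that("k-mer index lookup matches naive string search", {
  idx <- build_index(annotated_genome("toy", "ACGTACGT"),
                     aligner_config(k = 4))
  expect_equal(sort(index_lookup(idx, "ACGT")), c(1L, 5L))
  expect_equal(length(index_lookup(idx, "AAAA")), 0)
  expect_error(build_index(annotated_genome("toy", "ACGTACGT"),
                           aligner_config(k = 11)), "shorter")

  set.seed(4)
  g <- generate_genome(1000, seed = 4)
  cfg <- aligner_config(k = 8)
  idx <- build_index(g, cfg)
  for (start in sample(1:(1000 - 7), 25)) {
    km <- substr(g$sequence, start, start + 7)
    naive <- gregexpr(km, g$sequence, fixed = TRUE)[[1]]
    # gregexpr misses overlapping hits; verify as superset + membership
    hits <- sort(index_lookup(idx, km))
    expect_true(all(naive %in% hits))
    expect_true(all(substring(g$sequence, hits, hits + 7) == km))
  }
})

test_that("perfect unique reads get full score and mapq 60; exact repeats get mapq 0", {
  g <- generate_genome(4000, seed = 8)
  idx <- build_index(g)
  r <- align_read(substr(g$sequence, 1001, 1075), idx)
  expect_true(r$mapped)
  expect_equal(r$cigar, "75M")
  expect_equal(r$score, 150)
  expect_equal(r$mapq, 60)
  expect_equal(r$pos, 1001)

  # duplicate a 75-mer elsewhere -> exact tie -> mapq 0
  dupseq <- paste0(substr(g$sequence, 1, 2000),
                   substr(g$sequence, 1001, 1075),
                   substr(g$sequence, 2076, 4000))
  idx2 <- build_index(annotated_genome("dup", dupseq))
  r2 <- align_read(substr(g$sequence, 1001, 1075), idx2)
  expect_true(r2$mapped)
  expect_equal(r2$mapq, 0)
})

test_that("reported scores equal the unbanded Smith-Waterman oracle", {
  set.seed(17)
  g <- generate_genome(3000, seed = 17)
  idx <- build_index(g)
  for (i in 1:100) {
    start <- sample(1:(3000 - 74), 1)
    read <- substr(g$sequence, start, start + 74)
    read <- mutate_bases(read, sample(1:75, 2))
    if (sample(c(TRUE, FALSE), 1))
      read <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    r <- align_reads(read, idx)
    expect_true(r$mapped)
    expect_equal(r$score, sw_oracle_score(read, g$sequence))
  }
})

test_that("mapq never decreases as the best-vs-second score gap widens", {
  # two copies of a locus; interior substitutions in the second copy widen
  # the best-vs-second gap by 5 points each, so mapq must be nondecreasing
  base <- generate_genome(2000, seed = 23)$sequence
  copy <- substr(base, 501, 575)
  posns <- list(integer(), 38L, c(25L, 50L), c(19L, 38L, 57L),
                c(15L, 30L, 45L, 60L))
  set.seed(23)
  mapqs <- sapply(posns, function(p) {
    copy2 <- if (length(p)) mutate_bases(copy, p) else copy
    gg <- annotated_genome("two", paste0(base, strrep("T", 20), copy2))
    align_read(copy, build_index(gg))$mapq
  })
  expect_equal(mapqs[1], 0) # exact tie
  expect_true(all(diff(mapqs) >= 0))
})

test_that("pair alignment flags proper pairs and handles unmapped mates", {
  g <- generate_genome(6000, seed = 12)
  idx <- build_index(g)
  frag <- substr(g$sequence, 2001, 2300)
  m1 <- substr(frag, 1, 75)
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(frag, 226, 300))))
  pa <- pair_align(m1, m2, idx)
  expect_true(pa$pairs$pair_mapped)
  expect_true(pa$pairs$proper)
  expect_equal(pa$pairs$sum_score, 300)

  # same-strand mates are not proper
  pa2 <- pair_align(m1, substr(frag, 226, 300), idx)
  expect_true(pa2$pairs$pair_mapped)
  expect_false(pa2$pairs$proper)

  # unmapped mate contributes 0 to the score sum
  set.seed(3)
  junk <- paste(sample(c("A", "C", "G", "T"), 75, replace = TRUE),
                collapse = "")
  pa3 <- pair_align(m1, junk, idx)
  expect_false(pa3$pairs$pair_mapped)
  expect_equal(pa3$pairs$n_mapped, 1)
  s1 <- pa3$mates$score[pa3$mates$mate == 1]
  expect_equal(pa3$pairs$sum_score, s1)

  # insert outside limits is not proper
  far2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g$sequence, 5001, 5075))))
  pa4 <- pair_align(m1, far2, idx)
  expect_true(pa4$pairs$pair_mapped)
  expect_false(pa4$pairs$proper)
})

test_that("SAM round trip reproduces alignment records", {
  g <- generate_genome(5000, seed = 19, genome_id = "gA")
  sa <- coculture_species(g)
  sb <- coculture_species(generate_genome(5000, seed = 20, genome_id = "gB"))
  sim <- simulate_reads(sa, sb, mixture = 0.8, n_pairs = 120, seed = 21)
  pa <- align_pairs(sim$reads, build_index(g))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(pa, path)
  back <- read_sam(path)
  for (col in c("mapped", "pos", "strand", "cigar", "score", "mapq", "seq")) {
    expect_identical(back$mates[[col]][order(back$mates$read_id)],
                     pa$mates[[col]][order(pa$mates$read_id)],
                     info = col)
  }
  expect_equal(back$pairs$sum_score[match(pa$pairs$pair_id, back$pairs$pair_id)],
               pa$pairs$sum_score)
})

test_that("duplicate marking keeps the best pair and matches injected truth", {
  g <- generate_genome(3000, seed = 30)
  idx <- build_index(g)
  frag <- substr(g$sequence, 1001, 1250)
  m1 <- substr(frag, 1, 75)
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(frag, 176, 250))))
  m1_err <- mutate_bases(m1, 10)  # same 5' coords, lower score
  pa <- align_pairs(data.frame(pair_id = c("a", "b", "c"),
                               seq1 = c(m1, m1_err, substr(g$sequence, 2001, 2075)),
                               seq2 = c(m2, m2, as.character(
                                 Biostrings::reverseComplement(Biostrings::DNAString(
                                   substr(g$sequence, 2176, 2250)))))),
                    idx)
  d <- mark_duplicates(pa)
  expect_identical(d$duplicate[match(c("a", "b", "c"), d$pair_id)],
                   c(FALSE, TRUE, FALSE))

  # injected duplicates from the simulator are all flagged
  ga <- generate_genome(30000, seed = 41, genome_id = "A")
  gb <- generate_genome(30000, seed = 42, genome_id = "B")
  sim <- simulate_reads(coculture_species(ga), coculture_species(gb),
                        mixture = 1, n_pairs = 400, seed = 43,
                        error_rate = 0, duplicate_rate = 0.1)
  pa2 <- align_pairs(sim$reads, build_index(ga))
  d2 <- mark_duplicates(pa2)
  injected <- sim$truth$pair_id[!is.na(sim$truth$duplicate_of)]
  expect_equal(sum(d2$duplicate), length(injected))
})
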