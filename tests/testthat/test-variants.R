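toy_genome_for_pileup <- function(len = 200, seed = 90) {
  generate_genome(len, seed = seed, genome_id = "toy")
}

test_that("pileup counts bases, insertions and deletions CIGAR-aware", {
  g <- toy_genome_for_pileup()
  ref <- g$sequence
  reads <- do.call(rbind, lapply(1:10, function(i)
    mate_row(sprintf("r%02d", i), 51, "50M", substr(ref, 51, 100))))
  pu <- pileup(reads, g)
  col <- pileup_column(pu, 75)
  expect_equal(col$depth, 10)
  expect_equal(unname(col$counts[col$ref_base]), 10)
  expect_equal(sum(col$counts), col$depth)
  expect_equal(pu$depth[50], 0)
  expect_equal(pu$depth[101], 0)

  # 100 reads, 22 carrying an alt base at position 60
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 60, 60))[1]
  altseq <- paste0(substr(ref, 51, 59), alt, substr(ref, 61, 100))
  reads2 <- do.call(rbind, lapply(1:100, function(i)
    mate_row(sprintf("q%03d", i), 51, "50M",
             if (i <= 22) altseq else substr(ref, 51, 100))))
  col2 <- pileup_column(pileup(reads2, g), 60)
  expect_equal(unname(col2$counts[alt]), 22)
  expect_equal(unname(col2$counts[substr(ref, 60, 60)]), 78)

  # insertion anchored at preceding base; deletion spans count toward depth
  ins_seq <- paste0(substr(ref, 51, 60), "GT", substr(ref, 61, 100))
  del_seq <- paste0(substr(ref, 51, 60), substr(ref, 64, 100))
  mix <- rbind(mate_row("i1", 51, "10M2I40M", ins_seq),
               mate_row("d1", 51, "10M3D37M", del_seq),
               mate_row("m1", 51, "50M", substr(ref, 51, 100)))
  pu3 <- pileup(mix, g)
  exp_ins <- normalize_indel(ref, 60, substr(ref, 60, 60),
                             paste0(substr(ref, 60, 60), "GT"))
  exp_del <- normalize_indel(ref, 60, substr(ref, 60, 63),
                             substr(ref, 60, 60))
  expect_equal(pu3$ins$position, exp_ins$position)
  expect_equal(pu3$ins$inserted, substr(exp_ins$alt, 2, nchar(exp_ins$alt)))
  expect_equal(pu3$del$position, exp_del$position)
  expect_equal(pu3$del$del_len, 3)
  expect_equal(pu3$depth[62], 3)  # two bases + one deletion span
  expect_equal(pu3$del_span[62], 1)

  # inconsistent CIGAR is an explicit error
  bad <- mate_row("b1", 51, "49M", substr(ref, 51, 100))
  expect_error(pileup(bad, g), "CIGAR")
})

test_that("pileup depth equals the interval-overlap oracle on simulated data", {
  ga <- generate_genome(6000, seed = 91, genome_id = "A")
  gb <- generate_genome(6000, seed = 92, genome_id = "B")
  sim <- simulate_reads(coculture_species(ga), coculture_species(gb),
                        mixture = 1, n_pairs = 300, seed = 93, error_rate = 0)
  pa <- align_pairs(sim$reads, build_index(ga))
  pu <- pileup(pa, ga)
  m <- pa$mates[pa$mates$mapped, ]
  ref_widths <- vapply(m$cigar, function(cg) {
    l <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    o <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(l[o %in% c("M", "=", "X", "D", "N")])
  }, 1L)
  cov <- IRanges::coverage(IRanges::IRanges(start = m$pos,
                                            width = unname(ref_widths)),
                           width = 6000)
  expect_equal(pu$depth, as.integer(cov))
  # conservation: column counts sum to the number of overlapping reads
  expect_equal(colSums(pu$base_counts) + pu$del_span, as.numeric(pu$depth))
})

test_that("variant calling applies frequency, depth and count thresholds", {
  g <- toy_genome_for_pileup(300, seed = 94)
  ref <- g$sequence
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 150, 150))[1]
  altseq <- paste0(substr(ref, 101, 149), alt, substr(ref, 151, 175))
  mk <- function(n_alt, n_total) {
    do.call(rbind, lapply(seq_len(n_total), function(i)
      mate_row(sprintf("r%03d", i), 101, "75M",
               if (i <= n_alt) altseq else substr(ref, 101, 175))))
  }
  calls <- call_variants(pileup(mk(83, 100), g))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$vtype, "SNV")
  expect_equal(calls$position, 150)
  expect_equal(calls$frequency, 0.83)
  expect_equal(calls$depth, 100)
  expect_equal(calls$alt_count, 83)

  # a single supporting read at 1% stays below the 2% screen
  expect_equal(nrow(call_variants(pileup(mk(1, 100), g), min_freq = 0.02)), 0)
  # depth gate
  expect_equal(nrow(call_variants(pileup(mk(3, 5), g), min_depth = 10)), 0)
  # indels longer than the cap are not called
  long_ins <- paste0(substr(ref, 101, 150), strrep("A", 25),
                     substr(ref, 151, 175))
  reads <- do.call(rbind, lapply(1:20, function(i)
    mate_row(sprintf("L%02d", i), 101, "50M25I25M", long_ins)))
  expect_equal(nrow(call_variants(pileup(reads, g))), 0)
})

test_that("planted indel frequency is recovered from simulated reads", {
  ga <- generate_genome(5000, seed = 95, genome_id = "A")
  anchor <- 2500L
  ins <- variant_spec(anchor, substr(ga$sequence, anchor, anchor),
                      paste0(substr(ga$sequence, anchor, anchor), "T"))
  sa <- coculture_species(ga, list(list(variants = ins, frequency = 0.98)))
  sb <- coculture_species(generate_genome(5000, seed = 96, genome_id = "B"))
  sim <- simulate_reads(sa, sb, mixture = 1, n_pairs = 4000, seed = 97)
  pa <- align_pairs(sim$reads, build_index(ga))
  calls <- call_variants(pileup(pa, ga))
  norm <- normalize_indel(ga$sequence, anchor, ins$ref, ins$alt)
  hit <- calls[calls$vtype == "INS" & calls$position == norm$position &
                 calls$alt == norm$alt, ]
  expect_equal(nrow(hit), 1)
  sd98 <- sqrt(0.98 * 0.02 / hit$depth)
  expect_lt(abs(hit$frequency - 0.98), 3 * sd98 + 0.01)
})

test_that("the frequency matrix averages replicates and keeps absences empty", {
  mkcall <- function(freq) {
    out <- data.frame(genome_id = "A", position = 10L, ref = "C", alt = "T",
                      vtype = "SNV", depth = 100L,
                      alt_count = as.integer(freq * 100), frequency = freq)
    class(out) <- c("variant_calls", "data.frame")
    out
  }
  mat <- build_matrix(list(r1 = mkcall(0.17), r2 = mkcall(0.18),
                           r3 = mkcall(0.31)),
                      average_groups = list(s0 = c("r1", "r2", "r3")))
  expect_equal(unname(mat["A:10:C>T", "s0"]), 0.22)
  expect_equal(format_freq_percent(mat)["A:10:C>T", "s0"], "22.00")

  # absent cell
  empty <- mkcall(0.5)[0, ]
  mat2 <- build_matrix(list(s1 = mkcall(0.4), s2 = empty))
  expect_true(is.na(mat2["A:10:C>T", "s2"]))
  expect_equal(format_freq_percent(mat2)["A:10:C>T", "s2"], "")

  # single sample: matrix equals the call list
  mat3 <- build_matrix(list(only = mkcall(0.83)))
  expect_equal(dim(mat3), c(1L, 1L))
  expect_equal(unname(mat3[1, 1]), 0.83)
})

test_that("VCF output round-trips and is readable by an independent parser", {
  g <- toy_genome_for_pileup(300, seed = 98)
  ref <- g$sequence
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 150, 150))[1]
  altseq <- paste0(substr(ref, 101, 149), alt, substr(ref, 151, 175))
  reads <- do.call(rbind, lapply(1:50, function(i)
    mate_row(sprintf("r%03d", i), 101, "75M",
             if (i <= 11) altseq else substr(ref, 101, 175))))
  calls <- call_variants(pileup(reads, g))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path, contig_lengths = c(toy = 300L))
  back <- read_vcf(path)
  expect_equal(back$position, calls$position)
  expect_equal(back$frequency, calls$frequency)
  expect_equal(back$depth, calls$depth)

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(unname(as.integer(v@fix[, "POS"])), calls$position)
  expect_equal(unname(v@fix[, "REF"]), calls$ref)
  expect_equal(unname(v@fix[, "ALT"]), calls$alt)
})
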