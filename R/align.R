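#' Aligner configuration
#'
#' Scoring and seeding parameters for the k-mer-seeded banded Smith-Waterman
#' aligner. The index uses a k-mer size of 11 and a step of 1 by default; the
#' BWA-like score weights (match +2, mismatch -3, gap open -5, gap extend -2)
#' are exposed because downstream read assignment uses score *ratios*, which
#' are robust to the particular scheme. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param k K-mer size (>= 4).
#' @param step Index stride (>= 1).
#' @param match,mismatch,gap_open,gap_extend Alignment score weights;
#'   `match > 0 > mismatch`.
#' @param band Half-width of the DP band around a seed diagonal cluster (bp).
#' @param min_score_frac A read is called mapped only when its best local
#'   score reaches `min_score_frac * match * read_length`; this declares
#'   cross-species non-homologous reads unmapped.
#' @param max_clusters Maximum seed-diagonal clusters extended per read.
#' @param insert_limits Length-2 vector; insert-size range for a proper pair.
#' @param unmapped_score Score contribution of an unmapped mate to the pair
#'   score sum (conservative default 0).
#' @return A list of class `aligner_config`.
#' @export
aligner_config <- function(k = 11L, step = 1L, match = 2L, mismatch = -3L,
                           gap_open = -5L, gap_extend = -2L, band = 16L,
                           min_score_frac = 0.5, max_clusters = 16L,
                           insert_limits = c(50L, 1000L),
                           unmapped_score = 0L) {
  stopifnot(k >= 4, step >= 1, match > 0, mismatch < 0,
            gap_open <= 0, gap_extend <= 0, band >= 1,
            min_score_frac > 0, min_score_frac <= 1,
            length(insert_limits) == 2, insert_limits[1] <= insert_limits[2])
  structure(list(k = as.integer(k), step = as.integer(step),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 band = as.integer(band), min_score_frac = min_score_frac,
                 max_clusters = as.integer(max_clusters),
                 insert_limits = as.integer(insert_limits),
                 unmapped_score = as.integer(unmapped_score)),
            class = "aligner_config")
}

#' Build a k-mer index for a genome
#'
#' Hashes every k-mer of the forward strand at stride `step`; k-mers
#' containing non-ACGT bases are skipped.
#'
#' @param genome An [annotated_genome()] (or a plain nucleotide string).
#' @param config An [aligner_config()].
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(genome, config = aligner_config()) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence
  else toupper(as.character(genome))
  gid <- if (inherits(genome, "annotated_genome")) genome$genome_id else "genome"
  if (nchar(seq) < config$k) stopf("genome shorter than k = %d", config$k)
  xp <- cpp_build_index(seq, config$k, config$step)
  structure(list(ptr = xp, genome_id = gid, length = nchar(seq),
                 k = config$k, step = config$step, config = config),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> %s: %d bp, k=%d step=%d\n", x$genome_id,
              x$length, x$k, x$step))
  invisible(x)
}

#' Look up the positions of a k-mer in an index
#' @param index A [build_index()] result.
#' @param kmer A k-length nucleotide string.
#' @return Integer vector of 1-based positions (possibly empty).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_index_lookup(index$ptr, kmer)
}

min_score_for <- function(config, read_len) {
  as.integer(ceiling(config$min_score_frac * config$match * read_len))
}

#' Align a batch of reads against an indexed genome
#'
#' Seeds each read's k-mers (both strands) into the index, clusters hit
#' diagonals, extends the strongest clusters by banded local dynamic
#' programming, and reports the best placement. Mapping quality is the gap
#' surrogate `min(60, 2 * (best - second_best))` - 60 when no second
#' placement exists, 0 on a tie - so that the mapq filter downstream acts on
#' a monotone measure of placement ambiguity.
#'
#' @param reads Character vector of read sequences (ACGTN).
#' @param index A [build_index()] result.
#' @param config An [aligner_config()].
#' @param ids Optional read ids.
#' @return `data.frame` with one row per read: `read_id`, `genome_id`,
#'   `mapped`, `pos` (1-based leftmost), `strand`, `cigar` (with soft
#'   clips), `score`, `mapq`, `seq` (reference-oriented when mapped).
#' @export
align_reads <- function(reads, index, config = aligner_config(), ids = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  reads <- toupper(as.character(reads))
  ids <- ids %||% sprintf("r%06d", seq_along(reads))
  ms <- min_score_for(config, max(nchar(reads)))
  r <- cpp_align_batch(index$ptr, reads, config$match, config$mismatch,
                       config$gap_open, config$gap_extend, config$band,
                       ms, config$max_clusters)
  seq_out <- reads
  rev_idx <- which(r$mapped & r$reverse)
  if (length(rev_idx)) seq_out[rev_idx] <- revcomp(reads[rev_idx])
  data.frame(read_id = ids, genome_id = index$genome_id,
             mapped = r$mapped, pos = r$pos,
             strand = ifelse(r$mapped, ifelse(r$reverse, "-", "+"), NA),
             cigar = r$cigar, score = r$score, mapq = r$mapq,
             seq = seq_out)
}

#' Align a single read
#'
#' @inheritParams align_reads
#' @param read A read sequence.
#' @return One-row alignment record (see [align_reads()]).
#' @export
align_read <- function(read, index, config = aligner_config()) {
  align_reads(read, index, config, ids = "read1")
}

#' Align the mates of read pairs and summarize each pair
#'
#' Aligns both mates of every pair against one genome and derives the
#' pair-level quantities used by competitive assignment: the score sum over
#' mapped mates (an unmapped mate contributes `unmapped_score`, 0 by
#' default), the minimum mate mapq, and the proper-pair flag (both mates
#' mapped, convergent orientation, insert within `insert_limits`).
#'
#' @param reads `data.frame` with `pair_id`, `seq1`, `seq2` (as produced by
#'   [simulate_reads()] or [read_fastq_pair()]).
#' @param index A [build_index()] result.
#' @param config An [aligner_config()].
#' @return A list of class `pair_alignments`: `mates` (per-mate alignment
#'   records with `pair_id` and `mate`), `pairs` (per-pair summary:
#'   `pair_id`, `n_mapped`, `pair_mapped`, `sum_score`, `min_mapq`,
#'   `proper`), `genome_id`.
#' @export
align_pairs <- function(reads, index, config = aligner_config()) {
  stopifnot(all(c("pair_id", "seq1", "seq2") %in% names(reads)))
  n <- nrow(reads)
  a1 <- align_reads(reads$seq1, index, config,
                    ids = paste0(reads$pair_id, "/1"))
  a2 <- align_reads(reads$seq2, index, config,
                    ids = paste0(reads$pair_id, "/2"))
  a1$pair_id <- reads$pair_id; a1$mate <- 1L
  a2$pair_id <- reads$pair_id; a2$mate <- 2L
  mates <- rbind(a1, a2)
  pairs <- summarize_pairs(a1, a2, config)
  structure(list(mates = mates, pairs = pairs, genome_id = index$genome_id,
                 config = config),
            class = "pair_alignments")
}

#' @export
print.pair_alignments <- function(x, ...) {
  cat(sprintf("<pair_alignments> vs %s: %d pairs, %d mapped, %d proper\n",
              x$genome_id, nrow(x$pairs), sum(x$pairs$pair_mapped),
              sum(x$pairs$proper)))
  invisible(x)
}

summarize_pairs <- function(a1, a2, config) {
  n <- nrow(a1)
  s1 <- ifelse(a1$mapped, a1$score, config$unmapped_score)
  s2 <- ifelse(a2$mapped, a2$score, config$unmapped_score)
  n_mapped <- a1$mapped + a2$mapped
  sum_score <- ifelse(n_mapped > 0, s1 * a1$mapped + s2 * a2$mapped +
                        config$unmapped_score * (2L - n_mapped), NA_integer_)
  min_mapq <- pmin(ifelse(a1$mapped, a1$mapq, Inf),
                   ifelse(a2$mapped, a2$mapq, Inf))
  min_mapq <- ifelse(is.finite(min_mapq), min_mapq, NA_real_)
  mean_mapq <- (ifelse(a1$mapped, a1$mapq, 0) + ifelse(a2$mapped, a2$mapq, 0)) /
    pmax(n_mapped, 1L)
  mean_mapq[n_mapped == 0L] <- NA_real_
  # proper pair: both mapped, opposite strands, convergent, insert in limits
  both <- a1$mapped & a2$mapped
  end1 <- a1$pos + cigar_ref_len(ifelse(a1$mapped, a1$cigar, "1M")) - 1L
  end2 <- a2$pos + cigar_ref_len(ifelse(a2$mapped, a2$cigar, "1M")) - 1L
  opp <- both & !is.na(a1$strand) & !is.na(a2$strand) & a1$strand != a2$strand
  fwd_start <- ifelse(a1$strand == "+", a1$pos, a2$pos)
  rev_end <- ifelse(a1$strand == "-", end1, end2)
  insert <- rev_end - fwd_start + 1L
  proper <- opp & !is.na(insert) & insert >= config$insert_limits[1] &
    insert <= config$insert_limits[2] & fwd_start <= rev_end
  proper[!both] <- FALSE
  data.frame(pair_id = a1$pair_id, n_mapped = n_mapped,
             pair_mapped = both, sum_score = as.integer(sum_score),
             min_mapq = min_mapq, mean_mapq = mean_mapq, proper = proper)
}

#' Align one read pair
#'
#' Single-pair convenience wrapper around [align_pairs()].
#'
#' @param mate1,mate2 Read sequences of the two mates.
#' @param index A [build_index()] result.
#' @param config An [aligner_config()].
#' @param pair_id Pair identifier.
#' @return A `pair_alignments` object with one pair.
#' @export
pair_align <- function(mate1, mate2, index, config = aligner_config(),
                       pair_id = "pair1") {
  align_pairs(data.frame(pair_id = pair_id, seq1 = mate1, seq2 = mate2),
              index, config)
}

mate_five_prime <- function(pos, cigar, strand, mapped) {
  ifelse(!mapped, NA_integer_,
         ifelse(strand == "+", pos,
                pos + cigar_ref_len(ifelse(mapped, cigar, "1M")) - 1L))
}

#' Mark duplicate read pairs
#'
#' Among pairs whose two mates share 5' positions and strands, the pair with
#' the highest score sum is kept and the rest are flagged as duplicates
#' (the optical/PCR duplicate rule used by standard duplicate markers).
#' Pairs with an unmapped mate are never flagged.
#'
#' @param pa A [align_pairs()] result for one genome.
#' @return `data.frame` with `pair_id` and logical `duplicate`.
#' @export
mark_duplicates <- function(pa) {
  stopifnot(inherits(pa, "pair_alignments"))
  m <- pa$mates
  a1 <- m[m$mate == 1L, ]
  a2 <- m[m$mate == 2L, ]
  a1 <- a1[match(pa$pairs$pair_id, a1$pair_id), ]
  a2 <- a2[match(pa$pairs$pair_id, a2$pair_id), ]
  fp1 <- mate_five_prime(a1$pos, a1$cigar, a1$strand, a1$mapped)
  fp2 <- mate_five_prime(a2$pos, a2$cigar, a2$strand, a2$mapped)
  k1 <- paste0(fp1, a1$strand)
  k2 <- paste0(fp2, a2$strand)
  # canonical unordered key of the two mate endpoints
  key <- ifelse(k1 <= k2, paste(k1, k2, sep = "|"), paste(k2, k1, sep = "|"))
  eligible <- a1$mapped & a2$mapped
  dup <- rep(FALSE, nrow(pa$pairs))
  if (any(eligible)) {
    idx <- which(eligible)
    # keep the highest sum_score per key (stable on ties)
    o <- idx[order(key[idx], -pa$pairs$sum_score[idx])]
    dup_o <- duplicated(key[o])
    dup[o] <- dup_o
  }
  data.frame(pair_id = pa$pairs$pair_id, duplicate = dup)
}
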