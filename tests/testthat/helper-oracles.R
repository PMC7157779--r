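# Independent oracles and small fixture builders shared across tests.

# local Smith-Waterman score via Biostrings (full quadratic DP, unbanded);
# gap of length L costs gap_open + L * gap_extend in both conventions
sw_oracle_score <- function(read, genome, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  best <- -Inf
  for (q in c(read, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read))))) {
    s <- Biostrings::pairwiseAlignment(q, genome, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend,
                                       scoreOnly = TRUE)
    best <- max(best, s)
  }
  best
}

# independent translation via the Biostrings genetic code (bacterial code 11
# assigns the same residues); truncated at the first stop
bs_translate <- function(cds) {
  sub("\\*.*", "", bs_translate_full(cds))
}

# untruncated per-sequence translation (stops kept as "*"); no.init.codon
# disables the initiator-Met rule so this is a pure codon-table lookup
bs_translate_full <- function(cds) {
  n <- (nchar(cds) %/% 3) * 3
  as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1, n)),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# oracle for frameshift accounting: translate wild and mutant coding sequence
# (extended through downstream genome), count residues differing from wild
# before the first mutant stop, and locate that stop
frameshift_oracle <- function(wild_ext, mut_ext) {
  wild_aa <- strsplit(bs_translate_full(wild_ext), "")[[1]]
  mut_aa <- strsplit(bs_translate_full(mut_ext), "")[[1]]
  wild_stop <- which(wild_aa == "*")[1]
  wild_prot <- if (is.na(wild_stop)) wild_aa else wild_aa[seq_len(wild_stop - 1)]
  mut_stop <- which(mut_aa == "*")[1]
  last <- if (is.na(mut_stop)) length(mut_aa) else mut_stop - 1
  differs <- vapply(seq_len(last), function(i)
    i > length(wild_prot) || mut_aa[i] != wild_prot[i], logical(1))
  list(changed_aa_count = sum(differs),
       premature_stop_protein_pos = as.integer(mut_stop),
       first_changed_protein_pos = as.integer(which(differs)[1]))
}

# inject n_mm substitutions at distinct positions of a sequence
mutate_bases <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[sample.int(3, 1)]
  }
  paste(ch, collapse = "")
}

# a minimal mates table (as produced by align_reads) for pileup tests
mate_row <- function(read_id, pos, cigar, seq, pair_id = read_id,
                     strand = "+", score = 150L, mapq = 60L) {
  data.frame(read_id = read_id, genome_id = "toy", mapped = TRUE, pos = pos,
             strand = strand, cigar = cigar, score = score, mapq = mapq,
             seq = seq, pair_id = pair_id, mate = 1L)
}

# one-row pair summary for assignment-rule tests
pair_row <- function(pair_id = "p1", n_mapped = 2L, sum_score = 150L,
                     min_mapq = 60, mean_mapq = min_mapq, proper = TRUE) {
  data.frame(pair_id = pair_id, n_mapped = n_mapped,
             pair_mapped = n_mapped == 2L, sum_score = sum_score,
             min_mapq = min_mapq, mean_mapq = mean_mapq, proper = proper)
}

# pick the alt base of an SNV different from the reference at `pos`
alt_base_at <- function(genome, pos) {
  setdiff(c("A", "C", "G", "T"), substr(genome$sequence, pos, pos))[1]
}

# a small annotated toy gene on a padded genome; cds given 5'->3'
toy_gene_genome <- function(cds, strand = "+", pad = 30L, seed = 99L) {
  set.seed(seed)
  left <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                 collapse = "")
  body <- if (strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  else cds
  genes <- data.frame(gene_id = "toy_g001", start = pad + 1L,
                      end = pad + nchar(cds), strand = strand)
  annotated_genome("toy", paste0(left, body, right), genes)
}
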