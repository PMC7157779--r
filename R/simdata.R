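#' Annotated genome container
#'
#' A named nucleotide sequence plus simple bacterial CDS gene models. This is
#' the coordinate frame for every variant downstream: positions are 1-based
#' inclusive on the forward strand, as in GFF3.
#'
#' @param genome_id Text label for the genome (e.g. `"gsu"`).
#' @param sequence Nucleotide string over `{A,C,G,T}`.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`). Intervals are 1-based inclusive, non-overlapping, and each
#'   must span a whole number of codons.
#' @param circular Logical; circular chromosome flag (metadata only).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, sequence, genes = NULL, circular = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stopf("genome '%s': empty sequence", genome_id)
  if (grepl("[^ACGTN]", sequence)) stopf("genome '%s': non-ACGTN characters", genome_id)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character())
  }
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(genes)))
  if (nrow(genes)) {
    if (any(genes$start > genes$end)) stopf("gene with start > end")
    if (any(genes$start < 1L) || any(genes$end > nchar(sequence)))
      stopf("gene interval outside [1, %d]", nchar(sequence))
    if (any((genes$end - genes$start + 1L) %% 3L != 0L))
      stopf("gene length not divisible by 3")
    o <- order(genes$start)
    if (any(genes$start[o][-1] <= genes$end[o][-nrow(genes)]))
      stopf("overlapping gene models")
  }
  structure(list(genome_id = genome_id, sequence = sequence,
                 genes = genes, circular = circular),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %d gene(s)%s\n",
              x$genome_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes), if (x$circular) ", circular" else ""))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sample_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# one CDS of total length len (multiple of 3, incl. start and stop codons)
random_cds <- function(len, gc) {
  n_internal <- len / 3 - 2
  codons <- character(n_internal)
  i <- 1L
  while (i <= n_internal) {
    cod <- paste(sample_bases(3, gc), collapse = "")
    if (!(cod %in% STOP_CODONS)) {
      codons[i] <- cod
      i <- i + 1L
    }
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1))
}

#' Generate a random annotated genome
#'
#' Draws a random nucleotide sequence at a target GC content and embeds
#' `n_genes` non-overlapping CDS gene models, each beginning with `ATG` and
#' ending with a stop codon (on its own strand). Deterministic for a fixed
#' seed.
#'
#' @param length Genome length in bp.
#' @param n_genes Number of CDS genes to embed.
#' @param gc Target GC fraction in (0, 1); `1` and `0` are accepted as
#'   degenerate compositions for intergenic sequence.
#' @param seed Integer RNG seed.
#' @param genome_id Label for the genome.
#' @param min_gene_len,max_gene_len Bounds on CDS length (bp, multiples of 3
#'   after rounding, including start and stop codons).
#' @param circular Circular chromosome flag.
#' @return An [annotated_genome()].
#' @examples
#' g <- generate_genome(5000, n_genes = 3, gc = 0.6, seed = 7)
#' g$genes
#' @export
generate_genome <- function(length, n_genes = 0L, gc = 0.5, seed = 1L,
                            genome_id = "genomeA",
                            min_gene_len = 150L, max_gene_len = 900L,
                            circular = FALSE) {
  stopifnot(length >= 1, n_genes >= 0, gc >= 0, gc <= 1)
  set.seed(seed)
  seq_chars <- sample_bases(length, gc)
  genes <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), strand = character())
  if (n_genes > 0) {
    lens <- sample(seq(min_gene_len, max_gene_len, by = 3L), n_genes,
                   replace = TRUE)
    lens <- (lens %/% 3L) * 3L
    slack <- length - sum(lens)
    if (slack < n_genes) # require >= 1 bp spacing between genes
      stopf("cannot pack %d genes (total %d bp) into %d bp", n_genes,
            sum(lens), length)
    cuts <- sort(sample.int(slack - n_genes + 1L, n_genes, replace = TRUE)) +
      seq_len(n_genes) - 1L
    starts <- cuts + c(0L, cumsum(lens[-n_genes]))
    starts <- starts + 1L
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    for (i in seq_len(n_genes)) {
      cds <- random_cds(lens[i], gc)
      if (strands[i] == "-") cds <- revcomp(cds)
      seq_chars[starts[i]:(starts[i] + lens[i] - 1L)] <-
        strsplit(cds, "")[[1]]
    }
    genes <- data.frame(
      gene_id = sprintf("%s_g%03d", genome_id, seq_len(n_genes)),
      start = as.integer(starts),
      end = as.integer(starts + lens - 1L),
      strand = strands)
  }
  annotated_genome(genome_id, paste(seq_chars, collapse = ""), genes,
                   circular = circular)
}

#' Derive a diverged sister genome
#'
#' Applies independent per-site substitutions at rate `divergence` to produce
#' a second genome of known nucleotide identity (`1 - divergence`) with the
#' first — the controlled analogue of two cohabiting species' genomes. Gene
#' models are dropped (substitutions would corrupt CDS structure).
#'
#' @param genome An [annotated_genome()].
#' @param divergence Per-site substitution probability in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param genome_id Label for the derived genome.
#' @return An [annotated_genome()] without gene models.
#' @export
diverge_genome <- function(genome, divergence, seed = 1L,
                           genome_id = paste0(genome$genome_id, "_div")) {
  stopifnot(inherits(genome, "annotated_genome"),
            divergence >= 0, divergence <= 1)
  set.seed(seed)
  chars <- strsplit(genome$sequence, "")[[1]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    # substitute with a uniformly chosen *different* base
    idx <- match(chars[hit], BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  annotated_genome(genome_id, paste(chars, collapse = ""))
}

#' Specify a planted variant
#'
#' Variants use the left-anchored VCF convention: an insertion's `ref` is the
#' single anchor base and `alt` is the anchor plus the inserted bases; a
#' deletion is symmetric. `true_frequency` is the fraction of cells of the
#' species carrying the variant.
#'
#' @param position 1-based genome position of the (anchor) base.
#' @param ref,alt Reference and alternate alleles.
#' @param true_frequency Population frequency in \[0, 1\].
#' @return One-row `data.frame` with columns `position`, `ref`, `alt`,
#'   `vtype`, `true_frequency`.
#' @export
variant_spec <- function(position, ref, alt, true_frequency = 1) {
  ref <- toupper(ref); alt <- toupper(alt)
  vtype <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
  else if (nchar(ref) == 1L && nchar(alt) > 1L) "INS"
  else if (nchar(alt) == 1L && nchar(ref) > 1L) "DEL"
  else stopf("unsupported allele pair %s>%s (must be SNV or anchored indel)",
             ref, alt)
  if (vtype == "SNV" && ref == alt) stopf("SNV with ref == alt")
  if (vtype == "INS" && substr(alt, 1, 1) != ref)
    stopf("insertion alt must be anchored on ref (alt[1] == ref)")
  if (vtype == "DEL" && substr(ref, 1, 1) != alt)
    stopf("deletion ref must be anchored on alt (ref[1] == alt)")
  stopifnot(true_frequency >= 0, true_frequency <= 1)
  data.frame(position = as.integer(position), ref = ref, alt = alt,
             vtype = vtype, true_frequency = true_frequency)
}

check_variants <- function(genome, specs) {
  stopifnot(is.data.frame(specs),
            all(c("position", "ref", "alt", "vtype") %in% names(specs)))
  specs <- specs[order(specs$position), , drop = FALSE]
  for (i in seq_len(nrow(specs))) {
    v <- specs[i, ]
    obs <- substr(genome$sequence, v$position, v$position + nchar(v$ref) - 1L)
    if (obs != v$ref)
      stopf("variant at %d: ref allele '%s' does not match genome ('%s')",
            v$position, v$ref, obs)
  }
  if (nrow(specs) > 1) {
    ends <- specs$position + nchar(specs$ref) - 1L
    if (any(specs$position[-1] <= ends[-nrow(specs)]))
      stopf("overlapping variant specs")
  }
  specs
}

# apply (validated, position-sorted) variants to a sequence; right-to-left so
# coordinates stay valid
compose_haplotype <- function(sequence, specs) {
  if (nrow(specs) == 0) return(sequence)
  for (i in rev(seq_len(nrow(specs)))) {
    v <- specs[i, ]
    sequence <- paste0(substr(sequence, 1L, v$position - 1L), v$alt,
                       substr(sequence, v$position + nchar(v$ref),
                              nchar(sequence)))
  }
  sequence
}

#' Plant variants into a genome
#'
#' Produces the wild and mutant haplotype sequences of a two-allele
#' population: the mutant haplotype carries all planted variants, the wild
#' haplotype none.
#'
#' @param genome An [annotated_genome()].
#' @param specs `data.frame` of variant specs ([variant_spec()] rows).
#' @return A list with `wild` (the input sequence), `mutant` (edited
#'   sequence) and `variants` (validated, position-sorted specs with a
#'   `genome_id` column).
#' @export
plant_variants <- function(genome, specs) {
  stopifnot(inherits(genome, "annotated_genome"))
  specs <- check_variants(genome, specs)
  mutant <- compose_haplotype(genome$sequence, specs)
  specs$genome_id <- rep(genome$genome_id, nrow(specs))
  list(wild = genome$sequence, mutant = mutant, variants = specs)
}

#' Describe one coculture species for read simulation
#'
#' Each species is a genome plus zero or more mutant haplotype groups. A
#' haplotype group is a set of variants inherited together at a single
#' population frequency; groups segregate independently (linkage
#' equilibrium), so two variants with different frequencies go in different
#' groups. With a single group this reduces to the wild + single-mutant
#' two-haplotype model that matches near-complete selective sweeps.
#'
#' @param genome An [annotated_genome()].
#' @param haplotypes List of lists, each `list(variants = <spec data.frame>,
#'   frequency = <fraction>)`. `NULL` for an isogenic species.
#' @return An object of class `coculture_species`.
#' @export
coculture_species <- function(genome, haplotypes = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  haplotypes <- haplotypes %||% list()
  vars <- list()
  for (i in seq_along(haplotypes)) {
    h <- haplotypes[[i]]
    stopifnot(is.list(h), !is.null(h$variants), !is.null(h$frequency),
              h$frequency >= 0, h$frequency <= 1)
    sp <- check_variants(genome, h$variants)
    sp$genome_id <- rep(genome$genome_id, nrow(sp))
    sp$true_frequency <- rep(h$frequency, nrow(sp))
    sp$hap_group <- rep(i, nrow(sp))
    vars[[i]] <- sp
  }
  all_vars <- if (length(vars)) do.call(rbind, vars) else
    data.frame(position = integer(), ref = character(), alt = character(),
               vtype = character(), true_frequency = numeric(),
               genome_id = character(), hap_group = integer())
  # all variants across groups must be disjoint so composite haplotypes exist
  if (nrow(all_vars) > 1) {
    o <- order(all_vars$position)
    ends <- all_vars$position[o] + nchar(all_vars$ref[o]) - 1L
    if (any(all_vars$position[o][-1] <= ends[-length(ends)]))
      stopf("variants in different haplotype groups overlap")
  }
  structure(list(genome = genome, haplotypes = haplotypes,
                 variants = all_vars),
            class = "coculture_species")
}

# map positions in a composite-haplotype coordinate frame back to wild
# (reference) coordinates; positions inside inserted bases map to the anchor
composite_to_wild <- function(x, specs) {
  if (nrow(specs) == 0) return(x)
  specs <- specs[order(specs$position), , drop = FALSE]
  wild <- x
  delta <- 0L # composite minus wild, left of current variant
  for (i in seq_len(nrow(specs))) {
    v <- specs[i, ]
    c_anchor <- v$position + delta
    if (v$vtype == "INS") {
      a <- nchar(v$alt) - 1L
      inside <- x > c_anchor & x <= c_anchor + a
      wild[inside] <- v$position
      after <- x > c_anchor + a
      wild[after] <- wild[after] - a
      delta <- delta + a
    } else if (v$vtype == "DEL") {
      d <- nchar(v$ref) - 1L
      after <- x > c_anchor
      wild[after] <- wild[after] + d
      delta <- delta - d
    }
  }
  wild
}

#' Simulate a paired-end coculture read set with ground truth
#'
#' Draws `n_pairs` fragments from a two-species mixture: each pair comes from
#' species A with probability `mixture`, then from a composite haplotype of
#' that species obtained by including each haplotype group independently at
#' its population frequency. Fragments follow a normal insert-size model
#' truncated at `read_len`; mates are written 5'->3' (`/1` forward, `/2`
#' reverse-complemented) with independent per-base substitution errors.
#' Constant Phred-30 base qualities. Deterministic for a fixed seed.
#'
#' @param species_a,species_b [coculture_species()] objects.
#' @param mixture Probability a pair originates from species A.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (bp); the platform emulated uses 75.
#' @param insert_mean,insert_sd Normal insert-size model (bp).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer RNG seed.
#' @param duplicate_rate Optional fraction of extra PCR-duplicate pairs
#'   (same fragment, fresh errors) appended for testing duplicate marking.
#' @return A list of class `sim_readset`: `reads` (`data.frame` with
#'   `pair_id`, `seq1`, `seq2`), `truth` (one record per pair: origin
#'   `genome_id`, haplotype-group membership string `hap`, mate intervals
#'   projected to wild-genome coordinates, `duplicate_of`), `variants`
#'   (all planted variant specs) and `params`.
#' @export
simulate_reads <- function(species_a, species_b, mixture, n_pairs,
                           read_len = 75L, insert_mean = 300, insert_sd = 60,
                           error_rate = 0.002, seed = 1L,
                           duplicate_rate = 0) {
  stopifnot(inherits(species_a, "coculture_species"),
            inherits(species_b, "coculture_species"),
            mixture >= 0, mixture <= 1, n_pairs >= 1,
            error_rate >= 0, error_rate <= 1)
  set.seed(seed)
  species <- list(A = species_a, B = species_b)
  # composite haplotype cache per species: one sequence per subset of groups
  caches <- lapply(species, function(sp) {
    G <- length(sp$haplotypes)
    subsets <- lapply(seq_len(2^G) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(G) - 1L)) > 0L))
    seqs <- lapply(subsets, function(s) {
      v <- sp$variants[sp$variants$hap_group %in% s, , drop = FALSE]
      compose_haplotype(sp$genome$sequence, v)
    })
    list(G = G, seqs = seqs, subsets = subsets)
  })
  min_len <- min(vapply(species, function(sp) nchar(sp$genome$sequence), 1))
  if (min_len < read_len) stopf("genome shorter than read length")

  from_a <- runif(n_pairs) < mixture
  sp_idx <- ifelse(from_a, 1L, 2L)
  # group inclusion: for each species, per-group Bernoulli draws
  hap_mask <- integer(n_pairs)
  for (s in 1:2) {
    sp <- species[[s]]
    rows <- which(sp_idx == s)
    if (!length(rows)) next
    G <- length(sp$haplotypes)
    if (G == 0) next
    m <- integer(length(rows))
    for (g in seq_len(G)) {
      inc <- runif(length(rows)) < sp$haplotypes[[g]]$frequency
      m <- m + inc * 2L^(g - 1L)
    }
    hap_mask[rows] <- m
  }
  inserts <- pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
  hap_seq_len <- vapply(seq_len(n_pairs), function(i)
    nchar(caches[[sp_idx[i]]]$seqs[[hap_mask[i] + 1L]]), 1L)
  if (any(inserts > hap_seq_len)) {
    if (min(hap_seq_len) < insert_mean - 4 * insert_sd)
      stopf("genome shorter than the insert-size model")
    inserts <- pmin(inserts, hap_seq_len)
  }
  starts <- floor(runif(n_pairs) * (hap_seq_len - inserts + 1)) + 1L
  ends <- starts + inserts - 1L

  haps <- paste0(sp_idx, ".", hap_mask) # cache key per pair
  seq1 <- character(n_pairs); seq2 <- character(n_pairs)
  for (key in unique(haps)) {
    rows <- which(haps == key)
    s <- sp_idx[rows[1]]; m <- hap_mask[rows[1]]
    hs <- caches[[s]]$seqs[[m + 1L]]
    frag1 <- substring(hs, starts[rows], starts[rows] + read_len - 1L)
    frag2 <- substring(hs, ends[rows] - read_len + 1L, ends[rows])
    seq1[rows] <- frag1
    seq2[rows] <- revcomp(frag2)
  }

  apply_errors <- function(seqs) {
    nerr <- rbinom(length(seqs), read_len, error_rate)
    for (i in which(nerr > 0)) {
      pos <- sample.int(read_len, nerr[i])
      ch <- strsplit(seqs[i], "")[[1]]
      idx <- match(ch[pos], BASES)
      shift <- sample.int(3L, nerr[i], replace = TRUE)
      ch[pos] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
      seqs[i] <- paste(ch, collapse = "")
    }
    seqs
  }
  seq1 <- apply_errors(seq1)
  seq2 <- apply_errors(seq2)

  pair_id <- sprintf("p%07d", seq_len(n_pairs))
  # project mate intervals back to wild coordinates per pair
  m1w_s <- integer(n_pairs); m1w_e <- integer(n_pairs)
  m2w_s <- integer(n_pairs); m2w_e <- integer(n_pairs)
  for (key in unique(haps)) {
    rows <- which(haps == key)
    s <- sp_idx[rows[1]]; m <- hap_mask[rows[1]]
    sp <- species[[s]]
    v <- sp$variants[sp$variants$hap_group %in% caches[[s]]$subsets[[m + 1L]], ,
                     drop = FALSE]
    m1w_s[rows] <- composite_to_wild(starts[rows], v)
    m1w_e[rows] <- composite_to_wild(starts[rows] + read_len - 1L, v)
    m2w_s[rows] <- composite_to_wild(ends[rows] - read_len + 1L, v)
    m2w_e[rows] <- composite_to_wild(ends[rows], v)
  }
  hap_label <- ifelse(hap_mask == 0L, "wild",
                      vapply(seq_len(n_pairs), function(i) {
                        s <- caches[[sp_idx[i]]]$subsets[[hap_mask[i] + 1L]]
                        paste0("g", s, collapse = ",")
                      }, ""))
  gid <- c(species_a$genome$genome_id, species_b$genome$genome_id)[sp_idx]
  truth <- data.frame(pair_id = pair_id, genome_id = gid, hap = hap_label,
                      hap_mask = hap_mask,
                      frag_start = starts, frag_end = ends,
                      m1_wild_start = m1w_s, m1_wild_end = m1w_e,
                      m2_wild_start = m2w_s, m2_wild_end = m2w_e,
                      duplicate_of = NA_character_)
  reads <- data.frame(pair_id = pair_id, seq1 = seq1, seq2 = seq2)

  if (duplicate_rate > 0) {
    n_dup <- round(duplicate_rate * n_pairs)
    if (n_dup > 0) {
      src <- sample.int(n_pairs, n_dup, replace = TRUE)
      dup_id <- sprintf("p%07d", n_pairs + seq_len(n_dup))
      dreads <- data.frame(pair_id = dup_id,
                           seq1 = apply_errors(seq1[src]),
                           seq2 = apply_errors(seq2[src]))
      dtruth <- truth[src, ]
      dtruth$pair_id <- dup_id
      dtruth$duplicate_of <- pair_id[src]
      rownames(dtruth) <- NULL
      reads <- rbind(reads, dreads)
      truth <- rbind(truth, dtruth)
    }
  }

  all_vars <- rbind(species_a$variants, species_b$variants)
  structure(list(reads = reads, truth = truth, variants = all_vars,
                 params = list(mixture = mixture, n_pairs = n_pairs,
                               read_len = read_len, insert_mean = insert_mean,
                               insert_sd = insert_sd, error_rate = error_rate,
                               duplicate_rate = duplicate_rate, seed = seed)),
            class = "sim_readset")
}

#' @export
print.sim_readset <- function(x, ...) {
  cat(sprintf("<sim_readset> %d pairs (%d bp PE), mixture %.3g, %d planted variant(s)\n",
              nrow(x$reads), x$params$read_len, x$params$mixture,
              nrow(x$variants)))
  invisible(x)
}

#' Write simulation outputs to disk
#'
#' Writes genomes as FASTA, gene models as GFF3 (`type=CDS`, 1-based
#' inclusive), reads as a FASTQ pair (`/1`, `/2`, constant Phred-30
#' qualities), the truth table as TSV, and a JSON run manifest recording the
#' seed and parameters.
#'
#' @param sim A [simulate_reads()] result.
#' @param species_a,species_b The [coculture_species()] that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, species_a, species_b, dir) {
  stopifnot(inherits(sim, "sim_readset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in list(species_a, species_b)) {
    write_genome_fasta(sp$genome, file.path(dir, paste0(sp$genome$genome_id, ".fasta")))
    if (nrow(sp$genome$genes))
      write_genes_gff3(sp$genome, file.path(dir, paste0(sp$genome$genome_id, ".gff3")))
  }
  write_fastq(sim$reads, file.path(dir, "reads_1.fastq"),
              file.path(dir, "reads_2.fastq"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a genome as FASTA
#' @param genome An [annotated_genome()].
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  s <- Biostrings::DNAStringSet(genome$sequence)
  names(s) <- genome$genome_id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write gene models as GFF3
#' @param genome An [annotated_genome()].
#' @param path Output file.
#' @export
write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand, type = "CDS", ID = g$gene_id,
    phase = rep(0L, nrow(g)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `type == "CDS"` records for one sequence into the simple gene-model
#' table used throughout.
#'
#' @param path GFF3 file.
#' @return `data.frame` with `gene_id`, `start`, `end`, `strand`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  data.frame(gene_id = as.character(gr$ID),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Write a read pair table as FASTQ
#'
#' Mate ids follow the `/1`, `/2` convention; qualities are constant
#' Phred-30.
#'
#' @param reads `data.frame` with `pair_id`, `seq1`, `seq2`.
#' @param path1,path2 Output files for mate 1 and mate 2.
#' @export
write_fastq <- function(reads, path1, path2) {
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("seq", m)]])
    names(seqs) <- paste0(reads$pair_id, "/", m)
    qual <- Biostrings::PhredQuality(
      vapply(nchar(reads[[paste0("seq", m)]]), function(n)
        strrep("?", n), ""))
    qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
    Biostrings::writeQualityScaledXStringSet(qs, c(path1, path2)[m])
  }
  invisible(c(path1, path2))
}

#' Read a FASTQ pair into the read-table form
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return `data.frame` with `pair_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  id1 <- sub("/1$", "", sub(" .*", "", names(s1)))
  id2 <- sub("/2$", "", sub(" .*", "", names(s2)))
  if (!identical(id1, id2)) stopf("mate files disagree on pair ids")
  data.frame(pair_id = id1, seq1 = as.character(s1), seq2 = as.character(s2))
}
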