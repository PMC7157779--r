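# Bacterial (single-CDS) consequence annotation: no splicing, no UTRs; gene
# models are plain strand-aware intervals and translation uses the standard
# code (identical residue assignments in bacterial table 11).

CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a CDS nucleotide sequence
#'
#' Standard genetic code; a stop codon is rendered `"*"` and terminates the
#' reported protein. Codons containing non-ACGT characters translate to
#' `"X"`. A trailing partial codon is ignored (with a warning unless
#' `partial_ok`).
#'
#' @param cds Nucleotide string.
#' @param partial_ok Silence the partial-tail warning.
#' @param keep_stop Append the terminating `"*"` (default `FALSE`: the
#'   protein ends at the residue before the stop).
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds, partial_ok = FALSE, keep_stop = FALSE) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3 != 0 && !partial_ok)
    warning("CDS length not divisible by 3; trailing partial codon ignored")
  n_codon <- n %/% 3
  if (n_codon == 0) return("")
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(CODON_TABLE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    k <- stop_at[1]
    aa <- aa[seq_len(if (keep_stop) k else k - 1L)]
  }
  paste(aa, collapse = "")
}

# full (untruncated) per-codon translation, no stop termination
translate_codons <- function(cds) {
  n_codon <- nchar(cds) %/% 3
  if (n_codon == 0) return(character())
  codons <- substring(toupper(cds), 3 * seq_len(n_codon) - 2,
                      3 * seq_len(n_codon))
  aa <- unname(CODON_TABLE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# the CDS-coordinate offset (1-based) of a genome position within a gene
cds_offset <- function(position, gene) {
  if (gene$strand == "+") position - gene$start + 1L
  else gene$end - position + 1L
}

# extract the mutant gene region after applying one variant; returns NULL if
# the variant does not alter the CDS interval
apply_variant_to_gene <- function(v, gene, genome_seq) {
  gstart <- gene$start; gend <- gene$end
  if (v$vtype == "SNV") {
    if (v$position < gstart || v$position > gend) return(NULL)
  } else if (v$vtype == "INS") {
    # inserted bases sit between position and position+1
    if (v$position < gstart || v$position >= gend) return(NULL)
  } else { # DEL: deleted bases are position+1 .. position+|ref|-1
    del_lo <- v$position + 1L
    del_hi <- v$position + nchar(v$ref) - 1L
    if (del_hi < gstart || del_lo > gend) return(NULL)
  }
  boundary <- (v$position + nchar(v$ref) - 1L) > gend ||
    (v$vtype != "SNV" && v$position < gstart)
  region <- substr(genome_seq, gstart, gend)
  relpos <- v$position - gstart + 1L
  mutant <- if (v$vtype == "SNV") {
    paste0(substr(region, 1, relpos - 1L), v$alt,
           substr(region, relpos + 1L, nchar(region)))
  } else if (v$vtype == "INS") {
    paste0(substr(region, 1, relpos), substr(v$alt, 2, nchar(v$alt)),
           substr(region, relpos + 1L, nchar(region)))
  } else {
    keep_to <- min(relpos + nchar(v$ref) - 1L, nchar(region))
    paste0(substr(region, 1, relpos), substr(region, keep_to + 1L,
                                             nchar(region)))
  }
  list(mutant_region = mutant, boundary = boundary)
}

gene_cds <- function(gene, genome_seq) {
  s <- substr(genome_seq, gene$start, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}

#' Classify the coding consequence of a variant
#'
#' Compares the wild-type and mutant CDS translations of the overlapped gene.
#' SNVs are classified at their codon (`protein_pos = ceiling(offset / 3)`) as
#' synonymous, missense or nonsense; indels whose length change is not a
#' multiple of 3 are frameshifts, otherwise in-frame indels. Minus-strand
#' genes are handled by reverse-complementing; variants not overlapping the
#' gene are `intergenic`. Variants extending past a gene boundary are
#' classified by the overlapped portion and flagged `boundary`.
#'
#' @param v One variant (one-row `data.frame` with `position`, `ref`, `alt`,
#'   `vtype`, e.g. a [call_variants()] row or [variant_spec()]).
#' @param gene One gene-model row (`gene_id`, `start`, `end`, `strand`).
#' @param genome The [annotated_genome()] (or plain sequence string).
#' @return A list of class `consequence`: `gene_id`, `effect` (one of
#'   `intergenic`, `synonymous`, `missense`, `nonsense`,
#'   `frameshift_insertion`, `frameshift_deletion`, `inframe_indel`),
#'   `protein_pos`, `aa_ref`, `aa_alt`, `boundary`, and for frameshifts
#'   `changed_aa_count` and `premature_stop_protein_pos` (see
#'   [frameshift_consequence()]).
#' @export
classify_variant <- function(v, gene, genome) {
  genome_seq <- if (inherits(genome, "annotated_genome")) genome$sequence
  else toupper(as.character(genome))
  if (gene$start > gene$end || (gene$end - gene$start + 1L) %% 3L != 0L)
    stopf("invalid gene model '%s'", gene$gene_id)
  v <- as.list(v)
  res <- list(gene_id = gene$gene_id, effect = "intergenic",
              protein_pos = NA_integer_, aa_ref = NA_character_,
              aa_alt = NA_character_, boundary = FALSE,
              changed_aa_count = NA_integer_,
              premature_stop_protein_pos = NA_integer_)
  class(res) <- "consequence"
  app <- apply_variant_to_gene(v, gene, genome_seq)
  if (is.null(app)) return(res)
  res$boundary <- app$boundary

  if (v$vtype == "SNV") {
    off <- cds_offset(v$position, gene)
    ppos <- as.integer(ceiling(off / 3))
    wild_cds <- gene_cds(gene, genome_seq)
    mut_cds <- if (gene$strand == "-") revcomp(app$mutant_region) else
      app$mutant_region
    wild_aa <- translate_codons(wild_cds)[ppos]
    mut_aa <- translate_codons(mut_cds)[ppos]
    res$protein_pos <- ppos
    res$aa_ref <- wild_aa
    res$aa_alt <- mut_aa
    res$effect <- if (identical(wild_aa, mut_aa)) "synonymous"
    else if (identical(mut_aa, "*")) "nonsense"
    else "missense"
    return(res)
  }

  len_change <- nchar(v$alt) - nchar(v$ref)
  if (len_change %% 3L == 0L) {
    res$effect <- "inframe_indel"
    off <- cds_offset(v$position, gene)
    res$protein_pos <- as.integer(ceiling(off / 3))
    return(res)
  }
  res$effect <- if (v$vtype == "INS") "frameshift_insertion" else
    "frameshift_deletion"
  fs <- frameshift_consequence(v, gene, genome)
  res$protein_pos <- fs$first_changed_protein_pos
  res$changed_aa_count <- fs$changed_aa_count
  res$premature_stop_protein_pos <- fs$premature_stop_protein_pos
  res$start_lost <- fs$start_lost
  res
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("<consequence> %s: %s%s\n", x$gene_id, x$effect,
              if (!is.na(x$protein_pos))
                sprintf(" (protein pos %d%s)", x$protein_pos,
                        if (x$effect == "missense")
                          sprintf(", %s>%s", x$aa_ref, x$aa_alt) else "")
              else ""))
  invisible(x)
}

#' Quantify a frameshift's downstream protein consequence
#'
#' Translates the mutant CDS directly from the start codon, continuing into
#' downstream genomic sequence (a frameshift usually abolishes the original
#' stop), and reports the number of residues that differ from the wild-type
#' protein from the first changed codon up to (not including) the first
#' mutant stop, plus the mutant stop's codon index. Residues past the end of
#' the wild-type protein count as changed. No heuristics: both proteins are
#' obtained by direct translation.
#'
#' @param v A frameshift variant (one-row `data.frame` or list).
#' @param gene One gene-model row.
#' @param genome The [annotated_genome()] or sequence string.
#' @return A list: `changed_aa_count`, `premature_stop_protein_pos` (`NA` if
#'   no stop is reached before the genome ends), `first_changed_protein_pos`,
#'   `start_lost`.
#' @export
frameshift_consequence <- function(v, gene, genome) {
  genome_seq <- if (inherits(genome, "annotated_genome")) genome$sequence
  else toupper(as.character(genome))
  v <- as.list(v)
  len_change <- nchar(v$alt) - nchar(v$ref)
  if (v$vtype == "SNV" || len_change %% 3L == 0L)
    stopf("not a frameshift variant (length change %d)", len_change)
  app <- apply_variant_to_gene(v, gene, genome_seq)
  if (is.null(app)) stopf("variant does not overlap gene '%s'", gene$gene_id)

  # wild and mutant coding sequence extended through downstream genome
  if (gene$strand == "+") {
    down <- substr(genome_seq, gene$end + 1L, nchar(genome_seq))
    wild_ext <- paste0(substr(genome_seq, gene$start, gene$end), down)
    mut_ext <- paste0(app$mutant_region, down)
  } else {
    up <- substr(genome_seq, 1L, gene$start - 1L)
    wild_ext <- revcomp(paste0(up, substr(genome_seq, gene$start, gene$end)))
    mut_ext <- revcomp(paste0(up, app$mutant_region))
  }
  wild_aa <- translate_codons(wild_ext)
  mut_aa <- translate_codons(mut_ext)
  wild_stop <- which(wild_aa == "*")[1]
  wild_prot <- if (is.na(wild_stop)) wild_aa else
    wild_aa[seq_len(wild_stop - 1L)]
  start_lost <- length(mut_aa) == 0L || mut_aa[1] != "M"
  mut_stop <- which(mut_aa == "*")[1]
  last <- if (is.na(mut_stop)) length(mut_aa) else mut_stop - 1L
  upto <- seq_len(last)
  differs <- vapply(upto, function(i)
    i > length(wild_prot) || mut_aa[i] != wild_prot[i], logical(1))
  first_changed <- which(differs)[1]
  changed <- sum(differs)
  list(changed_aa_count = as.integer(changed),
       premature_stop_protein_pos = as.integer(mut_stop),
       first_changed_protein_pos = as.integer(first_changed),
       start_lost = start_lost)
}

#' Annotate a set of variant calls against gene models
#'
#' Classifies every call against every overlapping gene (or as intergenic).
#'
#' @param calls A [call_variants()] result (or planted-variant specs).
#' @param genome An [annotated_genome()] carrying gene models.
#' @return `data.frame` with one row per call: the call columns plus
#'   `gene_id`, `effect`, `protein_pos`, `aa_ref`, `aa_alt`,
#'   `changed_aa_count`, `premature_stop_protein_pos`, `boundary`.
#' @export
annotate_variants <- function(calls, genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  genes <- genome$genes
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, ]
    span_lo <- v$position
    span_hi <- v$position + nchar(v$ref) - 1L
    hit <- which(genes$start <= span_hi & genes$end >= span_lo)
    if (!length(hit)) {
      return(data.frame(v, gene_id = NA_character_, effect = "intergenic",
                        protein_pos = NA_integer_, aa_ref = NA_character_,
                        aa_alt = NA_character_, changed_aa_count = NA_integer_,
                        premature_stop_protein_pos = NA_integer_,
                        boundary = FALSE))
    }
    do.call(rbind, lapply(hit, function(h) {
      cq <- classify_variant(v, genes[h, ], genome)
      data.frame(v, gene_id = cq$gene_id, effect = cq$effect,
                 protein_pos = cq$protein_pos, aa_ref = cq$aa_ref %||% NA,
                 aa_alt = cq$aa_alt %||% NA,
                 changed_aa_count = cq$changed_aa_count,
                 premature_stop_protein_pos = cq$premature_stop_protein_pos,
                 boundary = cq$boundary)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
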