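test_that("translation follows the genetic code and terminates at stops", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("CCT"), "P")
  expect_equal(translate_cds("TCT"), "S")
  expect_equal(translate_cds("ATGNNTAAA"), "MXK")
  expect_equal(translate_cds("ATGTAAAAA"), "M")  # stop truncates
  expect_warning(translate_cds("ATGAA"), "partial")

  # random CDS vs the independent Biostrings code table
  set.seed(7)
  for (i in 1:20) {
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * sample(5:40, 1),
                        replace = TRUE), collapse = "")
    expect_equal(translate_cds(cds), bs_translate(cds))
  }
})

test_that("SNV consequences are classified at the right codon", {
  g <- toy_gene_genome("ATGCCTGGGTAA")
  gene <- g$genes[1, ]
  p0 <- gene$start

  # first base of codon 2: C>T gives the proline-to-serine missense
  cq <- classify_variant(variant_spec(p0 + 3, "C", "T"), gene, g)
  expect_equal(cq$effect, "missense")
  expect_equal(cq$protein_pos, 2)
  expect_equal(cq$aa_ref, "P")
  expect_equal(cq$aa_alt, "S")

  # third base of codon 2: CCT>CCC is synonymous
  cq2 <- classify_variant(variant_spec(p0 + 5, "T", "C"), gene, g)
  expect_equal(cq2$effect, "synonymous")

  # stop-gained: TGT -> TGA at the third base of codon 2
  g3 <- toy_gene_genome("ATGTGTGGGTAA")
  cq3 <- classify_variant(variant_spec(g3$genes$start[1] + 5, "T", "A"),
                          g3$genes[1, ], g3)
  expect_equal(cq3$effect, "nonsense")

  # outside the gene
  cq4 <- classify_variant(variant_spec(5, substr(g$sequence, 5, 5),
                                       alt_base_at(g, 5)), gene, g)
  expect_equal(cq4$effect, "intergenic")
})

test_that("indels classify as frameshift or in-frame by length change", {
  g <- toy_gene_genome("ATGCCTGGGTTTTAA")
  gene <- g$genes[1, ]
  p0 <- gene$start
  anchor <- substr(g$sequence, p0 + 3, p0 + 3)

  ins1 <- variant_spec(p0 + 3, anchor, paste0(anchor, "A"))
  cq <- classify_variant(ins1, gene, g)
  expect_equal(cq$effect, "frameshift_insertion")

  ins3 <- variant_spec(p0 + 3, anchor, paste0(anchor, "AAA"))
  expect_equal(classify_variant(ins3, gene, g)$effect, "inframe_indel")
  expect_error(frameshift_consequence(ins3, gene, g), "not a frameshift")

  del1 <- variant_spec(p0 + 3, paste0(anchor, substr(g$sequence, p0 + 4, p0 + 4)),
                       anchor)
  expect_equal(classify_variant(del1, gene, g)$effect, "frameshift_deletion")
})

test_that("frameshift consequences equal direct translation of the mutant CDS", {
  # insertion of A after position 6 of ATGAAACCCGGGTTTTAA
  g <- toy_gene_genome("ATGAAACCCGGGTTTTAA")
  gene <- g$genes[1, ]
  p0 <- gene$start
  anchor <- substr(g$sequence, p0 + 5, p0 + 5)
  v <- variant_spec(p0 + 5, anchor, paste0(anchor, "A"))
  fs <- frameshift_consequence(v, gene, g)

  # oracle: build the mutant genome text and translate both proteins fully
  mut_genome <- paste0(substr(g$sequence, 1, p0 + 5), "A",
                       substring(g$sequence, p0 + 6))
  orc <- frameshift_oracle(substring(g$sequence, p0), substring(mut_genome, p0))
  expect_equal(fs$changed_aa_count, orc$changed_aa_count)
  expect_equal(fs$premature_stop_protein_pos, orc$premature_stop_protein_pos)

  # insertion in the last codon before the stop: oracle agreement again
  g2 <- toy_gene_genome("ATGAAACCCTAA")
  gene2 <- g2$genes[1, ]
  a2 <- substr(g2$sequence, gene2$start + 7, gene2$start + 7)
  v2 <- variant_spec(gene2$start + 7, a2, paste0(a2, "G"))
  fs2 <- frameshift_consequence(v2, gene2, g2)
  mut2 <- paste0(substr(g2$sequence, 1, gene2$start + 7), "G",
                 substring(g2$sequence, gene2$start + 8))
  orc2 <- frameshift_oracle(substring(g2$sequence, gene2$start),
                            substring(mut2, gene2$start))
  expect_equal(fs2$changed_aa_count, orc2$changed_aa_count)
  expect_equal(fs2$premature_stop_protein_pos, orc2$premature_stop_protein_pos)
})

test_that("random coding variants agree with the brute-force translation oracle", {
  set.seed(202)
  g <- generate_genome(9000, n_genes = 5, seed = 202, genome_id = "ann")
  for (rep in 1:60) {
    gi <- sample(nrow(g$genes), 1)
    gene <- g$genes[gi, ]
    pos <- sample(gene$start:gene$end, 1)
    ref1 <- substr(g$sequence, pos, pos)
    kind <- sample(c("SNV", "INS", "DEL"), 1)
    v <- if (kind == "SNV") {
      variant_spec(pos, ref1, setdiff(c("A", "C", "G", "T"), ref1)[sample.int(3, 1)])
    } else if (kind == "INS") {
      if (pos >= gene$end) next
      variant_spec(pos, ref1, paste0(ref1, paste(
        sample(c("A", "C", "G", "T"), sample(1:5, 1), replace = TRUE),
        collapse = "")))
    } else {
      len <- sample(1:5, 1)
      if (pos + len > nchar(g$sequence)) next
      variant_spec(pos, substr(g$sequence, pos, pos + len), ref1)
    }
    cq <- classify_variant(v, gene, g)

    # oracle: edit the whole genome, translate the gene region directly
    mut_genome <- paste0(substr(g$sequence, 1, v$position - 1), v$alt,
                         substring(g$sequence, v$position + nchar(v$ref)))
    shift <- nchar(v$alt) - nchar(v$ref)
    wild_cds <- substr(g$sequence, gene$start, gene$end)
    mut_cds <- substr(mut_genome, gene$start, gene$end + shift)
    if (gene$strand == "-") {
      rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
      wild_cds <- rc(wild_cds); mut_cds <- rc(mut_cds)
      # minus strand: the edited forward interval maps to the same CDS window
      mut_cds <- rc(substr(mut_genome, gene$start, gene$end + shift))
    }
    if (kind == "SNV") {
      wp <- strsplit(bs_translate(wild_cds), "")[[1]]
      mp <- strsplit(bs_translate(mut_cds), "")[[1]]
      diff_at <- which(wp != mp[seq_along(wp)])
      if (cq$effect == "synonymous") {
        expect_length(diff_at, 0)
      } else if (cq$effect == "missense") {
        expect_equal(diff_at, cq$protein_pos)
        expect_equal(mp[diff_at], cq$aa_alt)
      } else if (cq$effect == "nonsense") {
        expect_lt(nchar(bs_translate(mut_cds)), nchar(bs_translate(wild_cds)))
      }
    } else {
      expected <- if (abs(shift) %% 3 == 0) "inframe_indel"
      else if (kind == "INS") "frameshift_insertion" else "frameshift_deletion"
      # deletions reaching beyond the gene are boundary cases
      if (!cq$boundary) expect_equal(cq$effect, expected)
    }
  }
})

test_that("minus-strand genes mirror plus-strand consequences", {
  cds <- "ATGCCTGGGAAATTTCGATAA"
  gp <- toy_gene_genome(cds, strand = "+")
  gm <- toy_gene_genome(cds, strand = "-")
  for (off in c(3, 4, 5, 9, 12)) {
    # same CDS-coordinate SNV on the two strands
    pos_p <- gp$genes$start[1] + off
    base_p <- substr(gp$sequence, pos_p, pos_p)
    alt_p <- setdiff(c("A", "C", "G", "T"), base_p)[1]
    cq_p <- classify_variant(variant_spec(pos_p, base_p, alt_p),
                             gp$genes[1, ], gp)
    pos_m <- gm$genes$end[1] - off
    base_m <- substr(gm$sequence, pos_m, pos_m)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    cq_m <- classify_variant(variant_spec(pos_m, base_m,
                                          unname(comp[alt_p])),
                             gm$genes[1, ], gm)
    expect_equal(cq_m$effect, cq_p$effect)
    expect_equal(cq_m$protein_pos, cq_p$protein_pos)
    expect_equal(cq_m$aa_alt, cq_p$aa_alt)
  }
})

test_that("any CCN codon with a first-position C>T yields the P>S missense", {
  for (n3 in c("A", "C", "G", "T")) {
    cds <- paste0("ATG", "CC", n3, "GGGTAA")
    g <- toy_gene_genome(cds)
    gene <- g$genes[1, ]
    cq <- classify_variant(variant_spec(gene$start + 3, "C", "T"), gene, g)
    expect_equal(cq$effect, "missense")
    expect_equal(cq$aa_ref, "P")
    expect_equal(cq$aa_alt, "S")
    expect_equal(cq$protein_pos, 2)
  }
})

test_that("annotate_variants joins calls to overlapping genes", {
  g <- generate_genome(4000, n_genes = 2, seed = 301, genome_id = "ann2")
  gene <- g$genes[1, ]
  pos <- gene$start + 4
  calls <- data.frame(genome_id = "ann2", position = pos,
                      ref = substr(g$sequence, pos, pos),
                      alt = alt_base_at(g, pos), vtype = "SNV",
                      depth = 100L, alt_count = 50L, frequency = 0.5)
  ann <- annotate_variants(calls, g)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$gene_id, gene$gene_id)
  expect_true(ann$effect %in% c("synonymous", "missense", "nonsense"))
  # intergenic position
  inter <- max(g$genes$end) + 5
  calls2 <- data.frame(genome_id = "ann2", position = inter,
                       ref = substr(g$sequence, inter, inter),
                       alt = alt_base_at(g, inter), vtype = "SNV",
                       depth = 10L, alt_count = 5L, frequency = 0.5)
  expect_equal(annotate_variants(calls2, g)$effect, "intergenic")
})
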