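#' Assemble a pipeline run configuration
#'
#' Exactly one of `simulate` or `reads` must be given. In simulate mode the
#' generator block defines the two genomes, the planted haplotype groups and
#' the per-sample mixtures and haplotype frequencies; in reads mode,
#' pre-existing FASTA/GFF3/FASTQ (or SAM) inputs are consumed.
#'
#' @param out_dir Output directory for the run.
#' @param seed Integer master seed; per-stage seeds derive from it.
#' @param simulate Simulate block, see [run_pipeline()].
#' @param reads Reads block: `list(genome_a =, gff_a =, genome_b =, samples =
#'   list(<name> = list(fastq1 =, fastq2 =)))` or per-sample `sam_a`/`sam_b`.
#' @param align An [aligner_config()].
#' @param assign An [assignment_config()].
#' @param call List of [call_variants()] arguments.
#' @param average_groups Passed to [build_matrix()].
#' @param protein_table Optional `data.frame` (`gene_id`, `stage`, `log2fc`)
#'   or TSV path for the frequency-expression join.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL, reads = NULL,
                            align = aligner_config(),
                            assign = assignment_config(),
                            call = list(), average_groups = NULL,
                            protein_table = NULL) {
  if (is.null(simulate) == is.null(reads))
    stopf("exactly one of 'simulate' or 'reads' must be provided")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, reads = reads, align = align,
                 assign = assign, call = call,
                 average_groups = average_groups,
                 protein_table = protein_table),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `align`, `assign` and `call` blocks are passed to [aligner_config()],
#' [assignment_config()] and [call_variants()] respectively.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = y$out_dir %||% ".",
    seed = y$seed %||% 1L,
    simulate = y$simulate,
    reads = y$reads,
    align = do.call(aligner_config, y$align %||% list()),
    assign = do.call(assignment_config, y$assign %||% list()),
    call = y$call %||% list(),
    average_groups = y$average_groups,
    protein_table = y$protein_table)
}

stage_log <- function(log, stage, ...) {
  entry <- list(stage = stage, ...)
  c(log, list(entry))
}

build_sim_inputs <- function(sim, seed) {
  ga <- do.call(generate_genome, modifyList(
    list(seed = seed, genome_id = "genomeA"), sim$genome_a))
  gb <- if (!is.null(sim$genome_b$divergence)) {
    do.call(diverge_genome, modifyList(
      list(genome = ga, seed = seed + 1L, genome_id = "genomeB"),
      sim$genome_b))
  } else {
    do.call(generate_genome, modifyList(
      list(seed = seed + 1L, genome_id = "genomeB"), sim$genome_b))
  }
  list(genome_a = ga, genome_b = gb)
}

#' Run the coculture pipeline end to end
#'
#' Stages execute in order simulate -> align -> assign -> variants ->
#' annotate -> report, communicating through files in standard formats
#' (FASTA/GFF3/FASTQ/SAM/VCF/TSV) under `out_dir`, so each stage is
#' independently re-runnable. The run manifest records the seed and
#' parameters; a rerun with the same config and seed is bit-identical for
#' the deterministic stages.
#'
#' In simulate mode the config's `simulate` block contains `genome_a`
#' (arguments to [generate_genome()]), `genome_b` (arguments to
#' [generate_genome()] or a `divergence` from genome A), `haplotypes_a` /
#' `haplotypes_b` (lists of `list(variants = <spec table>)` haplotype
#' groups), and `samples`: a named list where each sample sets `mixture`,
#' `n_pairs`, optional `read_len`/`insert_mean`/`insert_sd`/`error_rate`/
#' `duplicate_rate`, and `hap_freqs_a`/`hap_freqs_b` (per-group population
#' frequencies for that sample — the trajectory across samples).
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @return A list of class `pipeline_run`: per-sample assignments, variant
#'   calls, the frequency matrix, annotations, truth (simulate mode), the
#'   structured stage log and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config_yaml(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  # ---- inputs: simulate or load -------------------------------------------
  sims <- NULL
  if (!is.null(config$simulate)) {
    sb <- config$simulate
    g <- build_sim_inputs(sb, config$seed)
    genome_a <- g$genome_a; genome_b <- g$genome_b
    samples <- sb$samples
    stopifnot(!is.null(names(samples)))
    sims <- list()
    reads_by_sample <- list()
    for (si in seq_along(samples)) {
      s <- samples[[si]]
      name <- names(samples)[si]
      hap_a <- lapply(seq_along(sb$haplotypes_a %||% list()), function(gi)
        list(variants = sb$haplotypes_a[[gi]]$variants,
             frequency = s$hap_freqs_a[gi]))
      hap_b <- lapply(seq_along(sb$haplotypes_b %||% list()), function(gi)
        list(variants = sb$haplotypes_b[[gi]]$variants,
             frequency = s$hap_freqs_b[gi]))
      sp_a <- coculture_species(genome_a, hap_a)
      sp_b <- coculture_species(genome_b, hap_b)
      sim <- simulate_reads(sp_a, sp_b, mixture = s$mixture,
                            n_pairs = s$n_pairs,
                            read_len = s$read_len %||% 75L,
                            insert_mean = s$insert_mean %||% 300,
                            insert_sd = s$insert_sd %||% 60,
                            error_rate = s$error_rate %||% 0.002,
                            duplicate_rate = s$duplicate_rate %||% 0,
                            seed = config$seed + 100L + si)
      write_sim(sim, sp_a, sp_b, file.path(out, "sim", name))
      sims[[name]] <- sim
      reads_by_sample[[name]] <- sim$reads
    }
    log <- stage_log(log, "simulate", n_samples = length(samples),
                     genome_a_bp = nchar(genome_a$sequence),
                     genome_b_bp = nchar(genome_b$sequence))
  } else {
    rb <- config$reads
    genome_a <- load_genome(rb$genome_a, rb$gff_a, "genomeA")
    genome_b <- load_genome(rb$genome_b, rb$gff_b, "genomeB")
    reads_by_sample <- lapply(rb$samples, function(s)
      read_fastq_pair(s$fastq1, s$fastq2))
    log <- stage_log(log, "load", n_samples = length(reads_by_sample))
  }

  # ---- align + assign per sample ------------------------------------------
  idx_a <- build_index(genome_a, config$align)
  idx_b <- build_index(genome_b, config$align)
  assignments <- list(); calls_a <- list(); calls_b <- list()
  for (name in names(reads_by_sample)) {
    reads <- reads_by_sample[[name]]
    pa <- align_pairs(reads, idx_a, config$align)
    pb <- align_pairs(reads, idx_b, config$align)
    asg <- assign_readset(pa, pb, config$assign)
    assignments[[name]] <- asg
    dup_ids <- asg$table$pair_id[asg$table$rule == "duplicate"]
    write_sam(pa, file.path(out, sprintf("%s_vs_A.sam", name)))
    write_sam(pb, file.path(out, sprintf("%s_vs_B.sam", name)))
    write_assignment_tsv(asg, file.path(out, sprintf("%s_assignments.tsv", name)))
    jsonlite::write_json(asg$stats[c("n_pairs", "n_A", "n_B", "n_excluded",
                                     "ratio_A_to_B")],
                         file.path(out, sprintf("%s_assign_stats.json", name)),
                         auto_unbox = TRUE, digits = NA)
    log <- stage_log(log, "assign", sample = name,
                     n_pairs = asg$stats$n_pairs, n_A = asg$stats$n_A,
                     n_B = asg$stats$n_B, n_excluded = asg$stats$n_excluded)

    # ---- variants per genome ----------------------------------------------
    pu_a <- pileup(pa, genome_a, pair_ids = asg$a_pairs)
    ca <- do.call(call_variants, c(list(pu_a), config$call))
    calls_a[[name]] <- ca
    pu_b <- pileup(pb, genome_b, pair_ids = asg$b_pairs)
    cb <- do.call(call_variants, c(list(pu_b), config$call))
    calls_b[[name]] <- cb
    both <- rbind(ca, cb)
    write_vcf(both, file.path(out, sprintf("%s.vcf", name)),
              contig_lengths = setNames(
                c(nchar(genome_a$sequence), nchar(genome_b$sequence)),
                c(genome_a$genome_id, genome_b$genome_id)))
    log <- stage_log(log, "variants", sample = name,
                     n_calls_A = nrow(ca), n_calls_B = nrow(cb))
  }

  # ---- frequency matrix + annotation + report -----------------------------
  all_calls <- mapply(function(a, b) rbind(a, b), calls_a, calls_b,
                      SIMPLIFY = FALSE)
  mat <- build_matrix(all_calls, average_groups = config$average_groups)
  write_matrix_tsv(mat, file.path(out, "freq_matrix.tsv"))

  ann <- NULL
  union_calls <- unique(do.call(rbind, all_calls)[,
    c("genome_id", "position", "ref", "alt", "vtype")])
  if (nrow(union_calls)) {
    ann_parts <- list()
    for (g in list(genome_a, genome_b)) {
      sel <- union_calls[union_calls$genome_id == g$genome_id, , drop = FALSE]
      if (nrow(sel) && nrow(g$genes))
        ann_parts[[g$genome_id]] <- annotate_variants(sel, g)
    }
    if (length(ann_parts)) {
      ann <- do.call(rbind, ann_parts)
      rownames(ann) <- NULL
      write.table(ann, file.path(out, "consequences.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  log <- stage_log(log, "annotate",
                   n_variants = nrow(union_calls),
                   n_consequences = if (is.null(ann)) 0L else nrow(ann))

  join <- NULL
  if (!is.null(config$protein_table)) {
    pt <- config$protein_table
    if (is.character(pt)) pt <- read.table(pt, header = TRUE, sep = "\t")
    join <- frequency_expression_join(mat, pt)
    write.table(join, file.path(out, "frequency_expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("cobin")),
                   align = unclass(config$align),
                   assign = unclass(config$assign),
                   call = config$call,
                   samples = names(reads_by_sample),
                   log = log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(out_dir = out, genome_a = genome_a, genome_b = genome_b,
                 assignments = assignments, calls = all_calls,
                 matrix = mat, annotations = ann, join = join,
                 sims = sims, log = log),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d sample(s), %d variant row(s) -> %s\n",
              length(x$assignments), nrow(x$matrix), x$out_dir))
  invisible(x)
}

load_genome <- function(fasta, gff = NULL, fallback_id = "genome") {
  s <- Biostrings::readDNAStringSet(fasta)
  if (length(s) != 1) stopf("expected a single-sequence FASTA: %s", fasta)
  genes <- if (!is.null(gff)) read_genes_gff3(gff) else NULL
  annotated_genome(sub(" .*", "", names(s)[1]) %||% fallback_id,
                   as.character(s[[1]]), genes)
}

#' Join variant frequencies with protein abundance changes
#'
#' One row per (variant, downstream gene): the variant's pooled frequency
#' per stage from the frequency matrix alongside the gene product's log2
#' fold change per stage from a proteomics table. Genes missing from the
#' protein table at a stage are marked absent (`log2fc` `NA`,
#' `absent = TRUE`) — the proteomics statistics themselves are consumed as
#' given, not recomputed.
#'
#' @param mat A [build_matrix()] result whose columns include the stage
#'   names used in `protein_table` (e.g. `s0`, `s13`).
#' @param protein_table `data.frame` with `gene_id`, `stage`, `log2fc`.
#' @param genes Gene ids to report (default: all in `protein_table`).
#' @return `data.frame`: `variant`, `gene_id`, `freq_<stage>`,
#'   `log2fc_<stage>`, `absent_<stage>` for each shared stage.
#' @export
frequency_expression_join <- function(mat, protein_table,
                                      genes = NULL) {
  stopifnot(all(c("gene_id", "stage", "log2fc") %in% names(protein_table)))
  genes <- genes %||% unique(protein_table$gene_id)
  stages <- intersect(colnames(mat), unique(protein_table$stage))
  if (!length(stages) && length(genes))
    stages <- intersect(colnames(mat), protein_table$stage)
  if (!length(stages))
    stages <- colnames(mat) # empty protein table: frequencies only, all absent
  variants <- rownames(mat)
  out <- expand.grid(variant = variants, gene_id = genes,
                     stringsAsFactors = FALSE)
  if (nrow(out) == 0 && length(variants))
    out <- data.frame(variant = variants, gene_id = NA_character_)
  for (st in stages) {
    out[[paste0("freq_", st)]] <- unclass(mat)[out$variant, st]
    hit <- protein_table[protein_table$stage == st, , drop = FALSE]
    l2 <- hit$log2fc[match(out$gene_id, hit$gene_id)]
    out[[paste0("log2fc_", st)]] <- l2
    out[[paste0("absent_", st)]] <- is.na(l2)
  }
  out
}
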