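#' Compute a CIGAR-aware pileup over a genome
#'
#' Walks every mapped, non-duplicate read's CIGAR against the reference:
#' `M`/`=`/`X` runs contribute base counts, `I` runs are recorded as
#' insertions anchored at the preceding reference base, `D` runs as anchored
#' deletions (deleted columns still count toward depth via a deletion-span
#' count). Depth at a column is the number of reads whose alignment consumes
#' or spans it; insertion observations are kept alongside (they consume no
#' reference column).
#'
#' @param pa A [align_pairs()] result (or its `$mates` table) for reads
#'   assigned to this genome; duplicates should be removed first.
#' @param genome The [annotated_genome()] the reads were aligned to.
#' @param pair_ids Optional pair ids to restrict to (e.g. the assigned set).
#' @param exclude_pair_ids Optional pair ids to drop (e.g. duplicates).
#' @param indel_flank Indel-eligible depth requires a read to extend at least
#'   this many reference bases on both sides of a column; a local aligner
#'   soft-clips an indel this close to a read end, so reads that cannot
#'   express an indel are kept out of the indel-frequency denominator.
#' @return An object of class `cb_pileup`: `genome_id`, `ref` (reference
#'   string), `depth` (integer vector, length = genome length),
#'   `base_counts` (5 x L matrix, rows A,C,G,T,N), `del_span` (per-column
#'   deletion-span counts), `span_depth` (indel-eligible depth), `ins` and
#'   `del` tables of anchored indel observations with counts.
#' @export
pileup <- function(pa, genome, pair_ids = NULL, exclude_pair_ids = NULL,
                   indel_flank = 4L) {
  m <- if (inherits(pa, "pair_alignments")) pa$mates else pa
  stopifnot(inherits(genome, "annotated_genome"))
  gid <- genome$genome_id
  if (!is.null(pair_ids)) m <- m[m$pair_id %in% pair_ids, ]
  if (!is.null(exclude_pair_ids)) m <- m[!(m$pair_id %in% exclude_pair_ids), ]
  m <- m[m$mapped, ]
  L <- nchar(genome$sequence)

  base_counts <- matrix(0L, nrow = 5, ncol = L,
                        dimnames = list(c(BASES, "N"), NULL))
  del_span <- integer(L)
  ins_tab <- list(); del_tab <- list()

  if (nrow(m)) {
    qlen <- cigar_query_len(m$cigar)
    bad <- qlen != nchar(m$seq)
    if (any(bad))
      stopf("CIGAR inconsistent with read length for read %s",
            m$read_id[which(bad)[1]])
    pos_acc <- vector("list", 64); base_acc <- vector("list", 64); acc_i <- 0L
    for (cg in unique(m$cigar)) {
      rows <- which(m$cigar == cg)
      lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
      ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
      ref_total <- sum(lens[ops %in% c("M", "=", "X", "D", "N")])
      roff <- 0L  # reference offset from pos
      qoff <- 0L  # query offset
      for (k in seq_along(ops)) {
        op <- ops[k]; ln <- lens[k]
        if (op %in% c("M", "=", "X")) {
          starts <- m$pos[rows] + roff
          # (pos, base) observations for this run across all reads
          p <- rep(starts, each = ln) + rep.int(0L:(ln - 1L), length(rows))
          b <- unlist(strsplit(substr(m$seq[rows], qoff + 1L, qoff + ln),
                               ""), use.names = FALSE)
          acc_i <- acc_i + 1L
          pos_acc[[acc_i]] <- p; base_acc[[acc_i]] <- b
          roff <- roff + ln; qoff <- qoff + ln
        } else if (op == "I") {
          # record only when the read extends >= indel_flank reference bases
          # on both sides of the anchor, matching the spanning-depth
          # denominator used for indel frequencies
          anchor <- m$pos[rows] + roff - 1L
          seqs <- substr(m$seq[rows], qoff + 1L, qoff + ln)
          ok <- anchor >= 1L & (roff - 1L) >= indel_flank &
            (ref_total - roff) >= indel_flank
          if (any(ok))
            ins_tab[[length(ins_tab) + 1L]] <-
              data.frame(position = anchor[ok], inserted = seqs[ok])
          qoff <- qoff + ln
        } else if (op %in% c("D", "N")) {
          anchor <- m$pos[rows] + roff - 1L
          ok <- anchor >= 1L & (roff - 1L) >= indel_flank &
            (ref_total - roff - ln) >= indel_flank
          if (any(ok))
            del_tab[[length(del_tab) + 1L]] <-
              data.frame(position = anchor[ok], del_len = ln)
          for (d in 0L:(ln - 1L)) {
            idx <- m$pos[rows] + roff + d
            idx <- idx[idx >= 1L & idx <= L]
            tb <- tabulate(idx, nbins = L)
            del_span <- del_span + tb
          }
          roff <- roff + ln
        } else if (op == "S") {
          qoff <- qoff + ln
        } else if (op == "H") {
          # hard clip consumes nothing recorded here
        }
      }
      if (acc_i >= 60L) { # flush accumulators into counts
        base_counts <- base_counts +
          flush_base_counts(pos_acc[seq_len(acc_i)], base_acc[seq_len(acc_i)], L)
        acc_i <- 0L
      }
    }
    if (acc_i > 0L)
      base_counts <- base_counts +
        flush_base_counts(pos_acc[seq_len(acc_i)], base_acc[seq_len(acc_i)], L)
  }

  agg_indels <- function(tabs, cols) {
    if (!length(tabs)) {
      out <- data.frame(position = integer(), x = character(), count = integer())
      names(out)[2] <- cols
      return(out)
    }
    d <- do.call(rbind, tabs)
    key <- paste(d$position, d[[2]], sep = "\r")
    agg <- table(key)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    out <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                      x = vapply(parts, `[`, "", 2),
                      count = as.integer(agg))
    names(out)[2] <- cols
    out[order(out$position), , drop = FALSE]
  }

  depth <- as.integer(colSums(base_counts)) + del_span
  span_depth <- integer(L)
  if (nrow(m)) {
    s <- m$pos + indel_flank
    e <- m$pos + cigar_ref_len(m$cigar) - 1L - indel_flank
    ok <- s <= e
    if (any(ok))
      span_depth <- as.integer(IRanges::coverage(
        IRanges::IRanges(start = pmax(s[ok], 1L), end = pmin(e[ok], L)),
        width = L))
  }
  # left-align observations so the same event in ambiguous (homopolymer)
  # context aggregates under one anchor, then merge the shifted keys
  ins_out <- agg_indels(ins_tab, "inserted")
  if (nrow(ins_out)) {
    for (i in seq_len(nrow(ins_out))) {
      nv <- normalize_indel(genome$sequence, ins_out$position[i], "x",
                            paste0("x", ins_out$inserted[i]))
      ins_out$position[i] <- nv$position
      ins_out$inserted[i] <- substr(nv$alt, 2, nchar(nv$alt))
    }
    cnt <- tapply(ins_out$count,
                  paste(ins_out$position, ins_out$inserted, sep = "\r"), sum)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    ins_out <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                          inserted = vapply(parts, `[`, "", 2),
                          count = as.integer(cnt))
    ins_out <- ins_out[order(ins_out$position), , drop = FALSE]
  }
  del_out <- agg_indels(del_tab, "del_len")
  del_out$del_len <- as.integer(del_out$del_len)
  if (nrow(del_out)) {
    for (i in seq_len(nrow(del_out))) {
      p <- del_out$position[i]
      nv <- normalize_indel(genome$sequence, p,
                            substr(genome$sequence, p, p + del_out$del_len[i]),
                            substr(genome$sequence, p, p))
      del_out$position[i] <- nv$position
    }
    cnt <- tapply(del_out$count,
                  paste(del_out$position, del_out$del_len, sep = "\r"), sum)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    del_out <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                          del_len = as.integer(vapply(parts, `[`, "", 2)),
                          count = as.integer(cnt))
    del_out <- del_out[order(del_out$position), , drop = FALSE]
  }
  structure(list(genome_id = gid, ref = genome$sequence, depth = depth,
                 base_counts = base_counts, del_span = del_span,
                 span_depth = span_depth, ins = ins_out, del = del_out),
            class = "cb_pileup")
}

flush_base_counts <- function(pos_list, base_list, L) {
  p <- unlist(pos_list, use.names = FALSE)
  b <- unlist(base_list, use.names = FALSE)
  keep <- p >= 1L & p <= L
  p <- p[keep]; b <- b[keep]
  code <- match(b, c(BASES, "N"))
  code[is.na(code)] <- 5L
  matrix(tabulate((p - 1L) * 5L + code, nbins = 5L * L), nrow = 5L,
         dimnames = list(c(BASES, "N"), NULL))
}

#' @export
print.cb_pileup <- function(x, ...) {
  cat(sprintf("<cb_pileup> %s: %d bp, mean depth %.1f\n", x$genome_id,
              length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pu A [pileup()] result.
#' @param position 1-based reference position.
#' @return A list: `genome_id`, `position`, `ref_base`, `depth`, `counts`
#'   (named base + deletion-span counts summing to `depth`), `ins`
#'   (anchored insertion observations at this base).
#' @export
pileup_column <- function(pu, position) {
  stopifnot(inherits(pu, "cb_pileup"),
            position >= 1, position <= length(pu$depth))
  counts <- c(pu$base_counts[, position], del = pu$del_span[position])
  list(genome_id = pu$genome_id, position = as.integer(position),
       ref_base = substr(pu$ref, position, position),
       depth = pu$depth[position], counts = counts,
       ins = pu$ins[pu$ins$position == position, , drop = FALSE])
}

#' Call variants from a pileup with pooled allele frequencies
#'
#' Emits every allele whose supporting-read fraction `alt_count / depth`
#' reaches `min_freq` with `depth >= min_depth` and
#' `alt_count >= min_alt_count`. This is a pooled population-frequency
#' caller: the experiment sequences a population of cells, and the quantity
#' of interest is the proportion of reads supporting the mutation, not a
#' genotype. Indels longer than `max_indel_len` (20 by default) are not
#' called. Variants are reported left-anchored (VCF convention).
#'
#' @param pu A [pileup()] result.
#' @param min_depth Minimum column depth.
#' @param min_freq Minimum allele frequency in (0, 1\]; the targeted-screen
#'   default is 0.02 (2%).
#' @param min_alt_count Minimum supporting reads.
#' @param max_indel_len Longest indel called (bp).
#' @param regions Optional `data.frame` with `start`, `end` restricting the
#'   screen to target intervals (targeted-sequencing mode).
#' @return `data.frame` of class `variant_calls`: `genome_id`, `position`,
#'   `ref`, `alt`, `vtype`, `depth`, `alt_count`, `frequency` (rounded to 3
#'   decimals).
#' @export
call_variants <- function(pu, min_depth = 10L, min_freq = 0.02,
                          min_alt_count = 2L, max_indel_len = 20L,
                          regions = NULL) {
  stopifnot(inherits(pu, "cb_pileup"), min_freq > 0, min_freq <= 1,
            min_depth >= 1)
  L <- length(pu$depth)
  in_region <- rep(TRUE, L)
  if (!is.null(regions)) {
    in_region <- rep(FALSE, L)
    for (i in seq_len(nrow(regions)))
      in_region[regions$start[i]:regions$end[i]] <- TRUE
  }
  ref_chars <- strsplit(pu$ref, "")[[1]]
  depth <- pu$depth
  out <- list()

  # SNVs: non-reference base columns
  for (b in BASES) {
    cnt <- pu$base_counts[b, ]
    sel <- which(cnt >= min_alt_count & depth >= min_depth &
                   cnt / depth >= min_freq & ref_chars != b & in_region)
    if (length(sel))
      out[[length(out) + 1L]] <- data.frame(
        position = sel, ref = ref_chars[sel], alt = b, vtype = "SNV",
        depth = depth[sel], alt_count = cnt[sel])
  }
  # insertions (anchored at the base before); the indel denominator is the
  # spanning depth so reads unable to express an indel do not dilute it
  ins <- pu$ins
  if (nrow(ins)) {
    d <- pu$span_depth[ins$position]
    keep <- nchar(ins$inserted) <= max_indel_len & ins$count >= min_alt_count &
      d >= min_depth & ins$count / d >= min_freq & in_region[ins$position]
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        position = ins$position[keep],
        ref = ref_chars[ins$position[keep]],
        alt = paste0(ref_chars[ins$position[keep]], ins$inserted[keep]),
        vtype = "INS", depth = d[keep], alt_count = ins$count[keep])
  }
  # deletions (anchored at the base before)
  del <- pu$del
  if (nrow(del)) {
    d <- pu$span_depth[del$position]
    keep <- del$del_len <= max_indel_len & del$count >= min_alt_count &
      d >= min_depth & del$count / d >= min_freq & in_region[del$position]
    if (any(keep)) {
      p <- del$position[keep]
      out[[length(out) + 1L]] <- data.frame(
        position = p,
        ref = paste0(ref_chars[p],
                     substring(pu$ref, p + 1L, p + del$del_len[keep])),
        alt = ref_chars[p], vtype = "DEL", depth = d[keep],
        alt_count = del$count[keep])
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), ref = character(), alt = character(),
               vtype = character(), depth = integer(), alt_count = integer())
  calls <- calls[order(calls$position, calls$alt), , drop = FALSE]
  calls <- data.frame(genome_id = rep(pu$genome_id, nrow(calls)), calls)
  calls$frequency <- round(calls$alt_count / pmax(calls$depth, 1L), 3)
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' Left-align an anchored indel
#'
#' Shifts an anchored insertion or deletion to its leftmost equivalent
#' position (the VCF normalization convention), so that observations of the
#' same event in ambiguous (e.g. homopolymer) context share one key.
#' SNVs are returned unchanged.
#'
#' @param ref_seq Reference nucleotide string (or [annotated_genome()]).
#' @param position 1-based anchor position.
#' @param ref,alt Anchored alleles.
#' @return A list with normalized `position`, `ref`, `alt`.
#' @export
normalize_indel <- function(ref_seq, position, ref, alt) {
  if (inherits(ref_seq, "annotated_genome")) ref_seq <- ref_seq$sequence
  if (nchar(ref) == nchar(alt))
    return(list(position = position, ref = ref, alt = alt))
  if (nchar(alt) > nchar(ref)) { # insertion: ref = anchor, alt = anchor + S
    s <- substr(alt, 2, nchar(alt))
    L <- nchar(s)
    while (position > 1 &&
           substr(ref_seq, position, position) == substr(s, L, L)) {
      s <- paste0(substr(ref_seq, position, position), substr(s, 1, L - 1))
      position <- position - 1L
    }
    anchor <- substr(ref_seq, position, position)
    list(position = position, ref = anchor, alt = paste0(anchor, s))
  } else { # deletion of len bases after the anchor
    len <- nchar(ref) - 1L
    while (position > 1 &&
           substr(ref_seq, position, position) ==
             substr(ref_seq, position + len, position + len)) {
      position <- position - 1L
    }
    list(position = position,
         ref = substr(ref_seq, position, position + len),
         alt = substr(ref_seq, position, position))
  }
}

variant_key <- function(calls) {
  paste0(calls$genome_id, ":", calls$position, ":", calls$ref, ">", calls$alt)
}

#' Assemble a sample-by-variant frequency matrix
#'
#' Rows are variants keyed by `genome:position:ref>alt`, columns are samples;
#' cells hold the pooled allele frequency, `NA` where the variant was not
#' called in that sample. Optionally appends cross-replicate average columns
#' (means over the replicates of each stage, the quantity reported in
#' trajectory heat maps), computed with half-up rounding at 2 decimals in
#' [format_freq_percent()]-style reports.
#'
#' @param calls_by_sample Named list of [call_variants()] results, in sample
#'   order.
#' @param average_groups Optional named list mapping a new average column
#'   name to the sample names it averages, e.g.
#'   `list(s0 = c("s0_r1","s0_r2","s0_r3"))`.
#' @return A numeric matrix of class `cb_freqmat`.
#' @export
build_matrix <- function(calls_by_sample, average_groups = NULL) {
  stopifnot(is.list(calls_by_sample), length(calls_by_sample) >= 1,
            !is.null(names(calls_by_sample)))
  keys <- unique(unlist(lapply(calls_by_sample, variant_key)))
  mat <- matrix(NA_real_, nrow = length(keys), ncol = length(calls_by_sample),
                dimnames = list(keys, names(calls_by_sample)))
  for (s in names(calls_by_sample)) {
    cs <- calls_by_sample[[s]]
    if (nrow(cs)) mat[variant_key(cs), s] <- cs$frequency
  }
  if (!is.null(average_groups)) {
    for (g in names(average_groups)) {
      cols <- average_groups[[g]]
      stopifnot(all(cols %in% colnames(mat)))
      avg <- rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
      avg[is.nan(avg)] <- NA_real_
      mat <- cbind(mat, setNames(data.frame(avg), g)[[1]])
      colnames(mat)[ncol(mat)] <- g
    }
  }
  class(mat) <- c("cb_freqmat", class(mat))
  mat
}

#' Format a frequency matrix as percentages for reports
#'
#' Fractions become percentages rounded half-up to 2 decimals.
#' @param mat A [build_matrix()] result.
#' @return Character matrix.
#' @export
format_freq_percent <- function(mat) {
  out <- matrix(sprintf("%.2f", round_half_up(unclass(mat) * 100, 2)),
                nrow = nrow(mat), dimnames = dimnames(mat))
  out[is.na(mat)] <- ""
  out
}

#' Write a frequency matrix as TSV
#' @param mat A [build_matrix()] result.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(variant = rownames(mat), unclass(mat),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variant calls as VCF 4.2
#'
#' INFO fields: `DP` (depth), `AC` (supporting reads), `AF` (pooled allele
#' frequency).
#'
#' @param calls A [call_variants()] result.
#' @param path Output file.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cobin",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt-supporting read count\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Pooled allele frequency\">")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  body <- if (nrow(calls)) {
    paste(calls$genome_id, calls$position, ".", calls$ref, calls$alt, ".",
          "PASS",
          sprintf("DP=%d;AC=%d;AF=%s", calls$depth, calls$alt_count,
                  format(calls$frequency, trim = TRUE)),
          sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a cobin VCF back into a calls table
#' @param path VCF file written by [write_vcf()].
#' @return A `variant_calls` `data.frame`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    out <- data.frame(genome_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), depth = integer(),
                      alt_count = integer(), frequency = numeric())
    class(out) <- c("variant_calls", "data.frame")
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[`, "", 8)
  grab <- function(key) as.numeric(sub(sprintf(".*%s=([^;]+).*", key), "\\1",
                                       info))
  ref <- vapply(f, `[`, "", 4); alt <- vapply(f, `[`, "", 5)
  vtype <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                  ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  out <- data.frame(genome_id = vapply(f, `[`, "", 1),
                    position = as.integer(vapply(f, `[`, "", 2)),
                    ref = ref, alt = alt, vtype = vtype,
                    depth = as.integer(grab("DP")),
                    alt_count = as.integer(grab("AC")),
                    frequency = grab("AF"))
  class(out) <- c("variant_calls", "data.frame")
  out
}
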