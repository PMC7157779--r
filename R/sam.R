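# Minimal SAM 1.6 text interchange for the aligner's records. Flags honored:
# 0x1 paired, 0x2 proper pair, 0x4 unmapped, 0x8 mate unmapped, 0x10/0x20
# read/mate reverse, 0x40/0x80 first/last in pair, 0x400 duplicate. The AS
# tag carries the alignment score.

FLAG_PAIRED <- 0x1L; FLAG_PROPER <- 0x2L; FLAG_UNMAPPED <- 0x4L
FLAG_MUNMAPPED <- 0x8L; FLAG_REVERSE <- 0x10L; FLAG_MREVERSE <- 0x20L
FLAG_FIRST <- 0x40L; FLAG_LAST <- 0x80L; FLAG_DUP <- 0x400L

#' Write pair alignments as SAM
#'
#' @param pa A [align_pairs()] result.
#' @param path Output file.
#' @param duplicates Optional [mark_duplicates()] result; flagged pairs get
#'   the 0x400 flag.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pa, path, duplicates = NULL) {
  stopifnot(inherits(pa, "pair_alignments"))
  m <- pa$mates
  a1 <- m[m$mate == 1L, ]; a2 <- m[m$mate == 2L, ]
  ord <- match(pa$pairs$pair_id, a1$pair_id)
  a1 <- a1[ord, ]; a2 <- a2[match(pa$pairs$pair_id, a2$pair_id), ]
  proper <- pa$pairs$proper
  dup <- if (is.null(duplicates)) rep(FALSE, nrow(pa$pairs)) else
    duplicates$duplicate[match(pa$pairs$pair_id, duplicates$pair_id)]
  glen <- attr(pa, "genome_length") %||% max(c(1L, a1$pos, a2$pos), na.rm = TRUE)

  mk_flag <- function(self, other, first) {
    f <- FLAG_PAIRED + ifelse(first, FLAG_FIRST, FLAG_LAST)
    f <- f + ifelse(proper, FLAG_PROPER, 0L)
    f <- f + ifelse(!self$mapped, FLAG_UNMAPPED, 0L)
    f <- f + ifelse(!other$mapped, FLAG_MUNMAPPED, 0L)
    f <- f + ifelse(self$mapped & self$strand == "-", FLAG_REVERSE, 0L)
    f <- f + ifelse(other$mapped & other$strand == "-", FLAG_MREVERSE, 0L)
    f + ifelse(dup, FLAG_DUP, 0L)
  }
  mk_line <- function(self, other, first) {
    pos <- ifelse(self$mapped, self$pos, 0L)
    mpos <- ifelse(other$mapped, other$pos, 0L)
    end_self <- ifelse(self$mapped, self$pos + cigar_ref_len(
      ifelse(self$mapped, self$cigar, "1M")) - 1L, 0L)
    end_other <- ifelse(other$mapped, other$pos + cigar_ref_len(
      ifelse(other$mapped, other$cigar, "1M")) - 1L, 0L)
    tlen <- ifelse(self$mapped & other$mapped,
                   pmax(end_self, end_other) -
                     pmin(self$pos, other$pos) + 1L, 0L)
    tlen <- ifelse(self$mapped & other$mapped & self$pos > other$pos,
                   -tlen, tlen)
    tags <- ifelse(self$mapped, sprintf("AS:i:%d", self$score), "")
    ln <- paste(sub("/[12]$", "", self$read_id), mk_flag(self, other, first),
                ifelse(self$mapped, pa$genome_id, "*"), pos,
                ifelse(self$mapped, self$mapq, 0L),
                ifelse(self$mapped, self$cigar, "*"),
                ifelse(other$mapped, "=", "*"), mpos, tlen,
                self$seq, "*", sep = "\t")
    ifelse(nzchar(tags), paste(ln, tags, sep = "\t"), ln)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", pa$genome_id, glen),
           "@PG\tID:cobin\tPN:cobin")
  lines <- character(2L * nrow(pa$pairs))
  lines[seq(1, length(lines), by = 2)] <- mk_line(a1, a2, TRUE)
  lines[seq(2, length(lines), by = 2)] <- mk_line(a2, a1, FALSE)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into pair alignments
#'
#' Reads paired records written by [write_sam()] (or produced externally; the
#' alignment score is taken from the `AS` tag) and rebuilds the
#' `pair_alignments` structure used downstream, so that precomputed
#' alignments can replace the internal aligner.
#'
#' @param path SAM file.
#' @param config An [aligner_config()] (insert limits used to recompute the
#'   proper-pair summary when the 0x2 flag is absent).
#' @return A `pair_alignments` object.
#' @export
read_sam <- function(path, config = aligner_config()) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  sq <- lines[startsWith(lines, "@SQ")]
  gid <- sub(".*SN:([^\t]+).*", "\\1", sq[1])
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 1L)
  mapped <- bitwAnd(flag, FLAG_UNMAPPED) == 0L
  first <- bitwAnd(flag, FLAG_FIRST) != 0L
  as_tag <- vapply(f, function(x) {
    hit <- grep("^AS:i:", x[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub("AS:i:", "", hit[1])) else NA_integer_
  }, 1L)
  rec <- data.frame(
    read_id = paste0(vapply(f, `[`, "", 1), ifelse(first, "/1", "/2")),
    genome_id = gid,
    mapped = mapped,
    pos = ifelse(mapped, vapply(f, function(x) as.integer(x[4]), 1L), NA),
    strand = ifelse(mapped,
                    ifelse(bitwAnd(flag, FLAG_REVERSE) != 0L, "-", "+"), NA),
    cigar = ifelse(mapped, vapply(f, `[`, "", 6), NA),
    score = as_tag,
    mapq = ifelse(mapped, vapply(f, function(x) as.integer(x[5]), 1L), NA),
    seq = vapply(f, `[`, "", 10),
    pair_id = vapply(f, `[`, "", 1),
    mate = ifelse(first, 1L, 2L),
    duplicate = bitwAnd(flag, FLAG_DUP) != 0L)
  a1 <- rec[rec$mate == 1L, ]
  a2 <- rec[rec$mate == 2L, ]
  a2 <- a2[match(a1$pair_id, a2$pair_id), ]
  pairs <- summarize_pairs(a1, a2, config)
  structure(list(mates = rbind(a1, a2), pairs = pairs, genome_id = gid,
                 config = config),
            class = "pair_alignments")
}
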