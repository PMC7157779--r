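BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# reference length consumed by a CIGAR string (M/=/X/D/N consume reference)
cigar_ref_len <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  vapply(seq_along(cigar), function(i) {
    l <- as.integer(lens[[i]])
    o <- ops[[i]]
    sum(l[o %in% c("M", "=", "X", "D", "N")])
  }, integer(1))
}

# query length consumed by a CIGAR string (M/=/X/I/S consume query)
cigar_query_len <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  vapply(seq_along(cigar), function(i) {
    l <- as.integer(lens[[i]])
    o <- ops[[i]]
    sum(l[o %in% c("M", "=", "X", "I", "S")])
  }, integer(1))
}

# round half up to `digits` decimals (report convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
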