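#' Assignment-rule configuration
#'
#' Parameters of the competitive read-pair categorization: a pair is assigned
#' to genome A either when it maps to A and not to B, or when it maps to both
#' and the pair score sum in B is *strictly* less than `ratio_threshold`
#' (80% by default) of the score sum in A; pairs whose winning-genome mapping
#' quality falls below `mapq_min` (30 by default) are excluded.
#'
#' @param ratio_threshold Score-sum ratio threshold in (0, 1).
#' @param mapq_min Minimum mapping quality in the winning genome.
#' @param mapq_combine How the two mates' mapqs combine for the filter:
#'   `"min"` (conservative default) or `"mean"`.
#' @param rule_ii_mapped What "mapped to a genome" means for the score-ratio
#'   rule: `"any"` (default; one mapped mate suffices, the unmapped mate
#'   contributing 0 to the sum) or `"both"`.
#' @return A list of class `assignment_config`.
#' @export
assignment_config <- function(ratio_threshold = 0.80, mapq_min = 30L,
                              mapq_combine = c("min", "mean"),
                              rule_ii_mapped = c("any", "both")) {
  stopifnot(ratio_threshold > 0, ratio_threshold < 1,
            mapq_min >= 0, mapq_min <= 60)
  structure(list(ratio_threshold = ratio_threshold,
                 mapq_min = as.integer(mapq_min),
                 mapq_combine = match.arg(mapq_combine),
                 rule_ii_mapped = match.arg(rule_ii_mapped)),
            class = "assignment_config")
}

# vectorized categorization over aligned pair summary tables
categorize_table <- function(pa, pb, config) {
  stopifnot(identical(pa$pair_id, pb$pair_id))
  mapped_rule_i <- function(p) p$n_mapped > 0L # "unmapped" = both mates unmapped
  mapped_rule_ii <- if (config$rule_ii_mapped == "any")
    function(p) p$n_mapped > 0L else function(p) p$n_mapped == 2L
  ma <- mapped_rule_i(pa); mb <- mapped_rule_i(pb)
  ma2 <- mapped_rule_ii(pa); mb2 <- mapped_rule_ii(pb)
  sa <- ifelse(ma, pa$sum_score, 0L)
  sb <- ifelse(mb, pb$sum_score, 0L)
  thr <- config$ratio_threshold

  call <- rep("excluded", length(ma))
  rule <- rep("ambiguous", length(ma))
  rule[!ma & !mb] <- "both_unmapped"

  uniq_a <- ma & !mb
  uniq_b <- mb & !ma
  ratio_a <- ma2 & mb2 & (sb < thr * sa)
  ratio_b <- ma2 & mb2 & (sa < thr * sb)
  call[uniq_a] <- "A"; rule[uniq_a] <- "uniquely_mapped"
  call[uniq_b] <- "B"; rule[uniq_b] <- "uniquely_mapped"
  call[ratio_a] <- "A"; rule[ratio_a] <- "score_ratio"
  call[ratio_b] <- "B"; rule[ratio_b] <- "score_ratio"

  qual <- function(p) {
    if (config$mapq_combine == "min") p$min_mapq else p$mean_mapq %||% p$min_mapq
  }
  win_mapq <- ifelse(call == "A", qual(pa), ifelse(call == "B", qual(pb), NA))
  low <- call != "excluded" & (is.na(win_mapq) | win_mapq < config$mapq_min)
  call[low] <- "excluded"; rule[low] <- "low_mapq"

  data.frame(pair_id = pa$pair_id, call = call, rule = rule,
             sum_score_A = ifelse(ma, pa$sum_score, NA_integer_),
             sum_score_B = ifelse(mb, pb$sum_score, NA_integer_))
}

#' Categorize one read pair between two genomes
#'
#' Applies the competitive assignment rule to the alignments of a single
#' pair against genome A and genome B: assigned to A when (i) mapped to A
#' (at least one mate) and unmapped to B (both mates), or (ii) mapped to
#' both with the B score sum strictly less than `ratio_threshold` times the
#' A score sum; symmetrically for B; otherwise excluded as ambiguous. A pair
#' whose winning-genome mapq (minimum over mapped mates) is below `mapq_min`
#' is excluded as `low_mapq`; a pair unmapped in both genomes as
#' `both_unmapped`. Ties in the score sums are excluded (the rule uses a
#' strict inequality).
#'
#' @param pa,pb One-pair `pair_alignments` (or one-row pair summaries) for
#'   genomes A and B respectively.
#' @param config An [assignment_config()].
#' @return One-row `data.frame`: `pair_id`, `call` (`"A"`, `"B"`,
#'   `"excluded"`), `rule` (`uniquely_mapped`, `score_ratio`, `ambiguous`,
#'   `low_mapq`, `both_unmapped`), `sum_score_A`, `sum_score_B`.
#' @export
categorize_pair <- function(pa, pb, config = assignment_config()) {
  ta <- if (inherits(pa, "pair_alignments")) pa$pairs else pa
  tb <- if (inherits(pb, "pair_alignments")) pb$pairs else pb
  if (!identical(ta$pair_id, tb$pair_id))
    stopf("pair_id mismatch between the two genomes' alignments")
  categorize_table(ta, tb, config)
}

#' Competitively assign a read set between two genomes
#'
#' Categorizes every pair, then (matching the published order of operations)
#' marks duplicates *within* each assigned genome and demotes flagged pairs
#' to `excluded`/`duplicate`. The returned partition is exhaustive and
#' disjoint.
#'
#' @param pa,pb [align_pairs()] results against genomes A and B for the same
#'   read set.
#' @param config An [assignment_config()].
#' @param dedup Mark and exclude within-genome duplicate pairs (default
#'   `TRUE`).
#' @return A list of class `assignment`: `table` (per-pair call and rule),
#'   `a_pairs`, `b_pairs` (assigned pair ids), `stats` (counts per call and
#'   rule, and the assigned A:B pair ratio).
#' @export
assign_readset <- function(pa, pb, config = assignment_config(),
                           dedup = TRUE) {
  stopifnot(inherits(pa, "pair_alignments"), inherits(pb, "pair_alignments"))
  if (!setequal(pa$pairs$pair_id, pb$pairs$pair_id))
    stopf("the two genomes' alignments cover different pair sets")
  ord <- match(pa$pairs$pair_id, pb$pairs$pair_id)
  tb <- pb$pairs[ord, ]
  tab <- categorize_table(pa$pairs, tb, config)

  if (dedup) {
    for (side in c("A", "B")) {
      src <- if (side == "A") pa else pb
      ids <- tab$pair_id[tab$call == side]
      if (!length(ids)) next
      sub <- subset_pair_alignments(src, ids)
      d <- mark_duplicates(sub)
      dup_ids <- d$pair_id[d$duplicate]
      sel <- tab$pair_id %in% dup_ids
      tab$call[sel] <- "excluded"
      tab$rule[sel] <- "duplicate"
    }
  }

  counts <- table(factor(tab$rule, levels = c("uniquely_mapped", "score_ratio",
                                              "ambiguous", "low_mapq",
                                              "both_unmapped", "duplicate")),
                  factor(tab$call, levels = c("A", "B", "excluded")))
  n_a <- sum(tab$call == "A"); n_b <- sum(tab$call == "B")
  stats <- list(n_pairs = nrow(tab), n_A = n_a, n_B = n_b,
                n_excluded = sum(tab$call == "excluded"),
                by_rule = as.data.frame(counts,
                                        responseName = "n",
                                        stringsAsFactors = FALSE),
                ratio_A_to_B = if (n_b > 0) n_a / n_b else Inf)
  structure(list(table = tab, a_pairs = tab$pair_id[tab$call == "A"],
                 b_pairs = tab$pair_id[tab$call == "B"], stats = stats),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<assignment> %d pairs: A=%d, B=%d, excluded=%d (A:B ~ %.1f:1)\n",
              s$n_pairs, s$n_A, s$n_B, s$n_excluded,
              ifelse(is.finite(s$ratio_A_to_B), s$ratio_A_to_B, NA)))
  invisible(x)
}

# restrict a pair_alignments object to a set of pair ids
subset_pair_alignments <- function(pa, ids) {
  structure(list(mates = pa$mates[pa$mates$pair_id %in% ids, ],
                 pairs = pa$pairs[pa$pairs$pair_id %in% ids, ],
                 genome_id = pa$genome_id, config = pa$config),
            class = "pair_alignments")
}

#' Write the assignment table as TSV
#' @param assignment An [assign_readset()] result.
#' @param path Output file.
#' @export
write_assignment_tsv <- function(assignment, path) {
  write.table(assignment$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
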