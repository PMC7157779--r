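#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 starting
#' copies, the standard absolute-quantification calibration from a dilution
#' series of a cloned template. Amplification efficiency is
#' `10^(-1/slope) - 1` (a fraction; 1.0 means perfect doubling each cycle,
#' i.e. slope -3.321928).
#'
#' @param log10_copies Numeric vector of log10 template copies.
#' @param cq Numeric vector of Cq values.
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n`.
#' @examples
#' curve <- fit_standard_curve(2:9, 40 - 3.321928 * (2:9))
#' curve$efficiency  # 1.0
#' @export
fit_standard_curve <- function(log10_copies, cq) {
  stopifnot(length(log10_copies) == length(cq))
  if (length(unique(log10_copies)) < 3)
    stopf("need at least 3 distinct dilution levels (got %d)",
          length(unique(log10_copies)))
  fit <- lm(cq ~ log10_copies)
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n = length(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cq = %.4f + %.4f * log10(copies); R2 = %.4f; efficiency = %.1f%%\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification from a Cq value
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept) / slope)`.
#' Optionally converts gene copies to a cell estimate by dividing by the
#' species' per-genome 16S rRNA gene copy number (2 for
#' *G. sulfurreducens*, 4 for *P. aeruginosa*).
#'
#' @param cq Numeric vector of Cq values.
#' @param curve A [fit_standard_curve()] result.
#' @param species_id Optional label(s).
#' @param rrna_copies_per_genome Optional 16S copies per genome for
#'   `cell_estimate`.
#' @return `data.frame` of class `abundance_estimate`: `species_id`,
#'   `copies`, `log_copies`, and `cell_estimate` when requested.
#' @export
quantify <- function(cq, curve, species_id = NA_character_,
                     rrna_copies_per_genome = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stopf("invalid standard curve: slope must be negative")
  copies <- 10^((cq - curve$intercept) / curve$slope)
  out <- data.frame(species_id = species_id, cq = cq, copies = copies,
                    log_copies = log10(copies))
  if (!is.null(rrna_copies_per_genome))
    out$cell_estimate <- copies / rrna_copies_per_genome
  class(out) <- c("abundance_estimate", "data.frame")
  out
}

#' Species copy-number ratio label
#'
#' The rounded "N:1" dominance label for a pair of copy numbers (dominant
#' species over minority species), computed on raw 16S gene copies without
#' per-genome 16S correction; `N` is rounded to the nearest integer and
#' printed with a thousands separator from 1,000 up.
#'
#' @param g_copies Dominant-species copy number (numerator).
#' @param p_copies Minority-species copy number (denominator).
#' @return Character label such as `"3:1"` or `"3,980:1"`.
#' @examples
#' ratio_label(2.2e5, 6.6e4)  # "3:1"
#' ratio_label(1.6e7, 2.8e5)  # "57:1"
#' @export
ratio_label <- function(g_copies, p_copies) {
  stopifnot(g_copies > 0, p_copies > 0)
  n <- round(g_copies / p_copies)
  paste0(formatC(n, format = "d", big.mark = ","), ":1")
}

#' Determine a MIC from a two-fold dilution series
#'
#' The minimum inhibitory concentration is the lowest concentration with no
#' growth such that all higher concentrations also show no growth. Growth at
#' every level yields `"> max"`; no growth anywhere yields the lowest tested
#' concentration. A lower concentration inhibited while a higher one grew
#' (a skipped-well pattern) is flagged as an anomaly but does not change the
#' rule.
#'
#' @param concentrations Strictly decreasing two-fold series (mg/liter).
#' @param growth Logical vector: visible growth at each concentration.
#' @param positive_control Logical; the no-drug control must show growth for
#'   the assay to be valid.
#' @param tol Relative tolerance on the two-fold spacing check.
#' @return A list of class `mic_result`: `mic` (numeric; `Inf` when growth
#'   at all levels), `label` (e.g. `"250"` or `"> 500"`), `anomalies`
#'   (indices of skipped wells).
#' @examples
#' mic(c(500, 250, 125, 62.5), c(FALSE, FALSE, TRUE, TRUE))$mic  # 250
#' @export
mic <- function(concentrations, growth, positive_control = TRUE, tol = 0.25) {
  stopifnot(length(concentrations) == length(growth), length(growth) >= 1,
            is.logical(growth))
  if (!positive_control)
    stopf("invalid assay: positive control shows no growth")
  if (is.unsorted(rev(concentrations), strictly = TRUE))
    stopf("concentrations must be strictly decreasing")
  if (length(concentrations) > 1) {
    ratio <- concentrations[-length(concentrations)] / concentrations[-1]
    if (any(abs(ratio - 2) > 2 * tol))
      stopf("not a two-fold dilution series")
  }
  inhibited <- !growth
  # lowest concentration inhibited with all higher concentrations inhibited
  run_ok <- cumprod(inhibited) == 1 # TRUE while every level from the top is inhibited
  anomalies <- which(inhibited & !run_ok)
  if (!any(run_ok)) {
    res <- list(mic = Inf,
                label = paste0("> ", format(concentrations[1])),
                anomalies = anomalies)
  } else {
    m <- concentrations[max(which(run_ok))]
    res <- list(mic = m, label = format(m), anomalies = anomalies)
  }
  class(res) <- "mic_result"
  res
}

#' @export
print.mic_result <- function(x, ...) {
  cat(sprintf("<mic_result> MIC = %s mg/liter%s\n", x$label,
              if (length(x$anomalies))
                sprintf(" (skipped-well anomaly at level %s)",
                        paste(x$anomalies, collapse = ",")) else ""))
  invisible(x)
}

#' Read a qPCR dilution-series/Cq table
#'
#' Expects TSV columns `log10_copies` and `cq` (additional columns such as
#' `species_id` are kept).
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_cq_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("log10_copies", "cq") %in% names(d)))
  d
}
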