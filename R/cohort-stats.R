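# Cohort-level prevalence tables, Fisher exact rate comparisons,
# treatment-duration summaries, and the oncoprint-style wide table of
# reversion-positive patients.

#' Lineages considered canonically BRCA-associated
#' @export
BRCA_ASSOCIATED_LINEAGES <- c("breast", "ovarian", "prostate", "pancreas")

#' Half-up rounding of percentages
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Prevalence of a binary trait, per group
#'
#' Percentages are computed as 100 * count / denominator and rounded
#' half-up to one decimal, reproducing the conventional printed form.
#' Groups with zero denominator are omitted with a warning.
#'
#' @param cohort data.frame of patient records
#' @param indicator name of a logical column (the trait), or a logical
#'   vector
#' @param group name of a grouping column, or NULL for the whole cohort
#' @return data.frame with group, count, denominator, percent
#' @export
prevalence_table <- function(cohort, indicator, group = NULL) {
  stopifnot(nrow(cohort) > 0)
  ind <- if (is.character(indicator) && length(indicator) == 1)
    cohort[[indicator]] else indicator
  stopifnot(is.logical(ind), length(ind) == nrow(cohort))
  grp <- if (is.null(group)) rep("all", nrow(cohort))
         else if (is.character(group) && length(group) == 1) cohort[[group]]
         else group
  out <- lapply(unique(grp), function(g) {
    denom <- sum(grp == g)
    if (denom == 0) {
      warning("group ", g, " has zero denominator; omitted")
      return(NULL)
    }
    cnt <- sum(ind[grp == g])
    data.frame(group = g, count = cnt, denominator = denom,
               percent = round_half_up(100 * cnt / denom),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Prevalence percent from printed counts
#'
#' @param count,denominator counts
#' @return percent, half-up rounded to one decimal
#' @export
prevalence_percent <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  round_half_up(100 * count / denominator)
}

#' Two-sided Fisher exact comparison of two rates
#'
#' Exact two-sided p-value for the 2x2 table `[a b; c d]` by the
#' probability-mass criterion (sum of hypergeometric probabilities of
#' tables at most as probable as the observed one), with the conditional
#' maximum-likelihood odds ratio.
#'
#' @param a,b,c,d non-negative cell counts; all margins must be positive
#' @return list(odds_ratio, p_two_sided)
#' @export
compare_rates_fisher <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, c, b, d), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate margin in 2x2 table")
  ft <- stats::fisher.test(m, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value)
}

#' Median, minimum and maximum of a duration vector
#'
#' The median is the middle order statistic (mean of the middle two for
#' even n).
#'
#' @param values numeric, non-empty (months)
#' @return list(median, min, max)
#' @export
summarize_durations <- function(values) {
  if (length(values) == 0) stop("empty duration vector")
  list(median = stats::median(values), min = min(values), max = max(values))
}

#' Oncoprint-style table of reversion-positive patients
#'
#' One row per patient with at least one reversion call: lineage, germline
#' gene, reversion mechanism(s), loss-of-wild-type flag, and co-mutated
#' genes.
#'
#' @param cohort data.frame with patient_id, lineage and optionally
#'   `loss_of_wt` (logical)
#' @param calls a [call_reversions()]-style data.frame
#' @param comutations optional data.frame with patient_id, gene of other
#'   somatic drivers
#' @return wide data.frame, one row per reversion-positive patient
#' @export
oncoprint_table <- function(cohort, calls, comutations = NULL) {
  if (nrow(calls) == 0)
    return(data.frame(patient_id = character(0), lineage = character(0),
                      germline_gene = character(0), mechanisms = character(0),
                      n_reversions = integer(0), loss_of_wt = logical(0),
                      comutated_genes = character(0),
                      stringsAsFactors = FALSE))
  pts <- unique(calls$patient_id)
  rows <- lapply(pts, function(p) {
    pc <- calls[calls$patient_id == p, , drop = FALSE]
    cr <- cohort[cohort$patient_id == p, , drop = FALSE]
    com <- if (!is.null(comutations))
      paste(sort(unique(comutations$gene[comutations$patient_id == p])),
            collapse = ";") else ""
    data.frame(
      patient_id = p,
      lineage = if (nrow(cr)) cr$lineage[1] else NA_character_,
      germline_gene = paste(sort(unique(pc$gene)), collapse = ";"),
      mechanisms = paste(pc$mechanism, collapse = ";"),
      n_reversions = nrow(pc),
      loss_of_wt = if (nrow(cr) && "loss_of_wt" %in% names(cr))
        cr$loss_of_wt[1] else NA,
      comutated_genes = com, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
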