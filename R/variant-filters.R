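# Cohort- and variant-level filters applied before reversion analysis:
# tumor-mutational-burden exclusion, somatic-call filtering (blacklist
# regions, population recurrence, low-support rule) and the C-terminal
# last-exon germline filter.

#' Filtering configuration
#'
#' Thresholds for the pre-analysis filters. Defaults encode the standard
#' rules: patients with more than 20 nonsynonymous mutations per megabase
#' are excluded; somatic calls are removed when they fall in a blacklisted
#' interval, occur in 10 or more reference-population individuals, or have
#' VAF below 5\% with at most 3 supporting reads at depth below 20x
#' (a conjunction; set `low_support_conjunctive = FALSE` for the disjunctive
#' reading). Whitelisted variant keys (e.g. known-oncogenic alleles) always
#' survive.
#'
#' @param tmb_threshold mutations/Mb above which a patient is excluded
#' @param callable_mb default callable footprint (Mb) when a patient record
#'   lacks one
#' @param population_occurrence_max removal threshold on population counts
#' @param vaf_min VAF threshold of the low-support rule
#' @param read_support_min minimum alt reads to escape the low-support rule
#'   ("three or fewer" fails, so the default is 4)
#' @param coverage_min depth threshold of the low-support rule
#' @param blacklist data.frame (contig, start, end) of excluded intervals
#' @param whitelist character vector of variant keys always retained
#' @param cterminal_bounds named numeric: per-gene coding coordinate beyond
#'   which last-exon truncating variants are dropped
#' @param low_support_conjunctive if TRUE (default) the low-support rule
#'   requires all three clauses
#' @return list of class `FilterConfig`
#' @export
filter_config <- function(tmb_threshold = 20,
                          callable_mb = NA_real_,
                          population_occurrence_max = 10,
                          vaf_min = 0.05,
                          read_support_min = 4,
                          coverage_min = 20,
                          blacklist = NULL,
                          whitelist = character(0),
                          cterminal_bounds = numeric(0),
                          low_support_conjunctive = TRUE) {
  stopifnot(tmb_threshold >= 0, population_occurrence_max >= 0,
            vaf_min >= 0, read_support_min >= 0, coverage_min >= 0)
  if (!is.null(blacklist)) {
    stopifnot(all(c("contig", "start", "end") %in% names(blacklist)),
              all(blacklist$end >= blacklist$start))
  }
  structure(list(tmb_threshold = tmb_threshold, callable_mb = callable_mb,
                 population_occurrence_max = population_occurrence_max,
                 vaf_min = vaf_min, read_support_min = read_support_min,
                 coverage_min = coverage_min, blacklist = blacklist,
                 whitelist = whitelist, cterminal_bounds = cterminal_bounds,
                 low_support_conjunctive = low_support_conjunctive),
            class = "FilterConfig")
}

#' Tumor mutational burden
#'
#' @param nonsynonymous_count nonsynonymous mutation count
#' @param callable_mb callable megabases (> 0)
#' @return mutations per megabase
#' @export
compute_tmb <- function(nonsynonymous_count, callable_mb) {
  if (any(callable_mb <= 0)) stop("callable_mb must be > 0")
  nonsynonymous_count / callable_mb
}

#' Exclude hypermutated patients
#'
#' A patient is retained iff TMB <= threshold; strictly greater is excluded.
#'
#' @param cohort data.frame with columns `nonsynonymous_count` and
#'   `callable_mb`
#' @param cfg a [filter_config()]
#' @return the retained rows of `cohort`
#' @export
exclude_high_tmb <- function(cohort, cfg = filter_config()) {
  stopifnot(all(c("nonsynonymous_count", "callable_mb") %in% names(cohort)))
  tmb <- compute_tmb(cohort$nonsynonymous_count, cohort$callable_mb)
  cohort[tmb <= cfg$tmb_threshold, , drop = FALSE]
}

.in_blacklist <- function(contig, pos, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(FALSE)
  any(blacklist$contig == contig & blacklist$start <= pos &
      blacklist$end >= pos)
}

#' Filter somatic calls
#'
#' Applies, in order: whitelist rescue; blacklist-interval removal;
#' population-recurrence removal; the low-support rule (VAF < `vaf_min` AND
#' alt reads < `read_support_min` AND depth < `coverage_min`, when
#' conjunctive). Variants missing an annotation needed by a rule are flagged
#' indeterminate, retained, and logged.
#'
#' @param variants data.frame with columns variant_id, contig, pos, vaf,
#'   alt_reads, depth and optionally pop_occurrence
#' @param cfg a [filter_config()]
#' @return `variants` with added columns `retained` (logical) and `reason`
#'   ("pass", "whitelisted", "blacklist_region", "population_recurrent",
#'   "low_support", "indeterminate")
#' @export
filter_somatic_calls <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  reason <- character(n)
  retained <- logical(n)
  pop <- if ("pop_occurrence" %in% names(variants)) variants$pop_occurrence
         else rep(NA_real_, n)
  for (i in seq_len(n)) {
    key <- variants$variant_id[i]
    if (key %in% cfg$whitelist) {
      retained[i] <- TRUE; reason[i] <- "whitelisted"; next
    }
    if (.in_blacklist(variants$contig[i], variants$pos[i], cfg$blacklist)) {
      retained[i] <- FALSE; reason[i] <- "blacklist_region"; next
    }
    if (is.na(pop[i]) || is.na(variants$vaf[i]) ||
        is.na(variants$alt_reads[i]) || is.na(variants$depth[i])) {
      retained[i] <- TRUE; reason[i] <- "indeterminate"
      message(sprintf("variant %s: missing filter annotation; retained as indeterminate", key))
      next
    }
    if (pop[i] >= cfg$population_occurrence_max) {
      retained[i] <- FALSE; reason[i] <- "population_recurrent"; next
    }
    low_vaf <- variants$vaf[i] < cfg$vaf_min
    low_reads <- variants$alt_reads[i] < cfg$read_support_min
    low_cov <- variants$depth[i] < cfg$coverage_min
    low_support <- if (cfg$low_support_conjunctive)
      low_vaf && low_reads && low_cov else low_vaf || low_reads || low_cov
    if (low_support) {
      retained[i] <- FALSE; reason[i] <- "low_support"; next
    }
    retained[i] <- TRUE; reason[i] <- "pass"
  }
  variants$retained <- retained
  variants$reason <- reason
  variants
}

#' Drop C-terminal last-exon truncating germline variants
#'
#' Truncating variants (frameshift or nonsense) whose first coding position
#' lies in the transcript's last exon beyond the configured per-gene bound
#' are removed; they are predicted not to disrupt the functional domains.
#' Non-truncating variants and variants without a configured bound are
#' retained.
#'
#' @param germline_variants list of `Variant`
#' @param tx the gene's `CodingTranscript`
#' @param cfg a [filter_config()] with `cterminal_bounds[[tx$gene]]` set
#' @return the retained subset of `germline_variants`
#' @export
filter_cterminal <- function(germline_variants, tx, cfg = filter_config()) {
  bound <- cfg$cterminal_bounds[tx$gene]
  if (length(bound) == 0 || is.na(bound)) return(germline_variants)
  n_exon <- nrow(tx$exons)
  exon_cum <- cumsum(tx$exons$end - tx$exons$start + 1L)
  last_exon_cds_start <- if (n_exon == 1) 1L else exon_cum[n_exon - 1L] + 1L
  keep <- vapply(germline_variants, function(v) {
    ch <- tryCatch(project_to_cds(v, tx), error = function(e) NULL)
    if (is.null(ch)) return(TRUE)
    cons <- classify_consequence(tx, ch)
    if (!cons$class %in% c("frameshift", "nonsense")) return(TRUE)
    !(ch$cds_start >= last_exon_cds_start && ch$cds_start > bound)
  }, logical(1))
  germline_variants[keep]
}
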