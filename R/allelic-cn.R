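# Allele-specific copy-number model: segment profiles, the expected-VAF
# mixture model, per-variant zygosity by binomial likelihood, and gene-level
# biallelic classification.

#' Construct an allele-specific copy-number segment profile
#'
#' @param segments data.frame with columns contig, start, end, total_cn,
#'   minor_cn (minor is the lesser allele count; NA allowed, excluding the
#'   segment from LOH-dependent logic)
#' @param purity tumor purity in (0, 1]
#' @param ploidy tumor ploidy (metadata)
#' @return list of class `SegmentProfile`
#' @export
segment_profile <- function(segments, purity = 1, ploidy = NA_real_) {
  stopifnot(all(c("contig", "start", "end", "total_cn", "minor_cn") %in%
                names(segments)),
            purity > 0, purity <= 1)
  segments <- as.data.frame(segments)
  if (nrow(segments) > 0) {
    stopifnot(all(segments$end > segments$start),
              all(segments$total_cn >= 0, na.rm = TRUE),
              all(segments$minor_cn >= 0, na.rm = TRUE))
    ok <- is.na(segments$minor_cn) |
      (segments$minor_cn <= segments$total_cn - segments$minor_cn)
    if (!all(ok)) stop("minor_cn must be the lesser allele count")
    segments <- segments[order(segments$contig, segments$start), , drop = FALSE]
    for (ct in unique(segments$contig)) {
      s <- segments[segments$contig == ct, , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping segments on ", ct)
    }
    rownames(segments) <- NULL
  }
  structure(list(segments = segments, purity = purity, ploidy = ploidy),
            class = "SegmentProfile")
}

#' Expected variant allele fraction under the purity/copy-number mixture
#'
#' Tumor cells (fraction `purity`) carry `total_cn` copies of the locus, of
#' which `m` are mutated; admixed normal cells contribute two wild-type
#' copies. The expected VAF is therefore
#' `m * purity / (total_cn * purity + 2 * (1 - purity))`.
#'
#' @param purity tumor purity in (0, 1]
#' @param total_cn total copy number in tumor cells
#' @param m mutated copies, 0 <= m <= total_cn
#' @return expected VAF
#' @export
expected_vaf <- function(purity, total_cn, m) {
  stopifnot(purity > 0, purity <= 1)
  if (any(m > total_cn)) stop("m cannot exceed total_cn")
  if (any(m < 0)) stop("m must be >= 0")
  m * purity / (total_cn * purity + 2 * (1 - purity))
}

#' Classify zygosity of a variant from read counts and copy number
#'
#' Finds the most likely number of mutated copies `m` by maximizing the
#' binomial likelihood of the observed alt reads at the expected VAF for
#' each m in 1..total_cn, using the unique segment overlapping the variant.
#' Loss of the wild-type allele is called when the segment's minor copy
#' number is 0 and the best m equals the total copy number.
#'
#' @param v a `Variant` with vaf/alt_reads/depth (alt_reads and depth are
#'   used if present, else derived from vaf at nominal depth 100)
#' @param profile a [segment_profile()]
#' @return list of class `ZygosityCall`: variant_id, class (one of
#'   biallelic_loss_of_wt, heterozygous, indeterminate), best_m, segment
#' @export
classify_zygosity <- function(v, profile) {
  seg <- .overlapping_segment(profile$segments, v$contig, v$pos)
  out <- function(class, best_m = NA_integer_, segment = NULL) {
    structure(list(variant_id = v$variant_id, class = class,
                   best_m = best_m, segment = segment),
              class = "ZygosityCall")
  }
  if (is.null(seg) || is.na(seg$minor_cn) || seg$total_cn < 1)
    return(out("indeterminate"))
  depth <- if (!is.null(v$depth) && !is.na(v$depth)) v$depth else 100L
  alt <- if (!is.null(v$alt_reads) && !is.na(v$alt_reads)) v$alt_reads
         else if (!is.na(v$vaf)) round(v$vaf * depth) else NA
  if (is.na(alt)) return(out("indeterminate"))
  ms <- seq_len(seg$total_cn)
  ll <- vapply(ms, function(m) {
    # clamp away from 0/1: sequencing noise makes boundary VAFs unobservable
    p <- min(max(expected_vaf(profile$purity, seg$total_cn, m), 1e-6),
             1 - 1e-6)
    stats::dbinom(alt, depth, p, log = TRUE)
  }, numeric(1))
  best_m <- ms[which.max(ll)]
  cls <- if (seg$minor_cn == 0 && best_m == seg$total_cn)
    "biallelic_loss_of_wt" else "heterozygous"
  out(cls, best_m, seg)
}

#' Gene-level biallelic classification
#'
#' A gene is biallelic when a loss-of-function mutation shows loss of the
#' wild-type allele, or when an LoF mutation co-occurs with a homozygous
#' deletion, a fusion, or a second somatic LoF mutation.
#'
#' @param events data.frame with columns `type` (mutation,
#'   homozygous_deletion, fusion), `lof` (logical, meaningful for
#'   mutations), and optionally `zygosity_class` for mutations
#' @return logical: biallelic or not
#' @export
classify_biallelic_gene <- function(events) {
  if (nrow(events) == 0) return(FALSE)
  stopifnot(all(events$type %in% c("mutation", "homozygous_deletion", "fusion")))
  if (!"zygosity_class" %in% names(events))
    events$zygosity_class <- NA_character_
  muts <- events[events$type == "mutation", , drop = FALSE]
  lof_muts <- muts[!is.na(muts$lof) & muts$lof, , drop = FALSE]
  if (any(lof_muts$zygosity_class %in% "biallelic_loss_of_wt")) return(TRUE)
  if (nrow(lof_muts) == 0) return(FALSE)
  has_homdel <- any(events$type == "homozygous_deletion")
  has_fusion <- any(events$type == "fusion")
  has_homdel || has_fusion || nrow(lof_muts) >= 2
}
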