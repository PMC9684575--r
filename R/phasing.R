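# Cis/trans phasing of a somatic candidate against a germline variant,
# either by counting read pairs that span both sites or, for somatic
# deletions encompassing the germline site, by loss-of-wild-type inference
# from allele-specific copy number.

#' Read-pair observation records
#'
#' Builds a validated data.frame of per-fragment allele calls at the
#' germline and somatic sites. Allele codes: germline site in
#' \{ref, alt, deleted, uncovered\}; somatic site in \{ref, alt, uncovered\}.
#' A germline site removed by the somatic deletion on a fragment is coded
#' "deleted"; such fragments are uninformative for read-based phasing.
#'
#' @param fragment_id character vector
#' @param germ_allele,som_allele allele codes per fragment
#' @return data.frame of class `ReadPairObservation`
#' @export
read_pairs <- function(fragment_id, germ_allele, som_allele) {
  germ_allele <- as.character(germ_allele)
  som_allele <- as.character(som_allele)
  stopifnot(all(germ_allele %in% c("ref", "alt", "deleted", "uncovered")),
            all(som_allele %in% c("ref", "alt", "uncovered")))
  if (any(germ_allele == "uncovered" & som_allele == "uncovered"))
    stop("a pair must cover at least one site")
  structure(data.frame(fragment_id = as.character(fragment_id),
                       germ_allele = germ_allele, som_allele = som_allele,
                       stringsAsFactors = FALSE),
            class = c("ReadPairObservation", "data.frame"))
}

#' Count phase-informative read pairs
#'
#' A pair supports cis when it carries the alternate allele at both sites;
#' it supports trans when it carries the alternate at exactly one site and
#' the reference at the other. Pairs with an uncovered or deleted site are
#' uninformative.
#'
#' @param pairs a [read_pairs()] data.frame (may have 0 rows)
#' @return named integer vector c(n_cis, n_trans)
#' @export
count_informative_pairs <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0)
    return(c(n_cis = 0L, n_trans = 0L))
  g <- pairs$germ_allele; s <- pairs$som_allele
  n_cis <- sum(g == "alt" & s == "alt")
  n_trans <- sum((g == "alt" & s == "ref") | (g == "ref" & s == "alt"))
  c(n_cis = as.integer(n_cis), n_trans = as.integer(n_trans))
}

.phasing_result <- function(status, method, n_cis = 0L, n_trans = 0L) {
  structure(list(status = status, method = method,
                 n_cis_pairs = as.integer(n_cis),
                 n_trans_pairs = as.integer(n_trans)),
            class = "PhasingResult")
}

#' Phase by spanning read pairs
#'
#' At least three pairs spanning both sites and carrying both alternate
#' alleles are required to call cis; conflicting evidence (trans pairs at
#' least as numerous as cis pairs) demotes the call to ambiguous. A trans
#' call - an extension beyond the cis certification the method defines -
#' requires at least three trans pairs and zero cis pairs, and is flagged by
#' its status.
#'
#' @param pairs a [read_pairs()] data.frame
#' @param min_pairs cis-support threshold (default 3)
#' @return a `PhasingResult`
#' @export
phase_by_reads <- function(pairs, min_pairs = 3L) {
  n <- count_informative_pairs(pairs)
  status <- if (n[["n_cis"]] >= min_pairs && n[["n_trans"]] < n[["n_cis"]])
    "cis"
  else if (n[["n_trans"]] >= min_pairs && n[["n_cis"]] == 0L) "trans"
  else "ambiguous"
  .phasing_result(status, "read_pair", n[["n_cis"]], n[["n_trans"]])
}

#' Phase an encompassing somatic deletion by loss-of-wild-type inference
#'
#' When the somatic deletion removes the germline site no single fragment
#' can span both alterations. If the locus shows clonal loss of the
#' wild-type allele (overlapping segment minor copy number 0) then the
#' germline-bearing allele is the only substrate available for somatic
#' mutation, so the deletion must be in cis. The loss-of-wild-type state is
#' checked against the observed germline VAF: it must lie within
#' `vaf_tolerance` of the VAF expected when every tumor copy carries the
#' germline allele, `expected_vaf(purity, total_cn, total_cn)`.
#'
#' @param somatic somatic `CdsChange` (a deletion)
#' @param germline germline `CdsChange`
#' @param segment list/row with `total_cn` and `minor_cn` overlapping the
#'   locus
#' @param purity tumor purity in (0, 1]
#' @param germline_vaf observed tumor VAF of the germline variant
#' @param vaf_tolerance absolute tolerance on the VAF consistency check
#' @return a `PhasingResult` with method "loh_inference"
#' @export
phase_by_loh <- function(somatic, germline, segment, purity, germline_vaf,
                         vaf_tolerance = 0.10) {
  if (somatic$kind != "deletion")
    stop("LOH-based phasing applies to somatic deletions only")
  g_span <- c(germline$cds_start,
              germline$cds_start + max(germline$ref_len - 1L, 0L))
  s_span <- .change_span(somatic)
  if (!(s_span[1L] <= g_span[1L] && s_span[2L] >= g_span[2L]))
    stop("somatic deletion does not encompass the germline site; use read-pair phasing")
  if (is.na(segment$minor_cn) || segment$minor_cn != 0L)
    return(.phasing_result("ambiguous", "loh_inference"))
  exp_vaf <- expected_vaf(purity, segment$total_cn, segment$total_cn)
  if (is.na(germline_vaf) || abs(germline_vaf - exp_vaf) > vaf_tolerance)
    return(.phasing_result("ambiguous", "loh_inference"))
  .phasing_result("cis", "loh_inference")
}

#' @method print PhasingResult
#' @export
print.PhasingResult <- function(x, ...) {
  cat(sprintf("PhasingResult: %s (%s; cis pairs %d, trans pairs %d)\n",
              x$status, x$method, x$n_cis_pairs, x$n_trans_pairs))
  invisible(x)
}
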