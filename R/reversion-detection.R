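# Core reversion-mutation detection: window search for somatic candidates
# near a germline truncating variant, cis-phase confirmation, and the
# open-reading-frame restoration test.

#' Is a CDS change truncating?
#'
#' Truncating means frameshift or nonsense consequence on the transcript.
#'
#' @param change a `CdsChange`
#' @param tx a `CodingTranscript`
#' @return logical
#' @export
is_truncating <- function(change, tx) {
  classify_consequence(tx, change)$class %in% c("frameshift", "nonsense")
}

#' Find somatic reversion candidates near a germline truncating variant
#'
#' Somatic insertions/deletions (and delins) whose first affected codon lies
#' within `window_aa` codons of the germline lesion's first affected codon
#' are candidates. Substitutions are included only when the germline variant
#' is a nonsense substitution and the somatic substitution hits the same
#' codon (a nonsense-reverting point change). The window is symmetric.
#'
#' @param germline germline `CdsChange` (must be truncating on `tx`)
#' @param somatic_changes list of somatic `CdsChange`
#' @param tx a `CodingTranscript` (used for the nonsense-reversion check)
#' @param window_aa window half-width in codons (default 200)
#' @return list of candidates, each with a `distance_aa` attribute
#' @export
find_candidates <- function(germline, somatic_changes, tx = NULL,
                            window_aa = 200L) {
  g_codon <- affected_codon(germline)
  germline_nonsense <- !is.null(tx) && germline$kind == "substitution" &&
    classify_consequence(tx, germline)$class == "nonsense"
  out <- list()
  for (ch in somatic_changes) {
    d <- abs(affected_codon(ch) - g_codon)
    if (d > window_aa) next
    if (ch$kind == "substitution") {
      if (!(germline_nonsense && affected_codon(ch) == g_codon)) next
    }
    attr(ch, "distance_aa") <- d
    out[[length(out) + 1L]] <- ch
  }
  out
}

#' Test restoration of the open reading frame
#'
#' Applies the germline lesion and the somatic change(s) jointly to the
#' transcript CDS (a somatic deletion fully encompassing the germline lesion
#' annihilates it). The allele is restored when (i) the combined net length
#' shift of the surviving lesions is a multiple of 3 and (ii) translation of
#' the doubly mutated CDS reaches the natural stop with no premature stop
#' codon anywhere upstream.
#'
#' Mechanism taxonomy: `encompassing_deletion` when the somatic deletion
#' absorbed the germline change; `delins` when a somatic delins participates;
#' otherwise `compensating_indel`.
#'
#' @param tx a `CodingTranscript`
#' @param germline germline `CdsChange`
#' @param somatic list of somatic `CdsChange` (or a single change)
#' @param translate if FALSE, skip translating the mutated allele
#'   (`protein` is NA); useful in tight loops
#' @return list(restored, mechanism, net_shift, protein) where `protein` is
#'   the translated product of the doubly mutated allele
#' @export
check_orf_restoration <- function(tx, germline, somatic, translate = TRUE) {
  if (inherits(somatic, "CdsChange")) somatic <- list(somatic)
  res <- apply_changes(tx$cds_sequence, c(list(germline), somatic),
                       return_applied = TRUE)
  mut <- res$seq
  net <- nchar(mut) - nchar(tx$cds_sequence)
  stop_idx <- first_stop_codon(mut)
  restored <- (net %% 3L == 0L) && !is.na(stop_idx) &&
    stop_idx == nchar(mut) / 3L

  germline_annihilated <- any(vapply(res$annihilated, function(a)
    identical(a$cds_start, germline$cds_start) &&
      identical(a$ref, germline$ref) && identical(a$alt, germline$alt),
    logical(1)))
  mechanism <- if (germline_annihilated) "encompassing_deletion"
    else if (any(vapply(somatic, function(s) s$kind == "delins", logical(1))))
      "delins"
    else "compensating_indel"

  list(restored = restored, mechanism = mechanism, net_shift = net,
       protein = if (translate) translate_cds(mut) else NA_character_)
}

#' Call reversion mutations for one patient
#'
#' Implements the full detection chain for a patient bundle: for each
#' germline truncating variant in a modeled gene, somatic indels within the
#' codon window are phased - by spanning read pairs, or by loss-of-wild-type
#' inference when the somatic deletion encompasses the germline site - and
#' cis-phased candidates are tested for restoration of the open reading
#' frame. Multiple independent calls per patient are allowed (polyclonal
#' reversion).
#'
#' @param patient_id patient identifier
#' @param germline_variants list of germline `Variant`s
#' @param somatic_variants list of somatic `Variant`s (post-filtering)
#' @param transcripts named list of `CodingTranscript` (one per gene)
#' @param pairs data.frame of read-pair observations with columns
#'   germ_variant_id, som_variant_id, fragment_id, germ_allele, som_allele
#' @param segments data.frame of allele-specific copy-number segments
#'   (contig, start, end, total_cn, minor_cn)
#' @param purity tumor purity
#' @param window_aa candidate window in codons (default 200)
#' @param min_pairs cis read-pair threshold (default 3)
#' @param vaf_tolerance LOH-inference VAF tolerance (default 0.10)
#' @return data.frame with one row per confirmed reversion call (patient_id,
#'   gene, germline_id, germline_notation, somatic_id, somatic_notation,
#'   mechanism, phasing_method, n_cis_pairs, distance_aa, restored)
#' @export
call_reversions <- function(patient_id, germline_variants, somatic_variants,
                            transcripts, pairs = NULL, segments = NULL,
                            purity = NA_real_, window_aa = 200L,
                            min_pairs = 3L, vaf_tolerance = 0.10) {
  calls <- list()
  for (tx in transcripts) {
    g_on_tx <- Filter(function(v) identical(v$contig, tx$contig),
                      germline_variants)
    s_on_tx <- Filter(function(v) identical(v$contig, tx$contig),
                      somatic_variants)
    if (length(g_on_tx) == 0 || length(s_on_tx) == 0) next
    s_changes <- lapply(s_on_tx, function(v)
      tryCatch(project_to_cds(v, tx), error = function(e) NULL))
    keep <- !vapply(s_changes, is.null, logical(1))
    s_on_tx <- s_on_tx[keep]; s_changes <- s_changes[keep]

    for (gv in g_on_tx) {
      g_ch <- tryCatch(project_to_cds(gv, tx), error = function(e) NULL)
      if (is.null(g_ch)) next
      g_cons <- classify_consequence(tx, g_ch)
      if (!g_cons$class %in% c("frameshift", "nonsense")) next

      cand_idx <- which(vapply(seq_along(s_changes), function(i) {
        length(find_candidates(g_ch, s_changes[i], tx, window_aa)) == 1L
      }, logical(1)))

      for (i in cand_idx) {
        sv <- s_on_tx[[i]]; s_ch <- s_changes[[i]]
        g_span <- c(g_ch$cds_start,
                    g_ch$cds_start + max(g_ch$ref_len - 1L, 0L))
        s_span <- c(s_ch$cds_start, s_ch$cds_start + s_ch$ref_len - 1L)
        encompassing <- s_ch$kind == "deletion" &&
          s_span[1L] <= g_span[1L] && s_span[2L] >= g_span[2L] &&
          !(identical(g_span, s_span))

        if (encompassing) {
          seg <- .overlapping_segment(segments, tx$contig, gv$pos)
          if (is.null(seg)) next
          ph <- phase_by_loh(s_ch, g_ch, seg, purity, gv$vaf, vaf_tolerance)
        } else {
          pp <- if (is.null(pairs) || nrow(pairs) == 0) NULL else
            pairs[pairs$germ_variant_id == gv$variant_id &
                  pairs$som_variant_id == sv$variant_id, , drop = FALSE]
          ph <- phase_by_reads(pp, min_pairs)
        }
        if (ph$status != "cis") next

        orf <- tryCatch(check_orf_restoration(tx, g_ch, s_ch),
                        error = function(e) NULL)
        if (is.null(orf) || !orf$restored) next
        s_cons <- classify_consequence(tx, s_ch)
        calls[[length(calls) + 1L]] <- data.frame(
          patient_id = patient_id, gene = tx$gene,
          germline_id = gv$variant_id,
          germline_notation = g_cons$protein_notation,
          somatic_id = sv$variant_id,
          somatic_notation = s_cons$protein_notation,
          mechanism = orf$mechanism, phasing_method = ph$method,
          n_cis_pairs = ph$n_cis_pairs,
          distance_aa = abs(affected_codon(s_ch) - affected_codon(g_ch)),
          restored = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0) return(.empty_calls())
  do.call(rbind, calls)
}

.empty_calls <- function() {
  data.frame(patient_id = character(0), gene = character(0),
             germline_id = character(0), germline_notation = character(0),
             somatic_id = character(0), somatic_notation = character(0),
             mechanism = character(0), phasing_method = character(0),
             n_cis_pairs = integer(0), distance_aa = integer(0),
             restored = logical(0), stringsAsFactors = FALSE)
}

.overlapping_segment <- function(segments, contig, pos) {
  if (is.null(segments) || nrow(segments) == 0) return(NULL)
  hit <- which(segments$contig == contig & segments$start <= pos &
               segments$end >= pos)
  if (length(hit) != 1L) return(NULL)
  as.list(segments[hit, , drop = FALSE])
}
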