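# Reference coding model: transcripts, variants, CDS-level changes,
# sequence mutation and translation. All coordinates are 1-based inclusive
# (genomic and coding); VCF anchored-base indels are normalized on input.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Split a nucleotide string into codons
#'
#' Trailing bases beyond the last complete codon are dropped.
#' @param seq nucleotide string
#' @return character vector of 3-mers
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return(character(0))
  substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code; translation stops at the first in-frame
#' stop codon. Codons containing ambiguous bases translate to "X".
#'
#' @param seq nucleotide string (need not be a multiple of 3; trailing bases
#'   are ignored)
#' @param to_first_stop if TRUE (default) the returned protein ends before
#'   the first stop codon; otherwise stops are embedded as "*"
#' @return amino-acid string
#' @export
translate_cds <- function(seq, to_first_stop = TRUE) {
  codons <- split_codons(seq)
  if (length(codons) == 0) return("")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (to_first_stop) {
    st <- which(aa == "*")
    if (length(st) > 0) aa <- aa[seq_len(st[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Index of the first in-frame stop codon, or NA
#'
#' Stop codons start with T and continue with purines, so two stop codons
#' can never overlap; a non-overlapping regex scan therefore finds every
#' stop, and in-frame ones are those at positions = 1 (mod 3).
#' @keywords internal
first_stop_codon <- function(seq) {
  m <- gregexpr("TAA|TAG|TGA", seq)[[1L]]
  pos <- m[m > 0L & m %% 3L == 1L]
  if (length(pos) == 0) NA_integer_ else as.integer((pos[1L] + 2L) / 3L)
}

#' Reverse complement of a plain nucleotide string
#' @param x nucleotide string (ACGTN)
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0) return(x)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "")[[1L]]),
        collapse = "")
}

# ---------------------------------------------------------------------------
# CodingTranscript

#' Construct a coding transcript model
#'
#' A transcript is the substrate for all reading-frame arithmetic: an ordered
#' exon structure on a contig plus the spliced CDS. Exons are given 5'->3' in
#' transcript orientation (for "-" strand transcripts genomic coordinates
#' therefore decrease along the list). The CDS must begin with ATG, end with
#' a stop codon, contain no internal in-frame stop, and its length must match
#' the summed exon widths.
#'
#' @param transcript_id,gene identifiers
#' @param contig contig name
#' @param strand "+" or "-"
#' @param exons data.frame with columns start, end (1-based inclusive
#'   genomic), rows ordered 5'->3' in transcript orientation
#' @param cds_sequence spliced coding sequence; if NULL it is extracted from
#'   `contig_seq`
#' @param contig_seq full contig sequence (character), required when
#'   `cds_sequence` is NULL and used, when present, to verify the CDS
#' @return object of class `CodingTranscript`
#' @export
coding_transcript <- function(transcript_id, gene, contig, strand, exons,
                              cds_sequence = NULL, contig_seq = NULL) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            all(exons$end >= exons$start))
  exons <- as.data.frame(exons)[, c("start", "end")]

  # genomic position of each CDS base, in transcript order
  cds_genomic <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    if (strand == "+") seq(exons$start[i], exons$end[i])
    else seq(exons$end[i], exons$start[i])
  }), use.names = FALSE)
  if (anyDuplicated(cds_genomic))
    stop("exons overlap")
  if (is.unsorted(if (strand == "+") cds_genomic else rev(cds_genomic)))
    stop("exons not ordered 5'->3' in transcript orientation")

  if (is.null(cds_sequence)) {
    if (is.null(contig_seq)) stop("need cds_sequence or contig_seq")
    bases <- substring(contig_seq, cds_genomic, cds_genomic)
    cds_sequence <- paste(bases, collapse = "")
    if (strand == "-") cds_sequence <- chartr("ACGT", "TGCA", cds_sequence)
  }
  if (nchar(cds_sequence) != length(cds_genomic))
    stop("CDS length does not match exon widths")
  if (nchar(cds_sequence) %% 3L != 0L)
    stop("CDS length not a multiple of 3")
  if (substr(cds_sequence, 1L, 3L) != "ATG")
    stop("CDS does not start with ATG")
  n_codon <- nchar(cds_sequence) / 3L
  stop_at <- first_stop_codon(cds_sequence)
  if (is.na(stop_at) || stop_at != n_codon)
    stop("CDS must end with its first in-frame stop codon")

  structure(list(
    transcript_id = transcript_id,
    gene = gene,
    contig = contig,
    strand = strand,
    exons = exons,
    cds_sequence = cds_sequence,
    protein_sequence = translate_cds(cds_sequence),
    cds_genomic = cds_genomic
  ), class = "CodingTranscript")
}

#' @method print CodingTranscript
#' @export
print.CodingTranscript <- function(x, ...) {
  cat(sprintf("CodingTranscript %s (%s) %s:%s strand %s, %d exons, CDS %d nt / %d aa\n",
              x$transcript_id, x$gene, x$contig,
              paste(range(c(x$exons$start, x$exons$end)), collapse = "-"),
              x$strand, nrow(x$exons), nchar(x$cds_sequence),
              nchar(x$protein_sequence)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Variant and CdsChange records

#' Construct a variant record
#'
#' Alleles follow the trimmed convention: no shared anchor base. A deletion
#' has `alt == ""`, an insertion `ref == ""` (inserted sequence begins at
#' `pos`, i.e. between pos-1 and pos). Use [normalize_variant()] to convert
#' VCF-style anchored records.
#'
#' @param variant_id identifier
#' @param contig,pos genomic location (1-based)
#' @param ref,alt allele strings (may be empty, not both)
#' @param origin "germline" or "somatic"
#' @param vaf variant allele fraction in `[0,1]` or NA
#' @param alt_reads,depth read support
#' @return list of class `Variant`
#' @export
variant <- function(variant_id, contig, pos, ref, alt,
                    origin = c("somatic", "germline"),
                    vaf = NA_real_, alt_reads = NA_integer_,
                    depth = NA_integer_) {
  origin <- match.arg(origin)
  if (identical(ref, alt)) stop("ref must differ from alt")
  if (!is.na(alt_reads) && !is.na(depth) && alt_reads > depth)
    stop("alt_reads exceeds depth")
  structure(list(variant_id = variant_id, contig = contig, pos = as.integer(pos),
                 ref = toupper(ref), alt = toupper(alt), origin = origin,
                 vaf = vaf, alt_reads = alt_reads, depth = depth),
            class = "Variant")
}

#' Normalize a variant to trimmed-allele form
#'
#' Removes the shared suffix, then the shared prefix (advancing `pos`), which
#' maps VCF anchored-base indels onto the package's trimmed convention and
#' makes cis-pair matching deterministic.
#'
#' @param v a `Variant` (or any list with pos/ref/alt)
#' @return the normalized variant
#' @export
normalize_variant <- function(v) {
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt)) &&
         !(nchar(ref) == 1 && nchar(alt) == 1)) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  v$ref <- ref; v$alt <- alt; v$pos <- as.integer(pos)
  v
}

#' Construct a CDS-level change
#'
#' Coding-coordinate representation of a lesion. `cds_start` is the first
#' affected coding base for substitutions/deletions; for insertions the
#' inserted sequence begins at `cds_start` (between cds_start-1 and
#' cds_start).
#'
#' @param cds_start 1-based coding coordinate
#' @param ref reference allele on the coding strand ("" for insertion)
#' @param alt alternate allele on the coding strand ("" for deletion)
#' @return list of class `CdsChange` with fields cds_start, ref, alt,
#'   ref_len, alt_len, net_shift, kind
#' @export
cds_change <- function(cds_start, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt)) stop("ref must differ from alt")
  rl <- nchar(ref); al <- nchar(alt)
  kind <- if (rl > 0 && al == 0) "deletion"
          else if (rl == 0) "insertion"
          else if (rl == al) "substitution"
          else "delins"
  structure(list(cds_start = as.integer(cds_start), ref = ref, alt = alt,
                 ref_len = rl, alt_len = al, net_shift = al - rl,
                 kind = kind),
            class = "CdsChange")
}

# span of reference bases affected, [start, end]; empty (end < start) for
# insertions
.change_span <- function(ch) c(ch$cds_start, ch$cds_start + ch$ref_len - 1L)

#' First affected codon of a CDS change
#' @param ch a `CdsChange`
#' @return 1-based codon index
#' @export
affected_codon <- function(ch) as.integer(ceiling(ch$cds_start / 3))

# ---------------------------------------------------------------------------
# Projection

#' Project a genomic variant onto a transcript's coding coordinates
#'
#' Returns NULL for variants with no coding footprint (intronic, intergenic,
#' insertion points outside or at the edges of the CDS). On "-" strand
#' transcripts alleles are reverse-complemented onto the coding strand.
#' Deletions extending past the coding interval are clipped to it; the
#' clipped length is what the returned change records. The reference allele
#' is verified against the transcript CDS; a mismatch signals corrupt input.
#'
#' @param v a `Variant` (anchored-base records are normalized internally)
#' @param tx a `CodingTranscript`
#' @return a `CdsChange`, or NULL if the variant does not touch the CDS
#' @export
project_to_cds <- function(v, tx) {
  stopifnot(inherits(tx, "CodingTranscript"))
  if (!identical(v$contig, tx$contig))
    stop("variant contig does not match transcript contig")
  v <- normalize_variant(v)
  idx_of <- function(gpos) match(gpos, tx$cds_genomic)  # genomic -> cds index

  if (v$ref == "") {                     # insertion between pos-1 and pos
    i0 <- idx_of(v$pos - 1L); i1 <- idx_of(v$pos)
    if (is.na(i0) || is.na(i1) || abs(i1 - i0) != 1L) return(NULL)
    alt <- if (tx$strand == "-") revcomp(v$alt) else v$alt
    return(cds_change(min(i0, i1) + 1L, "", alt))
  }

  gspan <- seq(v$pos, v$pos + nchar(v$ref) - 1L)
  idx <- idx_of(gspan)
  coding <- which(!is.na(idx))
  if (length(coding) == 0) return(NULL)

  cds_idx <- sort(idx[coding])
  if (any(diff(cds_idx) != 1L))
    stop("variant reference spans non-contiguous coding bases")
  cds_ref <- substr(tx$cds_sequence, cds_idx[1L], cds_idx[length(cds_idx)])

  # verify reference allele against the transcript sequence
  obs <- substring(v$ref, coding, coding)
  obs <- paste(if (tx$strand == "-") rev(chartr("ACGT", "TGCA", obs)) else obs,
               collapse = "")
  if (obs != cds_ref)
    stop(sprintf("variant ref '%s' inconsistent with reference CDS '%s'",
                 v$ref, cds_ref))

  if (v$alt == "") {                     # (possibly clipped) deletion
    return(cds_change(cds_idx[1L], cds_ref, ""))
  }
  if (length(coding) != nchar(v$ref))
    stop("substitution/delins partially outside the coding interval")
  alt <- if (tx$strand == "-") revcomp(v$alt) else v$alt
  cds_change(cds_idx[1L], cds_ref, alt)
}

# ---------------------------------------------------------------------------
# Applying changes

#' Apply CDS-level changes to a coding sequence
#'
#' Changes must be coordinate-sorted and mutually non-overlapping, with one
#' exception: a pure deletion that fully encompasses another change absorbs
#' it (the inner change is annihilated) - this models large somatic deletions
#' that remove the germline lesion. Partial overlap is an ambiguous haplotype
#' and is an error.
#'
#' @param cds coding sequence string
#' @param changes list of `CdsChange`
#' @param return_applied if TRUE, returns a list with the mutated sequence
#'   and the surviving (non-annihilated) changes
#' @return mutated nucleotide string (or list, see `return_applied`)
#' @export
apply_changes <- function(cds, changes, return_applied = FALSE) {
  if (length(changes) == 0) {
    if (return_applied) return(list(seq = cds, applied = list(),
                                    annihilated = list()))
    return(cds)
  }
  ord <- order(vapply(changes, `[[`, integer(1), "cds_start"))
  changes <- changes[ord]
  n <- length(changes)
  L <- nchar(cds)
  for (ch in changes) {
    if (ch$cds_start < 1L || ch$cds_start > L + (ch$ref_len == 0))
      stop("change outside CDS")
    if (ch$ref_len > 0 && ch$cds_start + ch$ref_len - 1L > L)
      stop("change extends past CDS end")
    if (ch$ref_len > 0 &&
        substr(cds, ch$cds_start, ch$cds_start + ch$ref_len - 1L) != ch$ref)
      stop("change ref does not match CDS")
  }

  drop <- rep(FALSE, n)
  contains <- function(outer, inner) {
    so <- .change_span(outer); si <- .change_span(inner)
    if (outer$kind != "deletion") return(FALSE)
    if (inner$ref_len == 0)           # insertion point strictly inside
      return(inner$cds_start > so[1L] && inner$cds_start <= so[2L])
    si[1L] >= so[1L] && si[2L] <= so[2L]
  }
  overlaps <- function(a, b) {
    sa <- .change_span(a); sb <- .change_span(b)
    if (a$ref_len == 0 && b$ref_len == 0) return(a$cds_start == b$cds_start)
    if (a$ref_len == 0) return(a$cds_start > sb[1L] && a$cds_start <= sb[2L])
    if (b$ref_len == 0) return(b$cds_start > sa[1L] && b$cds_start <= sa[2L])
    sa[1L] <= sb[2L] && sb[1L] <= sa[2L]
  }
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (drop[i] || drop[j]) next
    if (contains(changes[[i]], changes[[j]])) drop[j] <- TRUE
    else if (contains(changes[[j]], changes[[i]])) drop[i] <- TRUE
    else if (overlaps(changes[[i]], changes[[j]]))
      stop("partially overlapping changes: ambiguous haplotype")
  }
  kept <- changes[!drop]

  out <- cds
  for (ch in rev(kept)) {               # right-to-left keeps coordinates valid
    out <- paste0(substr(out, 1L, ch$cds_start - 1L), ch$alt,
                  substr(out, ch$cds_start + ch$ref_len, nchar(out)))
  }
  if (return_applied)
    list(seq = out, applied = kept, annihilated = changes[drop])
  else out
}

# ---------------------------------------------------------------------------
# Consequence classification

#' Classify the protein-level consequence of a CDS change
#'
#' Frameshift iff the net length shift is not a multiple of 3. Frameshift
#' notation follows the X{codon}Yfs*N pattern, where the codon is the first
#' altered codon (`ceiling(cds_start/3)`) and N is the offset of the novel
#' stop in the shifted frame (the first changed residue counting as 1).
#'
#' @param tx a `CodingTranscript`
#' @param change a `CdsChange`
#' @return list with fields `class` (one of frameshift, nonsense,
#'   inframe_indel, missense, silent), `protein_notation`, and
#'   `mutant_protein`
#' @export
classify_consequence <- function(tx, change) {
  cds <- tx$cds_sequence
  mut <- apply_changes(cds, list(change))
  prot_ref <- tx$protein_sequence
  prot_mut <- translate_cds(mut)
  codon <- affected_codon(change)
  aa_ref <- substr(prot_ref, codon, codon)
  if (aa_ref == "") aa_ref <- "*"       # lesion in the stop codon

  if (change$net_shift %% 3L != 0L) {
    aa_new <- substr(prot_mut, codon, codon)
    stop_idx <- first_stop_codon(mut)
    if (!is.na(stop_idx) && stop_idx >= codon) {
      offset <- stop_idx - codon + 1L
      notation <- if (offset == 1L) sprintf("%s%d*", aa_ref, codon)
                  else sprintf("%s%d%sfs*%d", aa_ref, codon, aa_new, offset)
    } else {
      notation <- sprintf("%s%d%sfs*?", aa_ref, codon, aa_new)
    }
    return(list(class = "frameshift", protein_notation = notation,
                mutant_protein = prot_mut))
  }

  stop_idx <- first_stop_codon(mut)
  premature <- is.na(stop_idx) || stop_idx < nchar(mut) / 3L

  if (change$kind == "substitution") {
    if (identical(prot_mut, prot_ref))
      return(list(class = "silent",
                  protein_notation = sprintf("%s%d=", aa_ref, codon),
                  mutant_protein = prot_mut))
    if (premature)
      return(list(class = "nonsense",
                  protein_notation = sprintf("%s%d*", aa_ref, codon),
                  mutant_protein = prot_mut))
    aa_new <- substr(prot_mut, codon, codon)
    return(list(class = "missense",
                protein_notation = sprintf("%s%d%s", aa_ref, codon, aa_new),
                mutant_protein = prot_mut))
  }
  # in-frame indel / delins
  if (premature)
    return(list(class = "nonsense",
                protein_notation = sprintf("%s%d*", aa_ref, codon),
                mutant_protein = prot_mut))
  notation <- switch(change$kind,
    deletion = sprintf("%s%ddel", aa_ref, codon),
    insertion = sprintf("%s%dins", aa_ref, codon),
    sprintf("%s%ddelins", aa_ref, codon))
  list(class = "inframe_indel", protein_notation = notation,
       mutant_protein = prot_mut)
}
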