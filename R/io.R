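# Format readers and writers shared by all stages, plus the file-based
# pipeline orchestrator. All derived outputs are TSV (diff-able and
# test-friendly); run provenance goes to a JSON manifest.

#' Write contig sequences to FASTA
#' @param contigs named character vector of sequences
#' @param path output path
#' @export
write_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(unlist(contigs))
  names(x) <- names(contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read contig sequences from FASTA
#' @param path FASTA path
#' @return named character vector
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write the transcript exon table
#' @param exon_table data.frame (transcript_id, gene, contig, strand,
#'   exon_start, exon_end)
#' @param path output path
#' @export
write_transcripts <- function(exon_table, path) {
  utils::write.table(exon_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transcripts from an exon table and reference FASTA
#'
#' @param path exon-table TSV (one row per exon, rows ordered 5'->3' per
#'   transcript)
#' @param contigs named character vector of contig sequences
#' @return named list of `CodingTranscript` (by gene)
#' @export
read_transcripts <- function(path, contigs) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "contig", "strand", "exon_start",
            "exon_end")
  if (!all(need %in% names(tab)))
    stop("transcript table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(tab$transcript_id)) {
    rows <- tab[tab$transcript_id == id, , drop = FALSE]
    seq <- contigs[[rows$contig[1]]]
    if (is.null(seq)) stop("transcript ", id, ": contig not in FASTA")
    out[[rows$gene[1]]] <- coding_transcript(
      id, rows$gene[1], rows$contig[1], rows$strand[1],
      data.frame(start = rows$exon_start, end = rows$exon_end),
      contig_seq = seq)
  }
  out
}

#' Write variants as a minimal VCF v4.2
#'
#' Trimmed-allele records are converted to the VCF anchored-base
#' convention for indels (the base before the event is prepended, the
#' position moved to it). INFO carries ORIGIN, VAF, AD, DP and PID.
#'
#' @param variants data.frame with patient_id, variant_id, contig, pos,
#'   ref, alt, origin, vaf, alt_reads, depth
#' @param contigs named character vector of contig sequences (anchor bases)
#' @param path output path
#' @export
write_variants_vcf <- function(variants, contigs, path) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      nchar(contigs)),
              "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"germline or somatic\">",
              "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"variant allele fraction\">",
              "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"alt read count\">",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
              "##INFO=<ID=PID,Number=1,Type=String,Description=\"patient id\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    pos <- v$pos; ref <- v$ref; alt <- v$alt
    if (nchar(ref) == 0 || nchar(alt) == 0) {   # indel: anchored-base form
      anchor_pos <- pos - 1L
      anchor <- substr(contigs[[v$contig]], anchor_pos, anchor_pos)
      ref <- paste0(anchor, ref); alt <- paste0(anchor, alt)
      pos <- anchor_pos
    }
    info <- sprintf("ORIGIN=%s;VAF=%s;AD=%s;DP=%s;PID=%s", v$origin,
                    signif(v$vaf, 6), v$alt_reads, v$depth, v$patient_id)
    body[i] <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s", v$contig, pos,
                       v$variant_id, ref, alt, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variants from VCF
#'
#' Parses with vcfR and converts anchored-base indels to the package's
#' trimmed-allele convention.
#'
#' @param path VCF path
#' @return data.frame with patient_id, variant_id, contig, pos, ref, alt,
#'   origin, vaf, alt_reads, depth
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  get <- function(key) vapply(info, function(s) {
    hit <- regmatches(s, regexpr(paste0("(^|;)", key, "=[^;]*"), s))
    if (length(hit) == 0) NA_character_ else sub(paste0(".*", key, "="), "", hit)
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(patient_id = get("PID"), variant_id = fix$ID,
                    contig = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, origin = get("ORIGIN"),
                    vaf = as.numeric(get("VAF")),
                    alt_reads = as.integer(get("AD")),
                    depth = as.integer(get("DP")), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    nv <- normalize_variant(list(pos = out$pos[i], ref = out$ref[i],
                                 alt = out$alt[i]))
    out$pos[i] <- nv$pos; out$ref[i] <- nv$ref; out$alt[i] <- nv$alt
  }
  out
}

#' Write/read a generic TSV
#' @param df data.frame
#' @param path file path
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a segment table (FACETS-style dialect)
#'
#' Columns contig, start, end, tcn, lcn (and patient_id when present);
#' profile-level purity/ploidy go into "#key=value" header lines.
#'
#' @param segments data.frame with contig, start, end, total_cn, minor_cn
#' @param path output path
#' @param purity,ploidy optional profile metadata
#' @export
write_segments <- function(segments, path, purity = NA, ploidy = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(purity)) writeLines(sprintf("#purity=%s", purity), con)
  if (!is.na(ploidy)) writeLines(sprintf("#ploidy=%s", ploidy), con)
  out <- segments
  names(out)[names(out) == "total_cn"] <- "tcn"
  names(out)[names(out) == "minor_cn"] <- "lcn"
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment table
#'
#' Tolerates missing lcn values (NA; such segments are excluded from
#' LOH-dependent logic downstream, with a message).
#'
#' @param path segment TSV path
#' @return list(segments, purity, ploidy)
#' @export
read_segments <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getmeta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) == 0) NA_real_ else as.numeric(sub(".*=", "", hit[1]))
  }
  tab <- utils::read.delim(textConnection(grep("^#", lines, invert = TRUE,
                                               value = TRUE)),
                           stringsAsFactors = FALSE)
  names(tab)[names(tab) == "tcn"] <- "total_cn"
  names(tab)[names(tab) == "lcn"] <- "minor_cn"
  need <- c("contig", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(tab)))
    stop("segment table must have columns contig, start, end, tcn, lcn")
  if (anyNA(tab$minor_cn))
    message(sum(is.na(tab$minor_cn)),
            " segment(s) lack minor copy number; excluded from LOH logic")
  list(segments = tab, purity = getmeta("purity"), ploidy = getmeta("ploidy"))
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits reference FASTA, transcript TSV, germline and somatic VCFs, pair
#' TSV, segment TSV, cohort TSV and a ground-truth JSON.
#'
#' @param sim a [simulate_cohort()] result
#' @param outdir output directory (created if needed)
#' @return invisibly, the named vector of file paths
#' @export
write_cohort_bundle <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$reference$contigs, p("reference.fa"))
  write_transcripts(sim$reference$exon_table, p("transcripts.tsv"))
  write_variants_vcf(sim$germline, sim$reference$contigs, p("germline.vcf"))
  write_variants_vcf(sim$somatic, sim$reference$contigs, p("somatic.vcf"))
  write_tsv(sim$pairs, p("pairs.tsv"))
  write_segments(sim$segments, p("segments.tsv"))
  write_tsv(sim$cohort, p("cohort.tsv"))
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(reference = p("reference.fa"), transcripts = p("transcripts.tsv"),
              germline = p("germline.vcf"), somatic = p("somatic.vcf"),
              pairs = p("pairs.tsv"), segments = p("segments.tsv"),
              cohort = p("cohort.tsv"), truth = p("truth.json")))
}

#' Run the full detection pipeline from files
#'
#' Reads a cohort bundle (as written by [write_cohort_bundle()] or prepared
#' by hand in the same dialects), applies the somatic filters, calls
#' reversions per patient, classifies germline zygosity, and writes
#' calls.tsv, zygosity.tsv, filters.tsv and a JSON run manifest to
#' `outdir`.
#'
#' @param paths named list/vector with reference, transcripts, germline,
#'   somatic, pairs, segments, cohort
#' @param outdir output directory
#' @param cfg a [filter_config()]
#' @param window_aa,min_pairs,vaf_tolerance detection thresholds
#' @return invisibly, list(calls, zygosity, manifest)
#' @export
run_pipeline <- function(paths, outdir, cfg = filter_config(),
                         window_aa = 200L, min_pairs = 3L,
                         vaf_tolerance = 0.10) {
  for (f in c("reference", "transcripts", "germline", "somatic", "pairs",
              "segments", "cohort")) {
    if (is.null(paths[[f]]) || !file.exists(paths[[f]]))
      stop("missing input path: ", f)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  contigs <- read_fasta(paths[["reference"]])
  txs <- read_transcripts(paths[["transcripts"]], contigs)
  germline <- read_variants_vcf(paths[["germline"]])
  somatic <- read_variants_vcf(paths[["somatic"]])
  pairs <- read_tsv(paths[["pairs"]])
  segtab <- read_segments(paths[["segments"]])$segments
  cohort <- read_tsv(paths[["cohort"]])

  somatic <- filter_somatic_calls(somatic, cfg)
  filt <- somatic[, c("patient_id", "variant_id", "retained", "reason")]
  somatic <- somatic[somatic$retained, , drop = FALSE]

  calls <- list(); zyg <- list()
  for (p in unique(germline$patient_id)) {
    gv <- .df_to_variants(germline[germline$patient_id == p, , drop = FALSE])
    sv <- .df_to_variants(somatic[somatic$patient_id == p, , drop = FALSE])
    pp <- pairs[pairs$patient_id == p, , drop = FALSE]
    sg <- segtab[segtab$patient_id == p, , drop = FALSE]
    pu <- cohort$purity[cohort$patient_id == p][1]
    cl <- call_reversions(p, gv, sv, txs, pairs = pp, segments = sg,
                          purity = pu, window_aa = window_aa,
                          min_pairs = min_pairs,
                          vaf_tolerance = vaf_tolerance)
    if (nrow(cl) > 0) calls[[length(calls) + 1L]] <- cl
    prof <- segment_profile(sg[, c("contig", "start", "end", "total_cn",
                                   "minor_cn")], purity = pu)
    for (v in gv) {
      z <- classify_zygosity(v, prof)
      zyg[[length(zyg) + 1L]] <- data.frame(
        patient_id = p, variant_id = z$variant_id, class = z$class,
        best_m = z$best_m, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else .empty_calls()
  zyg <- if (length(zyg)) do.call(rbind, zyg) else
    data.frame(patient_id = character(0), variant_id = character(0),
               class = character(0), best_m = integer(0))

  write_tsv(calls, file.path(outdir, "calls.tsv"))
  write_tsv(zyg, file.path(outdir, "zygosity.tsv"))
  write_tsv(filt, file.path(outdir, "filters.tsv"))
  manifest <- list(
    inputs = as.list(paths),
    n_patients = nrow(cohort), n_reversion_calls = nrow(calls),
    thresholds = list(window_aa = window_aa, min_pairs = min_pairs,
                      vaf_tolerance = vaf_tolerance),
    version = as.character(utils::packageVersion("reversionscan")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(calls = calls, zygosity = zyg, manifest = manifest))
}
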