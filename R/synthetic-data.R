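# Synthetic-data generator: toy reference transcripts, simulated cohorts
# with planted germline truncating variants and frame-restoring somatic
# reversions, segment profiles with planted scar counts, and 96-channel
# catalogs drawn from known signature mixtures. Every generated object
# carries its ground truth so each pipeline stage can be tested without
# external data.

.SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA"))

#' Generate a random coding reference
#'
#' Produces toy transcripts with valid CDSs (ATG start, single terminal
#' stop, no internal stop) embedded in contigs with flanks and introns.
#' Transcripts alternate strand; the first two are named BRCA1 and BRCA2.
#' Deterministic per seed.
#'
#' @param seed integer seed
#' @param n_transcripts number of transcripts (default 2)
#' @param cds_codons codons per CDS including start and stop (recycled;
#'   default 600)
#' @param n_exons exons per transcript (recycled; default 3)
#' @return list with `transcripts` (named list of `CodingTranscript`),
#'   `contigs` (named character vector of contig sequences), and
#'   `exon_table` (data.frame, one row per exon)
#' @export
make_reference <- function(seed = 1L, n_transcripts = 2L, cds_codons = 600L,
                           n_exons = 3L) {
  set.seed(seed)
  cds_codons <- rep_len(cds_codons, n_transcripts)
  n_exons <- rep_len(n_exons, n_transcripts)
  genes <- c("BRCA1", "BRCA2",
             if (n_transcripts > 2) paste0("GENE", seq(3, n_transcripts)))
  txs <- list(); contigs <- character(0); rows <- list()
  for (t in seq_len(n_transcripts)) {
    nc <- cds_codons[t]
    stopifnot(nc >= 10)
    cds <- paste0("ATG",
                  paste(sample(.SENSE_CODONS, nc - 2L, replace = TRUE),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    L <- nchar(cds)
    k <- min(n_exons[t], max(1L, L %/% 90L))
    cuts <- sort(sample(seq(30L, L - 30L), k - 1L))
    bounds <- cbind(c(1L, cuts + 1L), c(cuts, L))
    flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
    layout <- flank(100L)
    exon_start <- integer(k); exon_end <- integer(k)
    for (e in seq_len(k)) {
      exon_start[e] <- nchar(layout) + 1L
      layout <- paste0(layout, substr(cds, bounds[e, 1L], bounds[e, 2L]))
      exon_end[e] <- nchar(layout)
      if (e < k) layout <- paste0(layout, flank(sample(80:150, 1L)))
    }
    layout <- paste0(layout, flank(100L))
    strand <- if (t %% 2L == 1L) "+" else "-"
    contig_name <- sprintf("ctg%d", t)
    if (strand == "+") {
      contig_seq <- layout
      exons <- data.frame(start = exon_start, end = exon_end)
    } else {
      Lc <- nchar(layout)
      contig_seq <- revcomp(layout)
      exons <- data.frame(start = Lc - exon_end + 1L,
                          end = Lc - exon_start + 1L)
    }
    tx <- coding_transcript(sprintf("TX%d", t), genes[t], contig_name,
                            strand, exons, cds_sequence = cds,
                            contig_seq = contig_seq)
    txs[[genes[t]]] <- tx
    contigs[contig_name] <- contig_seq
    rows[[t]] <- data.frame(transcript_id = tx$transcript_id, gene = genes[t],
                            contig = contig_name, strand = strand,
                            exon_start = exons$start, exon_end = exons$end,
                            stringsAsFactors = FALSE)
  }
  list(transcripts = txs, contigs = contigs,
       exon_table = do.call(rbind, rows))
}

# map a CDS-level change back to a genomic Variant on the transcript's
# contig (trimmed-allele convention). The change must sit within a single
# exon; returns NULL if it does not.
cds_change_to_variant <- function(tx, change, variant_id,
                                  origin = "somatic", vaf = NA_real_,
                                  alt_reads = NA_integer_,
                                  depth = NA_integer_) {
  s <- change$cds_start
  if (change$ref_len > 0) {
    idx <- tx$cds_genomic[seq(s, s + change$ref_len - 1L)]
    if (length(idx) > 1 && any(abs(diff(idx)) != 1L)) return(NULL)
    gstart <- min(idx)
    gref <- if (tx$strand == "+") change$ref else revcomp(change$ref)
    galt <- if (change$alt_len == 0) "" else
      if (tx$strand == "+") change$alt else revcomp(change$alt)
  } else {
    g0 <- tx$cds_genomic[s - 1L]; g1 <- tx$cds_genomic[s]
    if (abs(g1 - g0) != 1L) return(NULL)
    gstart <- max(g0, g1)               # insertion between gstart-1, gstart
    gref <- ""
    galt <- if (tx$strand == "+") change$alt else revcomp(change$alt)
  }
  variant(variant_id, tx$contig, gstart, gref, galt, origin = origin,
          vaf = vaf, alt_reads = alt_reads, depth = depth)
}

#' Simulation configuration
#'
#' Study conditions for the cohort simulator. Lineage mix and per-group
#' germline carrier rates follow the canonical pan-cancer cohort structure
#' (30\% BRCA-associated lineages; carrier rates 5.5\% in BRCA-associated
#' vs 1.4\% elsewhere). Reversions arise only in platinum-exposed truncating
#' carriers; the mechanism mix reflects the observed taxonomy
#' (deletions greatly outnumbering insertions and delins, a minority of the
#' deletions encompassing the germline site).
#'
#' @param seed integer seed
#' @param n_patients cohort size
#' @param lineage_mix named proportions summing to 1
#' @param carrier_rate_by_group named fractions for brca_associated / other
#' @param platinum_rate fraction of carriers with platinum exposure
#' @param reversion_rate_post_platinum reversion probability for
#'   platinum-exposed truncating carriers
#' @param polyclonal_rate probability a reversion-positive patient carries
#'   two independent reversions
#' @param mechanism_probs named probabilities over compensating_deletion,
#'   insertion, delins, encompassing_deletion
#' @param read_pairs_cis_min,read_pairs_cis_lambda cis spanning-pair count
#'   is min + Poisson(lambda)
#' @param pair_miscall_rate per-pair allele miscall probability
#' @param loss_of_wt_rate loss-of-wild-type probability for non-reversion
#'   carriers (reversion patients always show loss of wild type)
#' @param purity_range uniform purity interval
#' @param cds_codons toy transcript length in codons
#' @return list of class `SimulationConfig`
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 2000L,
                              lineage_mix = c(breast = 0.12, ovarian = 0.05,
                                              prostate = 0.07, pancreas = 0.06,
                                              lung = 0.14, colorectal = 0.09,
                                              other = 0.47),
                              carrier_rate_by_group = c(brca_associated = 0.055,
                                                        other = 0.014),
                              platinum_rate = 0.6,
                              reversion_rate_post_platinum = 0.25,
                              polyclonal_rate = 0.18,
                              mechanism_probs = c(compensating_deletion = 8 / 13,
                                                  insertion = 1 / 13,
                                                  delins = 1 / 13,
                                                  encompassing_deletion = 3 / 13),
                              read_pairs_cis_min = 5L,
                              read_pairs_cis_lambda = 3,
                              pair_miscall_rate = 0,
                              loss_of_wt_rate = 0.6,
                              purity_range = c(0.2, 0.9),
                              cds_codons = 600L) {
  stopifnot(abs(sum(lineage_mix) - 1) < 1e-8,
            abs(sum(mechanism_probs) - 1) < 1e-8,
            all(carrier_rate_by_group >= 0 & carrier_rate_by_group <= 1),
            platinum_rate >= 0, platinum_rate <= 1,
            reversion_rate_post_platinum >= 0,
            reversion_rate_post_platinum <= 1,
            pair_miscall_rate >= 0, pair_miscall_rate <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

# construct a frame-restoring somatic change for a germline change at codon
# g_codon; retries positions until the ORF test passes (the bridged frame
# must not contain a stop). Returns NULL if no candidate found.
.plant_reversion <- function(tx, g_change, mechanism, window_aa = 180L,
                             max_try = 200L) {
  L <- nchar(tx$cds_sequence)
  g_shift <- g_change$net_shift
  g_pos <- g_change$cds_start
  for (i in seq_len(max_try)) {
    if (mechanism == "encompassing_deletion") {
      lead <- sample(5:250, 1L)
      tail <- sample(5:250, 1L)
      s0 <- max(4L, g_pos - lead)
      e0 <- min(L - 3L, g_pos + max(g_change$ref_len - 1L, 0L) + tail)
      len <- e0 - s0 + 1L
      len <- len - (len %% 3L)          # own shift must be in-frame
      if (len < 3L) next
      e0 <- s0 + len - 1L
      if (e0 < g_pos + max(g_change$ref_len - 1L, 0L)) next
      ch <- cds_change(s0, substr(tx$cds_sequence, s0, e0), "")
    } else {
      offset <- sample(c(-window_aa:-1, 1:window_aa), 1L) * 3L
      s0 <- g_pos + offset + sample(0:2, 1L)
      if (s0 < 4L || s0 > L - 9L) next
      if (mechanism == "compensating_deletion") {
        # deletion of length l shifts by -l; need g_shift - l == 0 mod 3
        len <- (g_shift %% 3L) + sample(c(0L, 3L), 1L)
        if (len == 0L) len <- 3L        # germline already in-frame: skip
        if (s0 + len - 1L > L - 3L) next
        span <- c(s0, s0 + len - 1L)
        gspan <- c(g_pos, g_pos + max(g_change$ref_len - 1L, 0L))
        if (span[1L] <= gspan[2L] && gspan[1L] <= span[2L]) next
        ch <- cds_change(s0, substr(tx$cds_sequence, span[1L], span[2L]), "")
      } else if (mechanism == "insertion") {
        len <- (3L - (g_shift %% 3L)) %% 3L
        if (len == 0L) next
        ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
        if (s0 <= g_pos && s0 > g_pos - 2L) next
        ch <- cds_change(s0, "", ins)
      } else {                           # delins
        rl <- sample(2:6, 1L)
        al <- rl + ((-g_shift) %% 3L) - 3L
        if (al < 1L) al <- al + 3L
        if (al == rl) al <- al + 3L
        if (s0 + rl - 1L > L - 3L) next
        span <- c(s0, s0 + rl - 1L)
        gspan <- c(g_pos, g_pos + max(g_change$ref_len - 1L, 0L))
        if (span[1L] <= gspan[2L] && gspan[1L] <= span[2L]) next
        alt <- paste(sample(c("A", "C", "G", "T"), al, TRUE), collapse = "")
        ref <- substr(tx$cds_sequence, span[1L], span[2L])
        if (identical(ref, alt)) next
        ch <- cds_change(s0, ref, alt)
      }
    }
    ok <- tryCatch(check_orf_restoration(tx, g_change, ch),
                   error = function(e) NULL)
    if (!is.null(ok) && ok$restored &&
        ((mechanism == "encompassing_deletion") ==
           (ok$mechanism == "encompassing_deletion")))
      return(ch)
  }
  NULL
}

#' Simulate a cohort with planted reversion mutations
#'
#' Draws lineages and germline carrier status per the configured rates,
#' plants a frameshift germline lesion in BRCA1 or BRCA2 for each carrier,
#' and gives a configurable fraction of platinum-exposed carriers one or
#' two frame-restoring somatic reversions with supporting read pairs (or,
#' for encompassing deletions, a loss-of-wild-type segment and a consistent
#' germline VAF). Deterministic per seed.
#'
#' @param cfg a [simulation_config()]
#' @return list with `reference`, `cohort` (data.frame), `germline` and
#'   `somatic` (data.frames of variants with patient_id), `pairs`,
#'   `segments`, and `truth` (per-patient planted facts)
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  ref <- make_reference(seed = cfg$seed + 104729L, n_transcripts = 2L,
                        cds_codons = cfg$cds_codons)
  txs <- ref$transcripts
  contig_len <- vapply(ref$contigs, nchar, integer(1))

  n <- cfg$n_patients
  lineage <- sample(names(cfg$lineage_mix), n, TRUE, prob = cfg$lineage_mix)
  assoc <- lineage %in% BRCA_ASSOCIATED_LINEAGES
  carrier_rate <- ifelse(assoc, cfg$carrier_rate_by_group[["brca_associated"]],
                         cfg$carrier_rate_by_group[["other"]])
  carrier <- stats::runif(n) < carrier_rate
  gene <- ifelse(carrier, sample(c("BRCA1", "BRCA2"), n, TRUE,
                                 prob = c(0.4, 0.6)), "none")
  platinum <- carrier & (stats::runif(n) < cfg$platinum_rate)
  purity <- stats::runif(n, cfg$purity_range[1L], cfg$purity_range[2L])

  pid <- sprintf("P%04d", seq_len(n))
  germ_rows <- list(); som_rows <- list(); pair_rows <- list()
  seg_rows <- list(); truth <- list()
  loss_of_wt <- logical(n)
  vid <- 0L

  n_codons <- nchar(txs[[1]]$cds_sequence) / 3L
  for (i in seq_len(n)) {
    segs <- data.frame(patient_id = pid[i],
                       contig = names(contig_len),
                       start = 1L, end = unname(contig_len),
                       total_cn = 2L, minor_cn = 1L,
                       stringsAsFactors = FALSE)
    rev_entries <- list()
    if (carrier[i]) {
      tx <- txs[[gene[i]]]
      is_rev <- platinum[i] &&
        stats::runif(1) < cfg$reversion_rate_post_platinum
      loss_of_wt[i] <- is_rev || stats::runif(1) < cfg$loss_of_wt_rate

      # plant a 1-nt frameshift germline deletion mid-CDS, within one exon
      g_change <- NULL
      while (is.null(g_change)) {
        g_pos <- sample(seq(720L, nchar(tx$cds_sequence) - 720L), 1L)
        cand <- cds_change(g_pos, substr(tx$cds_sequence, g_pos, g_pos), "")
        vid <- vid + 1L
        g_vaf <- if (loss_of_wt[i]) expected_vaf(purity[i], 2L, 2L)
                 else expected_vaf(purity[i], 2L, 1L)
        gv <- cds_change_to_variant(
          tx, cand, sprintf("g%05d", vid), origin = "germline",
          vaf = g_vaf, alt_reads = as.integer(round(g_vaf * 120)),
          depth = 120L)
        if (!is.null(gv)) g_change <- cand
      }
      germ_rows[[length(germ_rows) + 1L]] <-
        data.frame(patient_id = pid[i], variant_id = gv$variant_id,
                   contig = gv$contig, pos = gv$pos, ref = gv$ref,
                   alt = gv$alt, origin = "germline", vaf = gv$vaf,
                   alt_reads = gv$alt_reads, depth = gv$depth,
                   stringsAsFactors = FALSE)
      if (loss_of_wt[i])
        segs$minor_cn[segs$contig == tx$contig] <- 0L

      if (is_rev) {
        n_rev <- 1L + (stats::runif(1) < cfg$polyclonal_rate)
        mechs <- sample(names(cfg$mechanism_probs), n_rev, TRUE,
                        prob = cfg$mechanism_probs)
        for (j in seq_len(n_rev)) {
          sv <- NULL
          for (try in 1:25) {           # re-plant if the lesion crosses an exon
            s_change <- .plant_reversion(tx, g_change, mechs[j])
            if (is.null(s_change)) next
            vid <- vid + 1L
            sv <- cds_change_to_variant(
              tx, s_change, sprintf("s%05d", vid), origin = "somatic",
              vaf = expected_vaf(purity[i], 2L, 1L),
              alt_reads = as.integer(round(expected_vaf(purity[i], 2L, 1L) * 120)),
              depth = 120L)
            if (!is.null(sv)) break
          }
          if (is.null(sv)) next
          som_rows[[length(som_rows) + 1L]] <-
            data.frame(patient_id = pid[i], variant_id = sv$variant_id,
                       contig = sv$contig, pos = sv$pos, ref = sv$ref,
                       alt = sv$alt, origin = "somatic", vaf = sv$vaf,
                       alt_reads = sv$alt_reads, depth = sv$depth,
                       pop_occurrence = 0L, stringsAsFactors = FALSE)
          if (mechs[j] != "encompassing_deletion") {
            n_cis <- cfg$read_pairs_cis_min +
              stats::rpois(1L, cfg$read_pairs_cis_lambda)
            germ_all <- rep("alt", n_cis)
            som_all <- rep("alt", n_cis)
            if (!loss_of_wt[i]) {       # wild-type fragments exist too
              germ_all <- c(germ_all, "ref", "ref")
              som_all <- c(som_all, "ref", "ref")
            }
            if (cfg$pair_miscall_rate > 0) {
              flip <- stats::runif(length(germ_all)) < cfg$pair_miscall_rate
              som_all[flip] <- ifelse(som_all[flip] == "alt", "ref", "alt")
            }
            pair_rows[[length(pair_rows) + 1L]] <- data.frame(
              patient_id = pid[i],
              fragment_id = sprintf("%s_f%03d", sv$variant_id,
                                    seq_along(germ_all)),
              germ_variant_id = gv$variant_id,
              som_variant_id = sv$variant_id,
              germ_allele = germ_all, som_allele = som_all,
              stringsAsFactors = FALSE)
          }
          rev_entries[[length(rev_entries) + 1L]] <-
            list(somatic_id = sv$variant_id, mechanism = mechs[j],
                 phasing = if (mechs[j] == "encompassing_deletion")
                   "loh_inference" else "read_pair")
        }
      }
      # passenger missense SNV in the carrier gene: an in-window candidate
      # that find_candidates must exclude
      p_pos <- sample(seq(g_change$cds_start - 90L, g_change$cds_start + 90L), 1L)
      ref_b <- substr(tx$cds_sequence, p_pos, p_pos)
      alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
      p_ch <- cds_change(p_pos, ref_b, alt_b)
      if (classify_consequence(tx, p_ch)$class == "missense") {
        vid <- vid + 1L
        pv <- cds_change_to_variant(tx, p_ch, sprintf("s%05d", vid),
                                    origin = "somatic",
                                    vaf = expected_vaf(purity[i], 2L, 1L),
                                    alt_reads = as.integer(round(expected_vaf(purity[i], 2L, 1L) * 120)),
                                    depth = 120L)
        if (!is.null(pv))
          som_rows[[length(som_rows) + 1L]] <-
            data.frame(patient_id = pid[i], variant_id = pv$variant_id,
                       contig = pv$contig, pos = pv$pos, ref = pv$ref,
                       alt = pv$alt, origin = "somatic", vaf = pv$vaf,
                       alt_reads = pv$alt_reads, depth = pv$depth,
                       pop_occurrence = 0L, stringsAsFactors = FALSE)
      }

      # trans decoy: a frame-restoring-capable somatic indel on the other
      # allele of a heterozygous carrier; only the phasing gate blocks it
      if (!is_rev && !loss_of_wt[i] && stats::runif(1) < 0.3) {
        d_change <- .plant_reversion(tx, g_change, "compensating_deletion")
        if (!is.null(d_change)) {
          vid <- vid + 1L
          dv <- cds_change_to_variant(tx, d_change, sprintf("s%05d", vid),
                                      origin = "somatic",
                                      vaf = expected_vaf(purity[i], 2L, 1L),
                                      alt_reads = as.integer(round(expected_vaf(purity[i], 2L, 1L) * 120)),
                                      depth = 120L)
          if (!is.null(dv)) {
            som_rows[[length(som_rows) + 1L]] <-
              data.frame(patient_id = pid[i], variant_id = dv$variant_id,
                         contig = dv$contig, pos = dv$pos, ref = dv$ref,
                         alt = dv$alt, origin = "somatic", vaf = dv$vaf,
                         alt_reads = dv$alt_reads, depth = dv$depth,
                         pop_occurrence = 0L, stringsAsFactors = FALSE)
            pair_rows[[length(pair_rows) + 1L]] <- data.frame(
              patient_id = pid[i],
              fragment_id = sprintf("%s_f%03d", dv$variant_id, 1:6),
              germ_variant_id = gv$variant_id,
              som_variant_id = dv$variant_id,
              germ_allele = c(rep("alt", 3), rep("ref", 3)),
              som_allele = c(rep("ref", 3), rep("alt", 3)),
              stringsAsFactors = FALSE)
          }
        }
      }

      truth[[pid[i]]] <- list(
        patient_id = pid[i], gene = gene[i],
        germline_id = gv$variant_id,
        germline_codon = affected_codon(g_change),
        loss_of_wt = loss_of_wt[i],
        reversions = rev_entries)
    }
    seg_rows[[length(seg_rows) + 1L]] <- segs
  }

  cohort <- data.frame(
    patient_id = pid, lineage = lineage, brca_associated = assoc,
    germline_status = gene, somatic_lof = "none",
    purity = purity, platinum = platinum,
    platinum_months = ifelse(platinum,
                             round(stats::rlnorm(n, log(5), 0.45), 1),
                             NA_real_),
    nonsynonymous_count = stats::rpois(n, 180L),
    callable_mb = 30, loss_of_wt = loss_of_wt,
    stringsAsFactors = FALSE)

  bind_or_empty <- function(rows, template) {
    if (length(rows) == 0) template else do.call(rbind, rows)
  }
  empty_var <- data.frame(patient_id = character(0), variant_id = character(0),
                          contig = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          origin = character(0), vaf = numeric(0),
                          alt_reads = integer(0), depth = integer(0),
                          stringsAsFactors = FALSE)
  empty_pairs <- data.frame(patient_id = character(0), fragment_id = character(0),
                            germ_variant_id = character(0),
                            som_variant_id = character(0),
                            germ_allele = character(0),
                            som_allele = character(0), stringsAsFactors = FALSE)
  list(reference = ref, cohort = cohort,
       germline = bind_or_empty(germ_rows, empty_var),
       somatic = bind_or_empty(som_rows,
                               cbind(empty_var, pop_occurrence = integer(0))),
       pairs = bind_or_empty(pair_rows, empty_pairs),
       segments = do.call(rbind, seg_rows),
       truth = truth, config = cfg)
}

#' Run reversion detection over a simulated cohort
#'
#' Convenience wrapper calling [call_reversions()] for every patient of a
#' [simulate_cohort()] bundle.
#'
#' @param sim a [simulate_cohort()] result
#' @return data.frame of reversion calls across the cohort
#' @export
scan_cohort <- function(sim) {
  txs <- sim$reference$transcripts
  out <- list()
  pts <- unique(c(sim$germline$patient_id, sim$somatic$patient_id))
  for (p in pts) {
    gv <- .df_to_variants(sim$germline[sim$germline$patient_id == p, ,
                                       drop = FALSE])
    sv <- .df_to_variants(sim$somatic[sim$somatic$patient_id == p, ,
                                      drop = FALSE])
    pp <- sim$pairs[sim$pairs$patient_id == p, , drop = FALSE]
    sg <- sim$segments[sim$segments$patient_id == p, , drop = FALSE]
    pu <- sim$cohort$purity[sim$cohort$patient_id == p]
    calls <- call_reversions(p, gv, sv, txs, pairs = pp, segments = sg,
                             purity = pu)
    if (nrow(calls) > 0) out[[length(out) + 1L]] <- calls
  }
  if (length(out) == 0) .empty_calls() else do.call(rbind, out)
}

.df_to_variants <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    variant(df$variant_id[i], df$contig[i], df$pos[i], df$ref[i], df$alt[i],
            origin = df$origin[i], vaf = df$vaf[i],
            alt_reads = df$alt_reads[i], depth = df$depth[i]))
}

# ---------------------------------------------------------------------------
# Scar-profile simulation

#' A toy genome build for scar-score simulation
#'
#' @param n_contigs number of contigs (default 16)
#' @param contig_length bp per contig (default 2e8)
#' @param cen centromere interval as c(start, end)
#' @return a [genome_build()]
#' @export
hrd_toy_build <- function(n_contigs = 16L, contig_length = 2e8,
                          cen = c(9.5e7, 1.05e8)) {
  genome_build(data.frame(contig = sprintf("chr%d", seq_len(n_contigs)),
                          length = contig_length,
                          cen_start = cen[1L], cen_end = cen[2L],
                          stringsAsFactors = FALSE))
}

#' Logistic detection sensitivity as a function of purity
#'
#' Stand-in model for the purity dependence of copy-number event detection:
#' `s(p) = 1 / (1 + exp(-slope * (p - midpoint)))`.
#'
#' @param purity purity in (0, 1]
#' @param slope,midpoint logistic parameters (defaults 10 and 0.35)
#' @return detection probability in (0, 1)
#' @export
detection_sensitivity <- function(purity, slope = 10, midpoint = 0.35) {
  1 / (1 + exp(-slope * (purity - midpoint)))
}

#' Simulate a segment profile with planted scar events
#'
#' Plants the requested numbers of LST, HRD-LOH and NtAI events on a toy
#' build, one event per chromosome arm, each constructed so that it
#' contributes to exactly one score: an LST event changes state mid-arm
#' between two balanced >= 10 Mb segments; an HRD-LOH event is an interior
#' 16 Mb minor-copy-0 segment insulated by sub-10 Mb buffers; an NtAI event
#' is a sub-10 Mb imbalanced segment at a telomere. Each event is then
#' independently detected with probability `s` (the logistic sensitivity at
#' the given purity, or 1 when `sens = 1`); undetected events leave the
#' baseline balanced state in place.
#'
#' @param scar_targets named or positional counts c(lst, hrd_loh, ntai)
#' @param purity tumor purity
#' @param build a [genome_build()] (default [hrd_toy_build()])
#' @param sens either the number 1 (perfect detection) or a list with
#'   `slope` and `midpoint` for [detection_sensitivity()]
#' @return list(profile, planted = c(lst, hrd_loh, ntai) actually planted,
#'   requested)
#' @export
simulate_segment_profile <- function(scar_targets, purity = 1,
                                     build = hrd_toy_build(),
                                     sens = 1) {
  tgt <- as.integer(scar_targets)
  stopifnot(length(tgt) == 3, all(tgt >= 0))
  names(tgt) <- c("lst", "hrd_loh", "ntai")
  arms <- do.call(rbind, lapply(seq_len(nrow(build$contigs)), function(i) {
    b <- build$contigs[i, ]
    rbind(data.frame(contig = b$contig, arm = "p", start = 1,
                     end = b$cen_start - 1, stringsAsFactors = FALSE),
          data.frame(contig = b$contig, arm = "q", start = b$cen_end + 1,
                     end = b$length, stringsAsFactors = FALSE))
  }))
  if (sum(tgt) > nrow(arms))
    stop("infeasible scar targets: more events than chromosome arms")
  s_prob <- if (identical(sens, 1)) 1
            else detection_sensitivity(purity, sens$slope, sens$midpoint)
  kinds <- rep(names(tgt), tgt)
  detected <- stats::runif(length(kinds)) < s_prob
  planted <- c(lst = 0L, hrd_loh = 0L, ntai = 0L)

  events <- vector("list", nrow(arms))   # per-arm event segment list
  for (k in seq_along(kinds)) {
    if (!detected[k]) next
    arm <- arms[k, ]
    alen <- arm$end - arm$start + 1
    ev <- switch(kinds[k],
      lst = {
        mid <- arm$start + floor(alen / 2)
        if (arm$arm == "p")
          data.frame(start = arm$start, end = mid, total_cn = 4L,
                     minor_cn = 2L)
        else
          data.frame(start = mid, end = arm$end, total_cn = 4L,
                     minor_cn = 2L)
      },
      hrd_loh = {
        s0 <- arm$start + 2e7
        rbind(data.frame(start = s0, end = s0 + 5e6 - 1, total_cn = 3L,
                         minor_cn = 1L),
              data.frame(start = s0 + 5e6, end = s0 + 2.1e7 - 1,
                         total_cn = 2L, minor_cn = 0L),
              data.frame(start = s0 + 2.1e7, end = s0 + 2.6e7 - 1,
                         total_cn = 3L, minor_cn = 1L))
      },
      ntai = {
        if (arm$arm == "p")
          data.frame(start = arm$start, end = arm$start + 8e6 - 1,
                     total_cn = 3L, minor_cn = 1L)
        else
          data.frame(start = arm$end - 8e6 + 1, end = arm$end,
                     total_cn = 3L, minor_cn = 1L)
      })
    events[[k]] <- cbind(contig = arm$contig, ev, stringsAsFactors = FALSE)
    planted[kinds[k]] <- planted[kinds[k]] + 1L
  }

  segs <- list()
  for (ct in build$contigs$contig) {
    clen <- build$contigs$length[build$contigs$contig == ct]
    ev <- do.call(rbind, Filter(Negate(is.null), events[arms$contig == ct]))
    ev <- if (is.null(ev)) ev else ev[order(ev$start), , drop = FALSE]
    cur <- 1
    if (!is.null(ev) && nrow(ev) > 0) {
      for (r in seq_len(nrow(ev))) {
        if (ev$start[r] > cur)
          segs[[length(segs) + 1L]] <- data.frame(
            contig = ct, start = cur, end = ev$start[r] - 1,
            total_cn = 2L, minor_cn = 1L, stringsAsFactors = FALSE)
        segs[[length(segs) + 1L]] <- data.frame(
          contig = ct, start = ev$start[r], end = ev$end[r],
          total_cn = ev$total_cn[r], minor_cn = ev$minor_cn[r],
          stringsAsFactors = FALSE)
        cur <- ev$end[r] + 1
      }
    }
    if (cur <= clen)
      segs[[length(segs) + 1L]] <- data.frame(
        contig = ct, start = cur, end = clen, total_cn = 2L, minor_cn = 1L,
        stringsAsFactors = FALSE)
  }
  profile <- segment_profile(do.call(rbind, segs), purity = purity)
  list(profile = profile, planted = planted, requested = tgt)
}

# ---------------------------------------------------------------------------
# Signature-mixture catalogs

#' Toy signature matrices for testing
#'
#' "disjoint" puts the two signatures on complementary halves of the 96
#' channels (maximal separation); "overlapping" draws two random smooth
#' profiles sharing support.
#'
#' @param type "disjoint" or "overlapping"
#' @param seed seed for the overlapping variant
#' @return a 96 x 2 [signature_matrix()]
#' @export
make_toy_signatures <- function(type = c("disjoint", "overlapping"),
                                seed = 1L) {
  type <- match.arg(type)
  if (type == "disjoint") {
    m <- matrix(0, 96, 2)
    m[1:48, 1] <- 1 / 48
    m[49:96, 2] <- 1 / 48
  } else {
    set.seed(seed)
    m <- matrix(stats::rgamma(192, shape = 1), 96, 2)
    m <- sweep(m, 2, colSums(m), `/`)
  }
  colnames(m) <- c("Signature.A", "Signature.B")
  signature_matrix(m)
}

#' Draw a mutation catalog from a known signature mixture
#'
#' Multinomial draw of `n_snvs` mutations from the mixture density
#' `sigs %*% weights`. Deterministic per seed.
#'
#' @param signature_mixture named weights on the simplex (names matching
#'   `colnames(sigs)`)
#' @param n_snvs number of mutations (> 0)
#' @param sigs a [signature_matrix()]
#' @param seed integer seed
#' @return list(catalog = `MutationCatalog96`, weights)
#' @export
simulate_catalog <- function(signature_mixture, n_snvs, sigs, seed = 1L) {
  sigs <- signature_matrix(sigs)
  w <- signature_mixture[colnames(sigs)]
  if (any(is.na(w))) stop("mixture names must match signature names")
  if (abs(sum(w) - 1) > 1e-8) stop("mixture must sum to 1")
  if (n_snvs <= 0) stop("n_snvs must be > 0")
  set.seed(seed)
  p <- as.numeric(sigs %*% w)
  counts <- as.integer(stats::rmultinom(1L, n_snvs, p))
  names(counts) <- rownames(sigs)
  list(catalog = structure(counts, class = "MutationCatalog96"),
       weights = w)
}
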