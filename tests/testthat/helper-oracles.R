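# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths: translation goes
# through seqinr, mutation through character-level splicing, Fisher p-values
# through explicit hypergeometric enumeration.

# single-exon toy transcript on a generated contig; the CDS is embedded
# with 50 nt flanks (reverse-complemented for "-" strand)
toy_tx <- function(cds, strand = "+", gene = "BRCA2", contig = "ctgT") {
  set.seed(nchar(cds))
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  layout <- paste0(flank(50), cds, flank(50))
  L <- nchar(layout)
  if (strand == "+") {
    contig_seq <- layout
    exons <- data.frame(start = 51L, end = 50L + nchar(cds))
  } else {
    contig_seq <- revcomp(layout)
    exons <- data.frame(start = L - (50L + nchar(cds)) + 1L, end = L - 50L)
  }
  tx <- coding_transcript("TXTOY", gene, contig, strand, exons,
                          cds_sequence = cds, contig_seq = contig_seq)
  list(tx = tx, contig_seq = contig_seq)
}

# a CDS that translates cleanly in every frame: poly-AAA body reads as
# lysines under any shift, so frame restoration is never blocked by a
# bridged-frame stop
polyA_cds <- function(n_codons) {
  paste0("ATG", strrep("AAA", n_codons - 2L), "TAA")
}

# random CDS without internal in-frame stops (rejection sampling on codons)
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# character-level splice oracle for applying one or two changes (germline g
# optionally annihilated by an encompassing somatic deletion s)
splice_oracle <- function(cds, changes) {
  chars <- strsplit(cds, "")[[1]]
  keep <- rep(TRUE, length(chars))
  ins <- vector("list", length(chars) + 1L)
  for (ch in changes) {
    if (ch$ref_len > 0)
      keep[seq(ch$cds_start, ch$cds_start + ch$ref_len - 1L)] <- FALSE
    if (ch$alt_len > 0)
      ins[[ch$cds_start]] <- c(ins[[ch$cds_start]], ch$alt)
  }
  out <- character(0)
  for (i in seq_along(chars)) {
    if (!is.null(ins[[i]])) out <- c(out, ins[[i]])
    if (keep[i]) out <- c(out, chars[i])
  }
  paste(out, collapse = "")
}

# ORF-restoration oracle: masks deleted positions of the original CDS,
# splices insertions, then scans codons directly. `g` is annihilated when
# the somatic deletion covers its span.
oracle_restored <- function(cds, g, s) {
  gs <- c(g$cds_start, g$cds_start + max(g$ref_len - 1L, 0L))
  ss <- c(s$cds_start, s$cds_start + s$ref_len - 1L)
  g_gone <- s$kind == "deletion" &&
    (if (g$ref_len == 0) g$cds_start > ss[1] && g$cds_start <= ss[2]
     else gs[1] >= ss[1] && gs[2] <= ss[2])
  mut <- splice_oracle(cds, if (g_gone) list(s) else list(g, s))
  n <- nchar(mut)
  if (n %% 3L != 0L) return(FALSE)
  codons <- substring(mut, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  st <- which(codons %in% c("TAA", "TAG", "TGA"))
  length(st) > 0 && st[1] == n / 3L
}

# translation oracle through seqinr (independent of the package's table
# lookup); returns protein up to but excluding the first stop
oracle_translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  aa <- seqinr::translate(strsplit(substr(seq, 1L, n), "")[[1]])
  st <- which(aa == "*")
  if (length(st) > 0) aa <- aa[seq_len(st[1] - 1L)]
  paste(aa, collapse = "")
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0L, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# the 12-variant filter panel: one variant per rule branch, survivors
# hand-enumerated (see test-variant-filters)
filter_panel <- function() {
  data.frame(
    variant_id = sprintf("v%02d", 1:12),
    contig = "ctg1",
    pos = c(100L, 500L, 900L, 1300L, 1700L, 2100L, 2500L, 2900L, 3300L,
            3700L, 4100L, 3350L),
    vaf = c(0.30, 0.04, 0.04, 0.04, 0.04, 0.06, 0.30, 0.30, 0.04, NA,
            0.30, 0.30),
    alt_reads = c(30L, 3L, 3L, 3L, 5L, 3L, 30L, 30L, 3L, 30L, 30L, 30L),
    depth = c(100L, 15L, 15L, 30L, 15L, 15L, 100L, 100L, 15L, 100L, 100L,
              100L),
    pop_occurrence = c(0L, 0L, 0L, 0L, 0L, 0L, 10L, 9L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  # v01 clean pass            v02 low_support (all three clauses)
  # v03 whitelisted rescue    v04 depth clause fails -> retained
  # v05 read clause fails     v06 vaf clause fails
  # v07 population >= 10      v08 population 9 -> retained
  # v09 blacklist interval    v10 missing vaf -> indeterminate, retained
  # v11 clean pass            v12 blacklisted but whitelisted -> retained
}

filter_panel_config <- function() {
  filter_config(blacklist = data.frame(contig = "ctg1", start = 3200L,
                                       end = 3400L),
                whitelist = c("v03", "v12"))
}
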