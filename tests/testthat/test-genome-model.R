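# CDS projection, mutation application and consequence classification.

test_that("projection maps a deep coding deletion to its HGVS-style coordinate", {
  ref <- make_reference(seed = 42, n_transcripts = 1, cds_codons = 2100,
                        n_exons = 4)
  tx <- ref$transcripts[[1]]
  # deletion of the single base at coding position 5946
  gpos <- tx$cds_genomic[5946]
  base <- substr(tx$cds_sequence, 5946, 5946)
  gref <- if (tx$strand == "-") chartr("ACGT", "TGCA", base) else base
  v <- variant("d5946", tx$contig, gpos, gref, "", origin = "germline")
  ch <- project_to_cds(v, tx)
  expect_equal(ch$cds_start, 5946L)
  expect_equal(ch$ref_len, 1L)
  expect_equal(ch$alt_len, 0L)
  expect_equal(ch$net_shift, -1L)
  # first affected codon: ceiling(5946 / 3) = 1982
  expect_equal(affected_codon(ch), 1982L)
  expect_equal(classify_consequence(tx, ch)$class, "frameshift")
})

test_that("intronic and flanking variants project to nothing", {
  ref <- make_reference(seed = 5, n_transcripts = 1, cds_codons = 120,
                        n_exons = 2)
  tx <- ref$transcripts[[1]]
  intron_pos <- setdiff(seq(min(tx$exons$start), max(tx$exons$end)),
                        tx$cds_genomic)[1]
  contig_seq <- ref$contigs[[tx$contig]]
  b <- substr(contig_seq, intron_pos, intron_pos)
  v <- variant("vi", tx$contig, intron_pos, b, setdiff(c("A","C","G","T"), b)[1])
  expect_null(project_to_cds(v, tx))
  v2 <- variant("vf", tx$contig, 3L, substr(contig_seq, 3, 3), "")
  expect_null(project_to_cds(v2, tx))
})

test_that("minus-strand projection reverse-complements alleles", {
  # hand-computed: cds base 1 is the A of ATG; on the minus strand the
  # contig carries its complement T at the highest-coordinate CDS position
  fix <- toy_tx(random_cds(10, seed = 3), strand = "-")
  tx <- fix$tx
  gpos <- tx$cds_genomic[1]
  expect_equal(substr(fix$contig_seq, gpos, gpos), "T")
  v <- variant("vm", tx$contig, gpos, "T", "C")
  ch <- project_to_cds(v, tx)
  expect_equal(ch$cds_start, 1L)
  expect_equal(ch$ref, "A")
  expect_equal(ch$alt, "G")
})

test_that("reference-inconsistent variants are rejected as corrupt input", {
  fix <- toy_tx(random_cds(20, seed = 8))
  tx <- fix$tx
  gpos <- tx$cds_genomic[10]
  wrong <- setdiff(c("A", "C", "G", "T"),
                   substr(tx$cds_sequence, 10, 10))[1]
  v <- variant("vx", tx$contig, gpos, wrong, "")
  expect_error(project_to_cds(v, tx), "inconsistent")
})

test_that("VCF anchored-base indels normalize to trimmed alleles", {
  del <- normalize_variant(list(pos = 100L, ref = "AT", alt = "A"))
  expect_equal(del$pos, 101L); expect_equal(del$ref, "T"); expect_equal(del$alt, "")
  ins <- normalize_variant(list(pos = 100L, ref = "A", alt = "AT"))
  expect_equal(ins$pos, 101L); expect_equal(ins$ref, ""); expect_equal(ins$alt, "T")
  snv <- normalize_variant(list(pos = 100L, ref = "C", alt = "T"))
  expect_equal(snv$pos, 100L); expect_equal(snv$ref, "C")
})

test_that("apply_changes handles identity, inverses and the splice oracle", {
  expect_equal(apply_changes("ATGAAATAG", list()), "ATGAAATAG")
  # delete then re-insert the same base at position 4: exact inverse pair,
  # applied as independent sequential edits
  del4 <- cds_change(4L, "A", "")
  expect_equal(apply_changes(apply_changes("ATGAAATAG", list(del4)),
                             list(cds_change(4L, "", "A"))),
               "ATGAAATAG")
  cds <- random_cds(20, seed = 11)
  ch <- list(cds_change(10L, substr(cds, 10, 10), ""),
             cds_change(25L, substr(cds, 25, 26), ""))
  out <- apply_changes(cds, ch)
  expect_equal(nchar(out), 57L)
  expect_equal(out, splice_oracle(cds, ch))
})

test_that("partially overlapping changes are rejected; encompassing deletions absorb", {
  cds <- random_cds(30, seed = 2)
  expect_error(apply_changes(cds, list(cds_change(10L, substr(cds, 10, 14), ""),
                                       cds_change(12L, substr(cds, 12, 20), ""))),
               "overlap")
  # a deletion covering positions 10-30 annihilates an inner deletion
  res <- apply_changes(cds, list(cds_change(15L, substr(cds, 15, 16), ""),
                                 cds_change(10L, substr(cds, 10, 30), "")),
                       return_applied = TRUE)
  expect_length(res$annihilated, 1L)
  expect_equal(nchar(res$seq), nchar(cds) - 21L)
})

test_that("apply order does not matter for disjoint change sets", {
  set.seed(99)
  for (rep in 1:20) {
    cds <- random_cds(sample(30:80, 1), seed = rep + 500)
    starts <- sort(sample(seq(4, nchar(cds) - 10), 3))
    if (any(diff(starts) < 5)) next
    chs <- lapply(starts, function(s)
      cds_change(s, substr(cds, s, s + sample(0:2, 1)), ""))
    all_at_once <- apply_changes(cds, chs)
    expect_equal(all_at_once, splice_oracle(cds, chs))
  }
})

test_that("translation agrees with an independent oracle on random mutants", {
  set.seed(7)
  for (rep in 1:25) {
    cds <- random_cds(sample(10:100, 1), seed = rep)
    s <- sample(seq(4, nchar(cds) - 6), 1)
    ch <- cds_change(s, substr(cds, s, s + sample(0:3, 1)), "")
    mut <- apply_changes(cds, list(ch))
    expect_equal(translate_cds(mut), oracle_translate(mut))
  }
})

test_that("consequence class is frameshift exactly when the shift is not 0 mod 3", {
  fix <- toy_tx(random_cds(60, seed = 21))
  tx <- fix$tx
  set.seed(13)
  for (rep in 1:40) {
    s <- sample(10:150, 1)
    rl <- sample(0:4, 1)
    al <- if (rl == 0) sample(1:4, 1) else sample(0:4, 1)
    if (rl > 0 && al == rl) next
    ref <- if (rl == 0) "" else substr(tx$cds_sequence, s, s + rl - 1)
    alt <- if (al == 0) "" else
      paste(sample(c("A", "C", "G", "T"), al, TRUE), collapse = "")
    if (identical(ref, alt)) next
    ch <- cds_change(s, ref, alt)
    cons <- classify_consequence(tx, ch)
    expect_identical(cons$class == "frameshift", ch$net_shift %% 3L != 0L)
  }
})

test_that("frameshift notation encodes the novel stop offset", {
  # ATG AAA GTA AGG CCC TGA; deleting position 4 gives ATG AAG TAA ...:
  # first altered codon 2 (K -> K), novel stop at codon 3, so K2Kfs*2
  fix <- toy_tx("ATGAAAGTAAGGCCCTGA")
  tx <- fix$tx
  ch <- cds_change(4L, "A", "")
  cons <- classify_consequence(tx, ch)
  expect_equal(cons$class, "frameshift")
  expect_equal(cons$protein_notation, "K2Kfs*2")
  mut <- apply_changes(tx$cds_sequence, list(ch))
  expect_equal(cons$mutant_protein, oracle_translate(mut))
})

test_that("in-frame and point consequences classify correctly", {
  fix <- toy_tx(polyA_cds(30))
  tx <- fix$tx
  expect_equal(classify_consequence(tx, cds_change(10L, "AAA", ""))$class,
               "inframe_indel")
  # AAA -> TAA at codon 5 is nonsense
  expect_equal(classify_consequence(tx, cds_change(13L, "A", "T"))$class,
               "nonsense")
  # AAA -> AAG stays lysine: silent
  expect_equal(classify_consequence(tx, cds_change(15L, "A", "G"))$class,
               "silent")
  # AAA -> ACA is missense
  expect_equal(classify_consequence(tx, cds_change(14L, "A", "C"))$class,
               "missense")
})

test_that("transcript invariants are enforced", {
  expect_error(toy_tx("ATGAAA"), "stop")            # no stop codon
  expect_error(toy_tx("ATGAATAGA"), "stop")         # internal stop misframe
  expect_error(toy_tx("TTGAAATAA"), "ATG")          # bad start
  expect_error(toy_tx("ATGAAAATAA"), "multiple")    # length not 0 mod 3
})
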