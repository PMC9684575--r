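# Window search, ORF-restoration logic, and the full per-patient call chain.

test_that("truncating classification separates frameshift/nonsense from the rest", {
  fix <- toy_tx(polyA_cds(40))
  tx <- fix$tx
  expect_true(is_truncating(cds_change(10L, "A", ""), tx))        # 1-nt del
  expect_false(is_truncating(cds_change(10L, "AAA", ""), tx))     # in-frame
  # substitution creating TAA at codon 8 (positions 22-24 are AAA)
  nonsense <- cds_change(22L, "A", "T")
  expect_true(is_truncating(nonsense, tx))
  expect_equal(classify_consequence(tx, nonsense)$class, "nonsense")
})

test_that("the candidate window is 200 codons, symmetric, indels-first", {
  g <- cds_change(3 * 1716L - 2L, "A", "")             # codon 1716
  at_codon <- function(codon, ref = "AA", alt = "") cds_change(3L * codon - 2L, ref, alt)
  cands <- find_candidates(g, list(at_codon(1723)), window_aa = 200L)
  expect_length(cands, 1L)
  expect_equal(attr(cands[[1]], "distance_aa"), 7L)
  g2 <- cds_change(3 * 1982L - 2L, "A", "")
  cands2 <- find_candidates(g2, list(at_codon(1998)), window_aa = 200L)
  expect_equal(attr(cands2[[1]], "distance_aa"), 16L)
  # 201 codons away: out of window; 200 exactly: in
  expect_length(find_candidates(g, list(at_codon(1716 + 201))), 0L)
  expect_length(find_candidates(g, list(at_codon(1716 - 200))), 1L)
  # substitutions are not candidates for a frameshift germline lesion
  expect_length(find_candidates(g, list(at_codon(1720, "A", "T"))), 0L)
})

test_that("nonsense-reverting substitutions are admitted as candidates", {
  fix <- toy_tx(polyA_cds(40))
  tx <- fix$tx
  g <- cds_change(22L, "A", "T")                        # TAA at codon 8
  same_codon <- cds_change(22L, "T", "C")               # reverts to sense
  other_codon <- cds_change(31L, "A", "C")
  expect_length(find_candidates(g, list(same_codon), tx), 1L)
  expect_length(find_candidates(g, list(other_codon), tx), 0L)
})

test_that("compensating indels restore the frame when no stop bridges the lesions", {
  fix <- toy_tx(polyA_cds(30))                          # 90-nt CDS
  tx <- fix$tx
  g <- cds_change(28L, "A", "")                         # -1 nt at codon 10
  s <- cds_change(40L, "AA", "")                        # -2 nt at codon 14
  res <- check_orf_restoration(tx, g, s)
  expect_true(res$restored)
  expect_equal(res$mechanism, "compensating_indel")
  expect_true(oracle_restored(tx$cds_sequence, g, s))
  # the germline lesion alone is not restored
  g_only <- check_orf_restoration(tx, g, list())
  expect_false(g_only$restored)
})

test_that("encompassing in-frame deletions and nonsense excisions restore", {
  fix <- toy_tx(polyA_cds(60))
  tx <- fix$tx
  g <- cds_change(50L, "A", "")
  s <- cds_change(40L, substr(tx$cds_sequence, 40L, 66L), "")   # 27 nt
  res <- check_orf_restoration(tx, g, s)
  expect_true(res$restored)
  expect_equal(res$mechanism, "encompassing_deletion")
  expect_true(oracle_restored(tx$cds_sequence, g, s))
  # germline nonsense codon excised by an in-frame somatic deletion
  gn <- cds_change(49L, "A", "T")                       # TAA at codon 17
  sn <- cds_change(49L, "AAA", "")                      # removes that codon
  resn <- check_orf_restoration(tx, gn, sn)
  expect_true(resn$restored)
})

test_that("restoration never co-occurs with a combined shift not 0 mod 3", {
  set.seed(19)
  for (rep in 1:30) {
    cds <- random_cds(sample(20:60, 1), seed = rep + 900)
    fix <- toy_tx(cds)
    gp <- sample(10:(nchar(cds) - 12), 1)
    g <- cds_change(gp, substr(cds, gp, gp), "")
    sp <- sample(setdiff(4:(nchar(cds) - 9), (gp - 6):(gp + 6)), 1)
    s <- cds_change(sp, substr(cds, sp, sp + sample(0:4, 1)), "")
    res <- check_orf_restoration(fix$tx, g, s)
    if (res$restored) expect_equal(res$net_shift %% 3L, 0L)
  }
})

test_that("implementation agrees with brute-force translation over all small deletions", {
  set.seed(4)
  disagreements <- 0L
  for (rep in 1:10) {
    nc <- sample(15:50, 1)
    cds <- random_cds(nc, seed = rep + 300)
    fix <- toy_tx(cds)
    L <- nchar(cds)
    gp <- sample(5:(L - 7), 1)
    g <- cds_change(gp, substr(cds, gp, gp), "")
    for (ds in 1:(L - 6)) for (dl in 1:6) {
      # a deletion overlapping the 1-nt germline span always encompasses it,
      # so no partial-overlap case arises here
      ch <- cds_change(ds, substr(cds, ds, ds + dl - 1L), "")
      impl <- check_orf_restoration(fix$tx, g, ch, translate = FALSE)$restored
      if (impl != oracle_restored(cds, g, ch)) disagreements <- disagreements + 1L
    }
  }
  expect_equal(disagreements, 0L)
})

# a hand-assembled patient bundle around one stop-free toy transcript
# (poly-A body, so frame restoration is purely arithmetic)
bundle_tx <- function() toy_tx(polyA_cds(200))$tx

mk_bundle_variant <- function(tx, ch, id, origin, vaf = 0.5) {
  reversionscan:::cds_change_to_variant(tx, ch, id, origin = origin,
                                        vaf = vaf, alt_reads = 40L,
                                        depth = 100L)
}

pair_df <- function(gid, sid, n_cis, n_trans = 0) {
  data.frame(fragment_id = sprintf("f%d", seq_len(n_cis + n_trans)),
             germ_variant_id = gid, som_variant_id = sid,
             germ_allele = c(rep("alt", n_cis), rep("alt", n_trans)),
             som_allele = c(rep("alt", n_cis), rep("ref", n_trans)),
             stringsAsFactors = FALSE)
}

test_that("call_reversions confirms a cis-phased frame-restoring candidate", {
  tx <- bundle_tx()
  cds <- tx$cds_sequence
  gp <- 300L                            # codon 100
  g <- cds_change(gp, substr(cds, gp, gp), "")
  s <- cds_change(321L, substr(cds, 321, 322), "")   # codon 107: distance 7
  expect_true(check_orf_restoration(tx, g, s)$restored)
  gv <- mk_bundle_variant(tx, g, "g1", "germline")
  sv <- mk_bundle_variant(tx, s, "s1", "somatic")
  calls <- call_reversions("pt1", list(gv), list(sv), list(tx),
                           pairs = pair_df("g1", "s1", 5))
  expect_equal(nrow(calls), 1L)
  expect_true(calls$restored)
  expect_equal(calls$phasing_method, "read_pair")
  expect_equal(calls$distance_aa, 7L)
  # same candidate with only 2 cis pairs: the phasing gate blocks the call
  calls2 <- call_reversions("pt1", list(gv), list(sv), list(tx),
                            pairs = pair_df("g1", "s1", 2))
  expect_equal(nrow(calls2), 0L)
})

test_that("two independent planted restorations yield two calls (polyclonality)", {
  tx <- bundle_tx()
  cds <- tx$cds_sequence
  gp <- 300L
  g <- cds_change(gp, substr(cds, gp, gp), "")
  s1 <- cds_change(345L, substr(cds, 345, 346), "")  # downstream clone
  s2 <- cds_change(279L, substr(cds, 279, 280), "")  # upstream clone
  expect_true(check_orf_restoration(tx, g, s1)$restored)
  expect_true(check_orf_restoration(tx, g, s2)$restored)
  gv <- mk_bundle_variant(tx, g, "g1", "germline")
  sv1 <- mk_bundle_variant(tx, s1, "s1", "somatic")
  sv2 <- mk_bundle_variant(tx, s2, "s2", "somatic")
  calls <- call_reversions("pt2", list(gv), list(sv1, sv2), list(tx),
                           pairs = rbind(pair_df("g1", "s1", 4),
                                         pair_df("g1", "s2", 6)))
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$somatic_id, c("s1", "s2"))
})

test_that("patients without truncating germline variants yield no calls", {
  tx <- bundle_tx()
  cds <- tx$cds_sequence
  miss <- cds_change(300L, substr(cds, 300, 300),
                     setdiff(c("A", "C", "G", "T"), substr(cds, 300, 300))[1])
  gv <- mk_bundle_variant(tx, miss, "g1", "germline")
  calls <- call_reversions("pt3", list(gv), list(gv), list(tx))
  expect_equal(nrow(calls), 0L)
})
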