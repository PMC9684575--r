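# Trinucleotide catalog construction and EM signature deconvolution.

test_that("catalog channels are complete and canonically ordered", {
  ch <- catalog_channels()
  expect_length(ch, 96L)
  expect_false(anyDuplicated(ch) > 0)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
})

test_that("purine-reference SNVs are folded onto the pyrimidine strand", {
  # A>C in context T[A]G reverse-complements to T>G in context C[T]A
  refseq <- c(c1 = "TAG")
  cat1 <- build_catalog(data.frame(contig = "c1", pos = 2L, ref = "A",
                                   alt = "C"), refseq)
  expect_equal(sum(cat1), 1L)
  expect_equal(unname(cat1["C[T>G]A"]), 1L)
  # pyrimidine input is left as-is (strand-convention idempotence)
  cat2 <- build_catalog(data.frame(contig = "c1", pos = 2L, ref = "T",
                                   alt = "G"), c(c1 = "CTA"))
  expect_equal(cat1, cat2)
})

test_that("catalogs conserve counts and skip contig-edge variants", {
  set.seed(12)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  pos <- sample(2:499, 100, TRUE)
  ref <- substring(seq1, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  cat3 <- build_catalog(data.frame(contig = "c1", pos = pos, ref = ref,
                                   alt = alt), c(c1 = seq1))
  expect_equal(sum(cat3), 100L)
  expect_message(
    cat4 <- build_catalog(data.frame(contig = "c1", pos = 1L,
                                     ref = substr(seq1, 1, 1),
                                     alt = "N"), c(c1 = seq1)),
    "flank")
  expect_equal(sum(cat4), 0L)
  expect_error(build_catalog(data.frame(contig = "c1", pos = 10L, ref = "A",
                                        alt = "C"),
                             c(c1 = "TTTTTTTTTTTTTT")),
               "inconsistent")
})

test_that("EM recovers degenerate and one-signature mixtures exactly", {
  sigs <- make_toy_signatures("disjoint")
  pure <- structure(as.integer(round(sigs[, 1] * 4800)),
                    names = rownames(sigs))
  fit <- fit_signature_weights(pure, sigs)
  expect_equal(unname(fit$weights[1]), 1, tolerance = 1e-6)
  k1 <- fit_signature_weights(pure, sigs[, 1, drop = FALSE])
  expect_equal(unname(k1$weights), 1)
  expect_error(fit_signature_weights(rep(0L, 96), sigs), "empty")
})

test_that("EM log-likelihood is monotone and matches grid search for K = 2", {
  sigs <- make_toy_signatures("overlapping", seed = 17)
  sim <- simulate_catalog(c(Signature.A = 0.3, Signature.B = 0.7), 5000,
                          sigs, seed = 4)
  fit <- fit_signature_weights(sim$catalog, sigs)
  expect_true(all(diff(fit$ll_trace) >= -1e-9))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  grid <- seq(0, 1, 0.01)
  x <- as.numeric(sim$catalog)
  ll <- vapply(grid, function(w) {
    p <- as.numeric(sigs %*% c(w, 1 - w))
    sum(x[x > 0] * log(p[x > 0]))
  }, numeric(1))
  expect_lte(abs(unname(fit$weights[1]) - grid[which.max(ll)]), 0.01)
})

test_that("mixture weights are recovered within Monte-Carlo tolerance", {
  sigs <- make_toy_signatures("disjoint")
  est <- vapply(1:10, function(s) {
    sim <- simulate_catalog(c(Signature.A = 0.44, Signature.B = 0.56),
                            10000, sigs, seed = s)
    signature_fraction(fit_signature_weights(sim$catalog, sigs),
                       "Signature.A")
  }, numeric(1))
  expect_lte(abs(mean(est) - 0.44), 0.03)
})

test_that("signature fractions are retrieved by name and sum to one", {
  sigs <- make_toy_signatures("disjoint")
  sim <- simulate_catalog(c(Signature.A = 0.5, Signature.B = 0.5), 1000,
                          sigs, seed = 1)
  fit <- fit_signature_weights(sim$catalog, sigs)
  expect_equal(signature_fraction(fit, "Signature.A") +
                 signature_fraction(fit, "Signature.B"), 1,
               tolerance = 1e-8)
  expect_error(signature_fraction(fit, "Signature.Z"), "unknown")
})

test_that("simulated catalogs are reproducible and validated", {
  sigs <- make_toy_signatures("overlapping", seed = 2)
  a <- simulate_catalog(c(Signature.A = 0.2, Signature.B = 0.8), 500, sigs,
                        seed = 9)
  b <- simulate_catalog(c(Signature.A = 0.2, Signature.B = 0.8), 500, sigs,
                        seed = 9)
  expect_identical(a$catalog, b$catalog)
  expect_error(simulate_catalog(c(Signature.A = 0.2, Signature.B = 0.8), 0,
                                sigs), "n_snvs")
  expect_error(simulate_catalog(c(Signature.A = 0.5, Signature.B = 0.6),
                                10, sigs), "sum to 1")
  # law of large numbers: empirical channel frequencies approach the mixture
  big <- simulate_catalog(c(Signature.A = 0.4, Signature.B = 0.6), 100000,
                          sigs, seed = 3)
  dens <- as.numeric(sigs %*% c(0.4, 0.6))
  expect_lt(max(abs(as.numeric(big$catalog) / 100000 - dens)), 0.005)
})
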