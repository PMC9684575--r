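# reversionscan

Detection of somatic *BRCA1/2* reversion mutations and quantification of the
homologous recombination deficiency (HRD) phenotype.

## The problem

Tumors in germline *BRCA1/2* carriers that have lost the wild-type allele
cannot repair double-strand breaks by homologous recombination and are
therefore sensitive to platinum chemotherapy and PARP inhibitors. Under that
selective pressure, resistance commonly emerges through **reversion
mutations**: a second somatic indel (or point change) on the mutant allele
that restores the open reading frame and hence BRCA function. Because
reversions only arise when the tumor depended on BRCA loss, finding one is
also retrospective evidence of a BRCA-mediated, HRD-driven tumor.

`reversionscan` is for computational oncologists who have germline and
somatic variant calls, read-pair observations and allele-specific copy-number
segments, and want to (a) call reversions with explicit phasing and
reading-frame evidence and (b) score the HRD phenotype of the same tumors.

## What it computes

**Reversion calls.** For a germline frameshift/nonsense variant projected to
CDS coordinates, somatic indels within ±200 codons are candidates. A
candidate is confirmed when:

1. it is in *cis* with the germline variant — at least 3 read pairs spanning
   both sites and carrying both alternate alleles, or, for a somatic
   deletion that removes the germline site, loss-of-wild-type inference
   (segment minor copy number 0 and germline VAF consistent with every
   tumor copy carrying the germline allele); and
2. the doubly mutated CDS restores the reading frame: combined net shift
   ≡ 0 (mod 3) and translation reaches the natural stop with no premature
   stop codon.

**HRD measures.** On a smoothed allele-specific segment profile:
LST (breakpoints between ≥10 Mb same-arm segments of differing state),
HRD-LOH (>15 Mb LOH segments not spanning a whole chromosome), NtAI
(imbalanced segments reaching a telomere without crossing the centromere),
and HRD-sum = LST + HRD-LOH + NtAI. Mutational-signature fractions are
fitted from 96-channel trinucleotide catalogs by maximum likelihood (EM on
the multinomial likelihood). Zygosity uses the mixture model
E[VAF] = m·p / (t·p + 2(1 − p)) with a binomial read-count likelihood.

A synthetic-cohort generator (`simulate_cohort()`,
`simulate_segment_profile()`, `simulate_catalog()`) plants all of these
event classes with known ground truth.

## Worked example

```r
library(reversionscan)

sim   <- simulate_cohort(simulation_config(seed = 42, n_patients = 1000))
calls <- scan_cohort(sim)
calls[, c("patient_id","gene","germline_notation","somatic_notation",
          "mechanism","phasing_method","n_cis_pairs","distance_aa")]
#>  patient_id  gene germline_notation somatic_notation          mechanism
#>       P0512 BRCA2        M322Rfs*18        K318Nfs*9 compensating_indel
#>       P0929 BRCA1         N270Ifs*4        R272Efs*6 compensating_indel
#>       P0998 BRCA2        G267Efs*33        R273Rfs*3 compensating_indel
#>  phasing_method n_cis_pairs distance_aa
#>       read_pair           9           4
#>       read_pair           8           2
#>       read_pair          12           6
```

Each row is one confirmed reversion: e.g. patient P0512 carries a germline
frameshift at codon 322 of the toy BRCA2 model (`M322Rfs*18`: novel stop 18
codons downstream) and acquired a somatic 2-nt deletion 4 codons away whose
shift cancels the germline shift; 9 spanning read pairs certify the two
lesions share an allele, and translation of the doubly mutated CDS reaches
the natural stop.

```r
build <- hrd_toy_build()
sp <- simulate_segment_profile(c(5, 3, 4), purity = 0.8, build = build, sens = 1)
hrd_sum(sp$profile, build)
#> HRD scores: LST 5 + HRD-LOH 3 + NtAI 4 = HRD-sum 12

sigs <- make_toy_signatures("disjoint")
cat96 <- simulate_catalog(c(Signature.A = 0.44, Signature.B = 0.56),
                          10000, sigs, seed = 1)$catalog
fit_signature_weights(cat96, sigs)
#> SignatureFit: 10000 mutations, logL -45590.549, 2 EM iterations
#>   Signature.B      0.551
#>   Signature.A      0.449

prevalence_percent(342, 31927)   # germline BRCA1 carriers in a 31,927-patient cohort
#> [1] 1.1
```

The planted scar counts (5, 3, 4) are recovered exactly at full detection
sensitivity, and the fitted signature weight recovers the simulated 0.44
mixture to within Monte-Carlo error.

A command-line wrapper for the main stages ships in
`inst/cli/reversion-scan.R` (subcommands `simulate`, `scan`, `hrd`,
`signatures`); `run_pipeline()` is the file-based entry point behind `scan`.

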