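---
title: "Detecting BRCA1/2 reversion mutations and quantifying the HRD phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting BRCA1/2 reversion mutations and quantifying the HRD phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reversionscan)
```

## The problem

A tumor arising in a germline *BRCA1/2* carrier that has lost its wild-type
allele cannot repair double-strand breaks by homologous recombination. This
homologous recombination deficiency (HRD) makes the tumor sensitive to
platinum chemotherapy and PARP inhibition — and under that selective
pressure, tumors frequently escape by acquiring a *reversion mutation*: a
second somatic change on the same allele that restores the open reading
frame (ORF), and with it BRCA protein function. Detecting reversions in
sequencing data therefore serves two purposes: it explains acquired
resistance, and, because reversions only arise when the tumor depended on
BRCA loss in the first place, it is retrospective evidence of a
BRCA-mediated phenotype.

`reversionscan` implements the full computational chain: projecting variants
onto a coding model, searching a codon window around the germline lesion,
establishing that germline and somatic changes lie in *cis*, testing ORF
restoration by explicit mutation and translation, and quantifying the HRD
phenotype through genomic scar scores, mutational-signature deconvolution
and zygosity inference. A first-class synthetic-cohort generator plants
every event class with known ground truth, so the whole chain is testable
without access-restricted patient data.

## The detection procedure

1. **Coding model.** One canonical transcript per gene: exon intervals on a
   contig plus the spliced CDS (validated: starts `ATG`, ends at its first
   in-frame stop, length divisible by 3). Genomic variants are normalized
   (shared prefix/suffix trimmed, which left-aligns indels and makes
   cis-pair matching deterministic) and projected to 1-based CDS
   coordinates, reverse-complementing alleles on minus-strand transcripts.
   Deletions are clipped to the coding interval; the clipped length is what
   enters frame arithmetic.

2. **Eligibility filters.** Patients with more than 20 nonsynonymous
   mutations per callable megabase are excluded (hypermutated tumors can
   acquire *BRCA1/2* indels without HRD). Somatic calls are removed when
   they fall in a user-supplied blacklist of repetitive regions, recur in
   10 or more reference-population individuals, or fail the low-support
   rule (VAF < 5% **and** at most 3 supporting reads **and** depth < 20x —
   a conjunction by default, with a configuration switch for the
   disjunctive reading, since the rule's phrasing chains the clauses).
   Known-oncogenic whitelisted alleles always survive. A configurable
   per-gene C-terminal bound drops last-exon truncations predicted not to
   disturb the functional domains.

3. **Window search.** For each germline frameshift or nonsense variant,
   somatic insertions/deletions whose first affected codon lies within 200
   codons of the germline lesion's first affected codon are candidates.
   The window is symmetric (confirmed reversions occur both up- and
   downstream of the germline lesion). Substitutions qualify only when
   they revert the germline nonsense codon itself.

4. **Cis phasing.** A candidate is certified in cis when at least **three**
   sequenced fragments span both sites and carry both alternate alleles.
   When cis and trans pairs conflict, we additionally require more cis than
   trans pairs — a conservative guard against sequencing artifacts that the
   threshold alone would not provide. A trans verdict (3+ trans pairs, no
   cis pair) is an extension flagged by its status; the method as published
   only certifies cis. For large somatic deletions that remove the germline
   site no fragment can witness both alleles, so phasing falls back to
   loss-of-wild-type inference: if the overlapping copy-number segment has
   minor copy number 0 and the observed germline VAF is consistent with
   every tumor copy carrying the germline allele, the deleted allele must
   be the germline-bearing one. "Consistent" means within an absolute
   tolerance of 0.10 (configurable) of the expected VAF; the clonality of
   the loss-of-wild-type event is operationalized by this gate.

5. **ORF restoration.** The germline and somatic changes are applied
   jointly to the CDS — a pure deletion fully encompassing another change
   absorbs it; partial overlaps are rejected as ambiguous haplotypes — and
   the allele is *restored* when the combined net length shift is a
   multiple of 3 **and** translation reaches the natural stop with no
   premature stop anywhere upstream (no stop codon may appear in the
   bridged, frame-shifted region between the two lesions). Mechanisms are
   labeled `compensating_indel`, `encompassing_deletion`, or `delins`.

The per-patient caller emits one call per confirmed candidate, so
polyclonal tumors with independent reversions produce multiple calls.

## The expected-VAF mixture model and zygosity

With tumor purity $p$, local total copy number $t$ and $m$ mutated copies,
and diploid wild-type normal admixture,

$$\mathrm{E}[\mathrm{VAF}] = \frac{m\,p}{t\,p + 2(1-p)}.$$

Zygosity of a variant is the likelihood-best $m \in \{1,\dots,t\}$ under a
binomial read-count model (success probability clamped to
$[10^{-6}, 1-10^{-6}]$, since an expected VAF of exactly 1 would assign
zero likelihood to any imperfect observation). Loss of wild type is called
when the segment's minor copy number is 0 and the best $m$ equals $t$. At
the gene level, a loss-of-function mutation is biallelic when it shows loss
of wild type, or co-occurs with a homozygous deletion, a fusion, or a
second somatic loss-of-function mutation.

## Genomic scar scores

All three scores are computed on a smoothed profile (segments under 3 Mb
removed, adjacent equal-state segments merged):

- **LST** — breakpoints between consecutive same-arm segments, both flanks
  at least 10 Mb (arm-clipped), with a change in allele-specific state.
  Transitions straddling the centromere do not count.
- **HRD-LOH** — segments with minor copy number 0 longer than 15 Mb that do
  not span their whole chromosome.
- **NtAI** — allelically imbalanced segments ($2\,\mathrm{minor} \neq
  \mathrm{total}$) reaching a telomere without crossing the centromere; no
  minimum length by default.
- **HRD-sum** — their unweighted sum.

Thresholds (3/10/15 Mb) follow the canonical published definitions of the
three scores and are configuration values; the goal is the canonical
definitions, not bit-compatibility with any particular segmentation-suite
release, whose version-specific deviations are acknowledged. Ploidy-relative
imbalance definitions and whole-genome-duplication adjustment are not
applied.

## Signature deconvolution

SNVs are folded onto the pyrimidine strand and counted in the 96
trinucleotide channels. Given a signature matrix $S$ (96 x K, columns on
the simplex), weights maximize the multinomial log-likelihood
$\sum_c x_c \log (\sum_k w_k S_{kc})$ by expectation-maximization from a
uniform start, with update $w_k \leftarrow w_k \sum_c x_c S_{kc} / (\sum_j
w_j S_{jc}) / N$ — monotone in the likelihood, run to a gain below
$10^{-8}$ (at most 10{,}000 iterations), and restricted to observed
channels so that signatures driven to zero weight cannot produce
indeterminate updates. No sparsity penalty or signature pre-selection is
applied, and no exome-territory channel renormalization (a hook exists for
supplying renormalized matrices). The package ships no signature catalog;
any matrix in the documented TSV layout (e.g. the COSMIC v2 set) can be
supplied, and all tests use small synthetic matrices so nothing need be
downloaded.

## What the synthetic cohort emulates

`simulate_cohort()` draws a cohort in the configured lineage mix (30%
BRCA-associated), plants germline carriers at 5.5% / 1.4% in
BRCA-associated / other lineages, gives each carrier a mid-CDS 1-nt
frameshift deletion in a toy BRCA1 or BRCA2 transcript, and plants
reversions in a configurable fraction (default 0.25) of platinum-exposed
carriers. Of reversion patients, 18% receive two independent reversions —
polyclonal reversion at roughly the rate seen in clinical series. The
mechanism mix likewise follows clinical series, where deletions dominate
(11 : 1 : 1 deletions : insertions : delins here, with 3 of the 11
deletions taken as encompassing). Cis support is 5 + Poisson(3)
spanning pairs per reversion (comfortably above the gate of 3); the
per-pair miscall rate defaults to 0 ("noise-free"). Reversion patients
always show loss of wild type at the gene segment, with the germline tumor
VAF set to the mixture model's expectation, which is what the LOH phasing
fallback tests. Decoys are included so the gates do real work: every
carrier gets an in-window somatic missense SNV (which the candidate filter
must reject), and 30% of heterozygous non-reversion carriers get a
frame-restoring-capable indel with trans-configured read pairs (which only
the phasing gate rejects).

What it does **not** emulate: read-level errors, alignment artifacts,
germline background variation, subclonal copy number, multi-exon-spanning
genomic deletions (planted lesions stay within one exon), or reversion by
structural rearrangement. Perfect recovery on these simulations therefore
validates the logic of the chain, not its robustness to raw-data noise —
the upstream caller's problem, outside this package's scope.

`simulate_segment_profile()` plants scar events one per chromosome arm on a
16-contig toy build (200 Mb contigs, centromere at 95–105 Mb), each event
engineered to contribute to exactly one score: LST events switch a >=10 Mb
arm segment to a balanced (4,2) state; HRD-LOH events are interior 16 Mb
(2,0) segments insulated by 5 Mb buffers (too short to qualify as LST
flanks); NtAI events are 8 Mb imbalanced telomeric caps (too short for LST,
too short for HRD-LOH). At full sensitivity, planted counts equal scored
counts exactly. Purity attenuation is modeled by an explicitly declared
logistic detection sensitivity $s(p) = 1/(1+e^{-10(p-0.35)})$ — a stand-in
for the real purity dependence of copy-number event detection (detection
degrades steeply below roughly one-third tumor content), existing solely
to make the qualitative purity trend testable. Each planted event is
dropped independently with probability $1-s(p)$.

## Numerical and design choices

- Coordinates are 1-based inclusive throughout (genomic and coding), with
  VCF anchored-base indels converted at the I/O boundary.
- Translation uses the standard nuclear code; the first in-frame stop
  terminates. The fast stop scan exploits the fact that stop codons begin
  with T and continue with purines, so two stops can never overlap and a
  non-overlapping regex search finds every one.
- Conflicting phase evidence demotes to ambiguous rather than erroring;
  the trans branch is reported but flagged as an extension.
- Segment assignment at a variant requires a unique overlapping segment;
  anything else is indeterminate. Segments lacking minor copy number are
  excluded from LOH-dependent logic with a logged message.
- Fisher's exact test (two-sided, probability-mass criterion) is delegated
  to `stats::fisher.test` and cross-checked in the test suite against an
  explicit hypergeometric enumeration oracle. Percentages round half-up to
  one decimal to match conventional printed values.
- The expected-VAF denominator uses diploid normal admixture,
  $t\,p + 2(1-p)$ — the field-standard mixture model.

## Problem sizes used in validation

The automated checks run: oracle equivalence of the ORF test on 500 random
coding sequences (60–240 nt) against brute-force enumeration of all somatic
deletions up to 6 nt (~400,000 cases); the phasing gate on 10,000 random
read-pair configurations; end-to-end recovery on three simulated cohorts of
2,000 patients; scar-score exactness over 100 simulated profiles; the
purity trend over 200 simulated tumors in 10 deciles; and signature
recovery over 50 catalogs of 10,000 mutations. These sizes give stable
Monte-Carlo behavior while keeping a full validation run in a few minutes
on one core.

## Known limitations

- One canonical transcript per gene; splice-site reversions, UTR effects
  and isoform resolution are out of scope, as are structural-variant
  reversions.
- The cohort-scale headline counts of the motivating study derive from
  access-restricted clinical data; the package validates the method's
  logic on synthetic cohorts rather than reproducing those counts.
- Scar-score values on real segmentations depend on the upstream
  segmentation parameters; comparisons across tools should be qualitative
  unless thresholds are harmonized.
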