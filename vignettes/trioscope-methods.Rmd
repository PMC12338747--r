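---
title: "Methods: trio-based de novo mutation discovery, phasing and postzygotic classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based DNM discovery, phasing and postzygotic classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A de novo mutation (DNM) is a variant carried by a child and absent from
both parents. Calling DNMs from sequencing data is dominated by artifact
control: inherited variants that look de novo because one parental
haplotype dropped out of the parent's data, recurrent sequencing errors
shared across unrelated samples, and context-specific noise around
homopolymers and tandem repeats all outnumber true events by orders of
magnitude. Long reads change what is knowable: because a single read spans
many inherited heterozygous sites, each read can be assigned to the
parental haplotype it came from, which (a) gives the parent of origin of a
DNM directly and (b) separates germline mutations (carried by *every* read
from the origin haplotype) from postzygotic mutations (PZMs; carried by
only a fraction of reads from one haplotype, so the locus effectively
shows three haplotypes).

trioscope implements this analysis as a reusable, fully testable pipeline
over tabular evidence: trio VCFs from two callers, a pedigree, a
read-evidence table (one row per read per interrogated site, carrying the
observed allele, quality tier and the alleles at spanned tagging SNPs) and
BED feature tracks. Alignment and upstream variant calling are out of
scope; the read-evidence table is the boundary, derivable from BAMs but
consumed as TSV so the whole pipeline runs on synthetic data with known
truth.

## Pipeline stages and their rules

1. **Candidate selection** (`select_candidate_snvs`). Union of the two
   callers' callsets; a site is a candidate for a child when both parents
   are genotyped 0/0, the child carries the alternate allele, and the
   child genotype quality is at least 20 in at least one caller's record.
   Parental GQ is deliberately not thresholded.
2. **Clustered-SNV filter** (`cluster_filter`). Any SNV belonging to a
   window of 1 kbp containing three or more of the same child's candidate
   SNVs is removed: dense candidate runs are the signature of a dropped
   parental haplotype, not of mutation. The sliding window is evaluated at
   every base offset, which is equivalent to removing any three candidates
   whose positions span at most 999 bp; a brute-force window scan backs
   this equivalence in the tests.
3. **Three-platform read validation** (`validate_snvs`). Long reads
   (HiFi, ONT) require mapping quality ≥ 59; short reads are not filtered
   on mapping quality. A child's HiFi reads must be blood-derived
   (cell-line reads can carry culture-acquired variants), parental HiFi
   may be blood or cell line. Base quality partitions reads into
   high (> 20), low (10–20) and discarded (< 10) tiers. A parent is
   *clean* on HiFi/Illumina with zero high-quality and at most one
   low-quality read carrying the de novo allele; ONT, being noisier,
   tolerates one high-quality and two low-quality reads. The caps are a
   conjunction: exceeding either disqualifies. A variant is inherited if
   any platform says inherited, and validated only with support
   (≥ 1 child de novo read, clean parents) on at least two platforms.
4. **Cohort recurrence** (`cohort_recurrence_filter`). The de novo allele
   must be absent from the HiFi reads of all unrelated samples (one
   unrelated carrier is tolerated inside a tandem repeat, where recurrent
   slippage is expected). Siblings never count as recurrence.
5. **Repeat-context AB filters** (`repeat_ab_filters`). Mean allele
   balance across platforms with ≥ 1 usable child read must exceed 0.05
   in TRs, and 0.10/0.08 in RepeatMasker regions (with/without TR
   overlap).
6. **Homopolymer filter** (`homopolymer_filter`). Substitutions in or
   within 1 bp of a homopolymer run whose reference or alternate allele
   equals the run base are removed (e.g. A→T on the edge of an A run).
   The run-length bound is ≥ 4, the shortest run commonly treated as an
   artifact source; the bound is a tunable argument.
7. **Cross-platform noise** (`cross_platform_noise_filter`). A platform is
   noisy when a parent shows two or more reads of a third allele; two
   noisy platforms fail the variant. The threshold is a design choice —
   the failure mode is described qualitatively in the field (noisy
   parental pileups with alleles unlike the de novo allele) but no
   numeric rule is standard.
8. **Phasing** (`phase_validated`). Informative SNPs are sites where the
   child is heterozygous and exactly one assignment of its two alleles to
   the two parents is consistent with the parental genotypes (this
   covers 0/0 × 0/1 → 0/1 and, by elimination, 1/1 × 0/1 → 0/1).
   Each usable child read (long reads, mapq ≥ 59, base quality ≥ 20 at
   the site) receives an inheritance score: ± 1 per matched informative
   SNP (negative = paternal), averaged with weights 1/max(1, distance).
   The `max(1, ·)` guards a zero distance; a score of exactly 0 leaves
   the read unassigned; a read allele matching neither parental allele at
   a tag site contributes nothing (it is a base-call error). A DNM is
   phased only when *all* of its de novo reads fall on one haplotype;
   reads on both yield CONFLICT. HiFi assignments win over ONT; ONT
   rescues HiFi-unphased variants; a variant with informative SNPs that
   neither platform can phase is excluded from the callset as a likely
   sequencing error, while a variant with no informative SNPs is retained
   unphased.
9. **Origin classification** (`classify_origins`). Per long-read
   platform, the origin-haplotype pileup gives the haplotype call:
   postzygotic with ≥ 2 reference and ≥ 1 alternate reads on the origin
   haplotype, germline with ≤ 1 reference read, ambiguous with no
   alternate reads. In parallel, the allele-balance route tests
   cross-platform AB concordance (chi-squared homogeneity on the
   platform × {ref, alt} table, α = 0.05, exact test when an expected
   cell is zero) and, if concordant, pools counts for a one-sided exact
   binomial test against 0.5; discordant ABs default the prediction to
   germline. Platform agreement wins; disagreement and double-ambiguity
   defer to the AB prediction. When exactly one platform is ambiguous the
   other platform's call stands — deferring to AB there would discard
   direct haplotype evidence. Because the binomial test is one-sided
   below 0.5, an AB of 1 (seen at a small number of real germline calls
   in repetitive DNA) can never be classified postzygotic.
   Indels use a noise-tolerant rule instead: postzygotic only when more
   than three reads on the origin haplotype differ from the called
   allele; the haplotype scope of that rule is an interpretation, as the
   source description does not state it explicitly.
10. **Rates and statistics**. Callable sites require both parents 0/0
    (autosomes, female X) and one high-quality, high-base-quality HiFi
    read in each trio member (child: blood only); male X/Y use only the
    transmitting parent and drop the parental genotype restriction.
    Rates divide counts by ploidy-adjusted callable length; confidence
    intervals bootstrap over children (10,000 percentile replicates by
    default) because children, not sites, are the exchangeable unit —
    the interval then absorbs between-child variance including age
    effects. Feature comparisons use a paired per-child t-test with
    Benjamini–Hochberg correction; pairing is a design choice (rates are
    paired by sample). Spectra use the 7-class pyrimidine-collapsed set
    with CpG>TpG split out; parental-age effects are ordinary least
    squares of per-child phased counts on the corresponding parent's age.

## The synthetic cohort generator

`calibrated_preset()` encodes the study conditions the package is calibrated
against: 42 families (31 quads, 11 trios; 73 transmissions), and per
child

* germline SNV counts as two independent Poisson draws — paternal mean
  `12.38 + 1.32 × father_age`, maternal mean `−0.20 + 0.46 × mother_age`
  (floored at 0). The slopes are the target age effects (mutations per
  year); the intercepts are solved so a child of 33/31-year-old parents
  expects 70 germline SNVs at a 3.98:1 paternal:maternal ratio. Modeling
  the two parental components separately (rather than one total count
  with per-mutation parent assignment) makes the OLS slope of
  paternal-haplotype counts on paternal age equal the generative slope;
  a shared-count model would attenuate it by the paternal fraction.
* PZM counts at 18% of the child's germline expectation (≈ 12.6 at mean
  ages), split 1.15:2.15 paternal:maternal; PZM cell fractions drawn
  from Beta(2.2, 7.8) (mean overall allele balance 0.22), truncated to
  (0.01, 0.495) so every PZM is sub-clonal.
* spectra with transition fractions 2.10/3.10 (germline) and 1.35/2.35
  (PZM), CpG>TpG at 0.15 vs 0.1155 (23% lower postzygotically), and PZM
  enrichment of A>C/A>T with A>G depletion.
* parental ages Normal(33, 5) and Normal(31, 4.5), truncated to
  [18, 55] — unstated in the source material, chosen as typical for
  contemporary cohorts; they only need to provide age spread for the
  regressions.
* platforms HiFi 30× / ONT 40× / Illumina 40×, with per-read error rates
  0.2% / 2% / 0.1% at the site (configuration defaults, not claims about
  any particular dataset) and reference bias 1.3% / 1.0% / 6.5% applied
  to alternate-carrying reads. The biases reproduce the observed mean
  germline allele balance of ≈ 0.48 while loading most of the bias onto
  short reads, where alignment reference bias is strongest; this also
  keeps long-read haplotype pileups clean enough that the ≥ 2-reference-
  read rule misclassifies few germline variants. Erroneous base calls
  draw their quality tier from a low-quality-heavy distribution
  (HIGH 0.05 / LOW 0.45 / DISCARD 0.50) — quality correlates with error,
  which is what makes strict high-quality parental read caps usable at
  30–40× depth.
* an inherited-SNP scaffold at density 1/1200 bp within ±25 kbp of every
  candidate site, with 55% of SNPs informative; scaffold alleles are
  threaded onto each child read consistently with the read's simulated
  parental haplotype.
* confounders per child: Poisson(1.5) dropped-haplotype runs (3+
  apparent child-only variants within ≤ 900 bp, truly inherited, with no
  alternate reads in the dropped parent), Poisson(3) recurrent artifacts
  (the same false allele in the HiFi reads of two unrelated children),
  Poisson(2) homopolymer-edge substitutions.

The default genome is a single 50 Mbp chromosome per trio with per-child
mutation counts kept at cohort scale, so per-base-pair rates are inflated
relative to a 2.9 Gbp genome by design; rate recovery is therefore
checked against the configured per-bp rate implied by the counts and the
simulated genome length, not against genome-scale literature rates.

**What the generator does not emulate.** Reads are emitted only at
candidate sites (a site-indexed evidence table, not genome-wide
pileups); background sequencing errors in unrelated samples' pileups are
not simulated, so cross-sample recurrence exists only through the
explicit recurrent-artifact channel; true mutation positions are kept
≥ 1.2 kbp apart, so chance clusters and chance multinucleotide pairs do
not occur and the cluster filter's false-positive rate on real data is
not measured here; there is no sequence-level read simulation (no
alignment artifacts beyond mapping-quality assignment), no indel or
structural-variant simulation, and the simulated cohort is autosomal
(the sex-chromosome candidate logic and callable rules are exercised by
targeted fixtures instead). A passing suite therefore demonstrates that
the *rules* are implemented faithfully and recover known truth under
realistic noise — not that any particular real dataset would yield the
same numbers.

## Numerical and degenerate-input choices

* Chi-squared homogeneity without continuity correction; a table with a
  zero expected cell falls back to Fisher's exact test; fewer than two
  platforms with reads is "concordant by convention" and flagged.
* A pooled AB test with zero total reads is an error (such a variant
  cannot have been validated).
* Wilcoxon signed-rank tests use the exact null where R's implementation
  provides it (small n, no ties) and the normal approximation with
  continuity correction otherwise; identical paternal/maternal vectors
  short-circuit to p = 1.
* Interval conventions are enforced at the I/O boundary: VCF and
  read-evidence positions are 1-based, BED tracks and callable masks
  0-based half-open; a DNM belongs to a feature iff its 0-based position
  lies in [start, end). Interval algebra goes through IRanges.
* All randomness in the generator flows from one seed drawn at entry;
  identical configuration and seed give byte-identical output files.
  The pipeline itself is deterministic except the bootstrap, which is
  seeded per run.

## Problem sizes

The bundled tests run a 4-family/8 Mbp cohort for module-level checks and
one full 42-family/73-transmission, 50 Mbp-per-trio cohort (≈ 2.2 M read
observations, ≈ 6,800 candidate sites) for end-to-end parameter-recovery
checks; the full run takes a few minutes on one CPU. `scripts/acceptance.R`
re-runs the full cohort from scratch at the given seed.

## Example

```{r example}
library(trioscope)
cohort <- simulate_cohort(calibrated_preset(seed = 1))
res <- run_pipeline(cohort)
print(res)
res$summary$germline_paternal_ratio
res$evaluation$germline_sensitivity
```
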