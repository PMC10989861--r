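---
title: "Mapping traits from k-mer counts in unphased heterozygous crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping traits from k-mer counts in unphased heterozygous crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbsa)
library(data.table)
```

## The problem

Crosses between two highly heterozygous diploid parents segregate four
parental haplotypes (A/B from parent 1, C/D from parent 2). When a binary
trait is controlled by a single haplotype — say, a dominant allele on
haplotype A — conventional mapping with parental SNPs struggles: markers
that distinguish *parents* cannot distinguish the two haplotypes *within*
a parent, and phased parental assemblies are rarely available in breeding
material.

`kbsa` implements a reference-free alternative: pool the progeny into two
phenotypic bulks, count canonical 31-mers per sample, aggregate them per
bulk, and test every k-mer for differential abundance between bulks.
k-mers tag haplotypes directly — any SNP private to haplotype A creates up
to *k* k-mers carried only by A — so the approach sees within-parent
structure that parent-level genotypes cannot. Enriched k-mers are then
assigned a parental origin from parental read sets, localized on a
reference (when one exists) by backtracking to their source reads and
binning read dosage, and finally used to pseudo-phase the causal parent's
two haplotypes from bulk allele frequencies.

## The expectation model

For an F1 intercross, gametes carry each of A, B, C, D with probability
1/4. Conditioning the 16 ordered F2 genotypes on the phenotype gives the
closed-form within-bulk allele frequencies that anchor interpretation:

```{r expect}
bulk_allele_frequencies("dominant", "A")$positive$freq
bulk_allele_frequencies("dominant", "A")$negative$freq
format_expectation("dominant")
format_expectation("recessive")
```

Under dominance the causal allele is *exclusive* to the positive bulk
(4/7 of its homologs versus 0), while each non-causal allele sits at
1/7 (14%) versus 1/3 (33%) — a 2.33-fold contrast (2.4 when the rounded
percentages are divided, the convention used by `format_expectation()`).
Under recessivity the causal allele is at 100% versus 20% (5-fold) and the
non-causal alleles are exclusive to the negative bulk. `detectability()`
applies a plain fold threshold (default 2.5) to these ratios: dominant
loci are expected to surface in one bulk only, recessive loci in both.
Note a deliberate asymmetry in the package, inherited from how the method
is normally operated: the *differential call* gates on |log2 fold change|
> 2.5 (a 5.66-fold contrast), while the *expectation reasoning* speaks in
plain folds. At the 5-fold recessive contrast this matters: causal k-mers
clear the adjusted-P gate but sit near the fold gate, so recessive
positive-bulk calls are a tail, not the bulk, of the causal k-mers (see
"Known limitations").

## The statistical core

For a k-mer seen $K_A$ times among $N_A$ total k-mer occurrences in bulk A
and $K_B$ of $N_B$ in bulk B (counts taken after a +1 pseudocount), the
two bulks are modeled as independent Poisson draws with rates $K_A/N_A$
and $K_B/N_B$; the null constrains both to the pooled rate
$(K_A+K_B)/(N_A+N_B)$. The log-likelihood-ratio statistic

$$G = 2\left[\ell(K_A;\hat\lambda_A N_A) + \ell(K_B;\hat\lambda_B N_B)
      - \ell(K_A;\hat\lambda_0 N_A) - \ell(K_B;\hat\lambda_0 N_B)\right]$$

is $\chi^2_1$ under the null (Wilks), giving a two-sided upper-tail P per
k-mer; Bonferroni correction over the number of k-mers actually tested
(the rows of the merged table) controls the family-wise error at the
k-mer scale, and a strict |log2FC| > 2.5 gate removes
statistically-significant-but-weak contrasts. Both gates are strict
inequalities. Because the alternative rates are the per-bulk MLEs, $G \ge
0$ always, with equality exactly when the normalized rates agree; the
implementation is validated against a direct Poisson log-pmf oracle to
$10^{-9}$.

Counting choices that matter:

* **Canonical counting** (lexicographic minimum of each k-mer and its
  reverse complement, odd *k* only). Reads sample both strands, so
  without canonicalization every downstream contrast would be
  strand-sensitive. `--no-canonical` equivalents exist on all counters.
* **$N$ = total occurrences**, not distinct k-mers: the Poisson rate
  $K/N$ is a per-instance rate. (Configurable at the `join_bulks()` level
  by passing explicit totals.)
* **Per-sample singleton removal** (count ≥ 2 within a sample) before
  bulk aggregation, then a **bulk minimum count of 5**. The bulk
  threshold can instead be read off the abundance histogram
  (`histogram_threshold()`): the count at the first interior local
  minimum between the error peak and the genomic peak, never below 2,
  falling back to 5 when the histogram is monotone.
* Non-ACGT characters break the sliding window rather than being cast to
  a base, so ambiguous positions create no phantom k-mers.

## The simulator

`sim_haplotypes()` + `simulate_pedigree()` + `simulate_reads()` emulate
the study design end to end: a random reference backbone; SNPs at 1/500 bp
with each haplotype independently carrying the reference or one alternate
base (conditioned on polymorphism), which yields heterozygous-in-one-
parent sites, homozygous-different sites, and haplotype-private alleles at
their natural frequencies; a pooled intercross of 52 F1 plants (two
distinct F1 parents drawn uniformly per F2, no selfing); recombination as
a Poisson number of crossovers per chromosome per meiosis (default 1)
with uniform breakpoints and no interference; binary traits assigned from
the planted causal haplotype (dominant: one copy; recessive: two); and
uniformly placed 150-bp reads from either strand with independent
substitution errors (default 0.2% per base, a typical post-QC short-read
rate) at 4x per progeny individual and 20x per parent. The default
scenario (`bsa_scenario()`) uses two 1-Mb chromosomes and sequences 8 F1
and 48 F2 individuals; the causal position defaults to 625 kb, the center
of a 50-kb dosage bin, so bin-distance statements about the locus are
unambiguous. Truth tables record every read's source homolog and
coordinates, so localization can be validated by interval arithmetic
without an external aligner (`write_truth_sam()` emits the same placements
as a valid SAM for tools that want one).

What the simulator does *not* model — and therefore what passing tests do
not establish about real data: indels and structural variants, base-
quality-dependent errors, GC or mappability bias, repeats (the backbone is
i.i.d. random, so 31-mers are essentially unique), segregation distortion,
and multi-locus epistasis. The last point is deliberate: real
pigmentation traits of this kind can involve suppressor interactions
that distort single-locus segregation ratios, and the simulator makes no
attempt at that — it implements the clean single-locus
dominant/recessive models only.

## Localization

Reads containing at least one enriched k-mer are selected
(`backtrack_reads()`, canonical matching) and their alignments counted in
consecutive nonoverlapping bins (default 200 kb; the desk-scale scenario
uses 50 kb) after discarding records with MAPQ < 40, secondary,
supplementary, or unmapped flags; each primary alignment is assigned to
the bin containing its leftmost aligned base. Per bulk and per bin, the
significant-read count is normalized to the bulk's total read count in
the same bin, and the track's `ratio` column is the positive-over-negative
ratio of normalized signals with a small pseudocount so empty bins sit at
a neutral 1 (default 1e-6 of the genome-wide mean normalized signal).

Which enriched set drives the track is configurable
(`run_bsa(track_set=)`): the default backtracks the *trait-associated
bulk's* enriched k-mers in both bulks, so the ratio reads directly as
that set's bulk specificity. At full study scale the alternative —
the union of both directions — is nearly identical because enrichment is
overwhelmingly one-sided there; at desk scale the union's
negative-direction calls cluster at the locus (the non-causal alleles'
14% vs 33% contrast is maximal exactly there) and flatten the ratio peak,
so the one-sided default localizes markedly better.

`call_peak()` seeds at the maximum-ratio bin (ties toward the lowest
coordinate) and extends while bins stay at or above half the seed ratio.

A resolution caveat that the package's own acceptance experiments
quantify: at the desk scale (56 progeny at 4x), the per-bin ratio carries
30–50% multiplicative noise because the depleted bulk contributes O(10)
significant reads per bin, and founder sampling from the F1 pool can
shift the empirical contrast maximum by a bin or two relative to the
planted truth. Across ten simulation seeds the top-ratio bin lands within
one 50-kb bin of the locus in about 8 of 10 runs, with the remainder two
bins (100 kb) off — comparable, after scaling, to the megabase-scale
intervals such studies report on real chromosomes. Expecting single-bin
precision from the ratio argmax at this sample size is optimistic; the
called peak interval is the more stable localization.

## Parental origin

An enriched k-mer is parent-specific when present in one parent's reads
(count ≥ 2, mirroring the singleton filter) and *completely absent*
(count 0) from the other's; below-presence in both is `absent`, anything
else `shared`. Strict absence is the defining rule; at high parental
depth sequencing errors can break it (an error has ~1% chance of
recreating any given specific k-mer at 20x), which is why both the
presence floor and absence threshold are configurable. On the default
scenario ≥95% of truly haplotype-private enriched k-mers are assigned to
the correct parent.

## The conventional-mapping comparator

`select_parental_snps()` keeps biallelic sites with QUAL ≥ 100, pooled
parental depth 25–70, homozygous for different alleles in the two parents
— the only sites where a read assigns to a parent unambiguously. Progeny
are genotyped in 100-kb bins from ≥ 50 informative reads (a read covering
a selected SNP and matching a parental allele exactly): parent-1 fraction
> 95% is `hom_P1`, < 5% `hom_P2`, otherwise `het` (simulated F2s average
~50% heterozygous bins, matching the expectation for this design). The
association scan is deliberately simple — a per-bin 2×3 contingency
chi-square of trait against genotype with a genome-wide threshold from
the 95th percentile of the max statistic over 1,000 trait permutations —
because the point being tested (parent-level markers cannot see
within-parent haplotypes) is model-agnostic; it does not reproduce any
specific published QTL engine's internals.

A caution from our simulations, documented rather than hidden: under the
*clean* single-locus dominant model, parent-level genotypes are not
independent of the trait — a carrier needs at least one parent-1-derived
homolog at the locus, so P(positive) is 3/4, 1/2, 0 for P1/P1, P1/P2,
P2/P2 bins, which a scan on 48 F2s has appreciable power to detect. In
real material, penetrance, epistasis, and small unbalanced bulks
attenuate this residual signal and such scans often come up empty. The
within-parent haplotype distinction (A vs B) remains invisible to
parent-level markers in either case, and that is the contrast the k-mer
pipeline exploits.

## Pseudo-phasing

Within a candidate interval, sites heterozygous in the focal parent and
cleanly homozygous in the other (depth and allele-fraction windows
following common caller practice: other parent 18–64x and ≤0.05/≥0.95,
focal 10–50x and ≤0.05/≥0.95/0.40–0.60, QUAL at the caller cap of 999,
SNVs only) each carry one focal-parent-specific allele. Its read fraction
among parental-allele reads is computed per bulk; sites with
|Δfraction| ≥ 0.25 between bulks are grouped as the trait-linked
haplotype (`hap1`), ≤ 0.10 as the balanced one (`hap2`), in between
`unclear`. The 0.25/0.10 defaults are chosen to separate the dominant
model's causal contrast (~4/7 vs ~0) from both noise and the non-causal
haplotype's weaker, opposite-signed 1/7-vs-1/3 contrast; they are
configuration, not constants of nature.
`haplotype_density_track()` windows the categorized sites so their
spatial pattern can be compared against the enriched-k-mer dosage track.

## Numerical and engineering choices

* k ≤ 31 so a k-mer packs 2 bits/base into one 64-bit word; the 2-bit
  order matches lexicographic order, so sorted packed keys decode to
  sorted strings.
* Per-sample counting is a radix sort + run-length encoding of the packed
  windows (sequential memory access); bulk aggregation uses an
  open-addressing hash. `count_and_join_bulks()` fuses counting,
  thresholds, and the outer join in one compiled pass; its equivalence to
  the composed R-level operations is asserted in the test suite, as is
  the counting core's equivalence to a naive substring dictionary.
* Parental tables for origin calls are probed by query
  (`count_kmer_subset()`) rather than materialized in full.
* Problem sizes in the shipped tests: module tests run on ≤ 0.6-Mb
  fixtures; the acceptance suite runs the full desk-scale design (2 x 1 Mb,
  56 progeny) over ten seeds plus one recessive counterpart.
* Ties: peak seeding breaks toward the lowest coordinate;
  `call_differential` applies strict inequalities at both gates, so
  boundary values are excluded; `bonferroni()` caps at 1.

## Known limitations

* The recessive positive bulk is tiny by construction (1/16 of F2s), so
  its calls ride on few individuals, and the 5-fold causal contrast sits
  between the reasoning threshold (2.5-fold) and the calling gate
  (5.66-fold): the package reports the measured causal fold directly
  rather than pretending the gate and the reasoning coincide.
* Bonferroni over millions of k-mers is deliberately conservative
  (the classical conservative choice); at 4x coverage this costs power for k-mers with
  bulk counts below ~25.
* No overdispersion: biological replicates of a bulk are Poisson under
  this model; a negative-binomial extension is out of scope.
* The simulator's i.i.d. backbone makes k-mers nearly unique; real
  genomes' repeats would send some enriched k-mers to many loci, which is
  exactly what the MAPQ ≥ 40 filter is for, but that filtering is only
  exercised here through synthetic flags.
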