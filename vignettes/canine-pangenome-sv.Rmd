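---
title: "Methods: structural-variant and mobile-element analysis of canine pangenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant and mobile-element analysis of canine pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(canisv)
```

# The problem

Canine genomes carry an unusually large load of dimorphic mobile-element
insertions: the carnivore-specific SINEC family (~200 bp) and full-length
LINE-1 elements (~6 kb). A pangenome graph built from several
haplotype-resolved assemblies projects this variation into a multi-sample
VCF in which each graph bubble becomes a (possibly multi-allelic) record
against the reference path, with the pre-insertion ("empty") allele
represented by exactly 1 bp — the VCF anchor base. `canisv` takes that VCF,
plus repeat annotations, and characterizes the structural-variant landscape:
what the variants are made of, how insertion alleles are shared and mutate
after insertion, which LINE-1s remain retrotransposition-competent, how fast
SINECs and LINE-1s insert per generation, and how exact short tandem repeats
relate to other annotation classes.

# Models and procedures

## SV locus extraction

Records are filtered in a fixed order: (i) any missing genotype among the
analysed haplotypes removes the site, then (ii) sites not variable among the
analysed samples are removed (variability is judged on allele indices of
analysed haplotypes only, so a site where all ten haplotypes differ from the
reference but agree with each other is removed), then (iii) sites where the
longest and shortest carried alleles differ by under `min_size_diff` (50 bp)
are removed. A site failing several filters is attributed to the first, so
the filter counts partition the input exactly — a property the test suite
asserts. Alleles carried by no analysed haplotype are dropped; the VCF
anchor base is kept for all size arithmetic (the empty site is 1 bp) and
stripped only for composition analysis. Ties for the longest allele break
to the lower allele index.

## Composition classification

The longest allele at each locus is classified against merged repeat
annotations, a symmetric-DUST low-complexity mask, and exact tandem-repeat
runs, in a fixed clause order with a 70% coverage criterion: (1) single
repeat type ≥ 70% (SINEC by name prefix; LINE/L1 and LTR/ERV by class
string; all other element classes pooled as "OtherRepeat"); (2)
DUST ∪ Simple_repeat ∪ Low_complexity ≥ 70% gives LowComplexity, re-labelled
VNTR or STR when tandem runs with unit ≥ 7 bp or ≤ 6 bp respectively cover
≥ 70% of the allele (full-allele denominator, consistent with every other
clause; exposed as configuration); (3) the union of DUST and all repeat
annotations ≥ 70% gives Mixed; (4) ≥ 5% gives Partial; (5) else
Unclassified. When two repeat types both pass 70% (possible with nested
annotations), the larger covered length wins, with ties broken
SINEC > LINE/L1 > LTR/ERV > OtherRepeat — the frequency order of these
classes in canine pangenomes. Repeat-type precedence over the
low-complexity clause follows the clause order: the low-complexity rule
applies only to loci not already classified.

Annotation merging joins fragments sharing an element ID whose gap contains
only Simple_repeat/Low_complexity annotations (or nothing), and absorbs
(CT)n/(AG)n/(TC)n/(GA)n and other simple repeats lying inside a merged
element interval — SINECs carry an internal (CT)~N~ microsatellite that
RepeatMasker habitually annotates separately. A gap occupied by a different
element (the nested-allele case) blocks merging. The operation is
idempotent.

## Symmetric DUST

`sdust_mask()` scores every subinterval of at most `window` (64) bases by
the triplet statistic S = Σ~t~ c~t~(c~t~−1)/2 normalized by (k−1), k the
number of triplets. An interval is reported when its normalized score
exceeds `threshold/10` (2.0 at the default threshold of 20) **and** no
proper subinterval scores higher — the perfect-interval rule. The second
condition matters: without it, every 64 bp window containing a poly(A) core
would be masked wholesale, and downstream consumers (such as the
transduction filter counting unmasked query bases) would see masks bleeding
~60 bp into unique sequence. Scoring is exact rational arithmetic (doubled
integer scores, cross-multiplied comparisons) in a small C++ kernel with
O(window) memory; the test suite proves equivalence against a brute-force
R oracle that recomputes every subinterval's counts independently.
Non-ACGT characters break triplets, so an `N` always splits a mask.

## Exact tandem repeats

`find_exact_tandem_repeats()` reports maximal runs satisfying
seq[i] = seq[i−p] for each period p, with at least 2 whole copies and a
4 bp minimum span (the span may end in a partial copy; copy counts are
whole). Units are primitive (a run of "ACAC" is reported at period 2, not
4) and canonicalized to the lexicographically smallest rotation so runs
match regardless of phase. Overlapping runs of different periods are all
reported; classification and enrichment consume the union. The minimum span
and copy count are deliberate defaults, exposed as arguments, since exact
scans admit several reasonable conventions. Classification computes the
unrestricted-unit scan lazily — only when the low-complexity clause is
reached — because element-classified alleles (the large majority) never
need it.

## Clean MEI loci, heterogeneity and sharing

A locus is a "clean" SINEC or LINE-1 locus when *every* observed allele is
either the 1 bp empty site (ANCESTRAL) or classifies to the element type
(DERIVED) — every allele is classified, not just the longest. Allelic
heterogeneity is the number of distinct derived allele sequences; the
generator plants it by mutating element copies ((CT)-run and A-tail length
changes) on sub-branches below the insertion branch. Allele sharing is
tabulated per individual (presence = either haplotype derived), giving
singleton counts, 2⁵−1 sharing profiles, per-sample heterozygous versus
homozygous derived counts, and conditional sharing given presence in a
designated sample. Loci with no observed ancestral allele count as present
in all carriers, because the ancestral state of an MEI locus is the empty
site by definition. Sex chromosomes are handled by configuration (an
`autosomes` list); the synthetic chromosomes are all autosomal.

## LINE-1 ORFs and 3′ transductions

Alleles whose LINE-1 annotation spans < 4 kb are skipped. ORFs of ≥ 300
codons on the element strand are matched to the consensus ORF1p/ORF2p by
local protein alignment (BLOSUM62); a call is intact when the alignment
covers ≥ 90% of the matched consensus protein. An allele is fully intact
when both proteins are intact. A SINEC inserted in-frame into ORF2 (the
nested, "Matryoshka" allele) yields an intact ORF2p call longer than the
consensus; the elongation is reported in codons.

The transduced candidate is the allele segment 3′ (element orientation) of
the longest LINE-1 annotation, after trimming the terminal poly(A) run
(≥ 5 A's, one internal non-A interruption allowed; a trailing non-A means
no poly(A) to trim — the transduced segment may legitimately end in the
second target-site-duplication copy). Candidates under 25 bp are dropped.
Alignments to the genome are filtered in order: unplaced targets; match
score (matches − mismatches − gap opens) < 25; fewer than 25 unmasked query
positions under the union of repeat annotations and DUST; within 7 kb
(nearest edge) of the locus. A surviving call fails when more than
`max_hits` (5) alignments remain (segmental duplication / repeat homology)
or when the best alignment's genomic span exceeds its query span by more
than 100 bp (fragmented alignment). The 7 kb edge rule, the score formula
and `max_hits` are documented choices exposed as configuration, since
"excess of alignments" admits no single canonical constant. Sources
resolve, within a 1 kb window, to the 3′ end of a reference-annotated
LINE-1 (REFERENCE_SOURCE), else to a dimorphic LINE-1 locus
(SEGREGATING_SOURCE — the resolution of a "parentless" transduction), else
PARENTLESS; calls sharing a source form families.

The alignment backend is a seed-and-extend matcher (25 bp exact seeds,
diagonal clustering, local Needleman–Wunsch rescoring of the seeded
window). It fulfils a single "align query to genome" contract, so an
external aligner can be substituted.

## Insertion rates

Pairwise divergence time is calibrated from SNP counts as T = D/(2µL):
both lineages accumulate substitutions, so pairwise differences grow at
2µ per base per generation. µ defaults to 4.5×10⁻⁹/bp/generation, the
standard canine calibration; L is the analysed genome size after removing
duplication-annotated intervals, and D counts biallelic SNP sites (all
alleles 1 bp) outside that mask where the two haplotypes differ. The rate
per comparison is r = N/T with N the clean element loci derived in the
focal haplotype and ancestral in the outgroup haplotype — insertions on one
lineage over one lineage's time span, which is what "one insertion per X
births" means. Ten comparisons are averaged: each of the nine non-outgroup
haplotypes against the outgroup's first haplotype, plus the outgroup's
first haplotype against a dog haplotype (so outgroup-lineage insertions are
not double-counted). For LINE-1s, loci whose annotation ends more than
100 bp short of the consensus 3′ end are removed first; such alleles arise
by deletion inside pre-existing elements, not by new insertion, and the
removal fraction is reported split by whether the locus lies inside a
reference-annotated LINE-1 (where such variants concentrate).

## STR enrichment

Observed overlap (bp) between exact-STR intervals and each merged
annotation class is compared with the mean over `n_perm` (100) permutations
in which every STR interval is re-placed uniformly at random — chromosome
chosen proportional to length, placements independent, overlaps permitted —
matching the genome-wide shuffle dialect of the standard tool. Fold =
observed / mean(permuted); a class covering the whole genome therefore has
fold exactly 1, which the tests assert. The generator's reference carries
planted SINECs whose (CT)-runs and A-tails are exact STRs, so the
STR-in-SINEC fold is materially above 1 at desk scale (~2×); the genome-wide
magnitude reported for real data additionally reflects the full SINEC copy
number of a real genome, which the 2 Mb synthetic reference does not emulate.

## Segmental duplications and identity

Pair tables are filtered at ≥ 1 kb and ≤ 10% divergence (base filter,
mitochondrial pairs excluded when configured), then subset to ≥ 10 kb and
≤ 5% for the recent-duplication summary. "Separation" between
intrachromosomal paralogs is the gap between their nearer ends (0 when
overlapping); pairs under 200 kb separation are tandem, the rest dispersed.
Interchromosomal pairs are centromeric when both interval starts lie within
5 Mb of the chromosome start (start-position test; full containment would
differ only for pairs straddling the boundary). Percentages are rounded
half-up to one decimal, and the centromeric share also to integer
precision, matching how such figures are conventionally printed.
Gap-excluded identity is matches/(matches+mismatches); gap-compressed
identity counts each maximal run of inserted or deleted bases as one
difference; mismatches come from =/X operations or from NM minus indel
bases for M-only CIGARs.

# The synthetic cohort

The generator is the package's oracle, not a fixture: every planted event
records its branch, carriers, target-site duplication, truncation,
transduction source and allele set.

**Genealogy.** A fixed labelled tree over five diploid samples:
((ACDsim, CCsim):1500, (SHsim, NGSDsim):1000):3000 generations, with the
wolf-like outgroup GWsim splitting at 20,000 generations. Dog haplotypes
coalesce within-sample at 500 generations; NGSDsim at 50 (captive
inbreeding, producing the expected heterozygosity deficit); GWsim at
10,000, reflecting the deep within-individual diversity of an outbred wolf.
The wolf coalescence depth matters for the rate estimator: a shallow value
would leave the outgroup self-comparison with so few SNPs that the N/T
ratio becomes noise-dominated and upward-biased.

**Events.** SINEC and LINE-1 insertions are drawn Poisson per branch at
0.0125 and 0.00125 per generation (≈ 710 and ≈ 71 expected events on the
57,050-generation tree at the 2 × 1 Mb default) — desk-scale stand-ins for
the real per-generation rates, keeping their ~10:1 ratio. An event is
carried by exactly the haplotypes below its branch. Insertions carry
target-site duplications drawn uniformly from 5–20 bp, duplicated on both
flanks; SINECs draw A-tail extensions and occasional 5′ truncations;
LINE-1s are full-length with probability 0.35, else 5′-truncated by
1–5 kb, and 20% of full-length copies carry a premature ORF2 stop. Fixed
small numbers of STR and VNTR expansions, LTR insertions, mixed/partial
composites, unclassifiable inserts, deletions, intra-LINE-1 3′-deletion
variants (most placed inside reference LINE-1 copies), nested
SINEC-in-LINE-1 alleles (the SINEC consensus is built codon-aligned and
stop-free in frame 0 so the nested ORF2 stays open), and 20 transductions
(tags copied from the sequence downstream of reference-fixed or segregating
source elements, placed > 7 kb from the source) complete the event set.
SNPs are planted per branch at Poisson(µ t L) with µ = 4.5×10⁻⁹.

**What it does not emulate.** No recombination, no coalescent variance in
topology, no sequencing or assembly error, no genome-scale repeat copy
numbers, and RepeatMasker truth annotations are exact rather than
score-based. Passing tests therefore demonstrate correctness of the
*procedures* under known truth — not that real-data annotation noise is
handled optimally.

**Determinism.** All randomness flows from a single integer seed
(`withr::local_seed`); the same seed yields byte-identical emitted files
and pipeline reports, which the tests verify by hashing.

# Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; VCF POS and
  RepeatMasker begin/end convert at the IO boundary (round-trip tested).
* Unphased `a/b` genotypes are accepted as ordered with a warning —
  haplotype-resolved assemblies are inherently phased.
* Alleles are uppercased on read; masking state travels as annotations,
  never as case.
* DUST window 64 / threshold 20 are the canonical published defaults.
* Problem sizes: module tests run on a 2 × 200 kb cohort; the acceptance
  checks and `scripts/acceptance.R` on the default 2 × 1 Mb design —
  chosen so the full suite completes in minutes while keeping ≥ 500
  planted SINECs, the regime where 20% rate recovery is a meaningful bound
  given Poisson noise.
* The LINE-1 rate on synthetic cohorts is reported but deliberately not
  bound to the planted per-generation rate: the fixed-count extras
  (transduction carriers, nested alleles) sit on top of the Poisson
  process, so only the SINEC rate has a clean planted truth.

# Known limitations

* The library annotator is greedy best-score-first local alignment; it will
  not reproduce RepeatMasker's substitution-matrix scoring or long-range
  defragmentation, and is intended for allele-scale sequences.
* The seed-and-extend alignment backend assumes high-identity targets; a
  diverged transduction (not generated here) would need an external
  aligner behind the same contract.
* `merge_repeat_annotations` merges same-ID fragments across empty gaps as
  well as simple-repeat-bridged ones; distinct elements interrupted by
  unannotated unique sequence under a shared ID are rare in practice but
  would merge.
* Overlapping graph bubbles are treated as independent VCF records; the
  extractor does not deduplicate nested records.
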