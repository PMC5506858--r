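---
title: "Models and methods behind the meningioma cohort analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the meningioma cohort analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meningiomics)
```

This vignette is the package's own account of the statistics it
implements: the models, the parameters that matter and their defaults,
what the synthetic cohort generator does and does not emulate, the
numerical choices, and the design decisions taken where the problem
was genuinely open.

## The setting

High-grade (WHO II–III) meningioma is characterized genomically by a
moderate somatic mutation burden with essentially one recurrently
mutated gene (*NF2*), widespread arm-level copy-number disruption
dominated by chromosome-22 loss, substantial spatial heterogeneity of
mutations across serial resections in contrast to stable copy-number
profiles, rearrangements that frequently arrive in complex clustered
events, and a sizeable fraction of mutations predicted to yield
MHC-presented neoepitopes. Each module of this package quantifies one
of these observations from standard interchange files (MAF-like
mutation TSV, SEG segments, BEDPE junctions with junction-context
columns, metadata TSV, affinity and expression TSV).

All internal coordinates are 1-based inclusive; BEDPE's 0-based
half-open intervals are converted at the boundary. Chromosome names
are normalized by stripping any `chr` prefix. "Nonsynonymous" always
means {missense, nonsense, splice_site, frameshift_indel,
inframe_indel}.

## Burden, allelic-fraction filter and spectrum

The allelic-fraction filter discards mutations with AF strictly below
0.1 — the boundary is kept. It is applied before driver and
recurrence analyses, where low-AF artifacts would masquerade as
subclonal drivers, but **not** to burden counts, which are reported
unfiltered by default (a flag enables filtered counting); both views
are legitimate and the unfiltered one avoids coupling burden to
purity. Hypermutators are flagged at burden > Q3 + 3·IQR of the
cohort's nonsynonymous counts and retained, since removing them would
distort cohort means that legitimately include such samples.

The substitution spectrum collapses each SNV to its
pyrimidine-reference representation (G>A is counted as C>T), giving
six classes; the spectrum is therefore invariant under
reverse-complement relabeling of the input, which the test suite
checks property-style. Wilcoxon rank-sum is the default two-group
test (burden distributions are right-skewed); Student's t is
available where approximate normality holds.

## Percent genome disrupted and arm calls

Disruption is the percentage of covered autosomal genome with
|log2 ratio| ≥ 0.2. Sex chromosomes are excluded because cohorts mix
sexes and single-copy sex chromosomes would read as artifactual loss.
The metric is invariant under segment splitting and monotone in the
threshold — two properties the suite asserts, since they are what
make the number comparable across differently-segmented profiles.

Arm events are called when at least 80% of an arm's covered length is
altered in one direction. The 0.2 / 0.8 pair are conventional
arm-call values; no published threshold exists for this exact
procedure, so both are exposed as arguments and stamped into the
report's configuration hash. Arm boundaries ship as an
hg19 cytoband-derived table (`load_arms("hg19")`); a two-chromosome
toy table supports the tests. Angiomatous meningiomas are excluded
from cohort arm-incidence denominators because their gain-dominated
profiles are qualitatively unlike the rest of the disease.

## Driver co-occurrence and detection power

Driver flags (NF2 mutation, chromosome-22 loss, canonical non-NF2
driver, TERT promoter) are derived from AF-filtered nonsynonymous
calls plus arm calls. The canonical non-NF2 list defaults to the four
most frequent drivers (TRAF7, KLF4, AKT1, SMO) plus the other
published meningioma drivers; it is an argument, and the tests use
only the four. Pairs are tested with Fisher's exact test
(`stats::fisher.test`; the suite separately verifies the two-sided
p against a direct hypergeometric enumeration). Benjamini–Hochberg
q-values are reported alongside raw p-values as standard practice for
a matrix of tests.

Detection power for a gene mutated at per-patient rate $p$ in a
cohort of $n$ patients with detection requiring $\ge k$ mutated
patients is the exact binomial tail $P(X \ge k)$,
$X \sim \mathrm{Bin}(n, p)$. `detectable_rate()` inverts the tail by
bisection (the tail is continuous and strictly increasing in $p$ for
$k \ge 1$, so the root is unique) to a power mismatch below $10^{-10}$.
Two summaries are returned: the exact root, and the smallest whole
percent at which the target power is reached. The whole-percent form
is the natural reading of a statement like "power to detect genes
mutated in at least 19% of patients": at 19% the power clears the
target, at 18% it does not, even though the exact root (0.1838)
rounds to 18. Defaults n = 115, k = 15 describe a combined
discovery-plus-extension cohort of 115 patients.

## Heterogeneity and recurrence phylogenies

A patient's distinct mutations (keyed by chrom:pos:ref:alt,
gene-independent) partition by presence count into ubiquitous (all
samples), shared (some, > 1) and private (exactly one); the three
counts always sum to the number of distinct events, and single-sample
patients are flagged unanalyzable rather than silently skipped.

Pairwise overlap defaults to the Jaccard index — symmetric, bounded,
and insensitive to which sample is "first". Because "percentage of
mutations shared" is also sometimes computed against a single
sample's total, that variant (`denominator = "first"`, or `"min"`) is
exposed. Discovery curves average the recovered fraction of the
patient's events over all size-m sample subsets, which equals the
average over all orderings; the suite checks this equivalence by
brute-force enumeration at k ≤ 5.

Phylogenies use only *powered* mutations: a site enters the tree when
a clonal mutation there would be detected with ≥ 95% probability in
**every** sample of the patient, under a Binomial(depth, expected AF)
model requiring ≥ 3 alt reads — the standard minimum-alt-read calling
heuristic — with expected clonal AF
$\pi m / (\pi\,\mathrm{CN} + 2(1-\pi))$ from each sample's purity.
Depth is the observed depth where the site was called and the
sample's mean coverage elsewhere. This filter removes
presence/absence asymmetries that are artifacts of coverage, not
biology.

Trees are neighbor joining (`ape::nj`) on 1 − Jaccard distances with
an all-absent germline outgroup for rooting; negative NJ branch
lengths are clamped to zero, and samples are sorted lexicographically
before joining so the result is input-order invariant.

**Topology call.** Linear evolution (each recurrence derives from the
previously resected tumor) predicts that chronological neighbors are
each other's closest relatives; branched outgrowth from a
geographically heterogeneous primary predicts that closest relatives
are chronologically scattered. For each consecutive pair in resection
order, the pair counts as adjacent when *either* member's set of
nearest neighbors in patristic distance (ties included, germline
excluded) contains the other; the adjacency score is the fraction of
consecutive pairs counted, and the call is linear at score ≥ 0.5. The
one-sided containment matters: in a perfect chronological ladder,
each sample's nearest neighbor is the next sample, while the strict
"mutual" formulation could never score an interior pair and would cap
the ladder's score at 1/3. With the one-sided form a perfect ladder
scores 1.0 and interleaved cherries score 0.

## Rearrangement events and mechanisms

Junctions of one sample are linked when any breakend of one lies
within 10 kb of any breakend of another on the same chromosome;
connected components are events, and components with ≥ 4 linked
junctions are complex (chromothripsis/chromoplexy-like). The 10 kb
window is a package choice — assembly-based SV callers do not publish
a linkage rule — and is an argument; the fraction of junctions in
complex events is monotone nondecreasing in the window, which the
suite asserts. Clustering is implemented as union–find over
position-sorted breakends (equivalent to, and tested against,
all-pairs transitive closure).

Mechanism classification is a deterministic decision table over
junction context, using the conventional cuts of the
microhomology-based framework: templated insertion ≥ 10 bp → MMBIR;
else microhomology ≥ 3 bp → MMEJ; else NHEJ. Repeat-overlap flags are
ingested and retained but no repeat-mediated (NAHR) class is emitted,
matching the three-mechanism summary the analyses need; junctions
with missing features are `unclassified` rather than guessed.

## Neoantigens and clonality

Peptide enumeration produces every window of lengths 8–11 (MHC-I) and
15 (MHC-II) containing an altered residue, truncated windows dropped;
a central missense in a long protein therefore yields exactly
8+9+10+11 = 38 class-I windows and 15 class-II, and a frameshift
yields all windows touching novel sequence with no wild-type partner.
Binding affinities are consumed, never predicted: the composite
affinity of a peptide is the median across predictors, the neoepitope
ratio is mutant median / wild-type median (scale-invariant by
construction), and the best epitope per mutation is the minimum
mutant median with ties broken by lower ratio then lexicographic
peptide, so selection is deterministic. Binders are called at
≤ 500 nM, the conventional affinity cutoff, exposed as an argument.

The simplified cancer cell fraction inverts the expected-AF model:
$\mathrm{ccf} = \mathrm{af}\,(\pi\,\mathrm{CN} + 2(1-\pi))/(\pi m)$,
capped at 1 with the raw value retained; mutations are clonal at
ccf ≥ 0.9. This is a point estimate — no posterior over multiplicity
or copy number — which is why the clonality cutoff is deliberately
high. The expression filter ranks genes by cross-sample mean, drops
the bottom 25% (floor of 0.25·G genes, ties at the cutoff broken by
gene name for determinism), and reports the fraction of
neoantigen-bearing genes retained.

## The synthetic cohort generator

`simulate_cohort()` exists so that every analysis stage can be tested
against known truth. Its defaults are the study conditions the
analyses assume:

* nonsynonymous burden Poisson with mean 23 for grade II–III samples
  (7 for grade I); the generator scales total mutation counts by the
  nonsynonymous class probability (0.78) so the nonsynonymous count
  is exactly Poisson by thinning;
* a C>T-dominated six-class spectrum (weight 0.45), presented on
  either strand with probability ½;
* purity uniform on [0.8, 0.99] (study samples were
  high-purity), mean coverage 100×;
* chromosome-22q loss in 56% of patients; NF2 mutation in 75% of
  22q-lost vs 5% of 22q-intact patients (marginal ≈ 46%); canonical
  non-NF2 drivers in 35% of patients without an NF2/22q event vs 2%
  with, reproducing the co-occurrence and exclusivity structure;
* recurrent arm events (1p, 6q, 10q, 14q, 18q losses; 17q, 20q
  gains) at elevated rates over a 1–2% background;
* rearrangement mechanisms MMEJ 0.45 / NHEJ 0.45 / MMBIR 0.10
  (end-joining > 90%); isolated junctions at Poisson mean 5 per
  sample with 21% translocations; complex events at Poisson mean 0.4
  per sample with ≥ 4 junctions each (mean 8, a desk-scale stand-in
  for the much larger events real tumors can carry) chained within a
  1 Mb footprint per involved chromosome, isolated events ≥ 10 Mb
  apart;
* best-epitope affinities lognormal (σ_log = 1.5) calibrated so
  P(≤ 500 nM) = 0.66; decoy pairs strictly worse; predictor values
  jittered multiplicatively then rescaled so the recomputed median is
  exact; 76% of neoantigen genes placed above the expression
  filter's cutoff.

Clone trees follow the infinite-sites convention: no back-mutation,
multiplicity 1, each clone's mutation set nested along its ancestry.
Multi-sample patients get one dominant clone per resection. Linear
topology chains the dominant clones (clonal succession), so mutation
sets accumulate chronologically; branched topology grows two sibling
lineages from a founder and alternates resections between them, so
chronological neighbors are always from different lineages — the two
regimes the topology classifier must separate. Sample-private
subclonal passengers (Poisson mean 3, CCF 0.3–0.7) add realistic
noise. Alt counts are binomial at the expected AF given CCF, purity
and local copy number (1 on lost 22q), with Poisson depth; a
mutation is emitted when ≥ 3 alt reads are drawn, the same threshold
the detection-power model assumes.

What the generator does **not** emulate: trinucleotide (96-class)
signatures, focal copy-number events, subclonal copy-number states,
read-level noise, germline contamination, multi-hit sites, and
realistic rearrangement breakend sequence context. Passing recovery
tests therefore demonstrates correctness of the bookkeeping and
inference under the stated generative model, not robustness to every
artifact of real sequencing data.

## Numerical choices and problem sizes

Bisection tolerances: detectable_rate stops at |Δpower| < 1e-10.
Nearest-neighbor ties in the topology score use a 1e-9 patristic
slack. Degenerate inputs return NA rather than 0 where a fraction's
denominator is empty (composition of an empty stratum, neoantigen
fraction with no nonsynonymous mutations), and error loudly where
analysis is impossible (no autosomal coverage, empty cohort after
histology exclusion, single-sample partition).

The test suite's simulation sizes were chosen to keep the full run
near two minutes while leaving comfortable statistical margins:
arm-event recovery on 200 single-sample patients, mechanism mixtures
on 2000 junctions, topology calls on 200 four-sample patients at 30
mutations per clone, CCF recovery on 400 draws at depth 100, binder
recovery on 1000 mutations, Fisher type-I error on 1000 replicates of
1000-sample tables, and exhaustive oracle sweeps (hypergeometric
enumeration at small margins plus randomized tables with margins up
to 30, orderings at k ≤ 5, transitive closure at 50 junctions).

## Known limitations

* The CCF model ignores multiplicity > 1 and subclonal copy number;
  CCFs near the clonality cutoff are sensitive to purity error.
* Arm calls assume segments are purity-uncorrected log2 ratios; no
  ploidy adjustment is attempted, so whole-genome-doubled samples
  would under-call.
* The topology score is defined for ≥ 2 samples but is coarse at 2–3
  samples, where a single pair decides the call.
* Junction linkage is per-sample; recurrent complex events shared
  across related samples are not linked cross-sample.
* Peptide enumeration handles missense and frameshift; in-frame
  indels and stop-loss extensions are not enumerated.
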