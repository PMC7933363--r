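---
title: "Methods: dual-caller deletion consensus, effect annotation, and enrichment"
author: "delscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-caller deletion consensus, effect annotation, and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Population resequencing at modest coverage (around 9x per individual)
produces structural-variant calls with substantial caller-specific error.
A standard defence is to call deletions with two independent callers and
keep only events both report. `delscan` implements that consensus analysis
end to end for deletion SVs across multiple populations: per-sample
dual-caller intersection, cross-sample clustering into segregating loci
with per-population allele frequencies, genomic-effect classification
against a gene annotation, per-sample allelic-state tabulation, gene-set
enrichment of the deletion-affected gene catalog, and a side procedure
that anchors genetic-map markers on an assembly from tabular alignment
hits.

Because real cohort data of this kind are far too large for routine
verification, the package ships a first-class synthetic-data generator
that emulates the statistical structure the analysis assumes. Every stage
is tested against the generator's known truth.

# The consensus model

**Reciprocal overlap.** Two deletion intervals $a$, $b$ on the same
chromosome match with reciprocal overlap

$$\mathrm{RO}(a,b) = \min\!\left(\frac{|a \cap b|}{|a|},
\frac{|a \cap b|}{|b|}\right),$$

a symmetric similarity in $[0,1]$. A consensus requires
$\mathrm{RO} \ge 0.5$; the comparison is inclusive because an overlap "of
50%" includes exactly 50%. All internal coordinates are 0-based half-open;
conversions to the 1-based conventions of VCF and GFF3 happen only in the
readers and writers, so positional arithmetic lives under a single
convention.

**Size gate.** Only deletions of 500 bp to 100 kb (inclusive at both
bounds — the conventional reading of a closed range) enter the analysis.
Both callers' call sets are gated before intersection.

**Per-sample intersection.** For each sample, a primary-caller deletion is
kept when at least one secondary-caller deletion matches it at the
threshold. Matching is greedy and one-to-one: candidate pairs are taken in
descending RO, ties broken by smaller start-position difference, then
smaller secondary start (then primary start and record identifiers, making
the result invariant to input row order). One-to-one matching prevents a
single broad secondary call from validating many fragmented primary calls.
Consensus calls carry the primary caller's coordinates and genotype — a
deterministic provenance choice exposed through `primary_caller` — falling
back to the secondary genotype when the primary one is missing.

**Loci.** Consensus calls from all samples are clustered by single linkage:
calls are linked when they match at the same RO threshold, and each
connected component is one locus. Reusing the intersection threshold is a
documented design choice, not an externally fixed rule; single linkage is
the least committal clustering consistent with "the same deletion seen in
several samples". The locus representative interval is the component-wise
lower median of member starts and ends (the lower of the two middle values
for even counts), so representatives are always observed breakpoints. If a
sample contributes several calls to one locus, its most severe genotype is
kept.

**Allele frequencies.** Within each population,

$$\mathrm{AF} = \frac{\#\text{deleted alleles}}
{2 \times \#\text{samples with a defined genotype}}.$$

Samples of the cohort without a call at a locus count as homozygous
reference — the usual absence-of-call semantics of multi-sample SV merging
— while missing genotypes leave the denominator entirely.

# Effect classification

Each locus receives exactly one class against the protein-coding genes of
the annotation, by severity priority:

1. **coding exon** — overlaps at least 1 bp of an exon;
2. **intronic** — otherwise overlaps a gene span;
3. **regulatory** — otherwise overlaps the 1000 bp immediately up- or
   downstream of a gene span (both sides, strand-ignoring);
4. **intergenic** — none of the above.

"Coding" means exon overlap rather than strictly CDS overlap: minimal
annotations often lack CDS features, and exon overlap is what a
figure-level per-class count needs. The flank is measured from the gene
span including UTR-bearing exons. The priority resolves multi-gene
conflicts for the single-class counts, while `genes_hit()` still reports
every contacted gene with its strongest per-gene contact (exon, intron, or
flank), so the catalog loses nothing.

The **gene catalog** collects genes contacted through exon or intron by a
locus whose allele frequency exceeds 5% *strictly* (">" read literally;
a locus at exactly 0.05 is excluded). The gated frequency is the maximum
per-population AF by default: the analysis asks whether *some* population
segregates the deletion at appreciable frequency, and the maximum is the
deterministic reading of that question. A pooled mode
(`af_mode = "pooled"`), which pools deleted alleles over all called
samples, is available because the choice is genuinely open; the two differ
exactly when a deletion is common in one population and absent elsewhere —
the biologically interesting case, which is why "max" is the default.
Genes contacted only through the flank are reported in a separate
regulatory catalog rather than silently dropped or silently merged.

# Allelic-state tabulation and caller agreement

Per sample, consensus deletions are counted as heterozygous (one deleted
haplotype) or homozygous (two). Population summaries report the mean and
the sample standard deviation (n − 1 denominator, the convention for
cohort variability) of both counts; single-sample populations report `NA`.
Caller agreement is the squared Pearson correlation of the two callers'
per-sample call counts, computed on size-filtered raw calls before the
intersection — the quantity that answers "do the callers see the same
per-sample signal", independent of the consensus step. Zero variance in
either count vector leaves the correlation undefined with a notice.

# Enrichment

Over-representation of the catalog in a gene set of size $K$ within a
background of $N$ protein-coding genes, with a query of size $n$ and $k$
hits, is the hypergeometric upper tail $P(X \ge k)$. The tail is summed in
log space (log-binomials via `lchoose`, combined with a log-sum-exp) so
that extreme parameters cannot underflow; $k = 0$ returns exactly 1 and
impossible $k$ exactly 0. One-sided over-representation is the only test
performed — depletion is not the question a deletion catalog asks.

Multiple testing uses the Benjamini–Hochberg step-up: with $m$ sorted
p-values, $q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, capped at 1, returned
in input order; significance is declared on $q < 0.05$, coupling the
stated 0.05 level to the stated adjustment. Adjustment is applied within
one gene-set collection (one GMT file) at a time, mirroring per-database
reporting. Two numerical notes: the implementation agrees with
`stats::p.adjust(method = "BH")` (checked in the tests, which also verify
the hand-computable example $(0.01, 0.02, 0.03) \to (0.03, 0.03, 0.03)$);
and adjusted q-values are not p-values — re-applying the adjustment to its
own output inflates non-maximal values, so only genuine fixed points such
as fully tied vectors survive re-adjustment unchanged.

p-values printed by hosted enrichment services for curated pathway and
disease databases are not reproduction targets: they depend on the
database versions and the cross-species identifier mapping in effect at
query time, which are external state.

# Marker anchoring

Each marker's best placement among its 12-column tabular alignment hits is
chosen by ranking e-value (ascending), then bitscore (descending), then
alignment length (descending). No e-value or identity cutoff is imposed by
default because the procedure being reproduced states none; optional
thresholds can be applied by filtering the hit table beforehand. Residual
ties after all three keys take the lexicographically smallest
`(subject, start)` and are flagged `ambiguous` rather than dropped, so
downstream consumers can exclude multi-mapping markers explicitly.
Minus-strand hits (subject end before subject start) are normalised to
forward intervals with the strand retained as metadata. The dual-genome
summary partitions a marker universe into mapped-in-both / A-only /
B-only / neither, and `genes_in_interval()` performs the candidate-gene
lookup under a QTL support interval (overlap of at least 1 bp with a gene
span).

# The synthetic cohort generator

The generator emulates what the analysis assumes about real data:

* a gene annotation of non-overlapping protein-coding genes (2–8
  non-overlapping exons each) over a small multi-chromosome genome;
* truth deletions with log-uniform sizes from 100 bp to 200 kb —
  deliberately wider than the 500 bp–100 kb gate, so the size filter is
  exercised with known expected pass counts;
* a planted effect class per deletion, realised by rejection sampling
  against the package's own classifier, which guarantees planted class =
  classified class by construction;
* per-population allele frequencies from a zero-inflated Beta model
  (frequency 0 with probability 0.3, otherwise Beta(0.4, 1.6)): many rare
  deletions, some common, some population-absent — the qualitative shape
  of a site-frequency spectrum without claiming demographic realism;
* per-sample genotypes drawn from Hardy–Weinberg proportions at those
  frequencies;
* two caller profiles with distinct sensitivity, breakpoint jitter,
  genotype-error rate, and false-positive load: a lumpy-like profile (many
  short false calls; sensitivity 0.85, 30 FP/sample, log10 size mean 2.9)
  and a manta-like profile (fewer, longer false calls; sensitivity 0.80,
  8 FP/sample, log10 size mean 3.6). Defaults are configuration, not
  contract.

Two construction guarantees keep ground truth exactly scoreable. First,
truth deletions keep at least `min_gap` (1 kb) distance from one another,
so no two truth events can merge into one locus even under jitter.
Second, false positives are placed by rejection so that they match neither
any truth deletion nor the other caller's false positives for the same
sample at the RO threshold; a false call can therefore never survive the
dual-caller consensus, and precision against truth is exactly 1. Under
50 bp jitter every emitted true call still matches its truth at
RO ≥ 0.5 for gate-passing sizes (worst case: a 500 bp deletion shrunk by
50 bp at both ends gives RO = 0.8), so per-carrier recovery equals the
product of the two sensitivities up to binomial noise.

Everything is deterministic given the single config seed; per-(caller,
sample) substreams are derived from it, so one sample's calls do not
depend on how many other samples are simulated.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: read-level evidence and alignment
artefacts (reference bias, repeats, mapping-quality effects), breakpoint
microhomology, correlated caller errors, linkage between loci, population
structure beyond independent per-population frequencies, and SV types
other than biallelic deletions. The tests validate the analysis logic, not
any caller's real-world error model.

# Problem sizes and numerical choices in the test-suite

The shipped study conditions are three populations of eight diploid
samples and 300 truth deletions; the end-to-end noise-free recovery check
and the byte-level determinism check run at this size. Simulation-heavy
property checks (noise robustness over 20 seeds, clustering and classifier
oracles) run on a reduced cohort of three populations of four samples with
120 truth deletions over two 8 Mb chromosomes — large enough for every
class and caller behaviour to appear, small enough to keep the whole suite
fast. The null calibration of the enrichment kernel uses large sets
(600–1400 genes in a background of 10,000 with a query of 5,000) where the
discrete hypergeometric tail is effectively continuous; with small sets
the attainable test size sits visibly below the nominal level and no
continuous calibration statement holds.

Further fixed numerical choices: interval validation requires non-empty
intervals (`end > start`); degenerate jittered calls are clamped to length
1; the locus representative uses the lower median; greedy matching and all
orderings have total deterministic tie-breaks; table artifacts are written
with fixed number formatting so identical configurations yield
byte-identical outputs.

# Limitations

The package intentionally performs no breakpoint refinement, no local
realignment or genotype re-calling from reads, no CNV dosage estimation,
and no parsing of non-deletion SV records beyond counting and skipping
them. Multi-allelic records are rejected rather than split, because silent
splitting risks genotype misassignment in a strictly biallelic analysis.
The marker module does not run any aligner and builds no linkage maps; it
consumes hit tables and reports placements and accounting.
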