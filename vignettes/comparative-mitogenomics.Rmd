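---
title: "Comparative clitellate mitogenomics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative clitellate mitogenomics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The biological setting

Animal mitochondrial genomes are compact circles of roughly 14–16 kb
carrying a nearly fixed inventory: 13 protein-coding genes (PCGs), 22
tRNAs, two rRNAs and one major non-coding (control) region. Within
Clitellata — the annelid clade containing earthworms and leeches — the
gene arrangement is strongly conserved: all 37 genes sit on one strand,
the putative control region (pCR) lies between *trnR* and *trnH*, the two
rRNAs lie between *trnM* and *trnL1* separated by the mid-rRNA *trnV*,
and *nad4L* overlaps the 5' end of *nad4*. Against this stable background,
tRNA-level changes — translocations, adjacent swaps, duplications,
losses — are the informative events, and a duplicated tRNA whose second
copy carries a shifted anticodon raises a concrete, testable question:
does synonymous codon usage shift with it?

The package's analytical spine is therefore: curate annotations with
explicit rules, normalize and compare circular gene orders, count codons
under the invertebrate mitochondrial code, and test codon-usage
homogeneity across genomes with an exact conditional test plus a
progressive subgroup search. A seeded generator of synthetic clitellate
genomes makes every stage testable without external sequence downloads.

## Coordinate and data-model conventions

Internally all features use 0-based half-open coordinates; GenBank I/O
converts to and from the 1-based inclusive convention. This was a
genuinely open choice (annotation sources do not dictate internal
arithmetic); half-open spans make length and junction arithmetic free of
±1 corrections. A feature crossing the circular origin is stored as one
contiguous span with `wraps_origin = TRUE`, rather than split into two
segments, because curation and control-region logic need single
contiguous spans; lengths are computed modulo the genome length.
Gene labels are normalized through a shipped, user-extensible synonym
table. The Leu/Ser tRNA paralogs are disambiguated by anticodon when one
is annotated (trnL1 = TAG-, trnL2 = TAA-, trnS1 = TCT-, trnS2 =
TGA-decoding, DNA alphabet); explicit `trnL1`-style names always win.
Duplicate copies of a gene keep their base label in the data model (the
rearrangement layer must see repeated labels to detect duplications) and
receive suffixed display identifiers (`trnD`, `trnD2`) only in exported
tables.

## Curation rules

**Start codons.** Candidate starts are `ATG`, `GTG`, `TTG` — the set
observed in clitellate mitogenomes; it is configurable for other taxa.
The scan walks in-frame triplets from the first base after the upstream
feature's 3' end over a window of `W = 10` codons and takes the first
candidate, except that an ATG anywhere in the window is preferred over a
nearer alternative codon. No published source specifies `W`; 10 codons
bounds the ambiguity while covering the start-codon shifts seen in
practice (e.g. the glossiphoniid TTG in *cox3*), and it is a visible
parameter. When the upstream feature overlaps the annotated CDS start
(the *nad4*-after-*nad4L* case), the scan falls back to the annotated
start — scanning from inside the upstream gene would be frame-shifted
nonsense.

**Stop codons.** Three mutually exclusive classes, applied in order:
(1) *canonical* — an in-frame `TAA`/`TAG` ends at or before the next
feature's start; (2) *partial_T* / *partial_TA* — the final in-frame
bases are `T` or `TA`, the downstream feature is a tRNA, and it abuts
directly (gap 0). The gap-0 requirement operationalizes
"tRNA-adjacent": a stop fragment separated from the tRNA by spacer
bases would not be rescued by transcript processing. These stops are
noted as completed to `TAA` by post-transcriptional 3' adenylation of
the mRNA — the standard polyadenylation mechanism; descriptions of this
phenomenon occasionally speak of adding amino-acid residues, which we
deliberately do not follow (adenylation acts on the transcript, not the
peptide), and the note records the interpretation rather than silently
correcting anything. (3) *overlap* — everything else, with the overlap
length into the downstream feature recorded.

## Gene-order comparison

Orders are circular sequences of signed labels. `normalize_order()`
rotates the circle so `cox1` is first and, if the anchor lies on the
minus strand, reverses and complements the whole order; `cox1` anchors
because every genome in scope encodes it. Breakpoint distance counts
signed cyclic adjacencies present in one order but absent from the other,
with an adjacency and its reverse-complement reading identified;
duplicated labels are rejected rather than arbitrarily paired, which
avoids hidden assignment choices (callers resolve duplications first).

`detect_events()` infers an event list greedily with fixed priority:
label multiset differences become duplications/losses; maximal
strand-flipped runs whose reversed labels are contiguous in the reference
become inversions (and are flipped back); remaining labels off the
longest common subsequence become translocations, with two adjacently
exchanged genes collapsed into one `adjacent_swap`. This mirrors how
rearrangements are annotated descriptively in comparative figures — by
parsimony of description, not by optimizing an edit distance (no
DCJ/inversion-distance machinery, deliberately). Composite event sets are
recovered best-effort; the guarantee we test is single-event recovery:
200 seeded draws per event kind applied to the clitellate template are
each recovered exactly (kind and genes). Sampled translocations displace
a gene by at least two positions because a one-position move *is* an
adjacent swap — the two descriptions are the same permutation — and the
sampler never moves the anchor, which defines the rotational frame.

## The exact R×2 homogeneity test

Conditioning on all margins, a table with first-column entries
$a_i$ has probability
$P(a) = \prod_i \binom{r_i}{a_i} / \binom{N}{c_1}$,
and the two-sided p-value sums $P$ over every margin-consistent table
with $P \le P_{obs}(1+\varepsilon)$. Probability ordering with
$\varepsilon = 10^{-7}$ is the prevailing two-sided convention for exact
contingency tests (it is what `stats::fisher.test` implements); the
relative tie tolerance makes the inclusion of probability-tied tables
deterministic under floating-point arithmetic.

The engine (C++, `src/fisher_rx2.cpp`) enumerates stage-wise over rows:

1. **Feasibility pruning** restricts $a_k$ to values completable to the
   column total.
2. **Suffix tables**, computed once per call by dynamic programming over
   (row index, remaining column sum): the maximum and minimum completion
   log-numerators and the total completion mass
   $M_k(s) = \sum_a \binom{r_k}{a} M_{k+1}(s-a)$. A child subtree lying
   entirely at or below the threshold contributes its whole mass in
   O(1); one lying entirely above is skipped in O(1). Only
   threshold-straddling subtrees are ever expanded or stored.
3. **Path clustering**: straddling partial paths at the same stage with
   equal remaining sum whose log-probabilities agree within a quantum
   $\delta$ are merged; weights accumulate exactly in linear space
   relative to the first-seen representative. All log-mass sums use
   log-sum-exp; contributions are exponentiated only as probabilities
   (≤ 1), so no intermediate overflows occur even though raw masses
   reach $e^{440}$.

$\delta$ is chosen from the enumeration size (itself counted by a DP
before the scan): below $10^7$ tables $\delta = 10^{-13}$, which merges
only exactly-tied paths — the scan is a full exact enumeration, and it
matches a naive full-enumeration oracle to at least ten significant
digits on 500 random tables in the test suite. Larger problems use
$\delta = 10^{-4}$, $10^{-3}$, or $3\times10^{-3}$ (above $10^{12}$
tables). Measured against finer-δ runs on the cases where both are
feasible, the clustered scan is accurate to about $5\times10^{-5}$ at
$\delta = 10^{-3}$ and $\sim10^{-4}$ at $3\times10^{-3}$ — orders of
magnitude tighter than any decision the p-value feeds. The quantization
is unbiased rounding, so errors average out rather than accumulate; the
boundary shell that must be expanded stays in the single-digit millions
of nodes for a 9×2 table with N = 658, which runs in about a minute.
Without clustering that shell exceeds $10^{10}$ nodes — we measured the
blowup — which is why the plain pruned DFS alone is not enough.

For subgroup *decisions* (is p above α?) the engine additionally
maintains running bounds — mass proven below the threshold versus that
plus all unresolved subtree mass — and stops as soon as the comparison
resolves; strongly heterogeneous subsets terminate within a few stages.
`homogeneous_subgroups()` runs these decision scans at a coarse
$\delta = 0.1$ and re-tests any subset landing within a factor 1.5 of α
with a full-accuracy scan, so borderline calls are always made at full
precision. Reported groups get their p-values recomputed exactly.

**Conservatism.** Exact conditional tests are conservative; the suite
verifies that the rejection rate at α = 0.05 over 2,000 null 4×2 tables
stays at or below 0.05 plus two standard errors.

**Subgroup reporting.** Subsets are enumerated largest-first and a
subset of an accepted group is never tested (it cannot be maximal), so
the output is exactly the set of maximal homogeneous subgroups. On the
packaged clitellate table this recovers the two published groups — the
five oligochaetes and the GAT-biased hirudinean trio — and one further
maximal five-genome subset whose p-value sits just above α = 0.05; a
search that reports *all* maximal subsets will legitimately surface such
near-threshold groups, which is why the reporting rule, not a curated
list, is the contract. α defaults to 0.05, the conventional reading of
"significant" where no explicit level is given.

## The Kruskal–Wallis helper

`kruskal_wallis()` wraps `stats::kruskal.test` (tie-corrected H,
χ²-upper-tail p on k−1 degrees of freedom) in the shape used for
comparing amino-acid frequency vectors across proteomes. Published
applications of this comparison do not always specify the grouping unit
precisely, so the operation is provided generically and its printed
values are not treated as re-derivable benchmarks.

## The synthetic-genome generator

`simulation_config()` fixes every draw with one seed. Defaults are the
study conditions of hirudinean mitogenomics, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| template | clitellate arrangement | all textual constraints hold: pCR between trnR/trnH, atp6–trnR junction, cox2–trnD–atp8, trnM–rrnS–trnV–rrnL–trnL1, nad4L→nad4; remaining tRNA placements are fixed editable data |
| start plan | ATG everywhere, TTG for *cox3* | the glossiphoniid shift |
| stop plan | mostly `partial_T`, two `partial_TA`, canonical where the next feature is a CDS, *nad4L* overlap (7 bp) | incomplete stops dominate real clitellate annotations |
| θ(GAT) for Asp | 0.85 | hirudinean GAT bias (observed GAT fractions ≈ 0.80–0.88) |
| tRNA length | 60–72 nt | observed range; anticodon at fixed offset 29–31 |
| pCR | 600 bp, A+T 0.78 | AT-rich control region at clitellate scale |
| CDS lengths | realistic per-gene values (cox1 1536 … atp8 156) | genome assembles to ≈ 15 kb |

Amino-acid content of CDS bodies is random (uniform by default,
reweightable); only codon usage within each amino acid is controlled,
because only codon usage is analyzed. The first `W − 1` codons after a
planned non-ATG start are drawn ATG-free (Met realized as ATA) so the
planned start is unambiguous under the curation rule — a generator
constraint that mirrors how real alternative starts are only annotatable
when no earlier ATG shadows them. Duplicated tRNA copies reuse the first
copy's sequence, optionally with a shifted anticodon and an unannotated
spacer, reproducing the duplication geometry the tRNA report measures.
Synthetic tRNAs are sequence-random outside the anticodon (no cloverleaf
folding — structure prediction is out of scope), rRNAs are random
placeholders, and no sequence-evolution model connects genomes: passing
tests demonstrate correctness of the bookkeeping, the statistics and the
detectors under known truth, not realism of the sequences themselves.
Real data add annotation noise, structural variation and phylogenetic
correlation that these fixtures deliberately do not emulate.

## The pCR and tRNA-duplication reports

The pCR is identified operationally as the *longest* intergenic span
(annotated control-region and noncoding features do not count as
coverage), with the positional clitellate signature — flanked by trnR
upstream and trnH downstream — reported as a separate conformance flag.
Published analyses identify the region positionally but do not state a
criterion; length is the natural operational choice, and keeping the
positional test as a flag rather than a filter means a translocated
control region is still found and reported as non-conforming. Copy
comparison uses global alignment with match +1, mismatch −1, gap −2
(via Biostrings), identity = matching columns / alignment columns; the
scoring is fixed and documented since "strong similarity" otherwise has
no metric.

## Problem sizes and determinism

The test suite and the acceptance script use: the full 9-genome exact
test (N = 658) once each; 500 random oracle-comparison tables (R ≤ 4,
N ≤ 40); 2,000 null tables for conservatism; 200 seeded draws per
rearrangement kind; and 100 synthetic genomes for curation recovery and
length conservation. These sizes keep a complete run in a few minutes
while leaving the statistical checks tight (a 1% failure rate over 200
draws would be detected; the binomial band on θ(GAT) is ±0.03). All
simulations are seed-deterministic, and the generator restores the
caller's RNG state.

## Known limitations

- GenBank parsing covers the LOCUS/FEATURES/ORIGIN dialect of standard
  mitogenome records (single- or two-segment `join` locations); it is
  not a general-purpose GenBank parser, and GFF3 is not supported.
- Event inference is descriptive and greedy; overlapping composite
  rearrangements can be reported as more events than the minimal
  scenario, and duplicated labels are excluded from breakpoint distance.
- The exact test's path clustering makes very large tables tractable at
  a documented ~1e-4 relative accuracy; callers needing more can pass a
  smaller `delta` explicitly and pay the time.
- Curation trusts the annotated gene spans; it does not discover ORFs,
  infer genetic codes, or fold tRNAs.
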