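---
title: "Methods: comparative analysis of small circular replicons"
author: "mgecompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of small circular replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgecompare)
```

# Scope and model

`mgecompare` analyses sets of small (roughly 8-14 kb) circular
replicons — archaeal plasmids and related mobile genetic elements — and
reconstructs their comparative-genomic structure: protein-coding gene
complements, candidate replication origins, gene families shared across
replicons, the pan-genome presence/absence structure, gene-content
distance trees, and the overlap between an external (for example viral)
proteome and the plasmid pan-genome. All coordinates inside the package
are 0-based half-open on the forward strand; an interval that crosses
the origin of a circular sequence is encoded with `end > length`
(`end - start <= length`), and GFF3/BED emission converts at the
boundary.

# ORF prediction on a circle

`find_orfs()` scans all six reading frames with the conventions
standard for this class of replicons: minimum length 39 codons (the
start codon through the last sense codon, stop excluded), start codons
ATG/GTG/TTG, stop codons TAA/TAG/TGA. Alternative starts are translated
as methionine. Codons containing N terminate scanning and a truncated
reading is never reported as an ORF. Overlapping and nested ORFs are
all reported; selection among them is the caller's concern.

The scan enumerates every circular stop codon exactly once by reading a
concatenated copy of the sequence, so origin-spanning ORFs need no
special casing; no reported ORF exceeds the sequence length, and a
reading frame of a circular sequence without any stop codon is reported
as a warning rather than as an unbounded ORF.

Where several in-frame starts share a stop codon, the reported start is
chosen by Shine-Dalgarno (SD) context, automating what is usually
manual start curation. `score_sd()` reports the longest contiguous
exact match between the SD consensus (default `AGGAGG`) and the window
4-20 bp upstream of the candidate start on the coding strand, with the
match nearest the start winning ties. If any candidate scores at least
`sd_min_match` (default 4), the candidate maximising (SD score, then
ORF length) is chosen; otherwise the most upstream (longest) candidate.
A contiguous-match score was chosen over a free-energy model because it
is simple to audit and the consensus is configurable; it is not a
claim about translation-initiation energetics. All candidate starts
with their scores are retained in a sidecar table
(`attr(orfs, "candidates")`) for manual curation.

# Replication-origin prediction

Replication origins of these replicons sit in large intergenic regions
and coincide with inflections of cumulative GC skew.
`cumulative_skew()` accumulates per-position increments (+1 for G, -1
for C, 0 otherwise). The mean increment is subtracted before
cumulation, so the circular walk closes at zero and its minima are
rotation-equivariant; the raw start-point-dependent cumulative plot
remains available (`center = FALSE`) for visual comparison with the
literature convention. A circular moving average (default width 100 bp
in the pipeline) suppresses walk noise before minima are called.

Candidate minima are circular local minima with prominence at least a
configurable fraction (default 0.1) of the profile range — the
prominence gate suppresses noise valleys while keeping genuinely
bistable profiles. `predict_ori()` scores every intergenic region of at
least `min_len` bp (default 150) by its circular distance to the
nearest candidate minimum (0 when the minimum falls inside) and breaks
ties by the number of repeats fully contained in the region. All
qualifying regions are returned, ranked; profiles with two valleys
legitimately yield two candidate origins, and the tool never
auto-resolves that ambiguity — real cases exist where a second, deeper
valley appears after horizontal acquisition of new sequence, and
the decision belongs to the analyst.

Repeat support uses `find_repeats()`: all maximal exact direct and
inverted repeats of at least `min_len` bp (default 12), wrap-aware,
ranked by length. Length rank is the only notion of significance
implemented; a statistical model of repeat enrichment is intentionally
out of scope.

# Homology and gene families

Protein comparison is optimal Smith-Waterman local alignment under
BLOSUM62 with affine gaps (open 11, extend 1; a gap of length *g* costs
11 + *g*), computed by `pairwiseAlignment()` from Biostrings; an
independently written dynamic-programming implementation serves as the
test oracle, never the production path. There is no E-value model: on
search spaces of a dozen small replicons, significance is expressed as
a raw-score floor (default 30) plus identity and coverage thresholds.
Identity is the fraction of identical alignment columns. Coverage is
measured against the shorter protein, matching how identity-over-region
is conventionally reported for domain-level relationships.

A pair is a *full* hit at identity >= 0.30 and coverage >= 0.70, and a
*partial* (domain-level) hit at identity >= 0.30 and coverage in
[0.25, 0.70). Families are the connected components of the full-hit
graph (single linkage); partial hits never merge families, because
modular proteins sharing one domain would otherwise chain unrelated
families together. `modular_map()` instead projects all hits of one
protein onto its coordinate axis, merging overlapping segments from the
same partner family — the representation used for modular replicase
architectures, where for instance a replicase may share only its
C-terminal domain with another family's full-length protein. Family
identifiers are assigned from sorted member lists, so identical
memberships always produce identical ids regardless of input order.

These thresholds are a design decision, not a published constant: the
original analyses of such plasmid families relied on profile searches
(PSI-BLAST, HHpred) and manual curation whose remote homologies direct
pairwise alignment cannot reproduce. Relationships detectable only at
the profile level are expected to be missed; the thresholds are
configurable in `homology_params()`.

# Pan-genome structure

`presence_matrix()` binarises family membership per replicon (paralogs
collapse to presence; member counts are kept in a sidecar attribute).
Two gene-content distances are implemented because the field's
gene-content programs do not agree on one formula: `jaccard` (default),
d = 1 − |A∩B|/|A∪B|, and `shared_min`, d = −ln(|A∩B|/min(|A|,|B|))
with empty intersections mapped to a configurable ceiling. The choice
is recorded in the run report.

Trees are inferred with Saitou-Nei neighbor joining implemented in the
package (`nj_tree()`), with a deterministic lowest-index tie-break on
the Q criterion and negative branch lengths clamped to zero with the
deficit shifted to the sister branch. NJ recovers additive matrices
exactly, which gives the test suite a sharp correctness criterion
(exhaustive least-squares search over all 15 five-taxon topologies, and
`ape::nj` as an independent cross-check on noisy matrices). Rooting is
left to the caller (`ape::root` with an outgroup replicon).

Subfamilies are delineated by single-linkage agglomerative clustering
on the distance matrix cut at k = 2 by default (or at a distance
threshold). Conservation classes follow the usual comparative-map
colour scheme: *core* (all replicons), *semi-conserved* (at least one
replicon of each subfamily, but not all), *group-specific* (two or more
replicons of exactly one subfamily), *singleton* (exactly one
replicon). The four classes partition the family set by construction.

# The synthetic-data generator

`generate_set()` produces replicon sets with planted ground truth so
that every stage can be validated without external downloads. The
default configuration emulates the structure of a small archaeal
plasmid family: eight replicons in two subfamilies of four; two core
families, of which the first is a large replication-cassette gene of
650-900 codons (mirroring the large replicase ORFs these plasmids
carry) and the second a small regulator-sized protein; three
semi-conserved families present in members of both subfamilies but not
all replicons; four group-specific families per subfamily, each
spanning its whole subfamily; and two singletons. Other protein
lengths are drawn from 80-400 amino acids, keeping replicon lengths in
the 8-14 kb band observed for such plasmids; a redraw loop rejects
length combinations that cannot be packed into that band and errors
when no packing exists. With group-specific families spanning their
whole subfamily, every within-subfamily Jaccard similarity strictly
exceeds every across-subfamily similarity for all realisable semi and
singleton assignments (worst case 6/11 within versus 5/13 across), so
the planted two-way split is recoverable by construction rather than
by luck.

Family members derive from a family ancestor by point substitutions at
`intra_family_divergence` (default 0.10, giving about 80% pairwise
identity within a family — comfortably above the full-hit thresholds —
while unrelated ancestors stay far below them). There is no indel
process: substitution-only evolution keeps identity and coverage
analytics exact. Genes are back-translated with skew-aware synonymous
codon choice, an `AGGAGG` motif is planted with its 3' end 8 bp
upstream of every start, and genes are placed around the circle with
intergenic spacers, one large region of 300-600 bp preceding the
replication cassette.

The planted origin sits in the middle of that large region. Downstream
of it, on the leading strand, skew-informative positions (spacer G/C
choices and synonymous third positions offering a G/C choice) carry G
with probability `ori_bias` (default 0.7), switching to C at the
antipode — a single-origin, antipodal-terminus model. Spacer G+C
probability is set after gene synthesis so the whole replicon lands
within ±3 points of the configured G+C target (default 45%). A direct
14 bp repeat pair is planted inside the origin region by default.

Random sequence of this length contains many chance open reading
frames above 39 codons, which real annotations remove by curation. The
generator instead refines each replicon until its ORF complement under
default parameters *equals* the planted gene set exactly: a stop codon
is written immediately upstream of every planted start (so no spurious
upstream extension can ever be chosen), and chance ORFs are eliminated
by planting stop codons in editable spacer positions or by swapping
synonymous codons inside genes. Slot choice is randomised within the
admissible window because overlapping chance ORFs on opposite strands
can otherwise resurrect one another through a cycle of deterministic
fixes. When a whole window admits no synonymous fix (for example a
minus-strand reading inside a gene whose local amino acids offer no
stop-compatible codons), a single amino acid of one planted protein is
exchanged; truth proteins are re-derived from the final sequence, so
truth is exact by construction. Whole-replicon rebuilds with fresh
draws handle the rare remaining corner cases. All randomness flows from
the single configured seed, and a fixed seed reproduces the set byte
for byte.

`generate_decoy_proteome()` emulates a viral genome that half-overlaps
the plasmid pan-genome: a configurable fraction of queries are diverged
copies of family representatives, the rest composition-matched random
proteins, with truth recording which is which.

What the generator does *not* emulate — indels, rate heterogeneity
across sites, recombination, gene fission/fusion, profile-level remote
homology, multi-origin replication, skew perturbation by recent
horizontal transfer — bounds what green tests mean: they demonstrate
that the implementation recovers planted structure under the stated
regime, not that the thresholds are optimal for every real data set.

# Validation studies and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`, recomputed by
`scripts/acceptance.R`) runs: ORF-call equality against a rotating
brute-force oracle on 100 random 600 bp circles; alignment-score
equality against an independent dynamic-programming implementation on
200 random peptide pairs up to 50 aa; exact recovery of 25 additive
4-taxon matrices (topology and branch lengths) plus topology agreement
with exhaustive least squares on 25 random 5-taxon matrices;
origin recovery on 50 single-replicon synthetic plasmids at
`ori_bias = 0.7` (rank-1 region contains the planted origin and the
skew minimum lies within 250 bp, required in at least 90%); full
pan-genome recovery on 20 eight-replicon sets (family partition at
adjusted Rand index 1.0, correct two-way split, every family's
conservation class correct, required in at least 95%); and a 12-protein
decoy proteome at 40% divergence with 6 planted homologues, which must
map exactly 6 queries and leave 6 orphans. These sizes keep the whole
suite within desk-scale runtimes while leaving each statistic enough
replicates to be meaningful.

# Numerical and degenerate-input conventions

* G+C content excludes N from the denominator; an all-N sequence is an
  error.
* Coding density is union coverage (overlaps counted once), wrap-aware;
  the sum-of-lengths convention is available as an option since
  published coding percentages do not always state which was used.
* The skew profile of an all-A/T sequence is flat; origin prediction
  then warns and returns no candidates rather than inventing one.
* Distance matrices must be symmetric and finite; NJ needs three taxa,
  and with exactly three the star tree with closed-form branch lengths
  is returned.
* Ties: NJ picks the lowest index pair; `choose_start` breaks SD ties
  by ORF length then coordinate; family ids derive from sorted member
  lists; subfamily labels come from `stats::hclust`, which is
  deterministic for a fixed input order.

# Known limitations

Pairwise alignment misses remote homologies that profile methods find,
so cross-element homologue maps built from distant relationships will
be incomplete under default thresholds. The origin model assumes a
single origin with an antipodal terminus; replicons with displaced or
multiple origins will show multi-valley profiles that the tool reports
but does not interpret. The GenBank reader covers the flat-file subset
needed for small replicon records (single-interval and contiguous
wrap-around `join` CDS locations); exotic compound locations are
skipped with a warning.
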