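---
title: "Comparative plastome architecture with plastarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome architecture with plastarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastarch)
```

plastarch analyses how chloroplast genomes differ in architecture between
closely related algae: overall composition and coding density, the large
inverted repeat (IR) and its "ebb and flow" at the single-copy junctions,
gene-order rearrangements measured as exact reversal distances, the load of
short dispersed repeats, and the distribution and mobility signature of
group II introns. This vignette explains the models and conventions behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices that were genuinely
open.

## Coordinates and containers

A genome is a `plastome`: a circular DNA string over `{A,C,G,T,N}` plus
typed, stranded features held in a `GRanges`. All coordinates are 1-based
inclusive — the GenBank/GFF3 convention — both internally and in every file
read or written, so there is no 0-based/1-based conversion boundary anywhere
in the package. Multi-interval features (trans-spliced genes, features
wrapping the circular origin) are stored as several ranges sharing a
feature id, with a `part` index preserving transcription order; the 5'-most
exon is always `part = 1`, which is also the position used when a gene must
be represented by a single marker.

Ambiguity codes collapse to `N` on input, and `N` is excluded from
composition statistics (both numerator and denominator of the A+T
fraction). In repeat finding, `N` never matches anything, including another
`N`; this prevents runs of ambiguous sequence from masquerading as repeats.

## Genome accounting

`annotation_accounting()` partitions each genome into coding, intron and
intergenic fractions using interval unions, so overlapping annotations are
never double-counted. Conserved genes are features of kind `gene`, `tRNA`
or `rRNA`, optionally restricted to a user-supplied reference list; ORFs
without similarity to known genes are deliberately excluded from the coding
fraction and counted as intergenic spacer, and genes duplicated in the IR
count once. The mean intergenic size divides total intergenic bp by the
number of maximal intergenic gaps on the circle; the two terminal gaps of
the linearized view merge across the origin. Dividing by gap count (rather
than by gene count) was an open choice; we prefer it because it makes the
mean the expected length of a random spacer.

## The inverted repeat and the quadripartite map

`detect_inverted_repeat()` returns the longest pair of disjoint segments of
the circle such that one is the exact reverse complement of the other.
Exactness (mismatch tolerance 0) is the default because plastid IR copies
are homogenized by recombination-mediated gene conversion and are expected
to be identical; a `tolerance` parameter chains collinear exact matches
across up to that many mismatched positions, and the number of mismatches
actually absorbed is always reported rather than silently accepted. Ties on
length are broken by the smallest start coordinate, making detection
deterministic; rotating the circle never changes the detected length.

The two single-copy arcs between the copies become SC1 and SC2, labelled
strictly by size (SC1 is the larger), never by gene content. The copy
followed by SC1 is labelled IR-A, so the circle always reads IRa, SC1, IRb,
SC2 and the four junctions are comparable between genomes.
`compare_junctions()` reports, for each junction, the gene spanning it and
how many bp of that gene lie inside the IR — the quantitative trace of IR
expansion and contraction — or the nearest gene when the junction falls in
a spacer.

```{r ir-demo}
sim <- simulate_plastome(sim_config(seed = 1, genome_length = 50000,
                                    n_genes = 20, ir_length = 8000,
                                    gene_length_range = c(200, 500)))
detect_inverted_repeat(sim$plastome, min_len = 5000)
```

## Signed gene orders and reversal distance

Gene order differences are measured on the signed permutation relating the
two genomes over their shared gene set. IR-duplicated genes are collapsed
to the IR-A copy (duplication outside the IR is an error, not a silent
choice), trans-spliced genes are positioned at their 5'-most exon, and the
circle is linearized by cutting just before an anchor gene and flipping, if
necessary, so the anchor reads forward. The anchor choice is arbitrary by
design: linear reversal distance after anchoring is invariant under the
dihedral symmetries of the circular order, a property the test suite checks
over every possible anchor on fixtures.

`reversal_distance()` computes the exact minimum number of reversals via
the breakpoint graph of the framed permutation:

d = (n + 1) − c + h + f

with `c` the number of alternating cycles, `h` the number of hurdles
(minimal unoriented components, plus a greatest hurdle when one unoriented
component contains all others) and `f` an indicator for the fortress
configuration in which every hurdle is protected. Hurdle and fortress
handling is implemented in full even though closely related plastomes
essentially never exercise it (their distances are tiny); correctness on
arbitrary synthetic permutations matters for the generator-driven tests.
The implementation is validated against an independent breadth-first-search
oracle over the complete reversal graph — exhaustively for every signed
permutation of up to 5 elements (and, during development, up to 7;
fortresses cannot occur at those sizes, so the fortress branch is exercised
only structurally). `sorting_scenario()` returns an explicit sequence of
exactly `d` reversals found greedily among distance-reducing reversals,
which always exist.

```{r reversal-demo}
reversal_distance(c(1L, -3L, -2L, 4L))
sorting_scenario(c(1L, -3L, -2L, 4L))
```

Rearrangement rates are expressed as reversals per 1,000 substitutions.
Substitutions come from a deliberately simple plug-in: a pairwise JC69 or
K80 closed-form distance over the gap- and N-free columns of a supplied
alignment, scaled by the number of retained sites. This replaces tree-based
codon-model branch lengths, which require an inferred phylogeny; when such
estimates exist they can be passed directly to `rearrangement_rate()`.
Saturated alignments (where the correction is undefined) raise an error
rather than returning an extrapolation.

## Dispersed repeats

`find_maximal_repeats()` reports every maximal exact repeated pair of at
least `min_len` bp (default 30), in both orientations: a pair is maximal
when extending either copy by one position breaks the match, each unordered
pair is reported once, and self-overlapping tandem copies are allowed.
Internally, shared k-mers (k = min(min_len, 31)) anchor extensions, with
per-diagonal bookkeeping so each maximal pair is extended once; circularity
is handled by modular extension from seed starts on the circle. The
implementation is required by the tests to agree exactly, hit for hit, with
a quadratic brute-force finder.

`mask_coverage()` merges every interval participating in any hit and
reports the covered fraction — plain interval union, with no scoring or
defragmentation heuristics. In the full comparison pipeline, the single
inverted hit that merely restates the IRa/IRb duplication is excluded, so
the coverage measures *dispersed* repeats; repeats lying inside the IR
copies still count.

## Introns: registry, positional homology, identity

Intron insertion sites are only comparable across taxa in a common
coordinate system, so sites are expressed as the reference-gene position of
the nucleotide immediately preceding the intron. `map_insertion_site()`
aligns the concatenated host exons to a homologous reference gene
(ends-free overlap alignment) and reads off the reference coordinate; if
the site falls in an alignment gap the nearest upstream reference position
is returned with an explicit approximation flag. Reference sequences (a
deeply diverging taxon's genes, bacterial rRNAs for ribosomal sites) are
user-supplied inputs: the convention is the contract, not the data.
Positional homologs are grouped by *exact* (gene, site) equality — one
nucleotide of disagreement means separate groups, which is the point of
mapping to a common reference first.

`pairwise_intron_identity()` quantifies how similar two intron copies are
over a global alignment whose identity denominator includes gap columns,
so the value reflects the full spans of both sequences. Defaults (match
+1, mismatch −1, first gap position −5, each further −2) are ordinary DNA
alignment parameters and are configurable; identity values quoted at a
fraction of a percent are therefore aligner-parameter dependent and should
be treated as approximate.

## EBS/IBS pairing and the mobility signature

Group IIA introns recognize their exons through base pairing between three
short motifs in intron domain I (EBS1, EBS2, delta) and complementary
stretches in the flanking exons (IBS1 at positions −6..−1, IBS2 at
−13..−7, delta-prime at +1 of the 3' exon). These window defaults are the
canonical IIA geometry and can be overridden per record; the delta/delta′
interaction is modelled at 1 nt by default (configurable to 3) because IIA
introns show a single delta′ contact. `pairing_profile()` pairs motif
against window antiparallel, counting Watson–Crick and G·T wobble pairs;
whether wobble counts as "complementarity" is genuinely ambiguous in the
field, so it is on by default and togglable. The verdict operationalizes
"perfect or nearly perfect": 0 mismatches is perfect, exactly 1 is
near-perfect, more is incompatible — the tightest defensible reading.

`mobility_signature()` classifies how an intron family spread. Under
ectopic retrohoming the exon-binding motifs of each copy diverge to match
that copy's new target, so inter-copy motif divergence D is high while each
copy's self-compatibility is preserved; under retrotransposition the motifs
stay near-ancestral and tolerate target mismatches, so self-compatibility C
collapses. The thresholds (retrohoming-like when D ≥ 0.2 and C ≥ 0.8;
retrotransposition-like when C < 0.5; otherwise indeterminate, as for a
family of identical perfectly pairing motifs, which carries no divergence
signal) are package defaults: the underlying argument is qualitative, and
the classifier's validity is established by synthetic-recovery tests — both
generator modes are recovered in 40/40 seeded families each — not by
literature constants.

```{r mobility-demo}
fam <- plant_intron_family(sim_config(seed = 2, family_size = 6,
                                      mobility_mode = "retrohoming"))
mobility_signature(pairing_family(fam$pairing_table))
```

## What the generator emulates — and what it does not

`simulate_plastome()` produces the architecture the analyses consume: a
circular genome at A+T 0.702 (the composition typical of these plastomes),
~100 named, stranded genes, an exact IR housing the rRNA operon (default
copy length 23,748 bp in a 204,438-bp circle, mirroring a real
oedogonialean genome), and a 63/37 split of the remaining circle into the
two single-copy arcs. The planted IR's flanking bases are adjusted so the
repeat is maximal — without this, one-position chance extensions would make
exact coordinate recovery fail about half the time. `apply_reversals()`
cuts only in intergenic gaps (never splitting a gene) and never touches an
IR copy, since reversing one copy would silently convert the IR into a
direct repeat; this mirrors the observation that real rearrangements
between close relatives sit inside the single-copy regions.
`evolve_sequence()` applies i.i.d. per-site JC69/K80 substitution;
`plant_repeats()` copies unique segments into intergenic space until a
target masked coverage is reached; `plant_intron_family()` builds one
ancestral IIA core and disperses diverged copies in either mobility mode.
The default per-site distance (0.07) is the order implied by one reversal
at ~0.4 reversals per 1,000 substitutions over a ~37-kb gene set.

Deliberately *not* emulated: indels and rate heterogeneity (sequence
evolution is substitution-only), codon structure within genes (genes are
random sequence), repeat family structure (each planted repeat has
independent copies), IR ebb-and-flow dynamics, and degraded IR remnants.
Passing the recovery tests therefore demonstrates correctness of the
measurement machinery on clean architectures, not robustness to the full
messiness of real annotations — misannotated exon boundaries or partially
homogenized IRs must be handled by the user-facing tolerance and gene-list
parameters.

Determinism is a contract: a `sim_config` (including its seed) yields
byte-identical outputs, and each component draws from its own seed
substream so changing one stage's parameters does not perturb another's
sampling.

## Numerical and scale choices

Test and acceptance runs use scaled-down instances chosen to keep the full
suite within a few minutes on one CPU while leaving every effect
unambiguous: 40–50-kb genomes with 20–60 genes, an 8-kb planted IR against
a 5-kb detection threshold, 2-kb sequences for brute-force repeat
equivalence (50 of them), 50-kb sequences for distance-estimator recovery
(where the planted d = 0.1 is ~30 standard errors above zero), 20 seeds
per recovery claim and 40 per mobility mode. Degenerate inputs are errors,
not guesses: all-N composition, saturated distances, zero substitution
counts, sub-threshold intron families, and infeasible generator packings
all raise typed error messages.

## Known limitations

* Fortress permutations require more elements than exhaustive BFS
  validation can cover (n ≤ 7); the fortress branch follows the published
  theory and is exercised structurally, but no exhaustive oracle backs it.
* The GenBank reader parses the FEATURES block dialect only (locations,
  qualifiers, join/complement), not full flat files.
* Repeat masking is plain interval union; tools that score and defragment
  repeat families will report somewhat different coverage on real genomes.
* `pairwise_substitutions()` is a two-sequence estimator; it does not
  replace tree-based distances when a phylogeny is available.
* Intron class (I/IIA/IIB) is taken from the annotation input; the package
  does not infer it from sequence.
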