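---
title: "Methods: small RNA discovery, classification and expression in hexamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA discovery, classification and expression in hexamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexamir)
```

hexamir implements the desk-side analysis chain of a plant small RNA
sequencing study in a species without a finished genome: eight
libraries (four tissues, a control and three abiotic stresses) are
cleaned to a putative small RNA population, mapped exactly onto a
reference contig compilation, screened for miRNA hairpins, classified
against a reference catalog, profiled by digital expression, and
scanned against a transcriptome for targets. This vignette explains
the model behind each stage, the tunable parameters and why their
defaults are what they are, the numerical choices, and what the
synthetic validation does and does not demonstrate.

## The elimination pipeline

Raw reads carry a 3′ sequencing adapter. `trim_adapter()` keeps the
insert preceding the left-most exact match of the adapter's first 8
bases (`seed_len`, configurable). Exact-seed trimming is deterministic
and auditable; we deliberately do not do mismatch-tolerant adapter
alignment, so inserts that happen to contain the seed are truncated
(probability ≈ 3.5 × 10⁻⁴ for a 30-nt read — negligible at the library
sizes involved, and such reads mostly fall into the junk-length
class).

Cleaning then applies four tests in a **fixed first-match priority
order** — length, low-complexity, invalid, t/rRNA — so each read lands
in exactly one accounting category and the identity

> putative = total − (length-filtered + low-complexity + invalid + t/rRNA)

holds separately for redundant reads and for unique sequences. The
order is a design choice (any fixed order yields disjoint categories;
re-running reproduces identical tallies). The individual rules:

* **Length** (16–30 nt, boundary inclusive): the Dicer product range
  plus margin; both bounds are parameters.
* **Low complexity**: a read is flagged when tandem runs (two or more
  back-to-back copies) of a single k-mer, k ≤ 3, cover at least 80% of
  its length. This operationalises "simple sequence repeats and tandem
  repeats" as a brute-force-verifiable rule. The implementation
  screens candidates with a vectorised necessary condition (a tandem
  covering c bases forces ≥ c/2 self-matches at lag k) and runs the
  exact rule only on the survivors; the two paths are tested for
  agreement.
* **Invalid**: any character outside A/C/G/U after RNA normalisation
  (N included); the empty string is invalid.
* **t/rRNA**: exact substring occurrence in a contaminant reference
  set or its reverse complement — deterministic, no alignment. An
  empty contaminant set warns and passes everything.

Because each rule is a pure function of the sequence, categories are
assigned once per distinct sequence and redundant tallies follow by
count aggregation, which is what makes the two conservation identities
exact rather than approximate.

## Exact mapping

`build_index()` records every forward-strand k-mer position (k = 16,
the minimum retained read length); queries anchor at their first 16
bases and are verified by substring comparison, with minus-strand hits
found by querying the reverse complement. All loci of a read are kept:
plant MIR genes are commonly multi-copy, and discarding multi-mappers
would bias discovery. The mapper is property-tested against a naive
window scan on both strands.

## Folding: two dynamic programs

`fold()` is a maximum-pairing-score nested-structure DP with pair
scores GC = 3, AU = 2, G:U = 1 and a minimum terminal loop of 3
unpaired bases — a deterministic stability surrogate whose optimum is
verified against exhaustive enumeration on short sequences. Its
traceback pairs the left-most base whenever pairing achieves the
optimum, with the nearest admissible partner, so results are unique. A
`folder` plug-in slot accepts an external thermodynamic folder that
honours the same `structure`/`score`/`pair_table` contract.

A maximum-score fold has no notion of helix stacking, and this matters
for hairpin screening: on a 200-nt window a genuine pre-miRNA stem is
routinely shredded, because scattering the mature's bases over short
spurious helices (in the terminal loop region or the flanks) ties or
beats the contiguous stem score. We measured roughly half of perfect
planted hairpins failing annotation screening under the general fold.
Thermodynamic folders avoid this through stacking energies; our
deterministic equivalent is **`fold_hairpin()`**: the same pair
scores, but the structure is constrained to a *single stem-loop* (one
terminal loop, no branching), with at most 6 unpaired bases per side
between consecutive pairs and a **skip penalty of 3 per unpaired base
enclosed by the stem** (bases outside the outermost pair and the
terminal loop are free). The penalty equals the strongest pair score,
so a diffuse bulge-ridden pairing cannot outscore a genuine contiguous
helix; 6-base bulges are ample for the 0–2 substitution damage real
star arms carry. With this folder, 100% of perfect planted hairpins
pass screening and return the planted star exactly — the property the
screening stage is specified to have.

## Hairpin screening (annotation criteria)

`evaluate_hairpin()` applies the community rules for plant miRNA
annotation: the mature must sit on one arm of a stem-loop (no partner
inside the mature, partners all on one side), be unpaired over at most
4 bases, and form a duplex with its star carrying 2-nt 3′ overhangs
and at most 4 mismatches. The reported precursor is trimmed to the
maximal stem-loop enclosing the duplex, which is why trimmed precursor
lengths (roughly 60–220 nt here) are decoupled from the ±100-nt search
window.

**Star register.** In an antiparallel helix every pair (t, partner(t))
shares the antidiagonal t + partner(t). `predict_star()` takes the
modal antidiagonal over the mature's paired positions as the duplex
register and reads the star as the span from the partner of mature
position L−2 to the partner of position 1, plus two 3′ bases — the
canonical Dicer register. Using the mode rather than the boundary
partners makes the call robust to unpaired ends and to chance one-base
helix extensions into the flank. A star is refused when fewer than
L−4 mature bases are paired.

**Duplex mismatches.** `duplex_mismatches()` counts positions that
form neither a Watson–Crick nor a G:U pair, with each unpaired base
beyond the overhangs counting 1 when lengths differ. Annotation tools
print mature/star pairs in two registers — the 2-nt-overhang register
(mature position m faces star position L−1−m) and the blunt
full-overlap register (m faces L+1−m); published true-novel tables are
frequently in the latter. We therefore return the minimum over both
register families anchored at either end, which also makes the count
symmetric in its arguments. The packaged 49-record true-novel table
illustrates this: its cited pair (tae_40) counts 0 mismatches in the
blunt register but 11 in the overhang register.

**Search strategy.** `screen_locus()` evaluates a deterministic
cascade of sub-windows inside the ±100-nt search region: asymmetric
windows (8 nt on the mature-arm side; 31, 46, 61, 76, 91 nt on the
other side, in both orientations — the long side must hold the loop,
star arm and overhang, so the grid covers terminal loops of 8–60 nt
with little flank noise), then the full symmetric window. A candidate
whose trimmed stem-loop sits strictly inside its window and whose
duplex is mismatch-free wins immediately; otherwise all windows are
screened and the best accepted candidate is kept (complete before
clipped, then fewest mismatches). This prevents both failure modes we
observed: a hairpin clipped at a tight window's edge masquerading with
a truncated star, and a spurious flank stem shadowing the genuine call.

When two accepted calls are each other's duplex (one read is the
other's predicted star), the more abundant read is kept as the mature —
the standard dominant-arm convention.

## Classification and naming

Categories follow the mismatch bands used for wheat: identical to a
catalog entry ⇒ *known*; 1–2 mismatches ⇒ *variant*; ≥ 3 mismatches or
no catalog ⇒ *novel*. Comparisons are ungapped; length-mismatched
pairs are compared at the best ungapped offset with overhanging bases
counting 1 each (whether the original variant class tolerated indels
is unstated; we count substitutions only). Novels whose predicted star
occurs **exactly** among the cleaned unique reads, at any count in any
library, are *true novel* (`tae_1…` in descending total count, ties
broken lexicographically); the rest are *candidate novel* (`tae_C1…`).
Families are derived from catalog ids by stripping the species prefix,
paralog letters and arm suffix (zma-miR156i-5p → MIR156).
Cross-species conservation is exact substring presence of the mature
(both strands) in each species' sequence set.

## Digital expression

TPM divides a miRNA's count by the **putative small RNA population
size of its library** (not the miRNA-only total) and multiplies by
10⁶, so TPM over the whole putative population sums to 10⁶ per library
— the conservation property the tests assert. Fold change is
log₂(treatment/control) on TPM; zeros are *flagged undefined rather
than imputed*, because a pseudo-count would silently move reads into
or out of the ≥ 2-fold selection (threshold 1.0 in log₂ units,
boundary inclusive). Venn membership uses detection = raw count > 0 by
default (configurable to a TPM threshold); each detected miRNA falls
in exactly one of the 2ᵏ − 1 regions. Clustering uses the uncentered
Pearson distance d(x,y) = 1 − Σxᵢyᵢ/√(Σxᵢ²·Σyᵢ²) with average linkage
(UPGMA, via `stats::hclust` on our distance); rows are ordered
lexicographically by label first so distance ties resolve
deterministically, and an all-zero profile is an error naming the
offending row. The linkage is cross-checked against a brute-force
UPGMA implementation.

## Target prediction

Scoring follows the Allen-style expectation penalty used by plant
target finders: per miRNA position (1 = 5′ end), mismatch +1, G:U
wobble +0.5, gap +2, everything doubled over positions 2–13; perfect
Watson–Crick pairs are free. We allow at most one gap per alignment
(plant sites rarely bulge more, and it keeps window enumeration
exact). The reporting cutoff is 3.0 — versions of the public tools
default to 3.0 or 5.0; we chose the stricter value and expose it
(`target_cutoff`). The scanner computes all window penalties
vectorised by prefix/suffix decomposition around the gap position and
is verified against exhaustive per-window scoring; overlapping
sub-cutoff windows collapse to the best one. Mode is cleavage ("C")
unless a mismatch or gap occupies miRNA positions 9–11 (an intact
centre is required for slicing), in which case translational
repression ("T"); for cleavage sites the expected cut falls between
the transcript bases facing miRNA positions 11 and 10, read off the
explicit alignment.

## The synthetic data generator

`make_genome()` plants hairpins — mature (20–22 nt, 21 most likely) +
terminal loop (8–60 nt) + reverse-complement arm with 0–2
substitutions — at non-overlapping positions in 45% GC background
(wheat-like; configurable). The planted star is the arm's 3′ portion
plus the two following bases, i.e. exactly what the 2-nt-overhang
register excises. `simulate_libraries()` draws, per library, a
multinomial mixture: planted miRNAs (50%; star reads at a 0.1
star:mature ratio, 0 for designed candidate-novels), contaminant
fragments (20%), degradation fragments of transcripts (20%),
junk-length reads (5%) and N-containing reads (5%), with read lengths
dominated by the 24-nt class as in real plant libraries.
`make_catalog()` gives designed hairpins exact copies (known) or
1–2-substitution homologs (variant) and pads with decoys kept ≥ 5
mismatches from every planted mature; `make_transcriptome()` plants
target sites of penalty classes 0, 1, ~2.5 and above-cutoff. Every
randomised operation takes an explicit seed and restores the caller's
RNG state.

Differential expression is modelled by per-library abundance
multipliers: exactly one hairpin per archetype (heat-induced ×4,
salinity-repressed ×0.25, water-deficit-induced ×4, leaf-enriched ×4,
root-specific with zero counts in the other tissues), the rest
constant. Keeping the differential mass small is deliberate: TPM is
compositional, so every induced miRNA deflates the apparent fold
change of the others by log₂(ΣW_treated/ΣW_control); with one ×4
hairpin among 20 the deflation is ≈ 0.2 in log₂ units, comfortably
inside the ±0.5 recovery tolerance, whereas several induced hairpins
would push the bias past it. This is a property of TPM itself, worth
remembering when interpreting real libraries.

**What the generator does not emulate** — sequencing errors and
quality profiles, hc-siRNA clusters and genomic repeats,
multi-isoform MIR families, partial-degradation ladders of the mature
itself, or a realistic genome size. Passing the end-to-end tests
therefore demonstrates the correctness of the pipeline's logic under
its stated assumptions, not its sensitivity on noisy real libraries.
One emergent realism is worth noting: degradation fragments sampled
from transcripts that carry perfect target sites are antisense to the
mature and map back into hairpin loci, producing extra candidate-novel
calls at true loci — real screens see the same phenomenon.

## Validation problem sizes

The end-to-end validation uses 20 planted hairpins across two 10-kb
contigs, eight libraries at 200,000 reads each and a 30-transcript
transcriptome; property suites use ≥ 200 random short sequences for
the folding oracle, ≤ 100-kb genomes for the mapping oracle, 100
random 8×8 matrices for the linkage oracle, and 100 random constructs
for the screening-monotonicity property. At these sizes the whole
suite runs in a few minutes on one CPU; the sizes are choices, and
every stage scales to larger inputs at the documented complexity
(mapping and cleaning linear in reads; folding quadratic in window
length per locus).

## Known limitations

* The elimination rules for low complexity and invalid reads are this
  package's declared operationalisations; published workbench tallies
  from real data are not expected to be reproducible under them.
* The pairing-score folds rank structures without thermodynamics; use
  the `folder` plug-in for free-energy structures when ViennaRNA-class
  tools are available.
* Hairpin screening ranks but does not threshold on folding score, and
  computes no shuffling-based significance.
* Target prediction has no accessibility/UPE term and caps gaps at
  one; degradome support is out of scope.
* Exact (mismatch-free) mapping means sequencing errors silently drop
  reads from discovery; that is the standard behaviour of this class
  of pipeline, not a bug, but it bounds sensitivity on real data.
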