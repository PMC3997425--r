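# hexamir

Small RNA discovery and digital expression profiling for plants without
a finished reference genome — built around the analysis design used for
hexaploid bread wheat (*Triticum aestivum*), where sequenced small RNA
libraries from multiple tissues and abiotic stresses are reduced to a
putative small RNA population, mapped onto an in-house contig
compilation, and screened for miRNA hairpins.

It is aimed at plant small RNA groups who want the whole desk-side
chain — read cleanup, hairpin calling, catalog classification,
expression profiling and target prediction — as composable, tested R
functions rather than a black-box workbench.

## What it computes

1. **Elimination pipeline.** Adapter trimming (exact 8-nt seed), then a
   fixed first-match cascade: length filter (16–30 nt), low-complexity
   filter (tandem k-mer coverage ≥ 80%, k ≤ 3), invalid-sequence filter
   (non-ACGU), t/rRNA removal (exact substring of a contaminant set,
   both strands). Survivors collapse to unique reads with per-library
   counts; accounting satisfies
   `putative = total − (length + low-complexity + invalid + t/rRNA)`
   for redundant and unique tallies independently.
2. **Exact mapping.** Every unique read is located on both strands of
   the reference contigs (hash-of-k-mers index with verification); all
   loci are retained.
3. **Hairpin screening.** Each locus is evaluated in a mature ± 100 nt
   search region under plant miRNA annotation (Meyers) criteria: mature
   and star on opposite arms of a stem-loop, 2-nt 3′ overhangs, at most
   4 duplex mismatches, mature unpaired over ≤ 4 bases. Structures come
   from two dynamic programs: a general maximum-pairing-score fold
   (pair scores GC/AU/GU = 3/2/1, terminal loop ≥ 3) and a stem-loop
   constrained fold used for screening (same scores, single terminal
   loop, bounded bulges, per-base skip penalty). The star register is
   the modal antidiagonal of the mature's pairs, shifted for the
   canonical Dicer 2-nt 3′ overhangs.
4. **Classification.** Against a miRBase-style mature catalog:
   identical ⇒ *known*, 1–2 mismatches ⇒ *variant*, ≥ 3 or absent ⇒
   *novel*; novels split into *true novel* (predicted star observed
   among the sequenced reads, named `tae_1…`) and *candidate novel*
   (star unseen, named `tae_C1…`). Cross-species conservation is exact
   presence of the mature in each species' sequence set.
5. **Digital expression.** TPM = count / putative-population size ×
   10⁶ (per library), log₂(treatment/control) fold changes with zeros
   flagged rather than imputed, ≥ 2-fold selection (boundary
   inclusive), tissue/stress Venn partitions, and unsupervised
   clustering with uncentered Pearson distance
   `d(x,y) = 1 − Σxᵢyᵢ/√(Σxᵢ²·Σyᵢ²)` under average linkage (UPGMA).
6. **Target prediction.** Antiparallel complementarity scanning of a
   transcriptome with the Allen-style expectation penalty (mismatch 1,
   G:U 0.5, gap 2; doubled over miRNA positions 2–13; ≤ 1 gap; cutoff
   3.0), silencing-mode call (cleavage unless positions 9–11 are
   disrupted) and the expected cleavage site between the transcript
   bases facing miRNA positions 10/11.

A seeded synthetic-data module generates the full study design —
contigs with planted hairpins, eight libraries (shoot, root, mature
leaf, spikelet, control, heat, salinity, water-deficit stress) with
24-nt-dominated length profiles, star:mature abundance ratios,
contaminants, a catalog with exact/homolog/absent entries, and
transcripts carrying target sites of designed penalty classes — so the
entire pipeline is exercised and validated without downloads.

## Worked example

```r
library(hexamir)

inp <- simulate_inputs(seed = 42, n_hairpins = 10, depth = 2e4,
                       n_transcripts = 12)
cfg <- inp$config
cfg$outdir <- "run_out"
rep <- run_pipeline(cfg)

rep$mirnas
#> $total           [1] 14
#> $known           [1] 3
#> $variant         [1] 2
#> $true_novel      [1] 3
#> $candidate_novel [1] 6
rep$elimination$putative_population
#> $redundant [1] 111976      $unique [1] 20473
rep$expression$de_count
#> [1] 3
rep$targets
#> $hits [1] 8                $mirnas_with_target [1] 8
```

The ten planted hairpins come back with their designed categories (3
known, 2 variants, 3 true novels with sequenced stars, 2 candidate
novels); the extra candidate-novel calls are antisense degradation
fragments of planted target sites that map back into hairpin loci — a
genuine property of this kind of screen, not an artifact of the
implementation. `run_out/` holds the elimination summary, collapsed
FASTA, hairpin GFF3, classification and TPM/fold-change tables, Venn
regions, the Newick dendrogram and a YAML run report.

A thin command-line front-end ships in `inst/exec/hexamir`
(`simulate`, `run-all`, `fixtures-check` subcommands).

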