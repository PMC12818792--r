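---
title: "Satellitome chromosomal mapping: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellitome chromosomal mapping: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

satchrom implements the computational core of a satellitome
chromosomal-mapping study: given a catalog of satellite-DNA (satDNA)
consensus monomers and a chromosome-level assembly, it locates every
family occurrence, merges overlapping hits into discrete loci, quantifies
copy number and genomic abundance per chromosome, classifies families by
chromosomal distribution, builds Kimura 2-parameter (K2P) divergence
landscapes, contrasts assembly-based with read-based abundance, and
detects terminal and interstitial telomeric `(TTAGGG)n` arrays. A
synthetic-satellitome generator with exact ground truth makes every one
of those steps testable end to end.

```{r, eval = FALSE}
library(satchrom)
res <- run_satellitome(out_dir = "satchrom_demo")
```

# The mapping model

Mapping follows the conventions of consensus-vs-assembly BLASTn
annotation. The internal matcher is a k-mer seed-and-extend aligner:

* exact seed k-mers (`seed_k = 13`) shared between the monomer (either
  orientation) and the assembly are extended ungapped in both directions
  under +1 match / −2 mismatch scoring with X-drop termination
  (`xdrop = 20`);
* hits are filtered at **identity ≥ 0.80** and **query coverage ≥ 0.80**
  of the monomer length, the standard stringent thresholds for this kind
  of annotation; e-values (ceiling `1e-5`) apply only to imported BLAST
  tabular hits, where the producer computed them — the internal matcher
  does not re-derive Karlin–Altschul statistics, because the identity and
  coverage filters dominate at these thresholds;
* per (family, chromosome), surviving hits from both strands are pooled
  and unioned whenever the inter-hit gap is at most `max_gap_merge`
  (default 0 bp: overlapping or exactly adjacent hits merge). A merged
  locus is strandless.

Two deliberate consequences are worth stating prominently. First,
head-to-tail tandem copies merge into **one locus**, so "copy number"
derived from merged loci counts discrete arrays, not monomer units; the
per-locus `monomer_units` column (locus length ÷ monomer length) carries
the complementary estimate. Second, the reported hit span runs to the
X-drop termination point rather than back to the best-scoring column.
With max-score trimming, a substitution on the boundary between two
tandem copies leaves a 1–5 bp gap between their hits and an array
fragments into several loci; with termination-point spans the hits abut
and the merge rule sees gap 0. At zero divergence the two conventions
coincide, so exact planted copies are still recovered with base-exact
intervals.

The matcher is ungapped by design: desk-scale speed, exact coordinate
arithmetic, and the fact that externally produced gapped hits can be
imported through `parse_blast_tab()` (12-column tabular format, 1-based
inclusive subject coordinates converted to 0-based half-open on entry).
Indel-rich divergent copies are expected to arrive via that path.
All internal coordinates are 0-based half-open; BED output is therefore
direct.

# Divergence model

Divergence of a mapped copy from its consensus is the standard Kimura
2-parameter distance

$$K = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big],$$

with transition fraction $P$ and transversion fraction $Q$ computed over
comparable columns only (gap and N columns are excluded pairwise, with no
gamma correction — the convention used by repeat-landscape tools).
Saturated pairs ($1-2P-Q \le 0$ or $1-2Q \le 0$) are flagged infinite,
never clamped. Because array copies start at an arbitrary monomer phase,
each locus is re-aligned against a head-to-tail **consensus dimer** (both
strands, best-scoring offset) before $P$ and $Q$ are counted; a locus
whose best alignment covers less than half of
`min(locus length, monomer length)` gets no divergence call rather than a
poor one.

Landscapes accumulate abundance (% of assembly bp, or % of read bases)
into 1%-wide K2P bins, 0–30% by default; bins extend automatically past
30% when saturating copies occur, so the bin sum always equals the total
abundance. The landscape mean is the abundance-weighted mean of bin
midpoints.

# Read-based abundance surrogate

Graph-clustering estimators of satDNA genome proportion see every
repetitive read, including copies too divergent to map against an
assembly under stringent thresholds. satchrom models that pathway
transparently rather than re-implementing community detection: each
simulated read is matched against every consensus dimer with the same
seed-and-extend matcher and assigned to its best-scoring family when
identity reaches a deliberately permissive floor (0.60 versus 0.80 for
mapping). Family abundance is assigned aligned bases over total read
bases, and per-read K2P feeds a read-based landscape.

One guard is needed that a threshold alone does not provide: under +1/−2
scoring any maximal ungapped segment has identity above 2/3, so a chance
13-mer seed in background sequence would always pass a 0.60 identity
floor. Assignment therefore also requires the aligned span to reach
`min_span_frac` (default 0.30) of the read length; with 100 bp reads this
keeps background false assignment below 0.1% while reads from genuinely
divergent copies (25% substitution) still align end-to-end, because the
expected score drift is positive even at that divergence. Aligned spans
of boundary-crossing reads may overshoot an array edge by roughly
`xdrop`/1.25 bases, a small (~5%) upward bias shared by alignment-based
estimators generally.

Comparing the two pathways (`compare_methods()`) reports the read-based
and mapped totals, their ratio, both mean divergences and per-bin
differences. Two mechanisms drive the mapped estimate below the
read-based one, and both are reproduced by the simulator: assembly
collapse of tandem arrays (`collapse_arrays()`) removes copies from the
reference, and the mapping identity threshold truncates the divergent
tail of each family, so the mapped landscape is younger on average — the
mapping-bias effect.

# The synthetic-satellitome generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests and the acceptance script:

* **15 chromosomes** of 200 kb each (a desk-scale stand-in for a
  ~0.7 Gb mussel-like assembly with n = 15), centromere at 0.45 of the
  length, `(TTAGGG)` × 50 telomeric caps at both termini (reverse
  complement at the 5' end);
* **~100 families** with log-uniform monomer lengths over 22–2,891 bp
  (the span observed in real satellitomes) and log-uniform per-family
  abundance summing to ~9% of the genome — a few dominant families and a
  long tail. Chromosome breadth follows abundance rank: the dominant
  ~15% of families are pan-chromosomal, the rarest 25% are restricted to
  a single chromosome, matching the observation that exclusive families
  are individually rare;
* **per-copy divergence** concentrated at 0–5% (|N(0.02, 0.015)|
  truncated) for 90% of families, with 10% "old" families at 0.12–0.25 —
  beyond the 0.80 mapping threshold, so a read-vs-mapped gap exists even
  without collapse;
* **placement**: 60% of families disperse individual copies uniformly,
  20% concentrate copies in a pericentromeric band (halfwidth 8% of the
  chromosome; restricted to 150–1,500 bp monomers so copies fit the
  band), 20% form one head-to-tail tandem array per chromosome.
  Individually placed copies keep ≥ 50 bp spacing so merged loci
  correspond 1:1 to planted copies. Pericentromeric families are placed
  first and large monomers before small ones, so rejection sampling does
  not strand a large copy in fragmented free space.

Mutation is substitution-only: exactly `round(d·L)` positions are
substituted per copy, transitions with probability κ/(κ+2) (κ = 2 by
default, the canonical transition bias). Keeping indels out preserves
exact truth coordinates and matches the K2P model assumptions; an indel
process would decouple planted coordinates from realized alignments
without changing what the pipeline is being tested for. A consequence
worth noting: planting substitutions at proportion *d* makes the
re-estimated K2P exceed *d* by the Jensen correction, which stays below
0.01 only up to roughly d ≈ 0.11 — recovery tests therefore target
d ≤ 0.10.

Reads are simulated single-end (abundance estimation does not use
pairing): Poisson read count at the requested coverage, uniform starts on
both strands, i.i.d. substitution errors (default 0.1%). Assembly
collapse truncates each contiguous planted array to
`ceiling(keep_fraction · copies)` copies and splices the sequence,
remapping truth coordinates exactly; single planted copies are arrays of
one and are never removed.

What the generator does **not** emulate — and what passing tests
therefore cannot show: higher-order repeat structure, unequal
crossing-over dynamics, indel-driven length variation, library/GC biases
in read sampling, and real assembler behaviour (collapse here is an
idealized truncation). Conclusions about real assemblies should lean on
the imported-BLAST path and treat the synthetic results as validation of
the arithmetic, not of assembler artefact models.

# Quantification and classification choices

* **Copy number** per (family, chromosome) is the merged-locus count, the
  discrete-hit metric; `monomer_units` is reported alongside.
* **Genome-wide totals** count cross-family overlapping base pairs once
  (interval union), extending the no-double-counting rule to the total.
* **Classification** is driven solely by presence: `chromosome_specific`
  = loci on exactly one chromosome, `pan_chromosomal` = on all, the rest
  `multi_chromosomal`, `unmapped` = no surviving loci. The conservative
  10-copies-per-chromosome noise threshold is carried as a separate
  `low_copy_flag` rather than suppressing families, because exclusive
  families are reported without that cut and low-copy occurrences may be
  biologically real.
* **Local enrichment** has no standard definition in density-shaded
  ideogram figures, so it is operationalized as the Gini index of
  per-window locus counts (`Σᵢ Σⱼ |xᵢ − xⱼ| / (2n² mean)`), flagged at
  ≥ 0.8; window (1 Mb at real scale, 20 kb in the desk-scale config) and
  threshold are configurable. Uniform counts give 0, a single occupied
  window out of four gives 0.75.
* **Pericentromeric fraction** is the fraction of locus midpoints within
  centromere ± band halfwidth; it requires an external centromere table
  (the simulator emits one).
* The per-family percentage denominators are genome length (with the
  per-chromosome percentage also reported), since published per-family
  percentages do not always state the denominator.

# Telomere detection

`scan_telomeric()` finds maximal runs of exact, phase-aligned motif
hexamers on the forward strand, scanning the motif and its reverse
complement separately; up to one interrupted unit between exact units is
bridged by default. Runs with ≥ 5 exact units are reported with span,
unit count and purity, then classified terminal when either endpoint lies
within 10 kb of a chromosome end, else interstitial (ITS). Both
`min_units` and the terminal window are configurable because "significant
ITS" has no standard definition — reported ITS counts are
threshold-dependent and should be read as such. Degenerate telomeric
variants are out of scope for the exact scan; the seed-and-extend matcher
pointed at a hexamer multimer covers fuzzy searches.

# Numerical and degenerate-input conventions

* Coordinates 0-based half-open everywhere; BLAST tabular converted at
  parse time; BED written directly.
* N bases are legal, never indexed, never counted as matches, and
  excluded from K2P denominators.
* Ties in the top-copy ranking break lexicographically by family id;
  interval merging treats gap = 0 as mergeable.
* Saturated K2P is `Inf` + flag; loci without a divergence call are
  dropped from landscapes with a warning; an all-unassigned read set
  yields a zero landscape, not an error.
* Every stochastic step takes an explicit seed (`withr::with_seed`, so
  the global RNG is untouched); identical seeds give byte-identical
  tables.
* `run_satellitome()` writes the fully resolved config (unknown keys are
  rejected) and a run log next to its outputs; every figure has a TSV
  twin — plots are decoration, numbers are the interface.

# Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data
built at run time: exact-recovery runs use a 5 Mb, 15-chromosome genome
with 30 families; landscape-recovery runs use 500 kb with five families
at d ∈ {0.01, 0.03, 0.05, 0.08, 0.10}; the method-discrepancy scenario
uses 600 kb genomes over five seeds with keep_fraction 0.5 and one
family at d = 0.25; the acceptance script's headline run uses the 3 Mb
default conditions above with 2× read coverage and keep_fraction 0.55.
These sizes were chosen as the smallest at which the estimators' sampling
error is comfortably inside the assertion tolerances.

# Known limitations

* Ungapped internal matcher: families whose copies carry many indels will
  be under-recovered unless hits are imported from a gapped aligner.
* The read-based pathway shares the catalog with mapping; it is a
  surrogate for clustering-based estimators, not a re-implementation, so
  it cannot discover families absent from the catalog.
* Copy number from merged loci undercounts monomer units in tandem
  arrays by design; use `monomer_units` for the complementary view.
* E-values are not computed for internal hits.
* Merging is per-family; cross-family overlaps are resolved only in the
  genome-total union, not merged into joint loci.
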