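---
title: "Replicate-aware stringency filtering: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-aware stringency filtering: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclean)
```

## The model

Amplicon surveys run in PCR triplicate give three noisy draws from the same
community. `ampliclean`'s central object is the OTU count table: one row per
OTU, one integer column per replicate, one semicolon-joined lineage per row.
OTUs collapse into *phylotypes* at the lowest assigned rank of their lineage
(`aggregate_phylotypes()`), and the filtering model is a two-parameter family
over phylotype counts `c_pr`:

> keep phylotype *p* iff `#{ r : c_pr >= m } >= k`,

optionally preceded by per-replicate singleton zeroing at OTU level. The five
named levels are `T0 = (1,1)`, `T1 = (1,1)` with zeroing, `T10 = (10,1)`,
`T10-R1 = (10,2)`, `T10-R2 = (10,R)`. The underlying assumption is a simple
error model: a PCR or sequencing artefact arises independently in one
replicate and is overwhelmingly likely to be seen exactly once there, while a
real community member at detectable abundance leaves a count of at least 2
somewhere. Under that model T1 is a consistency filter, and the T10 family
trades rare-but-real diversity for confidence.

Two structural facts the implementation relies on, and the test suite
re-proves on random tables:

* **Nesting.** `T10-R2 ⊆ T10-R1 ⊆ T10 ⊆ T1 ⊆ T0` on every input (any count
  ≥ 10 survives singleton zeroing). Consequently the core set across all
  levels equals the strictest level's set, and no phylotype is ever unique to
  a stricter level.
* **Sub-phylotype action of T1.** Singleton removal acts on OTU cells and
  only then re-aggregates: OTU tallies fall under T1 even where their
  phylotype survives, which is why the cascade must keep the source OTU table
  alongside the phylotype table.

## Tunable parameters

| parameter | default | unit | why |
| --------- | ------- | ---- | --- |
| `min_count` (`m`) | 10 for the T10 family | copies per replicate | the conventional "confidently present" threshold in replicated amplicon work |
| `min_replicates` (`k`) | 1 / 2 / R | replicates | concordance requirement; `T10-R2` resolves to the table's replicate count |
| `trim_head`, `trim_tail` | 10, 10 | bases | fixed-length removal of low-quality read ends on 100 bp HiSeq-type reads |
| `min_fraction` | 0.95 | proportion | retention rule "more than 95% of positions at Q ≥ 20", implemented as a **strict** inequality — exactly 95% fails, and a boundary test documents it |
| `q_threshold` | 20 | Phred | `Q >= 20` counts as a good call (standard threshold semantics) |
| `max_evalue` | 1e-5 | — | hits kept iff `evalue < 1e-5`, the usual gate for taxonomy-grade alignments |
| clustering `threshold` | 0.97 | identity | the canonical OTU radius; the greedy module is a stand-in for synthetic data only |

Quality is evaluated *after* trimming, since trimming exists to remove the
low-quality ends that would otherwise dominate the fraction.

## Conventions that had to be fixed

Several quantities have more than one defensible definition; the package
fixes each one explicitly rather than leaving it implementation-defined.

* **Phylotype identity.** A phylotype is keyed by its full lineage path, not
  its bare label: the same genus name under two conflicting parent paths
  stays two phylotypes and is reported, because merging would silently hide a
  reference-database disagreement. Unknown (empty) lineages form the
  single `"unknown"` phylotype.
* **Rank projection.** "At genus level, or the lowest available" is
  implemented as: the label at the requested rank when assigned, otherwise
  the *most specific* assigned label, flagged as a fallback. The alternative
  reading (most general available) would collapse everything to domain and
  defeat genus-level comparison.
* **Overlap denominator.** Shared percentages between two label sets use
  `100·|A∩B|/|A∪B|`: the union is the only denominator that makes "common
  across the two methods" symmetric. `method_overlap()` exposes `"a"`/`"b"`
  denominators for sensitivity checks, since published overlap figures do not
  always state theirs.
* **Rounding.** Level retention is rounded to two decimals and per-replicate
  mean retention to a whole percent, both half-away-from-zero (base `round()`
  is banker's and would turn e.g. a `.5` mean the wrong way).
* **Raw vs cumulative T10 baselines.** Whether the ≥10 thresholds are
  evaluated on raw counts or after singleton zeroing changes nothing about
  the surviving sets (any qualifying count is ≥ 10 > 1) but does change OTU
  tallies; `filter_cascade()` therefore reports both (`report` and
  `report_post_t1`).
* **Combined OTU tallies.** Across replicates, OTU counts use union
  semantics (distinct member OTUs of surviving phylotypes), with read mass
  reported separately.
* **Alignment identity.** The clustering stand-in defines identity as
  identical columns over alignment length *including gap columns*, from a
  Needleman–Wunsch alignment with match +1, mismatch −1, gap −1 and a
  deterministic traceback (diagonal, then gap-in-second, then gap-in-first).
  Aligners differ on all three choices; fixing them makes the module exactly
  reproducible by a brute-force oracle, which is the point of a stand-in.
* **Top-hit ties.** Per query: maximal bit-score, then minimal e-value, then
  input order. The tie-break is a package convention; ambiguity across
  equally-top subjects with different lineages is resolvable from the
  returned table.
* **FASTQ encoding.** Phred+33 only; anything decoding outside `[0, 60]` is
  rejected rather than re-guessed as a different encoding.

## What the generator emulates — and what it does not

`sample_community()` + `simulate_otu_tables()` produce: a lognormal
relative-abundance community (the standard species-abundance assumption)
over an internally consistent synthetic taxonomy with configurable lineage
truncation; multinomial per-replicate counts at a fixed depth; artefact OTUs
appended with count exactly 1 in exactly one replicate under perturbed,
unique lineages; and contaminant spikes (by default three terrestrial plants
at count 1). Ground truth is recorded per OTU, and every generator is
bit-reproducible under its seed.

Two deliberate idealisations matter for interpreting green tests:

* **Artefacts are exactly singletons.** Real chimeras and index hopping can
  exceed count 1 or recur across replicates; `messy = TRUE` draws geometric
  artefact counts for stress testing, under which recovery is only
  statistical. A green exact-recovery test establishes that T1 implements
  its contract, not that T1 removes all real-world artefacts.
* **The community sits above the detection floor.** Relative abundances are
  truncated below at `min_abundance` (default 1e-3, ≈10 expected copies per
  1e4-read replicate). Without the floor, an unbounded lognormal tail
  occasionally yields a true taxon whose *expected* count is ~1 per
  replicate; such a taxon is statistically indistinguishable from a
  singleton artefact, and the exact-recovery contract cannot hold for any
  filter. The floor is the generator's statement that a mock community built
  for exactness contracts must be observable; set `min_abundance = 0` to
  study the boundary regime, where recovery degrades gracefully rather than
  exactly.

The metagenome simulator draws query categories from an explicit
superkingdom mixture (default heavily bacterial with ~11% unknown), shares a
configurable fraction of cellular genera with the amplicon community, and
emits 1–5 gated hits per query whose top hit maps to the intended lineage
through the emitted taxonomy map. It does not model alignment biology:
bit-scores and e-values are draws, not alignment statistics, so it validates
the *selection and mapping* logic, not BLAST behaviour.

The FASTQ simulator draws per-base qualities i.i.d. (good with probability
`p_good_base`), so the kept fraction has a closed-form binomial-tail
expectation — the oracle the QC suite checks against. Real quality profiles
decay along the read; the trimming defaults, not the simulator, are what
address that.

## Numerical and degenerate-input choices

* Reads shorter than `trim_head + trim_tail` become empty reads and are
  tallied as length-dropped; `passes_quality()` on an empty read is an error
  by contract, forcing callers to route such reads to the length tally.
* An empty baseline in `retention_report()` is an error (retention against
  nothing is undefined); empty filtered tables are fine and report 0%.
* `venn_partition()` lists only non-empty regions; region sizes always sum
  to the union cardinality, which is the invariant tests rely on.
* Krona export renders the unknown lineage as the single label `"unknown"`
  and conserves count mass exactly.
* Percentages are computed on unrounded ratios and rounded only at the
  reporting edge.

## Limitations

* The greedy clustering stand-in is quadratic and intended for synthetic
  data at the scale of thousands of sequences; real OTU picking should be
  imported via `read_otu_table()` from dedicated tools.
* Phylotype comparison across databases with different rank vocabularies is
  out of scope: lineages are compared within one configured rank order
  (cellular and viral presets provided).
* The cascade filters on presence thresholds only; no rarefaction,
  compositional normalisation, or differential-abundance modelling is
  attempted, and read-depth differences between replicates are reported, not
  corrected.
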