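---
title: "Methods: from taxonomic classifications to community chemical metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from taxonomic classifications to community chemical metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commchem)
```

## The model

A 16S rRNA survey yields, per sample, read or ASV counts attached to
taxonomic names. Each taxon with reference genomes has a *reference
proteome*: the mean amino acid composition of its proteins. The package's
central object is the **community reference proteome** of a sample,

$$\bar{a} = \frac{\sum_t w_t\, a_t}{\sum_t w_t},$$

where $a_t$ is the per-protein mean amino acid composition of taxon $t$
and $w_t$ its read count in the sample. This is an *intensive* weighted
mean rather than a raw sum: carbon oxidation state and elemental ratios
are unchanged by that choice, but protein length and residue molecular
weight stay interpretable as per-protein expectations. The community
proteome is an inference from taxonomy, not a measurement; its metrics
quantify genomic adaptation of the detected community, not protein
expression.

### Chemical metrics

From atom counts $C,H,N,O,S$ and formal charge $Z$ (zero for the neutral
compositions used here):

* **Carbon oxidation state** $Z_\mathrm{C} = (Z - H + 3N + 2O + 2S)/C$.
  It is invariant under adding or removing whole H$_2$O units, which is
  why the terminal-water convention (below) cannot affect it; the test
  suite asserts this identity exactly.
* **Basis-species projection.** Any CHNOS composition is a unique linear
  combination of five basis species — glutamine, glutamic acid,
  cysteine, H$_2$O, O$_2$ (the QEC basis) — found by solving the 5×5
  element-balance system with a dense LU solve. The per-residue H$_2$O
  and O$_2$ coefficients are the stoichiometric hydration state
  $n\mathrm{H_2O}$ and oxidation state $n\mathrm{O_2}$. The basis matrix
  is checked for nonsingularity (|det| > 1e-12) and the coefficients
  reconstruct the input elements to better than 1e-9 on random
  compositions. Within a genome's proteins the element-based
  $Z_\mathrm{C}$ and reaction-based $n\mathrm{O_2}$ covary strongly
  (Pearson r ≥ 0.8 across Dirichlet-random compositions in the tests),
  while $n\mathrm{H_2O}$ is largely decoupled.
* **Elemental ratios** H/C, N/C, O/C, S/C; **length** (residues per
  chain) and **residue molecular weight** (standard average atomic
  masses: C 12.011, H 1.008, N 14.007, O 15.999, S 32.06 g/mol).
* **GRAVY**: count-weighted mean of the published 20-value
  Kyte–Doolittle hydropathy scale.
* **pI**: root of the net-charge model
  $Q(\mathrm{pH}) = \sum_\mathrm{basic} n_i/(1+10^{\mathrm{pH}-pK_i})
  - \sum_\mathrm{acidic} n_i/(1+10^{pK_i-\mathrm{pH}})$
  over the ionizable side chains (Asp, Glu, Cys, Tyr, His, Lys, Arg)
  plus `chains` amino and `chains` carboxyl termini.

All constants live in one plain TSV (`inst/extdata/`) exposed by
`aa_constants()`, so they are auditable and swappable.

## Numerical and design choices

**Terminal-water convention.** Metrics are per-residue quantities, so by
default elemental sums use residue (in-chain) formulas — terminal H$_2$O
excluded — and `terminal_water = TRUE` restores free-protein formulas.
$Z_\mathrm{C}$ and $n\mathrm{O_2}$ are provably identical either way;
$n\mathrm{H_2O}$ shifts by exactly `chains`/residues.

**pK set.** The pI model uses a Bjellqvist-style table (C-term 3.55,
Asp 4.05, Glu 4.45, His 5.98, N-term 7.5, Cys 9.0, Tyr 10.0, Lys 10.0,
Arg 12.0). The N-terminal pK is generic rather than residue-specific: a
community composition has no defined first residue, so residue-specific
refinement is not meaningful here. Termini are included for fractional
(community) compositions too — `chains` of each — because the reference
compositions are stored per protein (`chains = 1`); the table is a
replaceable argument for users who prefer another set.

**Bisection.** pI is found on [0, 14] to |Q| < 1e-4 or 100 iterations.
Q is strictly decreasing in pH, so the root is unique when both charge
signs are present. Because the stopping rule is on charge, the reached
pH is homogeneous in the composition only to ≈1e-5; the homogeneity
test uses that tolerance, all other metrics are scale-invariant to 1e-9.

**Strict alphabets.** Ambiguity codes (B, Z, X, U) are rejected, never
silently dropped: reference compositions are curated, and silent drops
would bias every downstream metric.

## Ingestion

The RDP Classifier's hierarchical output lists *cumulative* counts per
taxonomy node. `read_rdp_hierarchy()` decomposes them so each read is
counted once, at its deepest retained rank: a node's lowest-level count
is its cumulative count minus the cumulative counts of its decomposed
direct children. One fixed dialect is supported — tab-separated, header
row, columns `taxid`, `lineage`, `name`, `rank`, then one count column
per sample, with `lineage` an alternating name/rank path ending at the
row's node — validated strictly (a child sum exceeding its parent is an
error naming the node). Root- and domain-level residuals are dropped;
lineages containing a filter term (default Chloroplast, Mitochondria,
Eukaryota — the enumerable nonprokaryotic contaminants of 16S surveys;
extensible at call time) are removed and tallied. Retention spans phylum
down to `lowest_rank` (default genus); species counts collapse upward
into genus unless `lowest_rank = "species"`, which suits GTDB-style
references that include species. Counts may be fractional, since some
pipelines rarefy or normalize. The per-sample identity
`retained + dropped-above-phylum + filtered = classified total` is
asserted on every generated fixture.

`taxa_counts_from_tables()` is the pipeline-agnostic path: each OTU/ASV
is classified at its deepest non-empty rank between phylum and
`lowest_rank`, identical (rank, name) classifications are pooled, and
fully unassigned OTUs are dropped into a visible tally.

## Mapping

`map_taxa()` matches (rank, name) pairs exactly and case-sensitively
after whitespace trimming; fuzzy matching is deliberately absent because
a silent near-miss corrupts compositions invisibly. The sanctioned
escape hatch is the **mapping ledger**: ordered, annotated rules
`(source rank, name) → (target rank, name)` that may change rank (an
unplaced genus can map to a family-level reference). The automatic match
is tried first and a ledger rule only fires when it fails, so a rule can
never shadow an exact hit; rules are validated against the reference
database at the moment they fire, which lets the packaged starter ledger
coexist with small synthetic databases. Unmapped taxa are excluded, not
redistributed — the simplest defensible contract — and the
count-weighted unmapped percentage plus the most abundant unmapped taxa
are reported so the loss is visible. When classifier and reference
taxonomies come from the same source, mapping is complete by
construction; the fixture tests reproduce that 100% mapping rate.

## Reference database construction

`build_reference_proteomes()` consumes local protein FASTA files plus
GTDB-style taxonomy strings (`d__...;p__...;...;s__...`; empty fields
skipped). Per genome it stores the mean per-protein composition; per
taxon, at every rank in the lineage, the **unweighted** mean across
member genomes — the default, so heavily sequenced species do not
dominate a genus — with `weight = "protein"` available since the
alternative is equally defensible. Downloading GTDB/RefSeq is out of
scope; the builder is the local end of that pipeline.

## What the synthetic fixtures emulate — and what they do not

`make_refdb()` draws Dirichlet(1) amino acid frequencies scaled to a
fixed length of 300 residues per protein (a typical prokaryotic mean);
`make_rdp_fixture()` draws log-normal genus abundances (meanlog
log(100), sdlog 1 — a realistic skewed rank-abundance curve), assigns
chosen fractions of counts to a novel genus (unmappable) and a
chloroplast lineage (filterable), and writes the cumulative hierarchy
plus matching OTU/ASV tables. Ground truth — expected lowest-level
counts, unmapped percentage, and per-sample metrics via an independent
weighted-mean computation — is recorded at construction, never by
running the pipeline under test.

Dirichlet-random compositions span a realistic $Z_\mathrm{C}$ range
(≈ −0.3 to 0) but carry none of the covariance structure of real
proteomes (codon bias, GC content, thermal or halophilic signatures),
and the generated taxonomies are flat (domain–phylum–genus). Passing
tests therefore demonstrate the *arithmetic* of the pipeline — count
decomposition, mapping bookkeeping, weighted-mean aggregation and the
chemistry — not that any ecological signal will be recovered from real
data. Real analyses also hinge on classifier quality and reference
coverage, which are upstream of this package.

## Problem sizes

The property suites use 1000 Dirichlet-random compositions for the
$Z_\mathrm{C}$–$n\mathrm{O_2}$ covariation, 1000 random five-taxon
mixtures for the weighted-mediant bounds, and 20–25 random compositions
for the exact identities (element-balance reconstruction to 1e-9,
terminal-water invariance, homogeneity); fixtures run 2–4 samples over
6–12 genera. These sizes make the whole suite run in well under a
minute while leaving each property statistically meaningful.

## Known limitations

* Exact name matching means classifier/reference naming drift must be
  handled through the ledger; there is no fuzzy fallback by design.
* pI for community compositions inherits the generic-termini
  assumption; compositions dominated by non-ionizable residues still
  have termini and hence a defined pI.
* The mapping report weights unmapped percentages by counts summed over
  all samples; per-sample percentages are also provided but the headline
  number is the pooled one.
* No interoperability with in-memory phyloseq objects; plain tables are
  the exchange format, and exporting those from any pipeline is
  straightforward.
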