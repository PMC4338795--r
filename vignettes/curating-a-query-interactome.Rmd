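---
title: "Curating and analysing a single-protein interactome"
author: "ppicurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and analysing a single-protein interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(ppicurate)
```

# The problem

Curated protein–protein interaction (PPI) databases accumulate, for a
heavily studied protein, hundreds of experimental annotations of very
unequal quality: algorithmically expanded co-complex rows, cross-species
and chemical partners, and the same experiment entered several times under
bait/prey swaps or tag variants. Two major repositories annotating the same
literature typically overlap only partially, so a credible interactome for
one query protein requires filtering each export, merging them publication
by publication, and weighting each partner by the breadth of its evidence.
`ppicurate` implements that workflow end to end for a single query protein,
together with the three downstream analyses that usually follow: Gene
Ontology over-representation of the replicated partners, residue-level
profiling of self-interaction (dimerization) evidence, and overlap of the
interactome with GWAS risk loci.

# Curation model

Records are read from a PSI-MI TAB 2.7 style export (`readMitab()`) and a
BioGRID TAB 2.0 style export (`readBiogridTab2()`). Both readers apply
identifier canonicalization at parse time: isoform suffixes (`-2`) and
fragment chain identifiers (`-PRO_...`) are stripped so every form of a
protein shares one accession, while the raw identifier is retained. The
column layouts are configurable maps; the defaults expect 36 and 24
tab-separated columns respectively, and a 42-column PSI-MI dialect can be
accommodated by passing a modified `mitabColumnMap()`.

Three filters run in a fixed order (`curateDataset()`), chosen so the
provenance counts have a single well-defined meaning:

1. **Spoke-expansion removal.** Binary rows derived from n-member
   co-complexes by the spoke model may not reflect direct contact with the
   query and are dropped.
2. **Taxon filter.** Both interactors must carry the allowed taxon
   (default 9606). Chemical partners are detected by identifier namespace
   (ChEBI) rather than by a missing taxon, because exports are inconsistent
   about taxon fields for small molecules, and receive a `"chemical"`
   sentinel that this filter removes.
3. **Within-publication deduplication.** Two records are duplicates
   exactly when they share the publication, the unordered canonical pair
   (collapsing bait/prey swaps and tag variants), the detection method and
   the host organism. The first record in file order represents each
   duplicate class — the rule only requires keeping one, and file order
   makes the choice deterministic.

The TAB 2.0 layout has no host-organism column, so every BioGRID record
carries an `"unspecified"` host sentinel and its deduplication key
degenerates to (publication, pair, method).

## Cross-database merge

`mergeDatasets()` merges two curated datasets publication by publication:
a publication present in only one source is copied verbatim; when both
sources annotate it, the source with more annotations is taken wholesale;
on a tie the union of both record sets is re-deduplicated with the
duplicate rule keyed on *harmonized* method categories. The harmonization
map (`defaultHarmonizationMap()`) collapses vocabulary differences between
the sources — e.g. a protein kinase assay and "Biochemical Activity" are
the same experiment category, and the co-immunoprecipitation, pull-down
and affinity-capture variants all become Affinity Capture. During the tie
union the `"unspecified"` host sentinel matches any host: one source
records no host at all, so host equality would otherwise keep every
cross-database copy and the tie merge would never collapse anything. The
merge log records the per-publication source choice.

The merged records are split into heterologous (query–partner) and
homologous (query–query, i.e. self-interaction) sets, which are analysed
separately.

# Evidence tiers

`summarizeInteractors()` counts, per partner: supporting annotations (A),
distinct publications (P) and distinct harmonized methods (M). Methods are
counted after harmonization because the tiering question is "how many
*kinds* of experiment support this partner", not how many vocabulary
entries. The four occurrence tiers are:

| tier | rule |
|---|---|
| low | A = 1 |
| medium_low | P = 1, A ≥ 2 |
| medium_high | P ≥ 2, M = 1 |
| high | P ≥ 2, M ≥ 2 |

The corner case P = 1, M = 1, A ≥ 2 (possible when only the host system
differs) is not covered by the four published definitions; it has
within-publication replication, so it is assigned medium_low and flagged
in the summary table. The *filtered interactome* is the complement of the
low tier (partners with at least two annotations) and is the study set for
enrichment; the *complete interactome* (all partners) is used for the GWAS
overlap, since locus membership does not require replicated evidence.

`groupFamilies()` groups filtered interactors by a user-supplied
protein-to-family map and calls a family independently described when the
research groups behind its members' publications number at least two.
"Research group" has no operational definition in annotation data, so the
publication-to-group map is also supplied by the user (keying on last
author is typical).

# Over-representation analysis

`enrichGO()` is a standard hypergeometric over-representation test. With a
reference universe of N genes, K of them annotated to a term, and a study
set of n genes of which k are annotated, the reported p-value is the upper
tail P(X ≥ k) (computed with `stats::phyper`, which is numerically stable;
the test suite checks it against exact big-integer combinatorics to 1e-12
relative error for N ≤ 60). Annotations are propagated along `is_a` and
`part_of` edges before testing (the true-path rule), so a parent term
always holds at least its children's study counts; propagation is on by
default and switchable, since it is unknowable whether a given historical
web tool propagated or used a slim.

Multiple testing uses a Bonferroni factor m equal to the number of terms
actually tested, i.e. terms with at least `minGenes` (default 2) study
genes — the common ORA convention. Two reporting modes mirror the two
styles of public enrichment portals: `top10` returns the N smallest
adjusted p-values (ties broken deterministically by adjusted p, raw p,
term id), and `threshold` returns every term with adjusted p below a
cut-off (default 1e-7). The reference universe defaults to all genes in
the annotation table, the usual stand-in for a genome-wide reference.

Two summaries operate on grouped results (term groups are a user-supplied
mapping, since grouping enriched terms into themes is a judgement call):

* `intersectionMatrix()` — entry (i, j) is the percentage of group i's
  contributor genes that also contribute to group j; row-normalized, hence
  asymmetric; a final row gives each group's share of the whole study set.
  Empty groups yield undefined (NA) rows rather than zeros.
* `significanceComposition()` — each term is binned into significance
  level N = ⌈−log10(p_adj)⌉, clamped into a configured range (default 7 to
  16); the ceiling convention is a documented choice, as the exact binning
  of borderline p-values admits several readings. Within a level, a
  group's contribution is 100·g/n over non-"general" terms, where g counts
  the group's terms at that level and n all terms there; "general terms"
  are excluded as uninformative.

# Self-interaction profile

`buildResidueProfile()` turns region-annotated homologous records into a
per-residue support curve: coverage at residue i is the number of distinct
publications with at least one annotated fragment covering i. Fragments
from one publication are unioned first (via `IRanges::reduce`), so
overlapping constructs in a single paper count once. Single-residue
annotations contribute to coverage like any interval and are additionally
tallied in a separate point channel — they are the "dots" of a profile
figure, and their per-residue publication count is reported alongside the
curve. Only one of the two source layouts carries region features, so
records without regions simply do not contribute. A
`countBy = "annotations"` switch disables the per-publication union for
comparison.

# GWAS locus overlap

A risk SNP tags a locus, not a gene, so `matchInteractome()` intersects
the complete interactome with closed windows of ±`windowBp` (default
200 kb) around each SNP, using base-pair distances on the supplied
intervals. The SNP–gene distance is zero when the SNP lies inside the
interval and otherwise the distance to the nearer interval boundary, in
kbp. The operation is agnostic about interval semantics: supply CDS
intervals to measure distances to coding regions, or full gene spans
otherwise. Multiple SNPs near one gene produce multiple hits (reports are
per SNP), and hits inherit the partner's annotation counts and
high-throughput flag from the evidence summaries.

# Synthetic study conditions

`generateFixture()` writes every input the pipeline reads — the two
interaction exports, OBO ontology, GAF annotations, BED gene intervals,
SNP table, the four lookup maps, and a YAML run configuration — plus a
`truth.json` sidecar holding the expected value of every pipeline stage.
The default `fixtureSpec()` emulates a LRRK2-scale curation snapshot:

* 269 partners in tiers 207 low / 24 medium-low / 13 medium-high /
  25 high, over 63 heterologous publications (21 IntAct-only, 22 shared,
  20 BioGRID-only), with 6 shared publications planted as equal-count
  vocabulary conflicts that exercise the harmonized tie merge;
* junk rows per source (150 spoke, 40 non-human, 10 chemical, 35
  duplicates for the PSI-MI file; 20 non-human and 10 duplicates for the
  TAB 2.0 file, which structurally cannot contain spoke rows) so the raw
  totals land near the few-hundred-row scale of real exports, while the
  post-stage counts are known exactly by construction;
* 31 self-interaction publications (7 shared) with fragment regions in a
  catalytic-core segment of a 2527-residue protein and a handful of
  single-residue annotations;
* a 1000-gene reference universe, 40 background terms annotated at rate
  0.10 and 3 planted terms annotating 95% of the study set against a 2%
  background — effect sizes at which the planted adjusted p-values clear
  1e-7 by many orders of magnitude, which the generator verifies before
  writing (an unachievable specification errors out instead of silently
  producing a misleading truth);
* 187 risk SNPs (24 PD-like, 163 IBD-like) with 21 planted interactome
  hits at distances between 0 and 189 kb, each on its own chromosome, and
  decoy genes inside other SNP windows.

Identical seeds yield byte-identical bundles; the configuration stores
relative paths for that reason. The generator emulates the *structure* of
real curation data (overlap, duplication, vocabulary conflicts, planted
effects), not its content: identifiers are synthetic, annotation depth per
publication is uniform-ish rather than long-tailed, and ontology terms sit
flat under a single root, so passing the planted-truth tests demonstrates
the pipeline's bookkeeping and statistics, not robustness to every
idiosyncrasy of live database exports.

The test suite runs the full pipeline over a battery of twenty smaller
randomized specifications (roughly 30 partners, 16 publications, 300
reference genes, 500-residue protein) and requires every planted truth
field to be reproduced exactly; the sizes keep the whole battery within a
few minutes while still exercising every merge and filter path.

# Numerical and degenerate-input choices

* Zero-count evidence summaries are an error, not a tier.
* An empty filtered interactome skips the enrichment stage with a message
  (there is no study set to test); the profile and GWAS stages still run.
* An adjusted p of exactly 0 (numerically underflowed) is binned into the
  top significance level with a message.
* Study genes absent from the reference universe are dropped with a
  warning and counted, matching how public portals silently restrict to
  mappable identifiers — but here the count is reported.
* All analysis stages are deterministic; randomness lives only in the
  fixture generator, seeded through `fixtureSpec(seed = )`.

# Limitations

* No live database or UniProt/Entrez retrieval: identifier-to-symbol,
  family and research-group maps are user inputs.
* No MI-score or confidence filtering, and Bonferroni is the only
  correction offered — the workflow deliberately mirrors a conservative
  hand-curation protocol rather than a general enrichment toolbox.
* The merge rule assumes the source with more annotations for a
  publication subsumes the other; pathological cases where both sources
  hold disjoint halves of equal size are handled by the harmonized union,
  but disjoint halves of *unequal* size keep only the larger half.
* Figure reproduction is out of scope; the package exports plain TSV/SIF
  tables from which graphs can be drawn.
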