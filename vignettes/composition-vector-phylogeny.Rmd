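---
title: "Composition-vector phylogeny and taxonomy congruence with cvphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-vector phylogeny and taxonomy congruence with cvphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvphylo)
```

## The method

cvphylo infers prokaryotic phylogenies from whole proteomes without
alignments. Alignment-free comparison is the natural choice at genome scale:
genomes differ enormously in size and gene content, orthologue selection is
ambiguous, and lateral transfer undermines single-gene trees. The unit of
comparison is the K-peptide — a window of K consecutive amino acids inside
one protein — counted over all annotated protein products of a genome.

Raw K-peptide frequencies are dominated by neutral compositional drift. To
expose the selective signal, each observed frequency is compared with the
prediction of a (K−2)-th order Markov model fitted to the same proteome:

$$q(a_1 \dots a_K) \;=\; \frac{f(a_1 \dots a_{K-1})\; f(a_2 \dots a_K)}
                              {f(a_2 \dots a_{K-1})},$$

where each $f$ is a window count divided by its own total window count. The
composition-vector component for an observed peptide $w$ is the relative
deviation

$$a(w) \;=\; \frac{f(w) - q(w)}{q(w)} \quad (q(w) > 0), \qquad
  a(w) = 0 \;\; (q(w) = 0).$$

Two genomes are compared by the cosine correlation $C$ of their sparse
vectors, converted to the dissimilarity $D = (1 - C)/2 \in [0, 1]$. The
matrix of pairwise $D$ feeds Saitou–Nei neighbor joining; the *branching
order* of the resulting tree is the product. Branch lengths are retained
internally for diagnostics but suppressed in default output, because
length calibration assumes rate constancy that cannot hold across many
phyla; trees are therefore written topology-only unless lengths are
explicitly requested.

Validation is taxonomic rather than statistical: instead of bootstrap
resampling (which measures stability, not correctness), the tree's branching
order is confronted with a nine-rank reference classification, rank by rank.

## Parameters that matter

* **K (peptide length), default 3–8 in one run.** K is deliberately not
  tuned per dataset: the same K set is applied to all genomes, and watching
  how the branching order moves with K is part of quality control
  ([compare_k_topologies()]). For prokaryotic proteomes K = 5–6 is the
  established sweet spot; shorter peptides wash out signal, longer ones make
  vectors too sparse to intersect.
* **Canonical alphabet.** The 20 standard residues; windows containing
  `X B Z J U O *` or gaps are skipped entirely (only those windows — a draft
  annotation with scattered ambiguity codes still contributes almost all of
  its windows). Windows never cross protein boundaries.
* **`q = 0` components.** A peptide whose background prediction is zero
  scores 0 rather than infinity, and peptides never observed at length K are
  absent from the sparse vector even when `q > 0`. The alternative (explicit
  −1 scores for predicted-but-unobserved peptides) would densify the vectors
  massively for large K with no evidence it changes topologies; absence is
  this package's documented choice.
* **Frequencies, not raw counts, in the Markov ratio.** The two conventions
  differ by a near-unity factor for large proteomes; the frequency form is
  self-normalizing and is fixed here as the package's definition.

## The lineage dialect

Reference taxonomy arrives as one line per genome: an identifier followed by
tagged ranks, e.g.

```
GCF_000005845 <D>Bacteria<P>Proteobacteria<C>Gammaproteobacteria<O>Enterobacterales<F>Enterobacteriaceae<G>Escherichia<S>Escherichia coli<T>K-12
```

The nine tags `<D> <K> <P> <C> <O> <F> <G> <S> <T>` stand for Domain,
Kingdom, Phylum, Class, Order, Family, Genus, Species and sTrain. Both the
ASCII `<D>` and typographic `〈D〉` delimiters are accepted; ASCII is emitted.
The tag delimiter, not whitespace, separates fields, so taxon names may
contain spaces. Absent ranks are filled with the sentinel `Unclassified`; a
lineage containing any `Unclassified` is *incomplete*, which drives the
`{n + m}` accounting below. Since no single canonical sample of this format
is fixed elsewhere, the form above is this package's canonical dialect;
[read_lineage()]/[write_lineage()] round-trip it.

Genomes present as FASTA but missing from the lineage file get an
all-`Unclassified` lineage rather than an error — unannotated user genomes
are a normal situation, and placing them on the tree is precisely the use
case.

## Monophyly, convergence, and `{n + m}`

A taxon is **monophyletic** (operationally) when all its genomes are
represented exclusively by the leaves of a single clade of the rooted tree.
Otherwise its genomes fall into several maximal pure clades and the taxon is
**convergent**, rendered `Name{k/n}` per cluster of k among its n members.
One-genome taxa are flagged **singleton** so summaries are not inflated by
trivial monophyly. Collapsed-branch labels carry `{n + m}`: n members with
complete nine-rank lineage plus m incomplete ones, printed `{n}` when
m = 0 and `{0 + m}` when n = 0. Collapsing and lineage modification both
conserve the total genome count — an invariant asserted on every collapse
and report.

Two semantic choices were genuinely open:

* **Taxon identity.** Keying taxa by name alone would merge homonyms under
  different parents; keying by the strict full lineage prefix would split a
  named taxon whenever one member has `Unclassified` at a *shallower* rank
  (an unclassified kingdom would split every phylum, and the incomplete
  member could never be counted in its taxon's m). cvphylo groups genomes
  that share the name at the rank and have *compatible* shallower ranks —
  equal, or `Unclassified` on either side — via a deterministic union-find.
  Homonyms under different named parents stay apart; incomplete genomes stay
  in their named taxon.
* **`Unclassified` never licenses a collapse.** A clade of genomes sharing
  only `Unclassified` at a rank stays expanded; but incomplete genomes
  inside a named taxon's clade still count in its m.

Monophyly is evaluated on the rooted tree: "leaves in a single branch" is a
clade notion and requires a root. With an outgroup configured, rooting is on
the edge separating outgroup from ingroup (the package roots directly on the
adjacency structure, so a multi-genome outgroup always ends up as one child
of the root). Without an outgroup the pipeline midpoint-roots before
reporting — a reasonable default when rates are roughly clock-like, and the
only rank whose status can be affected is the one whose taxa straddle the
midpoint edge.

## Neighbor joining, determinism, tie-breaks

The pipeline's contract is *deterministic output for a fixed
configuration*. Three numerical choices serve it:

* Q-criterion ties in NJ are broken by the lexicographically smallest pair
  of cluster representatives (each cluster represented by its smallest leaf
  label, compared byte-wise, locale-independent).
* Pair iteration for the distance matrix is the upper triangle in input id
  order, each value mirrored; dot products accumulate through R's long-double
  `sum()` over a deterministic component order.
* All numbers are written with fixed `%g` formats, so reruns are
  byte-identical (asserted by a dedicated test and the acceptance script).

Negative NJ branch lengths are retained internally, never clamped: topology
is the product and lengths are diagnostic.

## The synthetic-data generator

[simulate_proteomes()] provides ground truth without downloads. A root
proteome (default 200 proteins × 300 residues, i.i.d. from a uniform
amino-acid profile) evolves along a guide tree whose edge lengths are
per-site substitution probabilities (default: balanced 8-leaf tree, 0.05
per edge); substitutions replace a residue uniformly among the other 19. The
defaults are large enough that K = 5–6 vectors are informative and small
enough for seconds-scale simulation. A lineage table is synthesized by
assigning each rank to a fixed tree depth (domain = root, strain = leaf), so
every taxon at every rank is exactly a clade of the true tree and the
expected report on the true tree is 100% monophyletic — the end-to-end
oracle for the taxonomy machinery. [perturb_lineage()] then reassigns chosen
genomes to wrong taxa to exercise convergence detection and the
modification/re-report workflow.

What the generator deliberately does **not** emulate: gene gain/loss,
lateral transfer, indels (the CV representation is window-based; indels only
shift windows), rate heterogeneity across sites, and realistic amino-acid
composition. Passing tests on this generator therefore demonstrate the
correctness of the counting, background subtraction, distance, tree and
reporting machinery under the point-substitution model — not that the method
resolves any particular real taxonomy.

## Problem sizes used in validation

The test-suite and acceptance-script study conditions are: 100 random
proteomes for the counting oracle; 200 random additive matrices (n ≤ 16)
for NJ recovery; 500 random tree/taxon assignments (n ≤ 12) for the
monophyly oracle; and 20 seeded replicates of the default 8-genome
simulation for end-to-end recovery at K = 5 and 6, where both K values
recover the true topology in every replicate and every named taxon is
reported monophyletic. These sizes keep a full validation run in minutes on
one core while leaving each property overdetermined.

## Known limitations

* Counting is pure R (vectorized `substring` + `table`); a genome of
  3–4 Mb annotated proteome takes a few seconds per K. For thousand-genome
  projects the per-genome CV cache ([build_cvs()]) amortizes the cost, but a
  compiled counting kernel would be the next step.
* Midpoint rooting without an outgroup can misplace the root under strong
  rate asymmetry; supply an outgroup for serious use.
* The union-find taxon grouping is transitive: a chain of pairwise
  compatible genomes merges even if its endpoints conflict at a shallower
  rank. With real reference taxonomies this requires a taxon that is itself
  inconsistently annotated.
* `Lineage.txt` parsing rejects duplicated genome ids and duplicated rank
  tags outright rather than guessing an intent.
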