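---
title: "Reference-anchored analysis of GH99 glycoside hydrolases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-anchored analysis of GH99 glycoside hydrolases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

Family GH99 of the CAZy classification contains two endo-acting
activities: the Golgi endo-α-1,2-mannosidase of animals (gene *MANEA*),
which trims glucosylated N-glycans, and the endo-α-1,2-mannanase of
bacteria and many protists, which degrades α-mannan. Which activity a
GH99 protein is predicted to carry is largely written in a handful of
sequence motifs, read in the residue numbering of the human MANEA
protein:

* **Position 189** — Tyr predicts a preference for glucose in the −2
  subsite (endomannosidase; minimal substrate GlcMan3), Trp predicts
  mannose (endomannanase; minimal substrate the Man4 tetrasaccharide).
  Other residues (e.g. the Leu seen in *Shewanella*) are reported as
  such without a substrate call.
* **The −2 loop, 195–199** (consensus D[E/D]NGE) — contacts the −2
  sugar; its N197H variant is the hallmark of the fish-specific CMANEAL
  ohnolog.
* **H[I/L]EPY, 222–226** and **position 323** — conserved landmarks of
  the catalytic domain, extracted and reported but not used in the
  activity rules.
* **The active-site motif, 404–407** (consensus EW[H/G]E) — carries the
  two catalytic glutamates E404 and E407. E404Q and EWHE→KWHE are
  treated as predicted-inactivating; both glutamates present predicts an
  active enzyme.

Everything in the package is anchored to these coordinates: queries are
never multiply aligned. Each query is globally aligned to the packaged
reference, the match/mismatch columns define a bidirectional position
map, and motifs, profile columns, logos and consensus sequences are all
read through such maps ("reference-anchored stacking"). Catalytic-domain
numbering used in consensus displays is shifted by −97 relative to
full-length numbering; `shift_numbering()` converts in both directions,
and the catalytic-domain span is taken as full-length position 98
onward.

## The packaged reference

The reference shipped in `inst/extdata/synthetic_manea_reference.fasta`
is a synthetic 462-residue sequence with the five canonical motifs
planted at their human-MANEA positions (Y189, DENGE at 195–199, HIEPY at
222–226, Y323, EWHE at 404–407) and background-frequency residues
elsewhere. It is a stand-in that preserves the coordinate semantics of
the real protein: every statement the package makes is relative to this
numbering, so any user can substitute the genuine human MANEA sequence
(UniProt-style FASTA) via the `reference` argument of the mapping,
annotation and profile functions without touching anything else.

## Pairwise alignment and the coordinate map

`global_align()` is a Needleman–Wunsch/Gotoh implementation (C++ core)
with subtractive affine gaps: a gap of length $k$ costs
$d_\text{open} + k\,d_\text{extend}$, defaults 11 and 1 with
BLOSUM62 — the conventional protein setting. Traceback ties are broken
deterministically (diagonal over vertical over horizontal), so every
result is reproducible. Two identity definitions are reported because
two different consumers need them: identity over aligned columns feeds
the distance matrix ($d = 1 - \text{identity}$), while identity over the
shorter sequence matches the cd-hit denominator used for clustering and
for the mapping floor.

`build_reference_map()` declares a query *unmappable* (rather than
failing) when identity over the shorter sequence falls below a floor,
default 0.15. Unmappable and partially mapped queries degrade to
`"?"`/undetermined downstream — partial transcript-derived proteins are
a fact of life in clade surveys and must not crash a cohort run. The
floor is deliberately permissive; raise it when the input is known to
be clean.

## Annotation rules

`annotate()` composes mapping, motif extraction and a small rule table.
Two rules deserve comment:

* **DYGE at 404–407** is classified as its own active-site class but its
  catalytic status is left *undetermined*, not *predicted_inactive*,
  although position 404 is a mapped non-glutamate. The DYGE motif is the
  consensus active site of the related GH71 family and occurs in some
  bona fide GH99 proteins; there is no direct activity evidence either
  way, so the package does not over-claim.
* **Position 189 alone decides the substrate call.** Loop variants are
  reported alongside but never override it; sequences with an exotic
  loop and a normal 189/404–407 are annotated from 189 and 404–407
  alone.

## Profiles and ohnolog classification

For MANEA / MANEAL / CMANEAL discrimination, one position-specific
scoring model per ohnolog is built from reference-anchored seed columns
over the catalytic domain. The log-odds score of residue $a$ at column
$j$ is

$$ s_{aj} = \log_2 \frac{(c_{aj} + \alpha q_a)/(n_j + \alpha)}{q_a} $$

with flat-Dirichlet pseudocount mass $\alpha$ (default 0.5) and
background $q$ (Robinson–Robinson frequencies). Queries are scored by
optimal global profile-to-sequence alignment under the model's affine
gap penalties; `X` scores 0 everywhere (background-neutral). A record is
labelled with the best model when its bit-score margin over the
runner-up reaches $\delta$ (default 2 bits), else `unclassified`.

Bit-score differences are used where a database search would compare
e-values: e-value calibration needs a database-size model that a
self-contained package cannot supply, and any monotone transform leaves
the cluster structure of the pairwise delta table unchanged. Ancestral
single-copy (non-gnathostome) sequences are expected to fall in the
MANEA cluster; there is deliberately no fourth class.

## Clustering

`greedy_cluster()` reproduces the semantics of
`cd-hit -c 0.95 -s 0.5 -g 1`: records sorted by length (ties by id),
each joining the best eligible existing representative (highest identity
≥ `c` among representatives passing the length cutoff) or founding a new
cluster. Identity is matches over the shorter sequence, computed by full
dynamic programming — cd-hit's short-word filter is an accelerator, not
part of the definition, and is not reproduced; at the scale this package
targets, correctness wins. cd-hit's identity denominator varies subtly
across its modes; the shorter-sequence denominator is fixed here and
used consistently.

Downstream prevalence counts species among *cluster representatives*
only. That matches how identity-clustered surveys behave — clustering
can eliminate hits from highly similar species and thereby lower
apparent prevalence, never raise it.

## Trees and decontamination

Distances are $1 -$ column identity on untrimmed pairwise alignments
(alignment trimming, common before maximum-likelihood phylogenetics, is
deliberately not reproduced: the decontamination rule below needs only
coarse topology). `neighbor_joining()` is canonical Saitou–Nei NJ, exact
on additive matrices, with Q-criterion ties broken by the smallest pair
of leaf labels and negative branch lengths clamped to zero (counted in
an attribute). NJ is used instead of maximum likelihood because the
procedure only consumes topology at desk scale; `ape::nj` serves as an
independent cross-check in the test suite, never as the implementation.

"Phylogeny-based decontamination" is rarely given an explicit criterion
in survey work, so this package defines one and labels it as its own in
the report metadata: per round, the NJ tree is midpoint-rooted and a
leaf is flagged when the smallest clade on its ancestor chain with at
least `k` leaves (default 3) has a majority taxogroup different from the
leaf's own, with the leaf's group a strict minority. Midpoint rooting is
what makes "enclosing clade" well defined on an unrooted tree; the naive
alternative (any edge-cut component) wrongly implicates the innocent
leaf next to which a long-branch foreign clade happens to attach. Two
safeguards apply: a round never removes every member of a taxogroup with
≥ `k` leaves, and rounds stop when nothing is flagged (which makes the
procedure idempotent on survivors) or after `max_rounds` (default 5).

## Logos and consensus

Position frequency matrices exclude gaps and undetermined positions from
counts; the information content of a column is
$\log_2 20 - H$ bits with $H$ the Shannon entropy of the column
frequencies. No small-sample correction is applied, and the gap fraction
is reported beside, not inside, the IC. A column with zero observations
has *missing* IC, not zero — an unobserved column is not a maximally
variable one. Consensus sequences report the modal residue when its
frequency among non-gap observations reaches the threshold $t$
(reporting thresholds 0.90 and 0.95), else `X`; majority-gap columns are
dropped from the consensus string and listed separately, so a consensus
never contains gap symbols.

## The synthetic cohort generator

`simulate_family()` exists so that every stage can be validated against
planted truth. Its defaults are the package's study conditions:

* the root is the packaged reference; each subfamily ancestor diverges
  from it at 0.25 substitutions per site (a realism choice on the order
  of the divergence between long-separated paralogs);
* within a subfamily, leaves diverge independently from the ancestor at
  the subfamily's `divergence` (default 0.15) on a depth-1 star, so the
  per-leaf divergence is exactly the stated rate; deeper balanced trees
  are available via `depth`;
* substitutions are uniform over the 19 alternative residues — the
  simplest defensible choice absent any generative model to emulate;
* planted motif states are written onto their positions *after*
  evolution, so ground truth is guaranteed; contaminants are generated
  inside their true subfamily and mislabelled with a foreign taxogroup;
* indels are off by default so reference mapping is exact; an optional
  single-deletion mode exists for stress testing only.

What the generator does *not* emulate: site-rate heterogeneity,
realistic phylogenetic structure, compositional bias, alignment-breaking
indel patterns, or fragmentary transcripts. Passing the recovery
experiments therefore demonstrates the correctness of the machinery on
data satisfying the generator's assumptions, not survey-grade accuracy
on real databases.

## Validation problem sizes

The packaged experiments use: complete alignment-oracle enumeration for
all word pairs up to length 2 over a four-letter alphabet plus 120–150
seeded random pairs up to length 6 (brute-force enumeration grows
exponentially; these sizes keep the oracle exact); all 15 labelled
five-taxon topologies plus 100 seeded additive matrices on 6–8 taxa for
NJ; a 600-record six-state cohort for annotation recovery; 3 × 100
held-out records (8 seeds per subfamily) at divergence 0.15 and
$\delta = 2$ bits for ohnolog classification, with ≥ 95% required
accuracy; 11 + 1 records for decontamination; four 5-record families at
1.5% divergence for clustering. `scripts/acceptance.R` re-runs all of
them from scratch for any seed.

## Known limitations

* The decontamination criterion is this package's operationalization;
  other groups' "multiple rounds of decontamination" may differ.
* Species joins between records and the taxonomy are exact-match only —
  no fuzzy name normalization is attempted.
* E-values are not computed anywhere; all profile comparisons are in
  bits.
* The NJ stand-in trades the statistical efficiency of
  maximum-likelihood trees for exactness and zero external dependencies;
  fine for incongruence screening, not for publishable phylogenies.
* Pure-R greedy clustering with full DP identities is quadratic; it is
  meant for cohorts of hundreds, not databases of millions.
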