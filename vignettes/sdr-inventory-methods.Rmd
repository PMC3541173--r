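---
title: "Methods: profile-HMM inventories of plant SDRs and their diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM inventories of plant SDRs and their diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sdrinventory)
```

## The problem

Short-chain dehydrogenases/reductases (SDRs) are an ancient superfamily of
NAD(P)(H)-dependent oxidoreductases. All members share a Rossmann-fold core,
an N-terminal dinucleotide-binding motif (a GxxxGxG glycine pattern) and a
YxxxK catalytic motif, but pairwise sequence identities between families are
low — often below 25% — which makes simple similarity search unreliable for
a genome-wide census. Profile hidden Markov models solve this: a
position-specific model trained on a curated alignment detects family
membership far below the twilight zone of pairwise alignment.

This package implements a complete inventory pipeline for predicted plant
proteomes: three tiers of profile HMMs combined through a decision tree with
explicit bit-score cutoffs, gene-model selection at multi-model loci,
homology-based rescue of truncated predictions, single-linkage construction
of orphan families, and the downstream diversification analyses
(occurrence classes over the plant taxon hierarchy, heat-map export, PCA,
neighbor-joining trees with bootstrap supports).

## The scoring model

A profile is built from a seed alignment with `build_profile()`. Columns
whose gap fraction is strictly below `gap_threshold` (default 0.5; a column
at exactly the threshold is excluded) become match states. Match emissions
are relative frequencies regularised by a BLOSUM62-mixture pseudocount: the
pseudocount density for a column is the BLOSUM62 conditional distribution
averaged over the observed residues, with total weight `pseudocount_weight`
(default 5). The heavy default is deliberate: seed alignments in this
workflow typically hold 3–10 sequences, and with a light pseudocount a
residue that is a plausible substitution of the column consensus but happens
to be unobserved would be penalised almost as hard as a random residue,
which collapses the score separation between true members and background at
the 45–50% identity level the pipeline must handle. Transitions are
estimated from the observed state paths with Laplace pseudocounts.

Scoring is local Viterbi in bits: uniform entry over match states, a fixed
exit probability of 0.05 at every match state (probability 1 at the last),
insert emissions equal to the background (Robinson–Robinson frequencies),
flanking residues free, ambiguity codes emitting at background (0-bit
contribution). Viterbi (best path) rather than forward defines the score:
the decisions downstream are thresholds on scores, which are insensitive to
this choice at the margins involved, and the best-path score admits a
direct path-enumeration oracle, which the test suite exploits (every score
on small random models is checked against explicit enumeration of all legal
state paths).

The published type cutoffs (classical 138, extended 108, intermediate 162,
divergent 160, complex 140 bits) and unknown floors (29 / 75 / 100 bits)
are the defaults of `type_cutoffs()` and apply to the real nomenclature
models they were defined for. For synthetic models the cutoffs are
calibrated: `calibrate_cutoff()` returns `min(positives) − margin`, floored
just above the strongest decoy, and errors on overlap rather than silently
emitting a useless threshold. Type-tier and broad-tier cutoffs are
calibrated on the curated seed representatives (not on every member): a
cross-family type alignment at 20–30% identity yields a deliberately broad
model, and demanding that *every* member beat every decoy at that tier
would be unachievable and is not what the tier is for — the unknown floor,
set just above the decoy ceiling, is the tier's wide net, exactly the role
floors play in the published workflow. Family-tier cutoffs are calibrated
the strict way: every full-length member passes, every member of every
other family and every decoy fails, with a 5-bit margin.

## The decision tree

`decide_sdr()` applies, in order: (1) family-tier pass ⇒ positive, with the
type read from the family suffix letter (…C classical, …E extended, …D
divergent, …U unknown, …A atypical — the convention used throughout the SDR
nomenclature); (2) broad-tier pass and type-tier pass ⇒ positive with the
best passing type (ties break classical > extended > divergent); (3)
broad-tier pass and a type score at or above its unknown floor ⇒ positive,
type *unknown* — a lone above-floor type hit without corroboration is not
enough; (4) recognition by a single tier defers the sequence: a rescue
assignment upgrades it, a whitelist entry (the hook for structure-based
literature inclusion, e.g. the atypical pinoresinol/isoflavone-reductase
family) makes it positive, an exclusion entry (e.g. medium-chain
dehydrogenases sharing only the cofactor motif) makes it negative, anything
else lands on the ambiguous list; (5) no recognition ⇒ negative. All
tie-breaks are deterministic (score, then fixed type order, then
lexicographic id), so permuting hit-table rows never changes a verdict.

Rescue (`rescue_truncated()`) aligns each non-positive sequence against all
positives and inherits type and family from the best-scoring homolog whose
alignment contains a 60-column window with strictly more than 50% identity.
Two readings of the published rule were possible — identity over the whole
alignment or over a 60-residue segment; the segment reading is implemented,
with the boundary pinned by tests (31/60 passes, 30/60 and 59/59 fail).
Rescue is attempted for every non-positive sequence, not only single-tier
ones, since truncated proteins may be missed by all HMMs. One further
reading choice: the rule is evaluated per candidate homolog and the best
*qualifying* homolog wins, so a spurious top-scoring alignment that lacks
the segment cannot veto a qualifying one.

Orphans (positives with no family) are single-linkage clustered with
`cluster_orphans()`: edges where the Karlin–Altschul E-value
(`E = K·m·n·exp(−λS)`, defaults K = 0.041, λ = 0.267, the conventional
gapped-BLOSUM62 constants) is at most 1e-40. Only the thresholding
behaviour is claimed: the absolute E-values of any particular search tool
are not reproduced, and clusters get synthetic ids (`NF01`, ...), not
nomenclature names. Each cluster reports its mean pairwise identity from a
progressive alignment and a representative (lowest mean p-distance,
lexicographic ties).

## Alignment and distances

`local_align()` is Smith–Waterman with affine gaps (BLOSUM62, gap open 11,
extend 1 — conventional protein defaults; the source methodology names no
parameters). A gap of length *k* costs `open + k·extend`. Tie-breaks are
deterministic: the reported alignment ends at the first best cell in
row-major order and the traceback prefers substitutions over gaps, which
minimises gap count among equal-scoring paths. The test suite checks scores
against exhaustive enumeration of all monotone matchings on short pairs.

`progressive_msa()` is a deliberately simple progressive scheme (not a
ClustalW clone): average-linkage guide tree on 1 − identity from pairwise
local alignments, then leaf-to-root profile–profile merges under the same
affine gap model, rows returned in input order. Pair orientation and merge
orientation are canonicalised by sequence content so the column content is
invariant under input permutation. Downstream consumers depend only on the
multiple-alignment contract (equal row lengths, degap recovers inputs).

`p_distance()` compares, for each pair, only columns where both rows carry
a residue (pairwise deletion); pairs with no comparable column become `NA`
and tree construction refuses them with the pair named — silent imputation
or capping would distort topologies. `poisson_correct()` is −ln(1−p),
in substitutions per site; p = 1 is an explicit saturation error and the
caller decides what to do.

## Trees and bootstrap

`neighbor_joining()` wraps the standard NJ agglomeration (via ape) and adds
the two behaviours the pipeline needs: undefined entries abort with the
offending pair, and negative branch estimates are clamped to zero with the
deficit moved to a sister branch so path lengths through the join are
preserved. For additive matrices the output path-length matrix reproduces
the input to 1e-9 (verified over 1000 random 5–8-leaf trees).
`bootstrap_support()` resamples alignment columns (not distance entries),
rebuilds distances and the NJ tree per replicate, and reports integer
percentage supports per internal bipartition of the original tree;
replicates with undefined or saturated distances are skipped and tallied,
and supports are percentages of the successful replicates. Fixed seeds give
byte-identical output. `write_newick()` writes branch lengths to six
decimals and quotes labels containing Newick metacharacters.

## The synthetic genome set

`make_genome_set()` emulates the statistical structure the inventory
assumes, at desk scale. Families descend from one random superfamily root
(250-residue classical core with the GxxxGxG cofactor motif at position 8
and YxxxK at position 150; extended ancestors append a 100-residue
C-terminal tail) through per-type intermediate ancestors (60% identity to
the root) and per-family ancestors (50% identity to the type ancestor —
families within a type are deeply diverged, as in the real superfamily).
Members mutate a fixed count of positions, drawn from the BLOSUM62
conditional excluding the original residue, so realized identity tracks the
target tightly; motif positions mutate at a tenth of the background rate;
sparse 1–3-residue indels occur at a rate proportional to the substitution
rate (and vanish at identity 1, so the identity-1 case is exact). Default
member-to-ancestor identities span 0.45–0.70, matching the within-family
conservation range reported for real plant SDR families (37–82%, most
48–62%).

Truncations replace a member by a contiguous window of 40–150 residues —
the lower bound sits below the 60-residue rescue window so both rescue-pass
and rescue-fail fragments occur. Multi-model loci gain a second, truncated
gene model. Decoys are half composition-matched shuffles of real members
(catalytic motif destroyed) and half medium-chain-dehydrogenase-like
background sequences carrying only the cofactor motif, which exercises the
exclusion path. Identical seeds give bit-identical FASTA and truth tables.

What the generator does *not* emulate: real secondary-structure
conservation (the fold-level signal that lets real type HMMs recognise
members at 15% identity), chromosomal clustering of paralogs, gene
structure, or nucleotide sequence. Passing the synthetic recovery tests
therefore demonstrates that the machinery is correct and well-calibrated on
data with planted truth, not that any particular cutoff transfers to a real
proteome.

`make_expansion_matrix()` emulates the family-by-genome distribution behind
the published heat map: background families draw Poisson counts around a
small mean (2), diversified families draw negative-binomial counts whose
mean rises across tiers (alga 2, bryophyte 6, lycophyte 12, angiosperm 25,
dispersion 4) — the pattern of secondary-metabolism families expanding with
vascular plants. Defaults are 49 families over 10 genomes with 10
diversified, mirroring the published matrix's shape.

## PCA of the distribution matrix

`pca_distribution()` is centered, unscaled PCA with families as individuals
and genomes as variables — the orientation in which family scores separate
expanded families and genome loadings show each genome's pull. Whether the
published analysis scaled variables is not stated; centered-unscaled is the
default here and the choice is recorded in the result's `centering` field.
Axes are ordered by decreasing variance and each loading vector's
largest-magnitude entry is made positive, a sign convention that makes
results reproducible across LAPACK builds. `pca_robustness()` repeats the
analysis after removing the family with the largest centered row norm and
reports the Spearman concordance of first-axis rankings — the published
analysis performed the same check after removing its most extreme family.
On the synthetic expansion matrix the first axis typically carries ~70–80%
of the variance; the published figure (79% on the real inventory) can only
be reproduced from the real supplementary data, which is out of desk-scale
scope, so the acceptance script reports the synthetic value under its own
name.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline on 10 families
across 4 genomes (one per taxon tier, three members per family and genome,
10% truncations, 5% multi-model loci, 20 decoys — about 145 proteins),
train 15 models, and verify ≥95% family recovery, zero decoys in the main
list, and rescue of every qualifying truncation. Oracle checks use ≥100
random instances per engine (models of ≤4 match states against sequences of
≤6 residues; pairs of ≤8 residues), NJ consistency uses 1000 random
additive matrices, and bootstrap determinism uses 500 replicates on an
8-taxon alignment. These sizes make every stage's correctness observable
while a full run stays in the minutes range on one core.

Other numerical choices: probabilities are validated to sum to 1 within
1e-9; profile serialization prints doubles at 17 significant digits so the
text round-trip is bit-exact; all randomness flows through explicit integer
seeds; undefined distances propagate as `NA` and fail loudly.

## Known limitations

- Synthetic type-tier models are broad by construction; their inclusion
  cutoffs guarantee only the curated representatives, so type assignment for
  weak members relies on the family tier and floors (mirrored after the real
  workflow's reliance on the family HMMs for most assignments).
- The whitelist/exclusion configuration replaces the human
  literature-and-structure review; the actual published whitelist content is
  not recoverable.
- No maximum-likelihood robustness trees, no E-value calibration for HMM
  bit scores, no DNA-level models, and no attempt to reproduce the real
  ten-genome inventory or its published trees.
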