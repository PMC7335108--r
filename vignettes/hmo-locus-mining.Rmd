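---
title: "Mining and comparing HMO-utilization gene loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and comparing HMO-utilization gene loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmoloci)
```

## The biological question

Butyrate-producing Clostridiales of the *Roseburia*–*Eubacterium* group
carry gene clusters that let them grow on human milk oligosaccharides
(HMOs) and on related host glycans such as mucin *O*-glycan fragments.
The canonical locus couples an ABC transporter (a solute binding
protein, SBP, that sets uptake specificity, plus permease subunits) with
two glycoside hydrolase activities: the two-subunit GH136
lacto-*N*-biosidase, which cuts lacto-*N*-tetraose into
lacto-*N*-biose (LNB) and lactose, and the GH112 LNB/GNB phosphorylase,
which phosphorolyzes the resulting disaccharides; a transcriptional
regulator and a sensor histidine kinase complete the cluster. Across a
pangenome this architecture yields a clean functional dichotomy:

* a genome with **both** a GH112 gene and at least one GH136 subunit can
  attack complex HMO/host glycans — a *primary degrader*;
* a genome with **only** GH112 can merely consume LNB/GNB released by
  others — a *secondary degrader*.

`hmoloci` operationalizes this analysis end to end: family assignment by
percent identity, locus calling by the co-occurrence rule, extraction and
comparison of the gene neighborhoods ("landscapes") around each GH112
anchor, per-SGB representative landscapes, and prevalence/degrader
reporting. A synthetic pangenome generator with full ground truth makes
every stage testable by exact recovery.

## Family assignment

Each annotated gene with a protein sequence is aligned against reference
sequences of the family vocabulary (`family_tokens()`). We use a global
(Needleman–Wunsch) alignment with match +1, mismatch 0 and linear gap
−1, and define

\[
\mathrm{PID}(a,b) = 100\cdot\frac{\text{identical columns}}
{\text{alignment columns (end gaps included)}} .
\]

Among co-optimal alignments the one with most matches is scored. Because
score \(S\) and matches \(M\) determine the number of aligned pairs
(\(S = M - \text{gap columns}\)), the column count follows in closed form
and the value is symmetric with no traceback — a property the tests
exercise directly against an independent matrix implementation.

A gene hits a family when its best identity against any of the family's
references reaches the threshold (default **70%**, the stringent cut-off
used to define high-confidence loci). The screen is exact, not
heuristic: every gene–reference pair is evaluated (a provable
length-ratio bound, \(\mathrm{PID}\le 100\cdot\min(|a|,|b|)/\max(|a|,|b|)\),
skips only pairs that cannot reach the threshold). There is no coverage
requirement by default, and ties between references are broken towards
the smallest reference id for determinism. Whether an identity screen of
this kind should run on nucleotide or protein sequences is a genuine
choice; the package works at the protein level so that one identity
definition covers the generator, the screen and the tests, and because
family membership is a protein-level notion.

## Locus calling and the degrader signature

A locus is called for every GH112 hit in a genome that also carries at
least one GH136 subunit hit *anywhere in the genome*. The genome-wide
(rather than windowed) co-occurrence rule matches how such loci are
defined in pangenome screens; window-level structure is assessed
downstream by `signature_check()`, which asks a landscape for the full
robust signature — GH112, a GH136 subunit, a transporter component
(SBP or PP) and a transcriptional regulator. Genomes with several GH112
paralogs produce one locus per anchor, but count once in prevalence,
keeping prevalence a genome-level statistic.

## Gene landscapes

For each anchor we take the `window` genes before and after it in
coordinate order on its contig (default **11** per side; figure-style
summaries elsewhere sometimes use 10, so the window is a parameter and
both values are exercised in the tests). Genes are tokenized by their
family hit when they have one (GH112 taking precedence on the anchor),
otherwise through a configurable keyword map on the product annotation
("solute binding" → SBP, "permease" → PP, "regulator" → TransR,
"histidine kinase" → HisK, "hypothetical" → HP), otherwise `OTHER`.

Anchors on the minus strand have their neighborhood reversed (and the
truncation flags swapped) so every landscape reads 5′→3′ through the
locus. This makes plus- and minus-strand loci directly comparable and
gives the central invariant of the module: mirroring a contig leaves
every landscape token-identical. The tests assert this exactly over
1000 random planted loci, along with window monotonicity (the landscape
at `n` is a centred contiguous sub-list of the landscape at `n+1`) and
the length bound `2n + 1`.

## Comparing landscapes

Landscape similarity uses the **optimal string alignment** (OSA,
restricted Damerau–Levenshtein) distance over tokens: unit-cost
insertion, deletion, substitution and adjacent transposition, with no
substring edited twice. Both gene membership and gene position matter.
Distances are computed over token lists, never concatenated characters,
so multi-character tokens cannot alias. OSA famously violates the
triangle inequality — `CA → ABC` costs 3 even though `CA → AC → ABC`
would cost 2 via an intermediate — and the test suite checks the kernel
against a memoized recursive oracle on *every* pair of token strings of
length ≤ 6 over a four-token alphabet (29.8 million ordered pairs), as
well as against an unmemoized recursive oracle in R on random strings.

Ordination is classical scaling (PCoA): square the distances,
double-center (\(B = -\tfrac12 J D^{(2)} J\)), eigendecompose, scale
eigenvectors by the square roots of the eigenvalues. Because OSA
distances are not Euclidean, some eigenvalues are negative; they are
clamped to zero for coordinates and reported in the result, so users can
judge the distortion. On genuinely Euclidean inputs the implementation
reproduces all pairwise distances to 1e−8 and agrees with
`stats::cmdscale`, which serves as an independent cross-check only.

"Most conserved gene neighborhood" per SGB is operationalized as the
**modal token string**, with deterministic tie-breaks: minimal mean OSA
distance to the group, then the lexicographically smallest string. The
representative is always a member of its group. `OTHER` tokens take part
in comparisons by default (`include_other = FALSE` drops them first);
both modes are tested.

## The synthetic cohort generator

`simulate_cohort()` emulates an SGB-structured pangenome with planted
loci. Defaults mirror the benchmark conditions used throughout the
package's validation:

| parameter | default | meaning |
|---|---|---|
| `n_sgbs`, `genomes_per_sgb` | 5 × 24 | cohort structure (120 genomes) |
| `identity_range` | 80–95% | planted-gene identity to references, uniform |
| `frac_gh112_only` | 0.15 | secondary-degrader fraction per SGB |
| `frac_no_locus` | 0.10 | locus-free fraction per SGB |
| `n_background_genes` | 30 | hypothetical-protein genes per genome |
| `rearrangement_rate` | 0.3 | probability of one locus rearrangement |

Category counts are exact by construction: per SGB of size \(n\),
\(\lfloor f_{\text{sec}} n\rfloor\) secondary and
\(\lfloor f_{\text{none}} n\rfloor\) locus-free genomes, remainder
primary, assigned in index order and shuffled under the cohort seed.
Loci follow one of two templates (`locus_templates()`): the compact
architecture and an extended one adding GH29/GH95 fucosidase genes.
One rearrangement operator is applied with the configured probability:
delete a non-anchor gene, insert a hypothetical-protein gene, or swap
two adjacent non-anchor genes — the three classes of neighborhood
variation the comparison stage must distinguish. The locus strand is
random per genome; on the minus strand the physical gene order is
reversed so the locus still transcribes 5′→3′.

Planted proteins are references mutated by substitution at
\(\mathrm{round}(L(1 - t/100))\) random positions, which lands within
±3 percentage points of the target identity \(t\); background genes are
random uniform proteins of 150–400 residues whose identity to any
reference stays far below any usable threshold (empirically < 40% across
1000 draws — asserted in the tests). Genomes are single contigs with
non-overlapping genes and 50 bp intergenic gaps, 1-based inclusive
coordinates. A single root seed drives indexed per-genome substreams, so
identical designs reproduce byte-identical cohorts.

The uniform identity distribution is a modeling choice: real
above-threshold hit identities have an unknown, certainly non-uniform
distribution. The generator also does not model nucleotide-level
evolution, phylogenetically structured identity decay, multi-contig
fragmentation, or annotation noise in product strings. Passing recovery
tests therefore demonstrate the *pipeline's* correctness under
controlled conditions — thresholding, co-occurrence logic, orientation
normalization, distance computation and reporting — not robustness to
annotation error or assembly fragmentation in real MAG collections.

## Numerical and degenerate-input choices

* Identity ties (co-optimal alignments) resolve to maximum matches;
  reference ties to the smallest `ref_id`; gene-order ties (equal start
  coordinates) to the smaller gene id.
* `pcoa()` requires `k < n` and a symmetric zero-diagonal matrix;
  an all-zero distance matrix yields all-zero coordinates.
* Empty cohorts and hit-free genomes propagate as valid empty results:
  `detect_loci()` returns a zero-row table, the pipeline writes an empty
  distance matrix and representative table, and prevalence is all-zero.
* Landscape extraction at contig edges records upstream/downstream
  truncation flags (swapped on minus-strand anchors) rather than
  padding.
* GFF3 output percent-encodes reserved attribute characters and contains
  no timestamps; all writers are deterministic so that identical inputs
  and configuration reproduce byte-identical artifact sets.

## Validation problem sizes

The shipped tests validate: the OSA kernel exhaustively at length ≤ 6
over 4 tokens; PCoA on 20 random points in 3-space; threshold
monotonicity on a 50-genome cohort; exact recovery (locus
precision/recall 1.0, categories, per-SGB prevalence, representative
landscapes) on the 120-genome benchmark cohort above; mirror invariance
on 1000 planted loci; and byte-level determinism of two full pipeline
runs. `scripts/acceptance.R` recomputes the same quantities from a
command-line seed.

## Limitations

* The homolog screen is an exact global-identity filter, not a local
  aligner: genes fused with unrelated domains, or references much longer
  than the query, are penalized by end gaps. A coverage-aware or
  local-alignment mode would be the natural extension for real MAGs.
* Co-occurrence is genome-wide; on fragmented assemblies where GH112 and
  GH136 land on different contigs of different bins this overcalls
  nothing but may *undercall* split genomes (cross-contig locus
  stitching is out of scope).
* OSA's triangle-inequality violations mean the PCoA embedding is an
  approximation whose distortion should be judged from the reported
  negative eigenvalues.
* Reference sequences shipped with the generator are synthetic; real
  screens must supply their own family references as
  `>ref_id|FAMILY|genome_label` FASTA.
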