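---
title: "Conservation profiling of protein alignments: methods and design"
author: "MSAcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation profiling of protein alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MSAcons)
```

## The problem

Residues that carry a protein's function — tunnel linings, gates, binding
and allosteric sites — are usually dispersed along the primary sequence but
adjacent in the folded structure. Judging whether such a *functional
compartment* evolves faster or slower than the rest of the protein requires
three ingredients: per-column conservation/variability scores over a
multiple sequence alignment (MSA) of homologs, a reliable mapping from
structure residue numbers onto alignment columns, and a statistical
comparison of the compartment's score distribution against the remainder.
MSAcons provides all three, plus the alignment-validation steps (consensus
similarity, pairwise-distance outlier screening) that such an analysis
depends on.

## Column bookkeeping

Every score works from the per-column symbol counts exposed by
`columnProfile()`. Two frequency conventions coexist deliberately:

* $p_i$ — residue frequencies at column $i$ with gaps (and unknown `X`)
  kept in the denominator;
* $q_i$ — residue frequencies renormalized over residue-carrying rows only;
* $n_i$ — the number of distinct residues present, gaps excluded.

Symbols are normalized on ingest: lowercase is uppercased, `.` gaps become
`-`, and any letter outside the 20-residue alphabet (B, Z, J, U, O, `*`)
becomes `X`. `X` is excluded from residue counts but still occupies a row
in every column total. This is a package decision, made to keep the
20-letter alphabet closed; it matters only for alignments containing
non-standard letters.

## The seven metrics

All metrics are reported per column, in *variability* orientation (larger =
more variable) unless stated; all-gap columns yield `NaN` everywhere.

**Shannon** $H_i = -\sum_a q_{a,i} \ln q_{a,i}$, in nats.
**Schneider** $H_i / \ln 20$. The denominator is fixed at $\ln 20$ rather
than $\ln \min(20, N)$; with fewer sequences than residue types the score
simply cannot reach 1, which is the behaviour we document rather than
hide.
**Kabat** $V_i = k_i N_i / n_{1,i}$ — distinct residue types times
residue-carrying rows over the majority-residue count; $V = 1$ exactly on
invariant columns.

**E-score** is built from the dominant-residue frequency with gaps kept in
the denominator:

$$P_i = \frac{\max(p_i)}{n_i}, \qquad
  P_i^{norm} = \frac{P_i}{\max_j P_j}, \qquad
  E_i = \frac{-\ln P_i^{norm}}{\max_j\left(-\ln P_j^{norm}\right)}.$$

Gaps lower $\max(p_i)$ without entering an entropy sum, so columns that
differ only in gap content remain distinguishable. The maximum in both
normalizations is taken over non-degenerate columns only, and
$\max(p_i)$ is taken over residues even when gaps dominate a column — a
gap can never be the "dominating symbol". If every column shares the same
$P$ the score is identically 0. $E \in [0,1]$; an invariant gapless
column scores 0 and (in any non-degenerate alignment) some column scores
exactly 1.

**Landgraf** uses a similarity matrix $S$ (default the bundled Gonnet
PAM250 matrix, `inst/extdata/gonnet250.txt`):

$$L_i = \frac{1}{N(N-1)} \sum_{j \neq k} w_j\, d(a_j \to a_k), \qquad
  d(a \to b) = S(a,a) - S(a,b),$$

summing over ordered residue pairs of the column (gapped and `X` rows
excluded), with per-sequence weights $w$. The distance is asymmetric
because the self-score shift differs between the two residues. This
concrete $d$ is our fixed, testable definition of the substitution-based
conservation index; $L = 0$ iff the column is invariant.

**UPGMA guide tree.** `upgmaTree()` performs standard arithmetic-mean
agglomeration (via the exact Lance–Williams update), node height = half
the merge distance. Ties at the minimum distance merge the pair containing
the lexicographically smallest leaf label first, which pins down the tree
(and everything derived from it) bit-for-bit. An independent
exhaustive-merge oracle in the test suite recomputes every cluster
distance from the original matrix and must agree on topology and heights
for all small cases.

**Real-valued Evolutionary Trace (RET)**

$$\rho_i = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g=1}^{n} H_{i,g},$$

where the $n$ groups at level $n$ are the subtrees left after removing the
$n-1$ highest internal nodes of the guide tree (height ties resolved by
the deterministic merge order) and $H_{i,g}$ is the gap-excluded Shannon
entropy of the column within group $g$. Sequence weighting is implicit:
redundant sequences cluster early and stop contributing once partitions
separate lineages. $\rho \ge 1$, with equality iff every group at every
level is invariant.

**Cumulative relative entropy (CRE)**

$$CRE_i = \sum_g \frac{N_g}{N} \sum_a p_{a,g} \ln\frac{p_{a,g}}{q_a},$$

a group-size-weighted KL divergence of subgroup column distributions from
the pooled one (gap-excluded on both sides; zero-frequency terms
contribute 0; a group with no residues at a column is skipped there with a
warning). The default partition cuts the UPGMA tree at half its root
height — a package choice where only "grouping by pairwise distances" is
prescribed by the method family; any explicit partition can be supplied.
CRE accepts no external sequence weights.

## Sequence weights and pseudo-counts

`henikoffWeights()` implements position-based weights: sequence $s$
accumulates $\sum_c 1/(k_c\, n_{c,x})$ with the gap counted as a symbol
type, normalized to sum 1. Weights may be passed to the four
frequency-based scores, to Landgraf and to the consensus; RET derives its
weighting from the tree, and CRE takes none.

Pseudo-counts (for Shannon, Schneider, Kabat and the E-score) follow the
substitution-probability scheme: $b_a = B \sum_b f_b\, g(a \mid b)$,
$p'_a = (n_a + b_a)/(N + B)$. Two defaults are our own, documented
choices, both overridable:

* $B = 5 k_c$, five times the number of distinct residues in the column —
  a standard magnitude for this scheme;
* $g(a \mid b)$ derived at runtime from the BLOSUM62 score matrix via the
  half-bit inversion $q_{ab} \propto p_a p_b\, 2^{S_{ab}/2}$ with
  Robinson–Robinson background frequencies, columns renormalized.

Pseudo-mass is spread over residues only; gap counts are never adjusted.
The correction is $O(B/N)$ and disappears as the alignment deepens, which
the tests verify by simulation at $N = 10^4$.

## Consensus and outlier screening

The consensus takes, per column, the most frequent residue iff its
frequency over *all* rows (gaps in the denominator, but gaps can never
win) strictly exceeds the threshold, else `X`. The default threshold 0.3
mirrors the 30%-identity homology rule of thumb, and "over 30%" is read as
a strict inequality. Ties are resolved alphabetically and flagged.

Two outlier routes: similarity to the consensus (over informative columns
only; low tail suspicious) and mean pairwise p-distance (high tail
suspicious). Distances are $1 - \mathrm{matches}/\mathrm{comparable}$ with
comparable = not-both-gap columns, a gap facing a residue counting as a
mismatch; the flagging rule is Tukey's $1.5 \times IQR$ fence on R's
default (type-7) quantiles. Both the distance and the cutoff are package
choices — the method family prescribes neither — and flags are advisory:
removal or trimming is always the user's decision, and re-alignment after
editing is delegated to external tools.

## Structure mapping

`readCompartmentTable()` parses the residue table (number, name, optional
numeric features). `correctNumbering()` converts sequential (observed)
numbering — what structure-analysis tools emit — into author numbering by
skipping residues listed in the PDB `REMARK 465` section for the chain:
with missing $\{5, 6\}$, sequential 5 becomes author 7. The inverse
(`authorToSequential()`) is exposed; records with insertion codes are
rejected rather than guessed at. `buildResidueMap()` then sends author
residue $r$ to the column of the $r$-th non-gap reference symbol.
Residue-name disagreements between table and reference warn rather than
error, since crystal and database sequences legitimately differ. Only the
REMARK 465 section of the PDB file is ever read.

## Compartment statistics

`ksCompare()` tests the compartment columns' scores against the remaining
columns with the two-sample Kolmogorov–Smirnov statistic
$D = \sup_x |F_1 - F_2|$ and the asymptotic p-value (delegated to
`stats::ks.test(exact = FALSE)`), the common choice at the scale of a few
hundred columns; NaN columns are dropped from both samples. The 0.05
significance level appears only in reporting, never inside the
computation, and no multiple-testing correction is applied across
compartments. `extremePositions()` returns the k least/most variable
columns of a set, honouring each profile's orientation flag, ties going to
the lower column index.

## The synthetic generator — and what it does not emulate

`generateMsa()` draws each column i.i.d. from a focal-residue mixture:
conservation level $c$ gives the focal residue probability
$c + (1-c)/20$, so level 1 forces invariance and level 0 is uniform — the
simplest mechanism with a monotone conservation knob. Gap blocks (a column
range gapped in a fraction of rows) emulate missing domains; duplicate
clusters emulate taxonomic bias; gap blocks are applied after duplication.
Everything is bit-reproducible from (arguments, seed), and the generator
restores the caller's RNG state.

The generator deliberately does **not** simulate a phylogeny, a
substitution process, or covariation between columns: rows are
exchangeable and columns independent. Passing tests therefore demonstrate
the correctness of the *computations* (formulas, bounds, invariances,
calibration) on alignments with known structure — not that any metric is
the best conservation estimator for real, phylogenetically correlated
data, where metric choice remains the analyst's judgement call.

`generateStructureFixture()` emits a mutually consistent (reference
sequence, compartment table in sequential numbering, PDB fragment with a
REMARK 465 section) triple, so the numbering-correction/mapping round
trip can be asserted exactly.

## Numerical conventions and degenerate inputs

* Natural logarithms throughout; normalized scores are base-invariant.
* All-gap columns: `NaN` for every metric, excluded from E-score maxima
  and from KS samples.
* UPGMA distance ties: $10^{-12}$ tolerance, lexicographic resolution;
  merge heights clamped to be nondecreasing against floating-point dips.
* Columns are 1-based in every user-facing table; trimmed alignments
  retain their original column indices (`columnProvenance()`).
* CSV output writes missing values as empty cells (never `"NA"` text) and
  round-trips value-for-value at six significant digits or better.

## Problem sizes used by the checks

The bundled verification script exercises a 60-sequence × 120-column
alignment with a 15-column conserved compartment, a 20-column gap block in
a third of the sequences, and two PDB-missing residues; KS calibration
uses 500–1000 replicates of 100 scores per group. These sizes were chosen
as representative of a focused single-domain analysis while keeping the
whole suite quick to run.

## Known limitations

* Clustal input follows the strict layout accepted by Biostrings (header
  line plus two blank lines); exotic dialects should be converted to
  FASTA first.
* The original integer-valued Evolutionary Trace is not implemented, only
  the real-valued variant.
* Author numbering is assumed to start at 1 and increase without
  insertion codes; structures with heteronumbering need manual renumbering
  first.
* Landgraf requires every residue in a column to be present in the
  substitution matrix; grouped (reduced-alphabet) alignments therefore
  need a matching group-level matrix.
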