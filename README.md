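# MSAcons

Conservation and variability profiling of protein multiple sequence
alignments, with mapping of dispersed structural residues ("functional
compartments" — tunnels, gates, binding sites) onto alignment columns and
statistical comparison of their evolutionary rate against the rest of the
protein.

## Who this is for

Protein engineers and structural bioinformaticians who have (i) an MSA of
homologs and (ii) a list of structure residues of interest — e.g. tunnel
lining residues from a cavity-analysis tool — and want to know which of
those positions are evolutionarily permissive (mutation candidates) and
whether the compartment as a whole evolves differently from the rest of
the structure.

## What it computes

Per alignment column, seven conservation/variability metrics:

| metric | definition | range |
|---|---|---|
| `shannon` | $H = -\sum_a q_a \ln q_a$ over gap-excluded residue frequencies | $[0, \ln 20]$ |
| `schneider` | $H / \ln 20$ | $[0, 1]$ |
| `kabat` | $k N / n_1$ (types × rows / majority count) | $\ge 1$ |
| `escore` | $E = \dfrac{-\ln P^{norm}}{\max(-\ln P^{norm})}$, $P = \dfrac{\max(p)}{n}$ with gaps kept in the denominator of $p$ | $[0, 1]$ |
| `landgraf` | weighted asymmetric substitution distances $d(a\to b) = S(a,a) - S(a,b)$ over column pairs (bundled Gonnet PAM250) | $\ge 0$ |
| `ret` | real-valued Evolutionary Trace: $1 + \sum_{n=1}^{N-1} \frac1n \sum_g H_{g}$ over UPGMA tree cuts | $\ge 1$ |
| `cre` | cumulative relative entropy: group-weighted KL divergence of subgroup column distributions from the pooled one | $\ge 0$ |

The E-score treats gaps as a letter that dilutes the dominant-residue
frequency without entering the entropy-style term, so gap-heavy columns
stay distinguishable; an invariant gapless column scores 0 and the most
variable column scores exactly 1.

Around the scores: Henikoff position-based sequence weights, BLOSUM-derived
pseudo-counts, reduced-alphabet "grouping mode", consensus-sequence and
pairwise-distance outlier screening, PDB `REMARK 465` missing-residue
numbering correction, residue-to-column mapping, two-sample
Kolmogorov–Smirnov compartment-vs-rest comparison, per-position CSV
tables, and profile/composition/ECDF/scatter plots. A seedable synthetic
generator (`generateMsa()`, `generateStructureFixture()`) produces
alignments with tunable per-column conservation, gap blocks and duplicate
clusters, plus consistent toy structures.

## Worked example

```r
library(MSAcons)

## a 30-sequence alignment whose first 20 columns are strongly conserved
aln <- generateMsa(30, 80,
                   conservation = c(rep(0.95, 20), rep(0.45, 60)),
                   seed = 7)
# in real use: aln <- readAlignment("homologs.fasta")

w   <- henikoffWeights(aln)                      # redundancy down-weighting
esc <- scoreConservation(aln, "escore", weights = w)
ret <- scoreRET(aln)                             # tree-based trace

round(scoreValues(esc)[1:8], 3)
#> [1] 0.465 0.189 0.000 0.190 0.190 0.304 0.000 0.189

consensusSequence(aln, threshold = 0.3)
#> ConsensusResult (threshold 0.30): LENGKYNCIDDYFMECMPCH...

## compare the conserved block (as if it were a mapped tunnel) to the rest
ksCompare(ret, compartmentCols = 1:20)
#> KS two-sample test: D = 1.0000, p = 1.872e-13 (n1 = 20, n2 = 60)

extremePositions(ret, 1:20, k = 3)
#> $least          $most
#> [1] 3 7 9       [1]  1 17 20
```

Low E-scores (columns 3 and 7 above score 0.000) flag invariant, likely
function-critical positions; the KS result says the 20-column compartment
is significantly more conserved than the remaining 60 columns; the
`least`/`most` lists are the prime conservation anchors and mutation
candidates within the compartment.

With a real structure, the compartment arrives as a residue table plus a
PDB file:

```r
comp <- readCompartmentTable("tunnel2.tsv")          # number, name, features
comp <- correctNumbering(comp, "structure.pdb", "A") # REMARK 465 skip rule
map  <- buildResidueMap(aln, "MYPROT_HUMAN")
cols <- compartmentColumns(map, comp, a = aln)
ksCompare(ret, cols, restCols = setdiff(map@columns, cols))
writeProfileCSV(assembleProfileTable(aln, list(esc, ret), map = map,
                                     compartments = list(comp),
                                     consensus = consensusSequence(aln)),
                "profile.csv")
```

The same pipeline is scriptable from a shell via `inst/cli/msacons.R`
(subcommands `validate`, `score`, `map`, `compare`, `plot`, `fixtures`).

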