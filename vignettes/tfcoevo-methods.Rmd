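---
title: "Methods: residue coevolution and DNA-binding specificity in TF families"
author: "tfcoevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue coevolution and DNA-binding specificity in TF families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoevo)
```

## The problem

Transcription factors (TFs) within one structural family share a
DNA-binding domain (DBD) yet bind different DNA motifs.  Two kinds of
signal in a family alignment bear on that specificity:

* **subclass-determining sites (TSDSs)** — alignment columns whose residue
  composition separates motif-defined subclasses of the family; and
* **coevolving residue pairs (CRPs)** — column pairs whose residues covary
  across family members, indicating shared evolutionary constraints.

`tfcoevo` implements the full inference chain connecting the two: cluster
TFs into subclasses from motif similarity, score columns for subclass
specificity, score column pairs for covariation with four statistics,
intersect their top deciles into CRPs, analyse the CRP network for
community structure and TSDS enrichment, and map pairs onto protein-DNA
complex structures to ask whether coevolving residues sit at or away from
the DNA interface.

## Motif subclassing

Motif similarity between two position weight matrices is the maximum, over
all ungapped offsets with at least `min_overlap = 4` overlapping columns
(and over the reverse-complement orientation of the second motif, on by
default), of the Pearson correlation between the flattened `4 x L`
overlapping sub-matrices.  Families are clustered by average-linkage
hierarchical clustering on `1 - similarity`.  The subclass count is chosen
by the elbow rule: the smallest `k` whose within-cluster sum of squares
(WSS), computed on rows of the similarity matrix as Euclidean feature
vectors, drops below 10% of the WSS of the unpartitioned family.
Subclasses with fewer than five members are flagged and excluded from
specificity scoring.  Three of these conventions — the linkage, the WSS
feature space and the orientation search — are genuinely open design
choices; they are explicit arguments with the defaults above rather than
hidden constants.

Subclass motifs can be merged with `merge_motifs()`: members are aligned
at their best offsets to the member with the highest information content
and averaged **over the region covered by every member**.  We chose
intersection rather than union coverage because the merged motif is used
as a subclass consensus; union coverage would dilute flanking columns
supported by a single member.  Merging exact offset-shifted copies
therefore returns the shared window, equal to either input on it.

## TSDS scoring

For every non-invariant column (columns with 100% residue identity carry
no specificity signal and are masked), three equal-weighted measures
compare the retained subclasses:

* **relative entropy (RE)** — mean over subclasses of the
  Kullback-Leibler divergence (bits) of the subclass residue distribution
  from the whole-family distribution, with a pseudocount of
  `lambda = 0.5` per residue class (set `lambda = 0` for the exact
  unsmoothed divergence);
* **physicochemical divergence (ED)** — mean pairwise Euclidean distance
  between subclass mean residue property vectors.  The property space is
  the five-factor Atchley solution, a fixed built-in table;
* **evolutionary-rate heterogeneity (ER)** — the ratio of mean
  between-subclass to mean within-subclass expected residue substitution
  distance at the column, where the substitution distance is
  `1 - normalised BLOSUM62 similarity`.  Both means are computed as
  frequency-weighted expectations, so identical subclass distributions
  give exactly `ER = 1`.  A small additive constant (`er_delta = 0.05`,
  on the [0, 1] distance scale) regularises the ratio so that a subclass
  that is invariant at a column yields a large but finite score instead
  of dividing by zero.

The combined statistic is the mean of the three column-wise z-scores.
Significance comes from a permutation test: TF-to-subclass labels are
permuted (which preserves every column's overall residue composition),
the combined statistic is recomputed, and
`p = (1 + #[perm >= obs]) / (n_perm + 1)`.  Permuting labels rather than
residues keeps within-column dependence intact and makes the null
exchangeable, so the p-values are valid (never zero, never above one) by
construction.  A column is called a TSDS when `p < 0.1`.  Whether such
p-values should be multiplicity-corrected before that cutoff is
ambiguous; the table therefore carries both the raw permutation p-value
(used for the call, matching the stated rule) and a Benjamini-Hochberg
adjusted column.  Gaps are ignored in all frequency estimates rather than
treated as a 21st symbol; a subclass entirely gapped at a column is
omitted from that column's statistics.

## Covariation statistics

All four statistics are computed per column pair on the sequences ungapped
at both columns (per-pair sample size `N`); a pair with fewer than two
co-observations is reported as missing.  Columns with gap fraction above
`max_gap_frac = 0.25` or zero diversity are excluded up front — covariation
with an invariant column is identically zero, and heavily gapped columns
have unstable pair counts.

* **MI** `= sum_ab p(a,b) log2[p(a,b) / (p(a) p(b))]`, in bits (base 2 is
  a stated convention, not a consequence of the definition).
* **MIp** `= MI - APC`, `APC(i,j) = MI(i,.) MI(j,.) / mean(MI)` with row
  means and the grand mean over off-diagonal scored pairs; the average
  product correction removes shared background/phylogenetic signal.
* **OMES** `= sum_ab (N_obs(a,b) - N_exp(a,b))^2 / N` with
  `N_exp(a,b) = n_i(a) n_j(b) / N`, summed over all residue-pair cells.
* **SCA** — the Frobenius norm of the conservation-weighted covariance
  tensor `phi_i^a phi_j^b (f_ij^ab - f_i^a f_j^b)` with
  `phi = |ln[f~(1-q) / ((1-f~) q)]|`, `f~ = (1-lambda) f + lambda q`,
  uniform background `q = 1/20` and regularisation `lambda = 0.03`.

No sequence weighting for redundancy is applied — many covariation tools
reweight similar sequences, but the chain here is defined on the plain
alignment, and the synthetic generator draws independent sequences, so
weighting would change the estimand without a reference to match.

Candidate pairs are the top 10% of scored pairs per method by nearest
rank: the threshold is the `ceiling(0.10 n)`-th largest score and ties at
the threshold are all included (an all-tied matrix selects everything,
with a warning).  **CRPs** are candidates supported by at least two
methods.  Method agreement is summarised by pairwise Jaccard coefficients.
The four score sets are also combined into a single matrix: per-method
min-max rescaling to [0, 1], quantile normalisation across methods (ties
receive the mean of the tied ranks' reference values), and averaging.
Both rankings — per-method deciles and the combined score — are kept,
because which of the two should rank "highly coevolving" residues for
downstream mutation selection is ambiguous; CRP calling uses the decile
rule.

## Network analysis

The CRP network has alignment columns as nodes and CRPs as edges.
Communities come from greedy (Clauset-Newman-Moore) modularity
optimisation; the merge dendrogram is cut explicitly at the maximum
modularity along the merge path.  Greedy agglomeration can land in a
local optimum — on small graphs the returned partition is usually, but
not always, the global modularity maximum; this is a known property of
the algorithm, not of its implementation.

TSDS clustering is tested by permutation: the observed fraction of edges
with both endpoints TSDS is compared with the same fraction under uniform
permutation of the TSDS labels over network nodes.  Label permutation was
chosen over degree-preserving edge rewiring because the question is about
the placement of labels on a fixed network.

Sequence-separation and block statistics: a pair is *distant* when its
endpoints are more than five alignment positions apart; it is
*out-of-block* when its endpoints lie in different blocks.  Blocks are
data, not something the chain computes — they are supplied as column
intervals, with a fallback heuristic that splits the alignment at columns
with gap fraction above 0.5.  A pair with an endpoint outside every block
is counted as out-of-block; this convention is documented rather than
inferred.

The motif-similarity consequence of a CRP is quantified by grouping TFs
by their ordered residue pair at the two columns (order matters: the
columns are distinct sites), computing each group's mean pairwise motif
similarity, and weighting group means by group size over the eligible
total.  CRP and non-CRP score distributions are compared with a Welch
t-test (the variance structure of the two sets is unknown, so the
unequal-variance form is the safe default).

## Structure mapping

Complexes are accepted when they contain both protein and DNA chains
(DNA residues DA/DC/DG/DT/DU) and their recorded resolution is below 4 A
(a stricter cutoff is the same parameter, not a separate code path; a
missing resolution record rejects unless overridden).  Alternate
conformers keep the highest-occupancy copy; waters and heteroatoms are
excluded; hydrogens, when present, participate in distances — the
distance definition is over *atoms*, with no atom-class restriction.

The domain row of the alignment is located in a chain by exact substring
match, falling back to global alignment (BLOSUM62, affine gaps); only
columns aligned to identical residues are mapped, and mapping is refused
below 60% identity.  Distances are shortest atom-atom Euclidean
distances; when a column maps into several chains the minimum over chains
is taken — conservative for interface distances.  A CRP is an **f-CRP**
when at least one endpoint lies strictly more than 10 A from the nearest
DNA atom.

FoldX is never executed; the package only writes `individual_list`
mutation files (`RA49G;` format, with wild-type validation against the
structure) and parses replicate ddG tables, averaging the five replicates
per mutant, flagging means above 2 kcal/mol as binding-disrupting, and
comparing groups with one-tailed Wilcoxon tests.

## The synthetic generator

`generate_family()` produces families with known ground truth:

* background columns i.i.d. uniform over a configurable alphabet subset —
  a simple null for false-positive checks;
* TSDS columns with one residue per subclass, flipped to a random
  background residue with probability `tsds_noise` (default 0.05);
* covarying pairs `(i, j, coupling)`: with probability `coupling`, the
  residue at `j` is the image of the residue at `i` under a fixed random
  bijection drawn once per pair.  At `coupling = 1` the pair's MI equals
  the source column's entropy, which makes the planted signal analytic;
* one PWM per TF: its subclass template perturbed per column by
  `Dirichlet(pwm_noise x template + 1)` (default concentration 50, i.e.
  tight, sharply informative motifs typical of curated TF databases).
  Subclass templates are sharp random consensus motifs,
  rejection-sampled so that no two templates exceed 0.5 best-offset
  similarity — subclasses model *distinct* binding specificities;
* toy protein-DNA complexes with fully controlled atom coordinates.

Everything is reproducible from a single integer seed.

What the generator does **not** emulate: phylogenetic tree structure
among sequences (rows are exchangeable, so the average product correction
has little to correct), indel structure beyond explicit gap placement,
correlated motif evolution, or raw binding-assay noise.  Passing the
recovery tests therefore demonstrates correctness of the chain under
planted signal, not performance on real families, where phylogeny and
alignment error add confounding.

## Problem sizes and test design

The validation suite runs the chain at sizes chosen to exercise every
code path while staying firmly in the regime where the planted signal is
identifiable: covariation oracles on 50 random alignments of up to 10
sequences by 8 columns against brute-force enumeration (agreement to
1e-10); pair recovery on 20 families of 200 sequences by 60 columns with
10 planted pairs at coupling 0.9; TSDS recovery on 3 subclasses of 20 TFs
with 5 planted columns at 5% noise (permutation depth 999) plus null
calibration on 300 unplanted columns; subclass recovery over 2-5 planted
template groups; exhaustive-modularity comparison on graphs of up to 8
nodes, where all partitions can be enumerated.  `scripts/acceptance.R`
recomputes the same quantities from scratch under a caller-supplied seed.

## Known limitations

* Greedy modularity optimisation can return a partition below the global
  optimum (see above); community structure on small CRP networks should
  be read qualitatively.
* The SPEER-like scorer follows the published design (RE + property
  distance + rate heterogeneity, equal weights) but is not a bit-exact
  reproduction of the SPEER binary; its p-values come from the label
  permutation null described here.
* No phylogenetic correction beyond APC, and no sequence redundancy
  weighting.
* Direct-coupling analysis and progressive multi-motif logo stacking are
  out of scope.
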