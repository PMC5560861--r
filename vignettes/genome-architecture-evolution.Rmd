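---
title: "Models and methods for genome architecture evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for genome architecture evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archevol)
library(ape)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not show
about real data.

## The two-state gain/loss model

Binary genome-architecture characters — intron presence at a homologous
alignment site, or a directed domain pair's presence in an orthocluster —
evolve on a rooted species tree under a continuous-time Markov chain on
{absent, present} with *branch-specific* gain rate $g_b$ and loss rate
$l_b$ (events per unit branch length). Along a branch of length $t$,

$$P(0 \to 1; t) = \frac{g}{g+l}\left(1 - e^{-(g+l)t}\right), \qquad
  P(1 \to 0; t) = \frac{l}{g+l}\left(1 - e^{-(g+l)t}\right).$$

The likelihood of an extant presence/absence matrix is computed by
Felsenstein pruning over sites, with per-node rescaling against underflow,
and is conditioned by default on each character being present in at least
one extant species: characters are discovered in extant annotations, so
the all-absent pattern is never observed, and ignoring that ascertainment
biases loss rates upward. Missing entries (species absent from the
orthocluster) contribute a flat partial likelihood.

Rates and the root presence probability are estimated by quasi-Newton
maximization (L-BFGS-B on log rates and the logit root probability),
declaring convergence when the log-likelihood improves by less than
$10^{-6}$, with at most 1000 iterations. Ancestral presence probabilities
and the expected gains $\sum_s P(\text{parent}=0,\text{child}=1 \mid
\text{data})$ and losses per branch come from the inside–outside
recursion; because posteriors condition on the observed data, the
ascertainment correction cancels there.

Two deliberate simplifications relative to the richer gene-content models
in the literature: there is a single rate class across sites (no
rates-across-sites categories), and copy number is not modelled for domain
pairs (presence/absence only). Both keep every quantity checkable against
brute-force enumeration over internal-state assignments, which the test
suite does exactly (agreement to $10^{-8}$ log-likelihood units on trees
with up to five internal nodes).

### Identifiability at the root

With a free root prior, the prior and the two transition matrices on the
root's child branches (five parameters) enter the likelihood only through
the joint distribution of the two root-children states (three degrees of
freedom). The rates on the two branches adjacent to the root therefore sit
on a maximum-likelihood ridge and are not estimable, no matter how many
sites are observed — a structural property of time-irreversible models on
rooted trees, not an optimizer failure. Parameter-recovery checks
consequently assess all branches except the two root-adjacent ones.
Posterior presence probabilities and expected event counts remain well
defined everywhere because they condition on the data.

Recovery accuracy on the 8-taxon, 5000-site simulations used in the
acceptance checks is typically within 25% relative error for branches with
at least 20 simulated events, but not uniformly so across random rate
draws: branch parameters with only tens of events carry sampling error of
order $1/\sqrt{\text{events}}$, and gain rates on short internal branches
partially trade off against rates on adjacent branches. The acceptance
script reports the max, median and fraction-within-25% at the seed it is
given rather than hiding this variability.

## Microsynteny

Collinear pairs are counted among single-copy orthologs only, and
"adjacent" means consecutive among the genes of the shared single-copy
ortholog set on a scaffold — intervening non-ortholog genes are ignored.
This matches the comparable-pairs denominator $N_{ij}$ and makes the
statistic robust to lineage-specific gene gain; strict genomic adjacency
is available via `mode = "strict"`. The permutation null shuffles gene
identities over the fixed gene positions of each genome, preserving
per-scaffold gene counts; for adjacency counting this is equivalent in
expectation to re-placing genes at random coordinates. For a single
scaffold of $n$ genes the expected shared adjacency count has the closed
form $2(n-1)/n$, which the tests verify by brute-force enumeration of all
permutations at $n = 5$ and against the Monte-Carlo null.

All pairwise nulls reuse one seeded random stream (common random numbers),
so datasets in which every pair has identical structure — e.g. simulations
with zero rearrangement — normalize to $r_{ij} = 1$ exactly for every
pair, not just the argmax pair.

## Intron sites

An intron is mapped to the alignment column of the amino acid whose codon
it interrupts; a phase-0 intron (between codons) is anchored to the
residue immediately 3′ of the intron. With $p$ coding nucleotides 5′ of
the intron both rules give residue $\lfloor p/3 \rfloor + 1$, and phase
$p \bmod 3$. Sites are merged across species on (column, phase): the same
column at different phases records independent gains. Site classification
uses a 3-column window centred on the site: *conserved* requires every
window column to have gap fraction ≤ 0.1 and the orthocluster to cover
≥ 80% of species; a window column gapped in more than half the rows marks
the region unalignable (*unclassifiable*); other gap failures are
*ambiguous*. The window width and both thresholds are arguments.

The signed gain/loss ratio of a node is
$r = \log_{10}((p_G + \varepsilon)/(p_L + \varepsilon))$ with
$\varepsilon = 10^{-6}$ to absorb zero percentages. The bootstrap
variance-to-mean ratio resamples sites with replacement under fixed rates
(100 replicates by default); values above 1 flag over-dispersed, less
reliable ancestral counts.

## Domain pairs, Dollo placement and networks

Architectures are decomposed by first collapsing consecutive repeats and
then emitting all ordered pairs $(d_i, d_j)$, $i < j$: A-B-B-C yields
A-B, A-C, B-C, and non-consecutive repeats yield self-pairs (A-B-A gives
A-A). Ancestral pair presence is called at posterior ≥ 0.9; node
diversification is classified gain- or loss-biased when the gain and loss
percentages differ by more than 5 points, and "dynamic stasis" otherwise.
Individual domains use Dollo parsimony: one gain at the most recent common
ancestor of the carriers, and one loss at the root of each maximal
all-absent subtree inside that clade — provably the minimal-loss
single-gain history, and verified against exhaustive enumeration for all
presence patterns on six-taxon trees.

Networks are undirected simple graphs (pair direction discarded;
self-pairs kept as a vertex attribute, not an edge). Louvain clustering
depends on vertex order, so a seeded vertex permutation makes results
deterministic per seed. The rewiring null applies 10 × |E| double-edge
swap attempts per replicate, rejecting self-loops and parallel edges,
which preserves every vertex degree exactly; the swap count is an
argument since no canonical value exists. Edges are unweighted by
default; function-oriented subnetworks follow orthocluster provenance
(all edges supported by an orthocluster containing a listed domain)
rather than vertex induction, with both modes available.

## TE landscapes and sequence conservation

Hit filters are inclusive at the boundary (70.0% identity and 80 bp pass).
$P_{qf}$ sorts families by copy count descending, breaking ties
lexicographically (the tie-break can move $P_{qf}$ at boundaries and is
therefore fixed and documented), and returns the percentage of families
needed to reach the fraction $q$ of copies. Identity histograms bin per
hit, not per copy, in 1% bins over [70, 100].

Cophenetic distances are path-length sums in gene trees. Lineage
comparisons use the two-sided Wilcoxon rank-sum test, exact for combined
samples ≤ 25 without ties (verified against full permutation enumeration
up to combined $n = 12$), normal approximation with tie and continuity
corrections otherwise. Distances are pooled across trees by default;
per-tree means are available since the choice is not forced by the method.

## The synthetic-data generator

The generator produces: intron histories simulated forward along the tree
under the same two-state transition probabilities the inference uses, with
true state changes recorded per branch; single-copy gene orders rearranged
by Poisson numbers of inversions and block translocations (no gene gain or
loss, preserving the single-copy premise of the synteny statistic);
ordered domain architectures whose gains append and losses delete domains,
with architectures recorded at every node; and TE landscapes with
power-law family sizes and burst-structured identities (truncated normal
around each burst mean). Every generator is deterministic given its seed.

What passing tests show: the estimators recover the generating process
they assume, the combinatorial statistics equal their enumeration oracles,
and the pipeline is deterministic. What they do not show: robustness to
model violations present in real data — rate variation across sites and
lineages, intron sliding, alignment error, incomplete annotations,
orthology mistakes, TE nesting — none of which the generator emulates. The
demo uses desk-scale problem sizes (8 species, hundreds to thousands of
characters, 100 permutation/bootstrap/rewiring rounds matching the
defaults), chosen so the full workflow runs in minutes on one CPU.

## Defaults worth knowing

| Parameter | Default | Where |
|---|---|---|
| permutation rounds (synteny null) | 100 | `shuffle_null` |
| rewiring replicates / swaps per edge | 100 / 10×|E| | `rewire_null` |
| bootstrap replicates (VMR) | 100 | `bootstrap_vmr` |
| ancestral call probability | 0.9 | `reconstruct_pair_history` |
| marker single-copy fraction / paralog species | 0.8 / 1 | `select_marker_orthoclusters` |
| site conservation: coverage / gap fraction / window | 0.8 / 0.1 / 3 | `classify_sites` |
| hit filters: identity / length | 70% / 80 bp | `filter_hits` |
| gain/loss ratio pseudo-count | 1e-6 | `gain_loss_ratio` |
| bias margin (diversification) | 5 points | `node_diversification` |
| ML convergence / max iterations | 1e-6 / 1000 | `fit_gain_loss_model` |

Isoform handling (the longest-CDS mRNA per gene) and the phase-0 anchoring
convention are this package's documented choices where the underlying
methods literature is silent; both are deterministic and stated here
rather than attributed elsewhere.
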