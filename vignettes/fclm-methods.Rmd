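---
title: "Split-wise phylogenomics with fclmap: models, quartet likelihoods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-wise phylogenomics with fclmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fclmap)
```

# What the package computes

`fclmap` interrogates a *single* phylogenetic split rather than inferring a
full tree. Given a concatenated amino-acid supermatrix and an assignment of
its taxa to four groups (clusters), Four-cluster Likelihood Mapping (FcLM)
asks, for every quartet consisting of one taxon per cluster, which of the
three unrooted quartet topologies

* T1: clusters 1,2 | 3,4
* T2: clusters 1,3 | 2,4
* T3: clusters 1,4 | 2,3

the data support. Each quartet contributes a likelihood triple
$(\ell_1, \ell_2, \ell_3)$, normalized to posterior weights
$p_i = e^{\ell_i - m} / \sum_j e^{\ell_j - m}$ (with $m = \max_i \ell_i$ for
numerical stability). The weights are barycentric coordinates in a
2-simplex, so the whole analysis can be drawn as a triangle with one dot per
quartet; the fraction of quartets whose largest weight backs each topology
is the headline support table. Because every quartet is evaluated
independently, FcLM exposes *conflicting* signal that a single best tree
cannot show.

Around that core the package implements the supporting workflow: compiling
*decisive* supermatrices (every retained gene covered in all four clusters),
screening alignments for contaminant or misaligned sequences by BLOSUM62
distance, and reconstructing morphological groundplans by unordered maximum
parsimony on a fixed tree. Seeded simulators generate all inputs with known
truth.

# Substitution model

Likelihoods use reversible empirical amino-acid models in GTR form:
$Q_{ij} = S_{ij}\pi_j$ for $i \neq j$, diagonal set so rows sum to zero, and
the whole matrix rescaled so $-\sum_i \pi_i Q_{ii} = 1$, i.e. branch lengths
are expected substitutions per site. LG and WAG exchangeabilities ship as
plain-text PAML-layout files under `inst/extdata/`; `read_paml_dat()`
accepts any user matrix in the same layout, and a Poisson (equal-rates)
model is built in. LG is the default throughout because it is the
best-fitting of the packaged matrices for typical insect transcriptome
supermatrices; `substitution_model()` exposes the choice.

Stationary frequencies default to the model's published values; the `+F`
variant — observed proportions in the analyzed alignment, gaps and `X`
excluded, with a $10^{-6}$ pseudo-count so no frequency is exactly zero —
is available through `empirical_frequencies()` and is what the analysis
scripts use, matching standard practice for large supermatrices.

Rate heterogeneity is the discrete-GAMMA approximation with equal-weight
categories. Both the category-mean and the category-median discretizations
are implemented; the median is the default (`use_median = TRUE`). Since raw
category medians do not average to one, both modes are renormalized to mean
exactly 1 — otherwise branch lengths would silently change units with the
discretization mode. Four categories is the default (`ncat`), the value
used by the mainstream ML tree programs; it is configurable.

Transition probabilities $P(t) = e^{Qt}$ come from the
$\pi$-symmetrized eigendecomposition: with $D = \mathrm{diag}(\sqrt{\pi})$,
$B = DQD^{-1}$ is symmetric, so $P(t) = D^{-1}V e^{\Lambda t} V^{\top} D$
with a guaranteed-real spectrum. Round-off can leave entries at about
$-10^{-16}$; these are clamped to zero and rows are left unrenormalized
(deviations are below $10^{-10}$).

# Quartet likelihood engine

For one quartet the likelihood of a topology is computed by Felsenstein
pruning, vectorized over compressed site patterns in a small C++ kernel.
Gaps and `X` contribute all-ones tip partials (fully marginalized missing
data), which is also how taxa absent from a gene enter the supermatrix.
Columns missing in all four rows carry no information (their site
likelihood is 1); they are removed up front and counted.

Branch lengths are optimized by coordinate ascent: Brent line searches on
the log of each of the five branch lengths, bounded to
$[10^{-8}, 100]$, iterated until the log-likelihood improves by less than
$10^{-4}$ (default) or 50 rounds. The search is deterministic; if the first
start (all branches 0.1) fails to converge a second start at 0.01 is tried
and the better fit kept, flagged `converged = FALSE` if neither settles.
When both bounds tie with the interior optimum the bound is preferred,
which keeps identical sequences exactly at the lower bound and prevents a
slow ridge walk toward the upper bound on saturated data.

The GAMMA shape can be held fixed, refit per topology, or — the default —
estimated once per quartet on the best topology of a quick first pass and
then fixed for the three final fits. The default keeps the triple
comparable: all three log-likelihoods are evaluated under the same
site-rate model, so differences reflect topology, not shape refitting.
Whether an original analysis fixes model parameters globally or refits per
quartet is a genuine design fork; both are supported (`alpha =` `"shared"`,
`"none"`, `"per_topology"` in `run_fclm()`/`evaluate_three_topologies()`).

In partitioned mode each partition carries its own exchangeabilities,
frequencies and shape, the five branch lengths are shared across partitions
(linked-branch-length model), and per-partition log-likelihoods are summed.
Linking keeps the triple comparable across partitions and mirrors how
partitioned supermatrix analyses are usually run; shapes are taken from the
supplied per-partition models and not refit.

# FcLM bookkeeping

Quartets are enumerated as the full cross product of the four clusters
(deterministic lexicographic order); the count is always the product of the
cluster sizes. Products at transcriptome scale (e.g. $>10^5$ quartets) are
cluster-computing jobs, so `run_fclm()` supports seeded uniform subsampling
(`max_quartets`) for desk-scale runs.

Two classifications are reported. The primary, used in the headline table,
is the argmax topology; exact ties are reported as their own `tie` category
rather than split among topologies — a float tie almost always means an
uninformative quartet, and keeping it separate leaves the three topology
percentages interpretable. The secondary seven-region classification
(three corners, three edges, center) depends on thresholds that are not
standardized anywhere; the defaults (corner at $p_i \ge 0.9$, center at
$\max p - \min p \le 0.05$) are configurable and the argmax table is the
one to quote. Quartets with no informative site (no column with two or
more observed residues) get weights $(1/3, 1/3, 1/3)$ and an
`uninformative` flag, and are retained in the denominator.

# Decisive supermatrix compilation

A dataset is decisive for a four-cluster question when every gene has at
least one sequence from each cluster, so every gene can in principle inform
the split. `select_decisive_genes()` applies exactly that rule;
`coverage_stats()` reports overall coverage as the percentage of present
gene-by-taxon cells and addressed-group coverage as the percentage of genes
covering all four clusters (by construction 100 after selection). Coverage
is defined at gene-cell granularity, not residue granularity: presence of a
gene is what the decisiveness argument is about, and partial-length
sequences still count as present.

Partition coordinates are stored 0-based half-open internally and written
1-based inclusive in RAxML-style partition files (`LG, gene001 = 1-250`),
the ecosystem convention. Absent gene/taxon blocks are filled with `-`,
which the likelihood engine treats identically to missing data.

# Alignment screening

The outlier screen compares every non-reference row of a gene alignment to
a designated reference set (at least three rows, so quartiles are defined).
The distance between two aligned rows is
$d = 1 - 2S_{ab}/(S_{aa} + S_{bb})$ over their overlap (columns where both
carry a residue), with $S$ the summed BLOSUM62 scores: zero for identical
rows, symmetric, and undefined when the overlap is empty. No standard
normalization of a BLOSUM score into a distance exists; this one was chosen
for those three properties and is stated here rather than asserted to match
any external tool.

The cutoff is $c = \text{mean} + 2.25\,(Q_3 - \text{mean})$ of the pairwise
reference distances. The multiplier operates on the distance from the upper
quartile to the mean; reading the cutoff as $2.25\,(Q_3 - \text{mean})$
alone (without the mean offset) collapses toward zero whenever the
reference distances are tightly clustered and would flag nearly everything,
so the offset form is the default and the bare form remains selectable
(`cutoff_form = "literal"`). A row is flagged when its minimal distance to
any reference exceeds $c$, or when its overlap with its closest-by-distance
reference is below 20 sites (configurable), or when no distance is defined
at all.

Flagged rows get one rescue attempt: the row is stripped of gaps and
re-aligned to the reference-only backbone by a global sequence-to-profile
aligner (BLOSUM62 column scores weighted by column residue frequencies,
affine gaps with open 10 / extend 1, insertions relative to the backbone
trimmed so column count is preserved). The profile aligner is an in-package
component so the pipeline is self-contained; a different aligner can be
substituted by replacing the realignment step, since the backbone contract
is just "same column count". After a second screening pass, persistently
flagged rows are removed and gap-only columns dropped.

# Groundplan reconstruction

Categorical characters are reconstructed on a fixed rooted tree under
unordered (uniform-cost) maximum parsimony. `fitch_steps()` is the classic
two-child downpass (polytomies are resolved by arbitrary zero-length
expansion first); `mpr_sets()` runs a uniform-cost Sankoff down- and
up-pass, which handles multifurcations natively, and reports at each node
the set of states realized by at least one most-parsimonious
reconstruction. Nodes with more than one state are flagged ambiguous;
a node whose set is disjoint from its parent's set is flagged apomorphic
(a change along the subtending branch is forced in every MPR).

Missing (`?`) and inapplicable (`-`) codings are both treated as "any
state" at zero forced cost — desktop parsimony tools differ in their exact
handling of inapplicable codings and of polymorphism, so the treatment here
is documented rather than claimed equivalent to any of them. Polymorphic
tips (`0/1`) constrain the tip to the coded subset. A character with no
observed variation still reconstructs over a binary state space so that
full-set ambiguity is representable.

# Synthetic data: what it does and does not emulate

The simulators generate: alignments evolved site-independently along a known
tree under the chosen model with per-site discrete-GAMMA rates (root drawn
from the stationary frequencies); Bernoulli gene-by-taxon presence with an
option to force a fraction of genes decisive; planted contaminants (a
genuine row with shuffled columns, or i.i.d. draws from LG frequencies);
and characters evolved by a symmetric k-state Markov chain. Everything is
driven by explicit seeds and is reproducible end to end.

Deliberately not emulated: indels (simulated rows are gapless until
coverage gaps are imposed), codon structure and selection, compositional
heterogeneity across lineages, alignment error other than the planted
kinds, and linkage between genes. Passing the simulation-based tests
therefore shows that the *algorithms* behave as specified under the model
they assume — not that real transcriptome data satisfy that model.

Default study conditions used by the tests and the analysis scripts: four
clusters on a known tree with the focal internal branch at 0.2
substitutions/site (0 for star-tree controls), LG with $\alpha = 1$, total
alignment length 2,000–3,000 aa from genes of 250 aa, presence probability
0.6–0.8, two planted contaminants per screened gene. Parameter-recovery
checks use a single quartet at 50,000 sites, where branch lengths recover
within 10% and the shape within 15%. These sizes keep a full desk run in
minutes while leaving the statistical behavior (split recovery,
star-tree balance, screen operating characteristics) clearly measurable.

# Numerical and degenerate-input policy

* Branch-length bounds $[10^{-8}, 100]$; bound preferred on ties.
* Site likelihoods are floored at $10^{-300}$ before the log (only reachable
  for genuinely impossible patterns under degenerate inputs).
* Exact argmax ties classify as `tie`; seven-region tie-breaks take the
  lowest topology index.
* An alignment with zero observed residues, an empty cluster, an empty
  keep-set, zero genes, or fewer than three references each raise an error
  naming the problem; a gene set with no decisive gene warns and returns an
  empty selection.
* All randomness flows through explicit seeds; `run_fclm()` uses its seed
  only for subsampling.

# Known limitations

The quartet engine is specialized to four taxa — it is not a general tree
likelihood, and there is no tree search, bootstrap, or rogue-taxon
analysis. Partitioned FcLM links branch lengths across partitions; fully
unlinked branch lengths are out of scope. The screen's distance and cutoff
are one defensible parameterization of a procedure whose published
descriptions underdetermine the algebra; both knobs are exposed. Ancestral
reconstruction is parsimony-only (no likelihood or Bayesian states), and
ordered or step-matrix characters are not supported.
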