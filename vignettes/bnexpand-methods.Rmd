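---
title: "bnexpand: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bnexpand: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnexpand)
```

## Scope and model

`bnexpand` learns discrete Bayesian networks over a set of pathway genes
from an expression compendium, summarizes equally top-scoring structures
as a consensus network, ranks out-of-network genes by how much their
addition improves the network score (single-gene "BN+1" expansion), and
associates sample-annotation words with discretization bins of a gene
pair by Fisher's exact test.

The data model is deliberately simple: after per-gene equal-frequency
discretization into `r` states (default 3), a DAG `M` over genes is
scored by its marginal likelihood under a multinomial model with a
uniform all-ones Dirichlet prior (the Cooper–Herskovits form of the BDe
family):

$$\ln P(D \mid M) = \sum_{i=1}^{n} \sum_{j=1}^{q_i}
  \left[ \ln\Gamma(r_i) - \ln\Gamma(N_{ij} + r_i)
       + \sum_{k=1}^{r_i} \ln\Gamma(N_{ijk} + 1) \right]$$

with $q_i$ the number of joint parent configurations of gene $i$,
$N_{ijk}$ the number of samples in which gene $i$ is in state $k$ while
its parents are in configuration $j$, and $N_{ij} = \sum_k N_{ijk}$.
Each family term is the log of the exact rational
$\frac{(r_i-1)!}{(N_{ij}+r_i-1)!}\prod_k N_{ijk}!$; the tests hold the
implementation to that identity against an independent factorial oracle
at $10^{-9}$ absolute tolerance.

Decisions taken where the design was genuinely open:

* **Prior over structures is uniform**: the score has no structure-prior
  term.  The phrase "structural prior" in this method family refers to
  the *starting topology* of a search, which remains fully mutable — not
  to a score component.
* **All-ones Dirichlet (CH), not BDeu.**  The all-ones metric is the
  classical one for this method; note it is *not* score-equivalent
  across Markov-equivalent DAGs, so no equivalence-class invariant is
  claimed anywhere.  A likelihood-equivalent BDeu variant is available
  via `search_config(prior = "bdeu", ess = ...)`.
* **`max_parents` defaults to 5.**  The score itself never caps fan-in,
  but $q_i = 3^{|pa_i|}$ makes large parent sets both statistically
  meaningless at a few hundred samples and computationally explosive; a
  cap of 5 is the convention of the structure-search tools this package
  follows.
* Log-gamma is used everywhere at run time (overflow-safe at compendium
  scale); exact factorial arithmetic appears only in test oracles.

## Preprocessing

**Coefficient of variation filter.**  c.v. = sample standard deviation
(n−1 denominator) divided by |mean|, computed on the values exactly as
read — expression compendia of the kind this tool targets ship
log-scale values, and the threshold (default 1.0) is applied directly to
them.  A gene with mean exactly 0 gets infinite c.v. and survives any
finite threshold.  Whether upstream analyses applied such thresholds to
logged or unlogged intensities is often unstated; both the threshold and
the input scale are caller-controlled here.

**Maximum-entropy discretization (q3).**  Per gene, samples are
rank-ordered and cut into `levels` bins (default 3; state 0 = lowest).
Cut positions are restricted to boundaries between *distinct* values, so
tied values can never straddle a bin boundary.  Among admissible cut
tuples the package maximizes the entropy of bin occupancy (equivalently
minimizes $\sum_b n_b \ln n_b$), which makes bins exactly equal whenever
the data allow it; remaining ties are broken by minimal largest bin,
then so that runs of equal values land in the lowest admissible state
(hence an all-constant gene is all state 0).  Worked consequences, both
under test: `[1,1,1,1,5,9]` becomes `[0,0,0,0,1,2]` (the four tied
values share a state and the remaining two samples fill the upper bins),
and an all-equal gene keeps arity 3 with every sample in state 0.
Because the rule is rank-based it is invariant under any strictly
increasing transform of a gene's values.  Arity is fixed at `levels`
even when a gene occupies fewer states, so $r_i$ is constant across
genes during scoring.

## Structure search

Search is simulated annealing over single-edge moves — add, delete,
reverse — chosen uniformly among the moves that are currently legal
(acyclicity and the parent cap respected).  Score improvements are
always accepted; a worsening $\Delta$ is accepted with probability
$e^{\Delta/T}$.  The budget unit is the *proposal* (a visited candidate
structure): search-size figures reported by tools of this family count
proposals, which is the only reproducible semantics.

Annealing schedule (all exposed in `search_config()`):

| parameter | default | meaning |
|---|---|---|
| `initial_temperature` | 100 | in log-score units; high enough that the early phase is a near-free random walk |
| `cooling_factor` | 0.9999 | geometric, per proposal; 2×10⁵ proposals cool 100 to ~2×10⁻⁷ |
| `reheat_after` | 500 | consecutive rejections before resetting to the initial temperature |
| `keep_top` | 5 | best *distinct* structures retained per run |
| `start_density` | 0 | random restarts start from the empty DAG; empty starts are unbiased and cheap, and the density is configurable to probe sensitivity |

The schedule itself is an implementation choice — the method this
reimplements names only "simulated annealing" — so the package treats it
as fully tunable and validates the *outcome* instead: on 4-node problems
(543 DAGs, enumerated exhaustively) the default search with 10 restarts
× 2×10⁴ proposals recovers the global optimum in ≥95 of 100 random
datasets.  Runs are deterministic given `rng_seed`; each restart draws
its own substream derived from the seed and the restart index, so
best-ever scores are monotone in the proposal budget at a fixed seed.

Networks "sharing the top score" are grouped with an absolute log-score
tolerance of 10⁻⁶ (`score_tolerance`): floating-point sums of identical
family terms can differ in their last bits.

## Consensus

Within the top group, an edge is directed in the consensus iff it
appears with the same orientation in *every* network; a skeleton is
undirected iff every network contains it but both orientations occur
*across* the group.  A single DAG cannot hold both orientations at once,
so "appearing in both directions" is read across networks — the only
internally consistent reading.  Support counts by orientation are
reported for every skeleton seen at least once.  Consequences under
test: the consensus of one network is that network (all edges directed),
and consensus edge sets shrink monotonically as networks join the group.
`compare_to_reference()` reports skeleton and orientation overlap
*separately*, since published overlap percentages of this kind rarely
state which was counted.

## BN+1 expansion

Each candidate gene is evaluated independently: the data are sliced to
the core genes plus that one candidate (keeping $q_i$ bounded and
matching the "plus one gene" semantics), the search starts from the core
topology with the candidate disconnected, and every edge — including
core edges — is mutable.  The candidate's score is the best network
found; the reported "induced" edges are the candidate's parents and
children in that network.

* The core fed to the expansion is a single top-scoring network; which
  one is an argument, defaulting to the first under deterministic sort —
  reproducibility is preferred over a literal random choice.
* Candidate RNG substreams are keyed by `(seed, candidate id,
  replicate)`, never by list position, so the ranking is invariant to
  evaluation order, and ties (e.g. duplicated candidates) break
  lexicographically by gene id.
* The rerank phase repeats the search `rerank_replicates` times per
  leading candidate and keeps the maximum; replicate 1 reuses the
  screen's substream, so a one-replicate rerank at the screen budget
  reproduces the screen exactly, and reranked scores can never fall
  below the screen's.
* Every expanded score is bounded below by the score of the seeded
  (isolated-candidate) network, because the start network itself is in
  the candidate set of the search.

Desk-scale default budgets (10⁵-proposal screens) replace the
10⁷–2.5×10⁷-proposal budgets of the compendium-scale analysis; the
algorithm is identical and the paper-scale values are reachable through
`expansion_config()`.

## Term enrichment

A *term* is any individual word in a sample's title or description.
Tokenization — lowercase, split on non-alphanumerics, drop tokens
shorter than 2 characters or purely numeric, per-sample set semantics —
is an artifact choice, disclosed here because the method's source
defines a term only as "any individual word".  There is no default
stop-word list: condition words like "biofilm" are exactly the signal
and must not be filtered (a caller-supplied list is accepted).

For a selected gene pair, every joint bin cell $(s_A, s_B)$ *and* every
marginal bin of either gene is tested — "a specific bin" is ambiguous
between the two readings, so both are computed and labelled.  The 2×2
table per (term, bin) is in-bin/out-of-bin × term/non-term; the
one-sided p-value is the upper hypergeometric tail, the two-sided
p-value the minimum-likelihood sum (relative tolerance 10⁻⁷ in the ≤
comparison, the standard convention), and Benjamini–Hochberg adjustment
is applied across all tested pairs.  The implementation sums
`dhyper` terms directly; tests hold it to an independent exact
enumeration at 10⁻¹² and to the worked fractions 37/924 and 74/924 for
the table (5,1,1,5).

## Synthetic data: what it emulates, what it does not

The generator produces: a sparse random DAG over ~8–30 three-state
variables (uniform random topological order, forward edges with
probability `edge_prob`), sharpened Dirichlet CPTs (one state carries
probability ≥ `strength`), Gaussian per-state emissions with strictly
increasing means (defaults 0/2/4, sd 0.5 — separations comparable to
log-expression dynamic range, noisy enough that discretization is
nontrivial but recoverable), a hidden regulator planted as a strong
parent of chosen core genes, independent noise genes, and metadata in
which a chosen term is planted in a chosen joint bin with `hit_rate`
versus `background_rate`.

Stated-world scales used by the validation suite, chosen once: 8 core
genes, strength 0.9, 20 noise candidates, 300 samples for expansion
recovery; 500 samples for structure recovery; `edge_prob = 0.25` for
ground-truth DAGs (the source states no edge density; 0.25 gives ~7
edges over 8 nodes, a sparse regulatory topology).  The planted
regulator's marginal distribution is uniform so its equal-frequency bins
align with its true states.

What a green test does *not* establish: the generator draws iid samples
from a stationary model with Gaussian emissions — it does not emulate
chip-level normalization artifacts, time-course autocorrelation,
knockout/over-expression intervention semantics (all samples are treated
as observational), or the curation noise of real annotation text.
Recovery rates measured here are therefore upper bounds on what the same
budgets achieve on real compendia.

## Numerical and degenerate-input choices

* Scores cache per-family terms by (child, parent set); incremental
  rescoring is exact because the score decomposes.
* Zero-sample data score 0 (= ln 1) for any DAG; empty candidate lists
  yield empty rankings, not errors.
* A gene with all-equal values discretizes to all state 0 with arity
  unchanged; bin edges are reported as ±∞ when a bin is empty, and
  `sum(value > edges)` always reconstructs the state.
* The compiled search represents parent sets as 64-bit masks and errors
  above 62 nodes; the R-level scorer has no such limit.
* Proposal selection with no legal moves (single-node graphs) leaves the
  structure unchanged but still consumes a proposal.

## Known limitations

* The annealing schedule is not tuned per problem; very flat score
  landscapes (tiny m) rely on the reheat mechanism and the best-ever
  tracker rather than on convergence of the chain.
* The all-ones prior is not score-equivalent across Markov-equivalent
  DAGs; consensus orientation therefore carries information from the
  score's asymmetry as well as from the data.
* Term enrichment treats words as independent tokens; controlled
  vocabularies, n-grams, and ontology mappings are out of scope.
* Multi-gene (BN+k) joint expansion and dynamic Bayesian networks are
  out of scope.
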