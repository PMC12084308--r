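---
title: "From free-association norms to semantic networks and priming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From free-association norms to semantic networks and priming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(assocnet)
```

## The pipeline at a glance

Free-association norms record, for each cue word, the first three words a
respondent (human or language model) associates with it, with each cue
repeated many times (100 repetitions is the design value of the "World of
Words" datasets). `assocnet` turns such norms into network models of
semantic memory and uses them to simulate semantic priming:

1. **Cleaning** (`preprocess_norms()`): normalize cues and responses,
   merge row groups whose corrected cues coincide, enforce exactly
   `target_repetitions` rows per cue, blank echoes and within-triple
   duplicates.
2. **Network construction** (`build_directed()`, `fold_undirected()`,
   `filter_network()`): count cue-to-response frequencies as directed edge
   weights, fold to an undirected graph keeping the larger weight per
   pair, then filter (lexicon, idiosyncratic edges, largest component).
3. **Spreading activation** (`spread()`, `activation_matrix()`,
   `normalize_matrix()`): simulate retention/propagation dynamics from
   each prime and normalize the resulting activation matrix.
4. **Priming statistics** (`run_priming()`, `priming_report()`,
   `bias_probe()`): paired Wilcoxon tests with matched-pairs rank-biserial
   effect sizes, and Spearman correlations between activation and lexical
   decision reaction times.
5. **Synthetic norms** (`generate_norms()`, `generate_probe_pairs()`):
   a generator with planted community structure, reversible noise, and a
   known relatedness signal, so that every step above can be validated
   without downloading any external dataset.

## Cleaning model

Token normalization applies, in a fixed order: lowercasing; removal of one
leading article (`a`, `an`, `the`) or the preposition `to` from responses
— never from cues, and never when the whole response is itself one of the
original cues (`a lot` stays `a lot`); replacement of underscores by
spaces; restoration of compounds that lost their spaces or hyphens
(`throwout` to `throw out`), via a one-to-one map built from the multiword
entries of a lexicon (`build_compound_map()`; ambiguous keys are dropped
entirely); spelling correction of cues and responses from a two-column
dictionary (which also maps British to American spelling, `colour` to
`color`); and lemmatization.

Lemmatization is deliberately noun-only: plural nouns become singular
(`men` to `man`, `dogs` to `dog`) while tensed verbs are never reduced
(`cooking`, `determined` pass through). It is implemented as an irregular
table plus conservative suffix rules (`-ies`, `-xes/-ses/-zes/-ches/-shes`,
`-oes`, then bare `-s` excluding `-ss/-us/-is`), and multiword tokens are
lemmatized on their final word only (`ice creams` to `ice cream`). When a
lexicon is supplied in the `cleaning_config()`, a suffix-rule singular is
accepted only if it is an attested lexicon entry, which prevents
overstripping (e.g. `lens`). Spelling correction runs before
lemmatization, mirroring the narrative order of the cleaning procedure the
package implements; the order is fixed rather than configurable.

After token normalization, rows are regrouped under their corrected cues
(so two spellings of a cue merge into one group) and every cue is brought
to exactly `target_repetitions` rows: groups that are short are padded
with all-blank rows, groups that are long are downsampled uniformly at
random without replacement. The downsampling is the only stochastic step
in cleaning; it uses the single seed recorded in the cleaning report, and
triples (rows) are the sampling unit, since the response triple is the
unit in which the data are delivered. Finally, responses equal to their
cue and repeated responses within a triple are blanked, earlier positions
winning. A second pass of `preprocess_norms()` over its own output fires
no counter — cleaning is idempotent — and cleaning can only merge cue
groups, never create new cues.

No "nonsense filter" is applied at this stage: deciding what counts as a
valid response is subjective, so implausible tokens are kept in the
cleaned table and dealt with structurally at the network stage, where the
lexicon filter removes nodes that are not words and the weight filter
removes one-off associations.

## Network model

The directed graph has an edge cue → response of weight equal to the
response's frequency for that cue; the sum of directed weights therefore
equals the number of non-blank responses, a conservation property the
tests exploit. Folding keeps, for each unordered pair, the larger of the
two directed weights (20 and 25 fold to 25). Filtering then applies, in
this order: remove nodes not in the lexicon; remove edges of weight 1
(idiosyncratic associations produced only once); keep the largest
connected component. The order is pinned by a regression test on a crafted
graph where reordering the stages changes the result. Lexicon membership
is tested on the cleaned surface form, lowercase, with the lexicon's
multiword separator mapped to a space and hyphens preserved — the same
conventions the compound map uses upstream.

Network statistics use the undirected conventions, density
$2E / (N(N-1))$ and average degree $2E / N$; reports print density to 4
decimals and degree to 1 decimal. Pairwise network comparisons report the
percentage of A-only, common (Jaccard, relative to the union), and B-only
nodes; the edge comparison applies the same three percentages to the
subgraphs induced by the common nodes, ignoring weights, and is flagged
undefined when those subgraphs carry no edges.

## Spreading-activation model

Activation starts concentrated on a prime node and evolves by synchronous
updates. With retention $r$, weight matrix $W$ and node strength
$s_j = \sum_i w_{ij}$, one step maps the activation vector $a$ to

$$a_i \leftarrow r\,a_i + (1 - r) \sum_j \frac{w_{ij}}{s_j}\, a_j ,$$

i.e. every node keeps the fraction $r$ and distributes the rest among its
neighbors proportionally to edge weights; isolated nodes keep everything.
An optional decay multiplies the state by $1-d$ per step, and activations
below a suppression threshold are zeroed. With $d = 0$ and no suppression
the dynamics are linear and conservative: total activation equals the
initial activation at every step, which the test suite verifies to
$10^{-9}$ relative tolerance against an independently assembled dense
transition operator on random graphs.

Defaults are pinned to the settings used for the priming validation:
initial activation equal to the number of nodes in the network, number of
steps equal to twice the network diameter, retention $r = 0.5$, no decay,
no suppression, weighted propagation, synchronous (Jacobi-style) updates.
The validation procedure this package models states that retention-style
parameters were left at their software defaults without printing the
values, so $r = 0.5$ is a declared assumption of this package; it is
carried in the resolved parameter set attached to every activation matrix,
so deviations are always visible. Synchronous updates were chosen because
asynchronous schedules would make results depend on an arbitrary node
order. The diameter is computed on the unweighted graph: weights here
encode association frequency (how readily activation flows), not
distances, and a weighted path-length convention would require a cost
transformation the underlying procedure never specifies.

The activation matrix stacks the final activation vectors of all primes
(rows = all network nodes, columns = primes). Normalization is L1, columns
first and then rows: each column is divided by its sum, then each nonzero
row by its sum. This controls for differences in node centrality — a hub
target would otherwise collect high activation from any prime — so the
normalized values reflect priming rather than frequency effects. Sum
normalization is the simplest scheme with that property; all-zero rows
(nodes unreachable from every prime) are left at zero and counted, and an
all-zero column is an error since with zero decay a prime always retains
activation.

## Priming and bias statistics

`run_priming()` excludes a pair unless its target and both primes are in
the network (the exclusion list and reasons are attached to the result;
used plus excluded always equals the input count). All primes of the
usable pairs enter one activation matrix, which is normalized jointly, and
each target's normalized activation is read off under its related and its
unrelated prime.

The paired test is the two-sided Wilcoxon signed-rank test, with zero
differences dropped before ranking (their count is reported) and at least
five nonzero differences required. The effect size is the matched-pairs
rank biserial,

$$\mathrm{ES} = \frac{T^+ - T^-}{T^+ + T^-},$$

where $T^+$ and $T^-$ are the sums of the ranks of positive and negative
differences: $+1$ when related primes always win, $-1$ when they always
lose, antisymmetric under swapping the two conditions. The sign convention
is positive for "related activation exceeds unrelated activation", which
makes the activation effect positive and the corresponding reaction-time
effect negative (related primes speed responses). The p-value comes from
the standard signed-rank distribution (exact for small samples without
ties), which the tests check against full enumeration of all $2^8$ sign
assignments at $n = 8$. The Spearman correlation between normalized
activation and z-scored reaction time is computed over all included
prime-target observations pooled (two per pair), with average ranks on
ties.

`bias_probe()` reuses the machinery for implicit-bias probes: each probe
pairs a target with a stereotype-consistent prime (doctor–man,
nurse–woman) and a stereotype-inconsistent one (doctor–woman, nurse–man).
The consistent prime plays the "related" role, so a positive effect size
indicates stereotype-consistent associations are stronger in the network;
an exactly symmetric network yields zero differences. An optional label
column analyzes probe groups separately.

## The synthetic generator: what it emulates, and what it does not

`generate_norms()` draws a vocabulary partitioned into communities;
responses to a cue come from the cue's own community with probability
`within_community_response_prob` (default 0.9) and follow a Zipf-like rank
distribution (exponent 1) inside each community, giving the heavy-tailed
response frequencies that make some associations strong and most weak.
Cues are the top-ranked words of each community, 500 cues over a
1500-word vocabulary by default, with 100 repetitions per cue and three
distinct non-echo responses per row. Noise is applied per cell on top of a
retained canonical table, with every corruption recorded in an invertible
ledger: misspellings (drawn from an internal reversible dictionary that is
also returned as the matching spelling map), leading articles, spurious
pluralization, blanked cells, and nonsense tokens guaranteed absent from
the lexicon — mirroring the division of labor in which cleaning repairs
recoverable damage and the network-stage lexicon filter removes the rest.
Default rates (2% misspelling, 2% article, 5% blank, 1% nonsense, 2%
pluralization) were chosen once as plausible for noisy free-association
data; with only reversible rules enabled, cleaning restores the canonical
table exactly, a property tested across seeds.

Probe pairs plant a known priming signal: the related prime is the
target's most frequent within-community response (so a strong direct edge
is guaranteed), the unrelated prime is a cue from a different community
with no direct co-association, and relatedness is the response share.
Reaction times follow the simplest monotone-negative model,
$RT = a - b \cdot \mathrm{relatedness} + \varepsilon$ with Gaussian noise
(defaults $a = 1$, $b = 3$, $\sigma = 0.2$ on the z-score scale), since
the phenomenon being modeled implies only that stronger relatedness
speeds decisions.

What the generator does **not** emulate: the actual frequency profile or
topic structure of human or LLM-generated norms, polysemy, morphological
variety beyond the planted noise rules, or any particular model's response
style. Passing the pipeline's tests on synthetic data therefore
demonstrates correctness of the mechanics (cleaning inverts its noise
model, networks count what the table contains, the simulator is exact,
planted signals are recovered with calibrated tests) — not that any
specific empirical dataset will show a particular effect size.

## Numerical choices and degenerate inputs

- Blank responses are a reserved sentinel (the empty string at the storage
  layer) and never enter a graph.
- Encoding is fixed to UTF-8; the Unicode minus found in published tables
  is normalized to ASCII hyphen-minus on read.
- Spelling maps resolve chains at load (so applying the map twice equals
  once) and reject conflicting duplicate keys and cycles.
- Downsampling ties are impossible (sampling without replacement); the
  largest-component tie breaks to the first component, and component ties
  do not arise in the tested configurations.
- `wilcoxon_paired()` refuses fewer than five nonzero differences but
  returns effect size 0 with p = 1 when *all* differences vanish (the
  degenerate "identical conditions" case); `spearman_rho()` errors on
  constant input, where rank correlation is undefined.
- The simulator's conservation and oracle-equivalence guarantees are
  verified to $10^{-9}$ (absolute and relative, respectively) on graphs of
  up to 12 nodes; linearity in the initial activation holds to machine
  precision.

## Problem sizes used in validation

The packaged checks run the generator at its study-scale defaults (500
cues × 100 repetitions, 50 probe pairs) for the parameter-recovery check,
smaller configurations (10–60 cues, 5–40 repetitions) for unit and
property tests, 100 random graphs of up to 12 nodes for the simulator
oracle, and 600 sign-flip replicates for the null-calibration check.
These sizes were chosen so the whole suite runs in well under a minute on
one core while still exercising the filtering, largest-component, and
normalization paths at non-trivial scale.

```{r example, eval = FALSE}
cfg <- synth_config(seed = 7)
gen <- generate_norms(cfg)
res <- preprocess_norms(gen$norms, cleaning_config_from_truth(gen$truth))
net <- filter_network(fold_undirected(build_directed(res$table)),
                      gen$truth$lexicon)
pairs <- generate_probe_pairs(cfg, gen$truth)
priming_report(run_priming(net, pairs))
```

## Known limitations

- The retention default (0.5) is an assumption, not a published value;
  analyses sensitive to it should sweep `retention` explicitly.
- The lemmatizer is rule-based and English-only; it is conservative by
  design and will leave exotic plurals untouched unless they are in the
  irregular table.
- The lexicon is an input. Results on real norms depend on which word
  list is supplied (the original procedure used WordNet); the package
  ships no lexicon of its own.
- Real human/LLM norms are not redistributable with this package, so the
  published dataset-level figures (cue counts, network sizes, empirical
  effect sizes) can be reproduced only after obtaining those files from
  their sources; the packaged validation reproduces the method, the
  arithmetic of the published network statistics, and the behavior of
  every pipeline stage on synthetic data with known ground truth.
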