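---
title: "Methods: coculture outcome prediction and mechanism ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coculture outcome prediction and mechanism ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `cocultr`, the defaults and their
units, the numerical choices that make results reproducible to the last bit,
and the deliberate limitations of the toy simulator. Code chunks are not
evaluated at build time; every snippet runs as shown against the installed
package.

## 1. The statistical model

### Composite trait vectors

Each organism $i$ is described by a binary trait vector $F^{(i)}$ (one bit
per capability — here, per possible exchange of an external metabolite in
each direction). An ordered coculture observation "response of $i$ grown
with $j$" is represented by the **composite vector**

$$F^{(i,j)} = [\,F^{(i)},\; F^{(j)}\,],$$

the responder's traits first, the partner's second (feature names carry the
suffix `_p`). The representation is deliberately asymmetric:
$F^{(i,j)} \ne F^{(j,i)}$ whenever the organisms differ, because the two
orders are two distinct observations with, in general, two different
outcomes. Traits are pure capability annotations; they must never be derived
from the measured responses themselves.

### Responses and labels

The default response is the **relative yield**
$X_{ij} = (B_{ij} - B_{ii})/B_{ii}$, the normalized change in the
responder's final biomass in coculture versus monoculture (diagonal entries
of an interaction table store $B_{ii}$, in gDW). Numeric responses become
two-class labels through a `label_rule()`:

* `sign` — `negative` iff $X < -\mathrm{tol}$, else `nonnegative`. Exact
  zero is nonnegative. The tolerance (default $10^{-9}$) exists because
  simulated yields of genuinely non-interacting pairs can differ from zero
  by floating-point noise; a boundary without a tolerance would let that
  noise pick the class.
* `cutoff` — for fold changes: `weak` iff response $\le$ cutoff (a fold
  change of exactly the cutoff is weak), `strong` above it.
* `binary` — 0/1 responses passed through.

### The forest

`train_forest()` grows `ntree` (default 500) binary decision trees on
bootstrap resamples (same size as the training set, drawn with
replacement). Binary features make splits trivial — value 0 goes left,
1 right — and the split maximizing the Gini impurity decrease among `mtry`
(default $\lfloor\sqrt{2n}\rfloor$ for $2n$ composite features) randomly
drawn candidates is chosen. Samples a tree never drew are that tree's
**out-of-bag (OOB)** samples; OOB votes provide an internal test estimate,
reported as balanced accuracy and as ROC/AUC over the vote fraction.

Determinism is part of the contract:

* one RNG substream per tree, derived from the single seed, so increasing
  `ntree` never reshuffles earlier trees;
* equal-gain split ties break towards the lowest feature index;
* a vote fraction of exactly 0.5 is called for the negative class.

The forest is written from scratch rather than wrapped from a library for
one load-bearing reason: the contribution decomposition below needs the
training class counts of **every** node plus the per-tree bootstrap
membership, which established implementations do not expose in a stable
way. An equivalence test in the suite checks that its OOB error stays
within 5 percentage points of `randomForest` on matched data and
hyperparameters.

### Feature contributions

Let $Y(v)$ be the positive-class fraction of training samples at node $v$.
For one sample and one tree, walk the root-to-leaf path; at each node
splitting on feature $f$ the child the sample is routed to changes the
fraction by $Y(\mathrm{child}) - Y(\mathrm{node})$, and these increments
accumulate per feature. They telescope: summed over the path they equal
$Y(\mathrm{leaf}) - Y(\mathrm{root})$. The per-sample contribution
$\varphi_f$ is the mean increment over the **counted trees** — the trees
for which a training sample is out-of-bag (new samples use all trees). This
gives the exact additivity identity checked to $10^{-9}$ in the tests:

$$\mathrm{baseline} + \sum_f \varphi_f = \text{mean leaf fraction over
counted trees}.$$

A `denominator = "total"` variant divides by `ntree` instead (a sensitivity
check in which the identity intentionally does not hold — it shrinks
contributions of heavily in-bag samples). The default is `"counted"`: a
mean over the trees actually consulted.

### Mechanism ranking

A candidate mechanism (e.g. "competition over metabolite $m$") maps to one
responder-half feature and one partner-half feature
(`candidate_map_competition()`: `upt_m` + `upt_m_p`;
`candidate_map_facilitation()`: `upt_m` + `sec_m_p`). The **net
contribution** of a candidate is the sum of its two features' $\varphi$
values. Competitive mechanisms are read from the negative end (most
negative net first), facilitative ones from the positive end; ties break
alphabetically by candidate name. Candidates absent from both halves of the
sample are ranked but flagged (`zero_presence`), since their contributions
can only arise through value-0 branches.

The economic yardstick is the expected number of wet-lab experiments. If
candidates were tested in uniformly random order, the first of $k$ true
mechanisms among $n$ candidates appears at expected position
$(n+1)/(k+1)$ (`expected_random_rank()`); with 194 candidates and one true
metabolite that is 97.5 experiments. `first_true_rank()` reports the
corresponding position under net-contribution ordering, and
`query_count_evaluation()` aggregates it over a labeled dataset.

## 2. The toy dFBA simulator

### What it is

`toy_pathway_model()` builds minimal stoichiometric organisms: each usable
substrate enters through an exchange reaction (bounds in mmol/gDW/h),
a conversion reaction turns it into a biomass precursor at a fixed yield
(gDW per mmol, drawn from `yield_range`, default 0.4–0.8), and the biomass
reaction drains the precursor. Optional by-products are emitted in fixed
proportion to consumption of the first substrate. **Decoy** exchanges give
an organism the genomic capability (trait bit 1) without any internal
pathway, so the flux is structurally zero — the analogue of annotated but
unused transporters, and the reason trait overlap is a noisy baseline.

`fba_solve()` maximizes biomass flux subject to $S v = 0$ and bounds
(negative exchange flux = uptake). `dfba_run()` time-steps a well-mixed
batch culture: at each step every organism's uptake of metabolite $m$ is
capped at $\min(V_{\max},\ \mathrm{amount}_m / (B_{\mathrm{demand}}
\cdot \Delta t))$ where $B_{\mathrm{demand}}$ is the summed biomass of all
organisms *able* to take $m$ up — a scarce pool is shared in proportion to
biomass. After the per-organism FBA solves, biomass updates as
$B \leftarrow B(1 + \mu\,\Delta t)$ and pools as
$m \leftarrow m + \sum_k v_{k,m} B_k \Delta t$. Defaults:
$\Delta t = 0.1$ h, 240 steps, $V_{\max} = 10$ mmol/gDW/h, $B_0 = 0.01$
gDW, supply 10 mmol per substrate. The run stops early when every growth
rate falls below $10^{-9}$ h$^{-1}$.

Interactions are **emergent**: nothing in the update rule encodes them.
`pairwise_campaign()` runs every monoculture and unordered pair from the
same initial environment and derives ground truth from the exchange-flux
time series — a metabolite is *contended* when both partners take it up,
and *facilitative* for $i$ when $j$ secretes it and $i$ consumes it, where
a flux only counts if it moves more than $10^{-9}$ mmol in some single
step. Organisms that fail to grow in monoculture get `NA` responses by
default (`require_mono_growth`), because a relative yield against a
non-growing reference is not meaningful.

### Numerical choices

* **Forward Euler, not exponential growth.** The linear update makes the
  mass-bookkeeping identity (final amount = initial + $\sum$ flux·B·dt)
  exact up to rounding, which the tests verify to $10^{-6}$ on every run.
* **Own LP solver.** The toy LPs are small and dense, but degenerate:
  by-product models routinely defeated the available general-purpose
  simplex implementations (Big-M phase failures, singular pivots, internal
  indexing errors) on a fraction of instances — unacceptable inside a
  simulator that solves thousands of LPs per campaign. `cocultr` therefore
  ships a two-phase primal simplex with Bland's rule (guaranteed
  termination), with variables shifted to non-negativity and upper bounds
  as slack rows; after phase 1, leftover zero-level artificial variables
  are driven out by degenerate pivots so phase 2 runs artificial-free.
  Tests cross-check it against closed-form yield·cap oracles on every
  instance and against an external LP routine on the instances that
  routine can solve.
* **Finite stand-in for unbounded fluxes** ($10^3$ mmol/gDW/h), far above
  any attainable toy flux.
* **LP caching** keyed by organism and caps (12 significant digits), since
  consecutive dFBA steps repeat identical solves while substrate is
  plentiful.

### Scenarios

* `single_competition` — each organism grows on exactly one substrate;
  organisms are grouped (`group_size`, default 4) so group members contend
  over exactly one metabolite and cross-group pairs do not interact. This
  yields abundant single-mechanism negative samples — the cleanest setting
  for evaluating mechanism ranking.
* `mixed` — a medium-restricted regime: only `n_supplied` (default 10) of
  the metabolite universe are in the medium; each organism's pathway
  repertoire covers a few supplied substrates (`diet_supplied`, default 2)
  and several unsupplied ones (`diet_unsupplied`, default 8), plus decoy
  secretion bits. Pairs compete over however many supplied substrates their
  diets share, while most trait bits are irrelevant to the medium. This is
  the regime in which a trained classifier should beat the naive
  Jaccard-overlap baseline — overlap counts all shared capabilities,
  whereas only medium-active ones matter. The suite asserts the forest's
  OOB AUC beats the Jaccard AUC on five seeded communities.
* `cross_feeding` — producer/consumer pairs: the producer secretes a
  by-product the consumer can grow on. Consumers also receive a small
  private substrate (20&nbsp;% of the standard supply) so they grow weakly in
  monoculture; without it their relative yields would be undefined
  (`NA` under `require_mono_growth`) and the facilitative class would
  vanish from datasets. This is a documented design choice of the
  generator, not a property of cross-feeding itself.

### The auxotroph-style generator

`generate_auxotroph_community()` emulates the structure of a panel of
single-auxotrophy strains: each strain's trait vector is all ones except
the one capability it lacks, and the synthetic fold change of responder $i$
with partner $j$ is log-normal around a high mean (default 4) when the
partner possesses $i$'s missing capability, and a low mean (default 1)
otherwise, separated by the fold-change-2 label rule. One deliberate
departure from an all-distinct design: auxotrophies are drawn from a pool
smaller than the strain count (default 10 capabilities for 14 strains). If
every strain lacked a distinct capability, every ordered pair would be
complementary and the dataset would contain a single class; shared
auxotrophies create the weak (non-rescuing) pairs that make the
classification problem well-posed.

## 3. Evaluation protocols

* `paired_split()` splits at the level of **unordered** pairs: the two
  ordered observations $(i,j)$ and $(j,i)$ always land on the same side, so
  a model is never tested on the mirror image of a training pair. The
  bootstrap inside the forest intentionally does *not* impose this
  constraint — it applies to train/test separation, not to resampling
  within a training set.
* `learning_curve()` sweeps training fractions (default 0.05–0.95),
  repeatedly splitting, training and scoring balanced accuracy on the
  held-out side; degenerate single-class training draws are redrawn (up to
  100 times). Balanced accuracy — the mean of sensitivity and specificity —
  is used throughout because outcome classes are heavily imbalanced.
* `community_size_sweep()` repeats the curve on random organism subsets of
  increasing size; subsets are drawn independently, so organisms may recur
  across draws.
* `balanced_subsample_train()` handles rare classes: each repeat keeps all
  rare-class samples plus an equal-size majority draw without replacement,
  then scores OOB balanced accuracy; the median over (default) 100 repeats
  is reported.

## 4. Problem sizes and limitations

The shipped defaults (20–24 organisms, 50 metabolites, 500 trees) are
package choices sized so that a full campaign — 210 simulations, forest
training, per-sample contributions for every negative sample — completes in
seconds on one CPU. They are not claims about any particular biological
dataset.

The simulator is a caricature by design: no Michaelis–Menten kinetics (the
cap rule only), no lag phases or death rates, no spatial structure, no
genome-scale models or SBML input, and a medium chosen by the generator
rather than calibrated to any organism. Its purpose is to produce labeled
data with *exact* ground truth so that the statistical machinery — composite
representation, forest, contributions, ranking, protocols — can be tested
end to end; transferring conclusions to real communities requires real
trait matrices and measured responses, which the package accepts through
the same TSV interfaces (`read_trait_matrix()`,
`read_interaction_table()`).
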