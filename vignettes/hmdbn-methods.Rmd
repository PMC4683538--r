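---
title: "Methods: hidden Markov dynamic Bayesian networks for time-varying regulatory inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hidden Markov dynamic Bayesian networks for time-varying regulatory inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmdbn)
```

## The problem

A dynamic Bayesian network (DBN) over genes $X_{1:N}$ explains each
observation $x_i(t)$ by the states of a parent set at the previous time
point, $x_{G_i}(t-1)$. The standard stationarity assumption — one graph and
one parameter set for the whole series — fails for processes such as
development or immune response, where regulatory inputs themselves turn
over. This package relaxes stationarity *per node*: the parent set of each
gene is allowed to switch over time among a small collection of
configurations, called **hidden graphs**, and the identity of the active
configuration is treated as the hidden state of a hidden Markov model
(HMM). A node-specific model is the 4-tuple
$(\{G_i^{(h)}\}_{h=1}^{H_i}, \pi_i, A_i, \Theta_i)$: the hidden graphs, a
prior over the graph active at the first transition, an
$H_i \times H_i$ graph-to-graph transition matrix, and one multinomial
conditional probability table (CPD) per graph. The emission probability of
the HMM at time $t$ is the CPD likelihood
$P(x_i(t) \mid G_i^{(h)}, x(t-1))$.

Because all edges point from time $t-1$ to time $t$ (contemporaneous edges
are disallowed) and the likelihood factorizes over nodes, every node can be
learned independently and the node-wise models reconciled afterwards into a
global piecewise-constant network; cycles across slices need no special
treatment.

## Scores

For a fixed hidden-graph set, the forward–backward algorithm yields
$\gamma_h(t)$, the posterior that time point $t$ was generated by graph
$h$, and the soft contingency counts
$\tilde N_{hjk} = \sum_t \gamma_h(t)\,\delta(x_i(t)=k,\; \mathrm{pa}_h(t-1)=j)$
with expected sample size $\hat N_h = \sum_t \gamma_h(t)$.

**BWBIC** (Baum–Welch BIC) is a Laplace approximation to the log marginal
likelihood of the CPDs evaluated with these expected counts:
$$\mathrm{BWBIC}_i \;=\; \sum_{h=1}^{H_i}\Big[\sum_{j,k}\tilde N_{hjk}\log\hat\theta_{hjk} \;-\; \frac{d_h}{2}\log \hat N_h\Big],
\qquad d_h = q_h\,(r_i-1),$$
where $q_h$ is the number of parent configurations of graph $h$ and $r_i$
the child's arity. With a single graph and hard posteriors this is exactly
the stationary BIC, and the package asserts that identity in its tests.
Because every time point contributes fractionally to every graph, data are
shared across segments — the property that distinguishes this score from
segment-wise stationary metrics.

When the transition matrix is optimized, the search criterion adds the
remaining part of the structural-EM objective: the expected
log-probability of the hidden-graph chain at its re-estimated prior and
transition matrix,
$\sum_h \gamma_h(1)\log\hat\pi_h + \sum_{h,h'}\big(\sum_t \xi_{hh'}(t)\big)\log\hat a_{hh'}$,
minus a BIC penalty of $\tfrac{1}{2}\,[(H-1) + H(H-1)]\log T$ for the
chain's own free parameters. This term is not optional decoration. The
CPD part alone is maximized by degenerate "mixtures" that split time
points between near-duplicate graphs — the expected-count likelihood can be
driven toward zero at no cost — whereas the chain term charges exactly the
price of that erratic switching, while leaving genuine, persistent regime
changes almost free. It vanishes when $H=1$, so the stationary limit is
still plain BIC. Under an ablation that freezes the transition matrix,
nothing is optimized there: the frozen chain contributes neither
likelihood nor parameters, and the criterion reduces to the expected-count
marginal likelihood alone (the degenerate mixtures cannot arise in that
regime, because EM cannot tailor the transitions to fund the switching).

**BIC** and **BDe** baselines implement the traditional stationary metrics
applied per segment: time points are hard-assigned to graphs by the
Viterbi path of the converged model (the Viterbi-training convention),
each graph is scored on its own demarcated counts only — log-likelihood
minus $\frac{d_h}{2}\log N_h$ for BIC, the Dirichlet-multinomial marginal
likelihood with a uniform equivalent-sample-size prior
$\alpha/(q_h r_i)$ per cell (default $\alpha = 1$; the value is a
convention, not estimated) for BDe — and the per-graph terms are summed.
The Viterbi path, not the per-time argmax, is essential here: when two
graphs are nearly tied the marginal argmax assigns each time point to
whichever graph happens to fit it best, and a stationary metric then
harvests that selection noise as spurious likelihood; the joint MAP path
under sticky optimized transitions stays put unless the evidence
accumulates. Under a frozen row-uniform matrix the two coincide — which
is exactly why the stationary metrics degrade there while the
expected-count score does not. The baselines deliberately contain no
chain term and no soft sharing: they are the comparison points for the
information-sharing claim.

## The search

Learning a node (`learn_node()`) is greedy hill climbing over *stationary*
candidate parent sets, which keeps the search space linear in $N$ per step
rather than exponential in the number of hidden graphs:

1. start from the empty parent set;
2. propose every single-parent addition (up to `max_fanin`, default 3) and
   deletion;
3. transform each candidate stationary set $S$ into a non-stationary model
   (below), score it, and accept the best strictly improving move;
4. stop when no move improves the score.

The transformation (`single_edge_hmm()`, `combine_edge_posteriors()`,
`identify_hidden_graphs()`, `refine_hmdbn()`) is the heart of the method:

* For each candidate parent $j \in S$, a 2-state HMM with hidden graphs
  $\varnothing$ and $\{j\}$ is fitted by an inner Baum–Welch EM; the
  posterior of the with-parent state is the time-evolving presence
  probability of the edge $j \to i$.
* Each edge is then classified by comparing three models under the BWBIC
  criterion (identification of the hidden graphs is part of the search
  machinery and is the same whichever metric the outer search uses for
  acceptance): no parent, parent always active, and the 2-state model. If
  the empty model wins, the presence is collapsed to 0 — a parent with no
  support must not dilute the configuration posteriors (a presence
  hovering near one half would otherwise spread mass over configurations
  that differ only by an uninformative parent). If the always-active model
  wins, the presence is collapsed to 1.
* Presence vectors are combined per time point as independent products
  into posteriors over all $2^{|S|}$ parent configurations; configurations
  whose expected occupancy exceeds 5% of $T$ (plus the globally dominant
  one, at most `H_max = 6`) become the hidden graphs.
* The full model over the retained graphs is refined by EM — emission
  update from maximum-likelihood CPDs, forward–backward, re-estimation of
  $\pi$ (posterior at $t=1$) and $A$ (pairwise-posterior ratios) — until
  the relative log-likelihood change falls below $10^{-5}$ or 100
  iterations. All M-steps are exact, so the log-likelihood sequence is
  nondecreasing; the suite asserts this on every refinement it runs.

Decoding (`decode_node()`) reports, by default, the hidden graph with the
highest marginal posterior at each time point — no edge-confidence
threshold is ever chosen — with Viterbi's joint MAP path as an option; the
two can disagree on ambiguous posteriors, and a constructed example in the
tests documents the divergence. A transition time is the first time point
governed by the new graph. `assemble()` unions the node-wise decoded
parent sets and merges breakpoints into global segments.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `score` | `bwbic` | search criterion; `bic`/`bde` run the identical search with the baseline metrics |
| `max_fanin` | 3 | parent-set cap; unbounded search is intractable at $N = 100$ |
| `H_max` | 6 | hidden graphs retained per node |
| `support_threshold` | 0.05 | occupancy fraction of $T$ below which a configuration is dropped |
| `smoothing` | 0.5 | pseudo-count for CPD initialization; scoring always uses unsmoothed estimates |
| `fixed_equal_transitions` | off | ablation: freeze $A$ row-uniform |
| `fixed_self_transition` | off | ablation: freeze $a_{hh} = s$, off-diagonal uniform |
| `bde_alpha` | 1 | equivalent sample size of the BDe prior |

Numerical conventions: emissions are floored at $10^{-12}$ inside the
recursions so EM-driven zero cells cannot zero a scaling constant
(per-step Rabiner scaling handles series beyond $10^4$ points);
$0\log 0 = 0$; $\log\hat N_h$ is floored at 0 so nearly unsupported graphs
keep a finite penalty; Viterbi and argmax ties break toward the lower
index; EM initializes $\pi$ uniform, $A$ with self-transition 0.9
(regimes persist a priori), and CPDs from the hard segmentation of the
combined configuration posteriors with pseudo-count 0.5. Score ties
between candidate moves favor the smaller parent set, so the default
search is fully deterministic — seeds matter only to the simulator.

## The synthetic benchmark

`make_benchmark_10node()` draws the small study design: 10 binary nodes,
a base network of 10 random edges (fan-in at most 3), 7 epochs separated by
6 single-edge changes, epoch lengths uniform in [20, 400] rescaled to 1019
observations in total. `make_benchmark_100node()` draws the large design:
100 nodes, 50 edges, 5 segments over 5000 observations, 1–3 edge changes
per boundary. Children follow a deterministic map of their parents with
probability `dependence_strength = 0.9` and take the opposite state
otherwise, so a strength of 0.5 carries exactly zero information; the
tests verify that calibration by direct estimation.

The default map is noisy-OR (a single parent is a noisy copy). Parity
(XOR) and random lookup tables are selectable, but parity is deliberately
*not* the default: the parity of two or more parents is marginally
independent of each individual parent, so no search built from single-edge
additions — this package's or any other's — could ever take the first step
toward such a node, and a benchmark built on it would measure the CPD
family rather than the structure-learning machinery.

The evaluation protocol scores edges per observation: at each time point
the predicted edge set is compared with the true one, precision (defined
as 1 when nothing is predicted) and recall (1 when no true edge exists)
are averaged over all time points, and F1 is the harmonic mean of the two
averages (per-time F1 averaging is available as an option). A mistimed
transition therefore costs exactly its overlap error rather than a whole
segment.

What passing these benchmarks does *not* show: the generator produces
binary states, node-specific single-edge changes, noise that is
conditionally independent across nodes and time, and no missing data.
Real expression series add measurement noise that survives binarization,
indirect and contemporaneous effects, and far shorter lengths; results on
such data depend materially on the discretization (per-gene mean or median
thresholding here — a deliberately parameter-free choice, since elaborate
discretizations are themselves a tuning risk).

## Problem sizes used by the shipped experiments

The packaged acceptance experiments re-run the ten-node design with 25
datasets per experimental arm (base seeds 1–25), which reproduces the
benchmark medians at desk scale in a few minutes for all eight arms; the
hundred-node design is exercised with 2 datasets as a scaled-down check.
Larger replications change only Monte-Carlo error, not the procedure.

## Known limitations

* Hidden graphs are restricted to subsets of one stationary candidate set
  per node, so a node whose regulators are disjoint across regimes is
  found only if the union respects `max_fanin`.
* Greedy search commits to locally optimal moves; no restarts are
  performed by default (the search is deterministic given the data).
* No uncertainty is attached to transition times or edges; the decoded
  network is a point estimate.
* Missing observations and replicate series are out of scope; inputs must
  be complete and single-trajectory.
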