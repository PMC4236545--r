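---
title: "From name-generator surveys to a township's complete network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From name-generator surveys to a township's complete network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(townnet)
```

## The problem

Population surveys of older adults in small communities can collect, for
every respondent (the *ego*), the people with whom they discuss important
matters (the *alters*): a spouse roster plus up to five discussion
partners, up to six members in total, each described by name, gender, age,
district of residence, relationship type, cohabitation, a 4-level
emotional-closeness code and an 8-level contact-frequency code, together
with a member-by-member "have they spoken to each other" matrix. When the
survey covers the *entire* older population of a township, the ego
networks can be fused into one *complete* (sociocentric) directed network,
which supports measures an ego network alone cannot: tie direction
(in-degree versus out-degree), positional centrality, brokerage between
administrative districts (*Ri*), and the component structure of the whole
community.

`townnet` implements that entire chain as a tested pipeline: a synthetic
township generator with planted ground truth, survey validation, the six
classic ego-network measures, rule-based entity resolution of duplicate
alter mentions, complete-network centralities, Gould–Fernandez brokerage,
a five-class weak-component typology, and grouped-means reporting tables
with one-way ANOVA.

Because raw data of this kind are personally identifying and not publicly
deposited, the package is exercised end-to-end on the synthetic generator;
every downstream stage is scored against the generator's known ground
truth.

## The measures

**Ego level.** For an ego network of size $m$ (spouse plus alters,
$0 \le m \le 6$): the composition proportions (female, kin, cohabiting
members over $m$); average closeness (mean of the 4-level codes); contact
volume $\sum_j \text{days}(c_j)$, where the 8 contact categories map to
approximate days of contact per year (365, 182, 52, 30, 12, 6, 2, 0.5 —
the four fixed anchors are categories 1, 2, 5 and 7; the remaining values
are monotone interpolations, configurable in the codebook); density
(acquainted member pairs over $\binom{m}{2}$); and bridging potential, the
indicator that some member is acquainted with no other member. Density and
bridging are undefined for $m < 2$ and are reported as missing — a
proportion of an empty pair set is indeterminate, and coercing it to 0
would bias group means. Density 1 logically forces bridging potential 0.

**Entity resolution.** Two mentions denote the same person when all four
criteria hold: at least two of three name tokens agree position-wise,
same gender, age difference strictly below 5 years, same district. Names
here are abstract 3-token strings standing in for 3-character names; the
position-wise comparison (surname position is meaningful) is a rule
option. Reports are first matched against the respondent roster (best
candidate by token matches, then age gap, then smallest id); the remainder
are clustered by the transitive closure (union–find) of pairwise matches,
because pairwise matching is not transitive and no merging procedure
beyond the rule itself is canonical — closure is deterministic and
order-independent. Canonical attributes come from the first contributing
report; conflicts are tallied in the resolution log.

**Node retention.** A merged person is excluded only when *both* (1) not
the spouse of any respondent *and* (2) resident outside the township. The
conjunction matters: an outside spouse is retained.

**Complete-network measures.** In/out-degree count directed ties.
Closeness and betweenness are computed on the undirected projection by
default ("all-closeness"): the surveyed network is nowhere near strongly
connected, and strict directed reachability would zero out most nodes.
Because even the undirected network is disconnected, plain closeness
($(N-1)/\sum_j d_{ij}$) is undefined; the default applies the
Wasserman–Faust reachable-set correction
$$ C(i) \;=\; \frac{|R_i|^2}{(N-1)\sum_{j \in R_i} d_{ij}}, $$
with $R_i$ the set of nodes reachable from $i$; isolates score 0.
Within-component and harmonic variants are selectable — no single
convention for disconnected graphs is privileged. Betweenness uses
fractional credit over equally short paths, normalized by
$(N-1)(N-2)/2$ unordered pairs (ordered pairs in directed mode).

**Brokerage.** For each node $i$, ordered two-paths $j \to i \to k$
($j \neq k$) are classified by the districts $g(j), g(i), g(k)$:
coordinator (all equal), gatekeeper ($g(j) \neq g(i) = g(k)$),
representative ($g(j) = g(i) \neq g(k)$), itinerant
($g(j) = g(k) \neq g(i)$), liaison (all distinct). The default
`"exclusive"` mode counts a two-path only when the endpoints are
disconnected otherwise (no direct tie $j \to k$ or $k \to j$), reading the
broker as connecting otherwise-unconnected people; classic
Gould–Fernandez counting (no exclusion) is first-class via
`mode = "classic"`, and both are reported side by side by the pipeline.
The five roles partition the qualifying two-paths, so the total equals
the two-path count — an invariant the tests enforce by exhaustive triad
enumeration.

**Components and typology.** Weak components (reachability ignoring
direction) are the default unit of community structure; strong components
are available but far too restrictive for discussion networks. Components
are ranked by size (ties broken by smallest member id for determinism)
and labelled: largest, second largest, size 3–7, dyads, isolates. A
non-top component of 8+ nodes — possible in principle, absent in the data
the typology was designed around — folds into the 3–7 class with a
warning rather than inventing a sixth class.

**Tables.** Grouped means are reported by age band (≤64, 65–74, ≥75),
gender, marital status (living with spouse versus
separated/divorced/widowed, with the rare never-married respondents
merged into the latter), 3-level education, and the 3-group recode of
5-level self-rated health ({1,2}, {3}, {4,5}). Significance comes from
one-way ANOVA implemented from the sum-of-squares decomposition (the
package owns this computation; the tests cross-check it against base R's
`oneway.test`). The "overall" footer is the unweighted mean over
non-missing respondents — equivalently, category means weighted by
category size; alternative weights can be supplied. The skewness
estimator is the adjusted Fisher–Pearson $G_1$ (the default of the major
statistical packages of the study's era); the plain moment ratio $g_1$
is a switch. Whether the spouse counts as "kin" in the composition
numerator is a codebook switch, on by default (the kin proportions this
produces are consistent with spouse-inclusive coding in comparable
surveys).

## The synthetic township generator

`generate_township()` emulates the survey's data-generating process with
known ground truth. Its defaults describe the study conditions the
package is designed around, taken from the published marginals of a real
rural township of 860 older adults and spouses, and they are fixed — not
tuned per analysis:

* `n_population = 860`, `p_response = 814/860` (the published response
  rate), `n_districts = 10` with equal weights;
* `p_married = 0.76` and `mean_alters = 2.31` (Poisson, truncated at 5),
  so the expected network size is near 3.07;
* `acquaintance_density_target = 0.98`: each member pair is acquainted
  with this probability, matching the observed near-total density;
* closeness codes drawn with mean ≈ 3.28, contact categories mixed to a
  per-member mean near 230 days/year, education 0.30/0.41/0.29;
* `p_external_alter = 0.30`: the share of mentions pointing outside the
  township, matching the observed exclusion flow (about a third of merged
  persons fail the residence criterion);
* identifier noise: one name token perturbed with probability 0.2, age
  misreported uniformly within ±3 years (must stay below 5 so planted
  duplicates remain matchable);
* self-rated health on the 5-point scale, linked to network size through
  a latent slope of 0.10 per member — calibrated so the mean network
  sizes of the three health groups reproduce the published 2.85 / 3.21 /
  3.42 pattern.

Two heterogeneity mechanisms give the generated network a realistic
component structure rather than one giant component. First, external
orientation is a *household* trait: each household draws a propensity
$p \sim \mathrm{Beta}(\nu \bar p, \nu(1-\bar p))$ (concentration
$\nu = 0.8$, shared by both spouses) that its members' alters live
outside the township. Second, who gets named is weighted by
$\mathrm{Exp}(1)$ popularity times $(1-p)$ — households oriented outward
are also less visible inside the village. Together these produce the
observed mass of dyadic components (externally-oriented couples naming
only each other) and an overdispersed in-degree. The concentration was
calibrated against the published component-class shares (dyads ≈ 9.5% of
nodes) and then frozen.

Identities are distinguishable by construction: the generator resamples
name tokens until no two distinct persons in the same district-and-gender
block within the match-relevant age window share two token positions
(buffer $5 + 2 \times$ age noise for roster members, 5 years for invented
outsiders). Without this, chance collisions would make the planted ground
truth unrecoverable *in principle* — no resolver could achieve the exact
zero-noise recovery the module guarantees.

If `segregated_district` is set, that district's members name alters only
among themselves, are never named by outsiders, and their health scores
are shifted down by `segregated_srh_penalty` (an integer decrement on the
5-point scale, floored at 1 — the realized mean shift is slightly smaller
than nominal when draws hit the floor). This plants a geographically
segregated block with worse self-rated health whose recovery — as the
second-largest weak component with the lowest class-mean health — the
acceptance tests verify across seeds.

**What the generator does not emulate.** Kinship structure beyond the
spouse (no family trees), naming reciprocity and transitivity (real
discussion ties cluster more), interviewer effects and item nonresponse,
longitudinal waves, and realistic onomastics (tokens are uniform draws,
not Korean names). Passing tests therefore demonstrate correctness of the
*computations* and recoverability under the *modelled* noise, not
robustness to every failure mode of real survey data. The generated
largest-component share (~0.85) also remains somewhat above the published
0.76, since the naturally segregated district of the real township is not
planted by default.

## Numerical and degenerate-input choices

* Undefined statistics propagate as `NA` and are never coerced to zero;
  grouped means are over valid respondents only.
* Age bins are closed on the left at 65 and 75; the match rule is strict
  (`gap < 5`), and ANOVA returns `NA` markers (not errors) for fewer than
  two groups or zero total variance, `F = Inf, p = 0` for perfect
  separation with zero within-group variance.
* Component ranking ties break on the smallest member id, making the
  typology deterministic under relabeling and reruns.
* The oracle comparisons in the test suite run at 1e-12 (centralities,
  against an independent BFS/path-counting implementation) and 1e-10
  (ANOVA against the closed form); the generator's stochastic checks use
  problem sizes of 400–860 persons and 10 seeds for recovery rates, and
  100 random graphs of 5–60 nodes (50 grouped digraphs for brokerage) for
  oracle equivalence.
* All randomness flows through a single seed; `generate_township()`
  restores the caller's RNG state, and identical configurations reproduce
  every pipeline output byte for byte.

## Limitations

Rule-based matching with a fixed threshold cannot express uncertainty; a
probabilistic record-linkage model is out of scope, as are community
detection, edge weights, eigenvector-style centralities, post-hoc pairwise
tests and any causal claims about the health associations the tables
describe. The closeness convention on disconnected graphs is a genuine
modelling choice — three variants are provided, and none is labelled
"correct".
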