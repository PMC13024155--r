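---
title: "Modeling brain-state dynamics with explicit-duration hidden semi-Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling brain-state dynamics with explicit-duration hidden semi-Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statedyn)
```

## The model

`statedyn` treats a resting or task fMRI scan as a sequence of visits to a
small number of recurring brain network states. The observed data for one
scan are $Y_1, \dots, Y_T$, where each $Y_t \in \mathbb{R}^R$ holds the BOLD
signal of $R$ regions of interest at timepoint $t$ (sampled every TR
seconds). An unobserved state label $S_t \in \{1, \dots, K\}$ evolves as a
*semi-Markov* chain, and conditional on the state the data are multivariate
normal:

$$Y_t \mid S_t = k \;\sim\; \mathcal{N}(\mu_k, \Sigma_k).$$

Each state is therefore a mean activity pattern $\mu_k$ together with a
covariance $\Sigma_k$; the correlation matrix derived from $\Sigma_k$ is the
state's weighted functional-connectivity network.

Unlike an ordinary HMM, whose implicit geometric dwell distribution forces
the most probable sojourn to be a single timepoint, the hidden *semi*-Markov
model gives every state an explicit dwell distribution $p_k(d)$ on
$d \in \{1, 2, \dots\}$ and forbids self-transitions: the chain enters a
state, stays for a random dwell $d \sim p_k$, then jumps to a different
state according to a transition matrix $A$ with $A_{kk} = 0$. The model
parameters are $(\mu_k, \Sigma_k, A, p_k, \pi)$, with $\pi$ the initial
state distribution.

Two conventions fix the boundary behavior. The first dwell starts at the
first analyzed timepoint (the scan is trimmed upstream precisely so that the
signal is stationary there), and the final dwell is *right-censored*: its
contribution is the survival probability $P(d \ge \text{observed length})$,
because the state was still ongoing when the scan ended. With this
convention the probabilities of all length-$T$ label paths sum to one and
the likelihood agrees exactly with the package's generative sampler, which
truncates the final sampled dwell at $T$. For the same reason the first and
last observed dwells of a decoded sequence are excluded from dwell-time
summaries — their true lengths are unknown.

Dwell distributions are truncated at `max_dwell` timepoints (default 50,
i.e. 100 s at TR = 2 s) and renormalized; this bounds the
$O(T \cdot K \cdot \text{max\_dwell})$ recursions and is far beyond any
plausible sojourn in this setting. Two dwell families are available: the
default shifted Poisson, $d - 1 \sim \text{Poisson}(\lambda_k)$, which is
the standard explicit-duration choice and guarantees $d \ge 1$ with mean
$\lambda_k + 1$; and a free nonparametric pmf on `1..max_dwell`.

## Estimation and decoding

A *single* set of states is estimated from all scans pooled: scans enter the
E-step as independent sequences (they are never concatenated, so no spurious
transition bridges two scans). The E-step runs an explicit-duration
forward–backward pass per scan, entirely in log space, implemented in C++.
The M-step has closed forms for $\mu_k$, $\Sigma_k$ (with a ridge of
$10^{-6}$ times the mean diagonal to guard states with small
responsibility), $A$, and $\pi$. The dwell-rate update maximizes the
expected dwell log-likelihood — including the right-censored survival terms,
so EM monotonicity holds exactly — by a one-dimensional search per state.
Iteration stops when the relative log-likelihood change falls below `tol`
(default $10^{-6}$) or at `max_iter`. Because EM is a local optimizer, each
fit is restarted `n_starts` times (default 5) from k-means initializations
with seeds derived from the master seed, keeping the best final
log-likelihood. A state whose total responsibility collapses below
$10^{-8}$ is re-seeded at the worst-fit timepoints and the event is logged.

Per-scan state sequences come from a duration-aware Viterbi pass: the
jointly most probable duration-respecting path, with ties broken toward the
lower state index and then the shorter dwell so decoding is deterministic.
The implementation is validated against exhaustive enumeration of all label
paths on small problems, and against a standard HMM when all dwell mass sits
at one timepoint.

## Choosing the number of states

`select_k()` fits each candidate $K$ (default range 3–7) with the same
multi-start protocol and seed, computes the minimum pairwise Euclidean
distance between fitted state means, and keeps the candidate with the
*largest* minimum distance — the most clearly differentiated states. Ties
break toward the smaller $K$. Distances are computed on raw means (a
z-scored variant is available via `scale = TRUE`).

This maximin heuristic has a known failure mode that users should
understand: when the true states are very unevenly spaced, a smaller-$K$ fit
that merges the two *closest* states leaves fitted means that are farther
apart than the true minimum pairwise gap, so the rule prefers the smaller
$K$. It reliably recovers the generating $K$ when states are comparably
distinct, which is the regime where "number of distinct states" is
well-defined; the package's selection validation therefore places generating
means on a regular simplex (all pairwise distances equal) via
`generate_params(..., mean_geometry = "simplex")`. For irregular geometries
an information-criterion approach would be preferable, but is out of scope
for the analysis path reproduced here.

## Dynamics summaries and group inference

From each decoded sequence the package derives, per state: occupancy (the
percentage of timepoints spent there), transition frequency (the number of
*entries*, i.e. change-points whose destination is the state — the initial
state is not counted as an entry, though an inclusive flag exists), and the
list of dwell lengths with the first and last runs excluded.

Occupancy and transition frequency give one value per scan, averaged into
one value per participant. Group differences in these participant-level
means are tested by a label-permutation test: group labels are permuted *at
the participant level* (both scans of a participant always travel together),
the absolute difference of group means is the two-sided statistic, and the
p-value uses the add-one estimator $(1 + \#\{\text{null} \ge
\text{obs}\})/(n_{\text{perm}} + 1)$ with 500 permutations by default. With
500 permutations the smallest attainable p-value is $1/501 \approx 0.002$.

Dwell times resist a participant-level summary (participants contribute
very different numbers of dwells), so dwell distributions are pooled within
group, smoothed into a discrete density on `1..max_dwell` (Gaussian kernel,
Silverman's-rule bandwidth on the integer data, floored at $10^{-10}$ and
renormalized so Kullback–Leibler divergences stay finite), and compared by
the symmetrized KL divergence $\tfrac12(\mathrm{KL}(p\|q) +
\mathrm{KL}(q\|p))$. Symmetrization removes the arbitrary choice of
direction; directed variants are available by flag. The permutation null
again reshuffles participant labels; a permutation that leaves a group with
no dwells for the state is redrawn and counted.

Each dynamic property (occupancy, transitions, dwell-KL) forms its own
Benjamini–Hochberg family across the $K$ states at level 0.05.

What FDR control does *not* promise is exact localization: occupancy
percentages sum to 100 per scan, so a genuine increase in one state's
occupancy is necessarily spread as a small decrease over the other $K - 1$
states, and with $15$ null state-by-property tests the step-up procedure is
expected to flag a spillover or null state in a nontrivial fraction of
datasets. The package's end-to-end validation quantifies exactly this: the
designed contrast is detected in the designated state in essentially every
simulated cohort, while "perfect" localization (no other state flagged
anywhere) occurs less often, at the rate the FDR arithmetic predicts. For
the same accounting reason, a dwell-only group manipulation shifts entry
counts of *all* states nearly uniformly (entries scale with the number of
segments), so the designed-effect generator contrasts both the designated
state's dwell rate and its transition-column weight, mirroring how
occupancy, entries, and dwells co-vary in real group differences.

## State characterization

Each state's covariance is converted to a correlation matrix (the weighted
network), negative edges and the diagonal are zeroed (the *positive
network* — weights are kept, no density threshold), and communities are
found by Newman's spectral method: recursive leading-eigenvector bisection
of the resolution-scaled modularity matrix $B = A_{\text{adj}} - \gamma k
k^\top / 2m$ with deterministic Kernighan–Lin-style single-vertex
fine-tuning, stopping when no split increases
$Q = \tfrac{1}{2m}\sum_{ij}(A_{ij} - \gamma k_i k_j / 2m)\,
\delta(c_i, c_j)$. The default resolution is $\gamma = 1$. Spectral
bisection is a heuristic: on small graphs the package's tests verify
$Q_{\text{spectral}} \le Q_{\text{exhaustive}}$ over all set partitions and
exact recovery on canonical two-community graphs.

Activity maps z-score each region's $K$ state means *across states* (mean
0, SD 1 per region, with an SD floor of $10^{-12}$ for constant regions), so
a map entry reads "how active is this region in this state relative to the
other states".

## Relating dynamics to an outcome score

For each state and each measure (occupancy, transition frequency) the
package fits the mixed model

$$\text{score} \sim \text{measure} + \text{group} +
\text{measure}\times\text{group} + \text{drinks} + (1 \mid \text{participant}),$$

by REML through `lme4`, with the mindfulness group as the reference level
and the measure entering untransformed (occupancy in percent, entries as
counts). Wald $t$ statistics use a residual degrees-of-freedom
approximation ($n_{\text{obs}} - n_{\text{fixed}}$); Satterthwaite or
Kenward–Roger corrections are deliberately out of scope. Interaction
p-values are FDR-corrected across the model family, and any flagged model
is refit within each group (`measure + drinks + (1 | participant)`). When
every participant contributes a single scan the random intercept is not
identifiable and the fit collapses, exactly, to ordinary least squares; a
singular random-intercept fit is reported with a warning and proceeds as
the boundary case.

## The synthetic cohort generator

Because the motivating study's scans are not public, the package ships a
generator that emulates the design: 36 regions spanning two subnetworks,
two groups of 15 and 17 participants, two scans each, 281 usable timepoints
at TR = 2 s (a 297-volume scan after removing 10 leading volumes and 3
timepoints at each end). Emission parameters are shared between groups —
states are population-level, as in pooled estimation — and group effects
enter only through dwell rates and transition rows. The default contrast
mirrors the study's findings qualitatively: the mindfulness group dwells
longer in and transitions more often into state 2, the control group favors
states 1 and 3, and states 4–6 do not differ. The outcome score is
$\text{intercept} + \sum_k \beta_k \,\text{occupancy}_k + b_{\text{participant}}
+ \varepsilon$ with $\beta_2 = -0.06$ per occupancy percentage point by
default, clipped to the instrument's 1–10 scale (clipping is logged). One
master seed drives a hierarchical stream (parameters, paths, observations,
scores), so each component is individually reproducible.

The generator makes no attempt to emulate hemodynamic convolution,
autocorrelated within-state noise, scanner drift, or motion artifacts.
Passing tests on these cohorts therefore validate the *estimation and
inference machinery* — not robustness to the preprocessing realities of
fMRI, which are upstream of this pipeline's inputs.

## Numerical choices and problem sizes

All recursions run in log space; no scaling-factor variant is used, which
keeps the implementation directly comparable to brute-force enumeration.
The covariance ridge, density floor, dwell truncation, activity-map SD
floor, and Viterbi tie-breaks are described above with their defaults. The
validation suite uses deliberately scaled problems chosen to exercise each
property at comfortable statistical resolution: exhaustive oracles at
$K = 2$, $T \le 6$; parameter recovery at $K = 3$, $R = 6$, 20 scans of 200
timepoints; selection over candidates 2–5; end-to-end localization on
full-size cohorts (64 scans of 281 timepoints) with $R = 12$ regions and 20
replicates; and 100–1000 replicates for coverage and type-I calibration.

## Known limitations

* The maximin state-count rule is only reliable for comparably spaced
  states (see above).
* The shifted-Poisson dwell M-step assumes the truncation bound is far in
  the tail; with `max_dwell` close to typical dwells the rate update would
  be biased.
* Permutation p-values are bounded below by $1/(n_{\text{perm}}+1)$;
  reported values of 0.002 at 500 permutations are floor values.
* FDR controls the expected false-discovery proportion, not the
  probability of any false flag; see the localization discussion above.
* The mixed models use a residual-df Wald approximation, which is mildly
  anti-conservative in small samples compared to Satterthwaite.

## A small worked example

```{r example, eval = FALSE}
co <- generate_cohort(n_group1 = 4, n_group2 = 4, T = 120,
                      truth = default_ground_truth(R = 12, K = 3, seed = 1),
                      seed = 1)
cfg <- run_config(n_permutations = 199, n_starts = 2, max_iter = 40,
                  max_dwell = 30, seed = 1)
res <- run_pipeline(co$scans, co$manifest, config = cfg, K = 3)
print(res)
```
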