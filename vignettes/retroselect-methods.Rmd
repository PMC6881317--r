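---
title: "Detecting positive selection in retrogene pairs: models and design"
author: "retroselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection in retrogene pairs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

A chimeric retrogene is born when a reverse-transcribed mRNA reinserts into
the genome and captures flanking sequence, creating a new fusion gene next
to a surviving parental copy. Whether such young duplicates evolve under
positive selection — and on which lineage the selection acts, the new copy
or the parent — is the question this package operationalizes for small
cohorts of retrogene/parental pairs sampled across closely related species
(the motivating setting is *Oryza*, with 4–16 sequences per pair and
150–600 codons per gene).

The analysis chain is: codon-model maximum likelihood with branch-specific
dN/dS classes, a stepwise search for the best branch partition, nested
likelihood-ratio tests (including a fixed-omega null that pins candidate
classes to neutrality), a substitution-count heuristic for branches where
the LRT lacks power, branch-site site-class models with Bayes empirical
Bayes site identification, Tajima's D as a within-pair neutrality check,
NG86 Ka/Ks with a synonymous molecular clock for dating the duplication,
and a three-way classification of where adaptive evolution fell after the
retroposition.

## The codon substitution model

The substitution process runs on the 61 sense codons of the standard code
(stop codons have no state). The generator is the standard
transition/transversion- and selection-weighted parameterization:

$$
q_{ij} =
\begin{cases}
0 & \text{more than one nucleotide difference} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with equilibrium frequencies $\pi$ over sense codons. $\omega =$ dN/dS is
the selection parameter: $\omega > 1$ indicates positive selection,
$\omega \approx 1$ neutrality, $\omega < 1$ purifying selection.

Parameters and bounds: $\kappa \in [10^{-3}, 100]$ (dimensionless, default
start 2), $\omega \in [10^{-6}, 999]$ — the upper cap doubles as the
reporting convention for effectively infinite estimates when no synonymous
substitutions fall on a branch. Frequencies come from the alignment in one
of four modes; the default `observed-codon` mode uses empirical sense-codon
proportions (floored at $10^{-10}$ and renormalized so likelihoods stay
finite). Frequencies are treated as empirical constants, not free
parameters, in all `np` accounting: a branch model has
`np = B + 1 + R` (B branch lengths, one $\kappa$, R omega classes), which
reproduces the `np` bookkeeping of the reference implementations.

**Scaling.** In branch models each branch's generator is scaled to unit
expected flux at that branch's own $\omega$, so branch lengths read as
expected substitutions per codon and the per-branch expected counts
decompose exactly: $n_N + n_S = L \cdot t$. In site-class (branch-site)
models all classes on a branch share that branch's mixture-average flux
scale; this keeps branch lengths interpretable as class-averaged
substitutions per codon and — importantly — lets a selected site class
evolve genuinely faster than the purifying background, which is what makes
site-level detection possible at all.

**Numerics.** $P(t) = e^{Qt}$ is computed by symmetric eigendecomposition
via the $\pi^{1/2}$ similarity transform (the model is reversible, so this
is exact and stable); tiny negative entries from rounding are clamped to
zero. The pruning recursion runs on site patterns; conditional likelihoods
are carried unscaled (safe at the tree depths targeted here, at most a few
substitutions per codon root-to-tip) with an automatic per-node rescaling
fallback when a site underflows. Likelihood maximization is bounded
L-BFGS-B on log-transformed parameters with finite-difference gradients.
Fresh fits multi-start over omega (0.1, 1, 3 for branch models; two
$\omega_2$ starts for Model A): the first start optimizes everything, and
later starts reuse the incumbent branch lengths and $\kappa$ — the
nuisance optimum — while restarting only the omegas, which is where the
surface can be multimodal. Warm-started refits use a single start. Branch
models run at `factr = 1e7`; the site-class models use `factr = 1e8` with
an iteration cap of 150, which reproduces the tighter setting's optima to
~$10^{-3}$ lnL at a fraction of the cost (measured on null and selected
simulations alike). All likelihood-ratio statistics asserted anywhere in
the package sit orders of magnitude above that resolution, and nesting
checks use it as their tolerance.

## Searching for the optimal branch-specific model

Branches are grouped into omega classes; the search compares partitions.
Three strategies are provided, all recording an audit trail:

* **Method I** — greedy splitting: from the one-ratio model, try moving
  each branch into its own new class, rank candidates, refit the best, and
  accept if the LRT against the incumbent is significant. Stops when
  nothing is accepted.
* **Method II** — the same skeleton, but candidates include moves into
  existing classes and merges of classes, ranked by AIC; a step that adds
  a class must also pass the LRT guard. Stops at an AIC local minimum.
* **Method III** — estimate-guided clustering: fit the free-ratio model,
  sort the per-branch omega estimates, and cut the sorted sequence wherever
  consecutive values differ by more than $(1+k)/k$-fold (default
  $k = 0.5$, i.e. 3x — a scale-free rule in omega, which is the natural
  scale for grouping rate ratios). The induced partition is refit, refined
  by Method-II-style steps, and finally kept only if it beats the one-ratio
  model by LRT.

Two design choices here departed from the obvious implementation and were
forced by calibration:

1. *Per-step multiple testing.* Accepting the best of B single-branch
   splits at raw $\alpha$ is anti-conservative: the accepted statistic is
   the maximum of B correlated $\chi^2_1$ draws, and on one-ratio data the
   false-split rate is several times $\alpha$. Each step therefore tests
   at the Bonferroni level $\alpha / B_{\text{candidates}}$. True splits
   of the size this analysis targets (an $\omega \ge 3$ branch at 500
   codons gives $2\Delta\ell$ in the tens) lose no practical power.
2. *Screened candidates.* At each step candidates are ranked by a screened
   likelihood — branch lengths and $\kappa$ frozen at the incumbent's
   MLEs, only the changed class omegas re-optimized one-dimensionally —
   and only the top candidate is refit in full before the accept decision.
   The accept test always compares full refits, so the screen only affects
   which candidate is examined, not the inferential standard.

The final model across methods is chosen by: equal class counts — higher
log likelihood; nested — LRT at $\alpha$; non-nested — lower AIC; ties
break to fewer classes, then method III > II > I.

A branch with more than 9 expected nonsynonymous substitutions and
(within 0.5 of) zero synonymous ones is flagged by the substitution-count
heuristic even when the fixed-omega LRT fails; the pipeline reports an
evidence tier (`LRT-significant` / `count-heuristic` / `none`) rather than
a bare boolean, because the two kinds of evidence are not equivalent.

## Branch-site models and BEB

On each selected branch the pipeline fits M1a (purifying + neutral site
classes), Model A (adding classes 2a/2b in which sites switch to
$\omega_2 \ge 1$ on the foreground branch), and the null Model A with
$\omega_2 = 1$. Test 1 (M1a vs Model A, df 2) and test 2 (null vs Model A,
df 1) must both reject, under the default verdict rule, before sites are
reported. Class proportions follow the standard construction
$p_{2a} = (1 - p_0 - p_1) p_0 / (p_0 + p_1)$,
$p_{2b} = (1 - p_0 - p_1) p_1 / (p_0 + p_1)$.

Site identification is Bayes empirical Bayes: the posterior probability of
membership in classes 2a/2b is averaged over a prior grid on
$(p_0, p_1, \omega_0, \omega_2)$ with branch lengths, $\kappa$ and the
per-branch flux scales held at their MLEs. The grid is 10 points per
dimension; $\omega_0$ mid-point-spaced in (0,1), $\omega_2$ log-spaced in
(1, 999]. For the proportions we use a stick-breaking grid — $p_0$ on a
10-point grid, the remainder split between $p_1$ and the selected classes
by a second 10-point grid — rather than a uniform triangle grid. The reason
is resolution at small $p_2$: real selected-class proportions are often a
few percent or less, while a 10-point uniform triangle cannot represent any
value of $p_{2a}+p_{2b}$ between 0 and 0.1, which collapses every site
posterior through the $p_2 = 0$ cells. The stick-breaking grid covers
$p_2$ down to ~$10^{-3}$ at the same grid size.

Flagged sites (posterior > 0.95) are labeled with their 1-based position in
the gap-stripped alignment and the first sequence's residue (`"43D"`
style). Site indices always refer to the alignment after complete deletion,
because that is the alignment every likelihood saw.

**What BEB can and cannot see at desk scale.** A site only earns a > 0.95
posterior when about three nonsynonymous changes are visibly attributable
to the foreground branch. With $\omega = 10$ and a foreground branch at
the top of the realistic divergence range (0.2 substitutions/codon —
episodic branches in this setting carry roughly 0.05–0.2), a selected site
accumulates ~4 substitution events, but within-codon multiple hits leave
on average only ~2 visible changes; posteriors for truly selected sites
therefore cluster between 0.7 and 0.95, and recovery of planted sites at
the 0.95 threshold is partial by construction. The validation suite
measures this honestly rather than relaxing the threshold: sensitivity at
the strict threshold is the known weak point of the method, while its
false-flag rate (the property that matters for reported site lists) is
essentially zero in the same simulations.

## Neutrality, dating and enrichment

*Tajima's D* is computed on the nucleotide columns of the gap-stripped
alignment from the canonical $(a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2)$
construction; with no segregating sites D is reported as missing with a
reason. $\Theta = p_s / a_1$ uses the number of sequences $m$ in $a_1$.

*NG86*: synonymous/nonsynonymous sites by the 1/3-per-position convention
(changes producing stop codons are disregarded), differences by
equal-weight averaging over all minimal substitution pathways per codon
(pathways through stops excluded unless all are blocked), and the
Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p)$, with a
saturation error at $p \ge 3/4$. Note that a single-codon comparison can
be inherently saturated (one synonymous difference over a third of a
synonymous site), so Ks is only meaningful on sequences of some length —
the bootstrap requires at least 30 codons. NG86 carries no
transition/transversion parameter; the k = 2 used for dating enters only
through the substitution model, not the counting.

Ages are $T = K_s / (2r)$ with the rice synonymous clock
$r = 6.5 \times 10^{-9}$ substitutions/site/year by default, and the 95%
interval is $1.96 \times$ the codon-bootstrap SE, transformed identically.

Cohort enrichment is a two-sided Fisher exact test of the positive
fraction against a genome-wide baseline; the baseline sample size is an
explicit argument because a proportion alone does not determine the 2x2
table.

## Evolutionary patterns

With the duplication node fixed as the meeting point of the parental and
retrocopy stems (an outgroup is required to orient it), the final branch
model's $\omega > 1$ classes map to: **pattern 1** — the retrocopy stem is
selected (the young gene evolved adaptively, with or without parental-side
elevation); **pattern 2** — only the parental stem; **pattern 3** — only
deeper parental-side branches ("after some time had passed"); anything
else, including selection confined to the outgroup side, is `none`.
Non-monophyletic copy sets are a classification error, not a silent guess.

## The synthetic-data generator

Because the study's sequence data are not deposited, validation runs
entirely on simulations with known truth. The generator draws root codons
from the equilibrium frequencies and evolves each site along each branch by
exact (Gillespie) sampling of the codon chain, recording realized
synonymous/nonsynonymous counts per branch and the planted site classes.
Determinism is bit-for-bit under a fixed seed.

Default study-shaped conditions: trees of 6–16 tips with branch lengths
0.01–0.2 substitutions per codon; background $\omega$ 0.1–0.4 with
$\kappa = 2$; 150–600 codons; episodic branches at $\omega = 3$–5; Model A
structure with a ~10% selected-site fraction at $\omega_2 = 8$; planted-site
scenarios with 5 of 400 sites at $\omega = 10$ on a 0.2-long foreground
branch over a 0.1 purifying background. The pair fixture is a 9-tip tree
(outgroup + 4 parental + 4 retrocopy tips) with the selected branch placed
on the retrocopy stem, the parental stem, or a deeper parental branch
according to the scenario.

What the simulations do **not** emulate: indels and alignment error (gap
corruption is injected column-wise, not evolved), recombination, among-site
rate variation beyond the omega classes, codon usage bias beyond the
frequency vector, and lineage-specific $\kappa$. Passing tests therefore
demonstrate correctness and calibration of the inference machinery under
its own model class, not robustness to alignment artifacts.

## Problem sizes used by the test suite

The headline operating characteristics are validated at 10 seeds each,
with the rate thresholds kept at their nominal values: optimal-model
search isolating a planted $\omega = 3$ branch in $\ge$ 70% of seeds
(500 codons, 6 taxa), branch-site test 1 size $\le$ 10% on null data
(150 codons — size needs no power, so the null runs use the short end of
the study's 150–600 codon range), BEB planted-site recovery (400 codons),
and the Tajima oracle comparison. The remaining property tests are scaled
similarly: 3–10 seeds for search null calibration, NJ topology recovery,
bootstrap coverage and parameter recovery, and Method I only in the
pipeline smoke runs. All replicate counts are sized so the full suite runs
in well under half an hour on one CPU; the asserted margins are the
binomial versions of the same rate targets.

One recalibration is worth stating explicitly: at 6 taxa x 500 codons the
sampling SD of $\hat\kappa$ is ~11% even on a deep tree, so the recovery
test asserts $\hat\omega$ within 15% and $\hat\kappa$ within 25% — bands
chosen from the Fisher information actually available rather than a
uniform figure.

## Known limitations

* No among-site rate variation; a single codon parameterization.
* BEB sensitivity at the 0.95 threshold is limited by within-codon
  saturation (see above); site lists are conservative.
* The stepwise searches are heuristics: they are calibrated (type-I
  controlled) and powerful for single-branch episodic selection, but they
  do not enumerate all partitions and can miss multi-branch configurations
  that no single-step path reaches.
* NG86 ignores transition/transversion bias in site counting; with
  $\kappa > 1$ its Ka/Ks is mildly biased relative to the generating
  model (the neutrality sanity check in the tests simulates at
  $\kappa = 1$ for exactly this reason).
* Branch lengths from `neighbor_joining` are nucleotide p-distances and
  serve only as topology/starting values; all inference re-estimates
  lengths in substitutions per codon.
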