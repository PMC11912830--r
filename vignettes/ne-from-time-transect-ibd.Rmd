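---
title: "Inferring recent Ne trajectories from time-transect IBD sharing"
author: "ibdtransect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring recent Ne trajectories from time-transect IBD sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdtransect)
```

## The model

Identity-by-descent (IBD) segments are long haplotype stretches that two
individuals co-inherit from a recent common ancestor. Because recombination
breaks long segments quickly, the length distribution of segments above a few
centimorgans is informative almost exclusively about the last ~50–100
generations — which makes IBD sharing the signal of choice for *recent*
effective population size (Ne), and makes it robust to the deep-history
confounding that affects allele-frequency and LD-based methods.

Ancient-DNA datasets are time transects: sample sets $S_1,\dots,S_n$ collected
at generations $t_1 < \dots < t_n$ before the most recent set. `ibdtransect`
models IBD sharing both within each set and across every pair of sets, on a
single discrete generation clock with 0 at the most recent set.

For a haplotype pair sampled at $(t_i, t_j)$ that coalesces at global
generation $g \ge \max(t_i, t_j)$, the total branch length available for
recombination is $t^* = (g - t_i) + (g - t_j)$ (equivalently $2t - \Delta t$
with $t$ measured from the younger sample and $\Delta t = |t_i - t_j|$). Under
a Poisson model of recombination along a chromosome of genetic length $L$
Morgans, the expected density of segments of length $l$ is

$$f_K(l, t^*) = 2 t^* e^{-t^* l} + (L - l)\, (t^*)^2 e^{-t^* l},$$

the two terms covering chromosome-end and interior segments. Integrating the
density over $(0, L]$ yields $1 + t^* L$ segments and total length $L$ — both
conservation laws are tested to $10^{-6}$ by quadrature.

The probability of coalescing exactly at $g$ under a trajectory
$\mathbf{N_e}$ is the discrete survival product

$$\phi(g) = \frac{1}{2 N_e[g]} \prod_{i=\max(t_i,t_j)}^{g-1}
  \Bigl(1 - \frac{1}{2 N_e[i]}\Bigr),$$

and the expected genome-wide density for the pair is
$f_N(l) = \sum_\mathrm{chrom} \sum_g f_K(l, t^*(g))\, \phi(g)$, summed over a
horizon of $G$ generations (default $G = 150$; under the fitted demographies
almost all $\ge 8$ cM segments coalesce far more recently, and the deeper tail
is regularization-dominated).

Two bookkeeping choices deserve a note. First, coalescence *at*
$g = \max(t_i, t_j)$ — the younger lineage running into the older sample's own
haplotype — is included with probability $1/(2N_e[g])$, and the survival
product for later generations starts at $\max(t_i,t_j)$; this is the unique
convention under which $\phi$ is a proper probability mass (partial sums
converge to 1) and under which the discrete-generation simulator below agrees
with the formula. Second, the trajectory has length $T_{\max} = G + \max_i t_i$
with indices $0 \dots T_{\max}-1$, so each pair's sum runs over exactly $G$
generations starting at $\max(t_i, t_j)$.

For a constant size the continuous-time limit has the closed form implemented
in `constant_ne_density()`,

$$f_N(l) = \frac{e^{-l\Delta t}}{A^3}\bigl(8 N_e B + 2\Delta t A B +
  (L - l)\,\Delta t^2 A^2\bigr), \quad A = 1 + 4N_e l,\; B = 1 + 4N_e L,$$

obtained by integrating $f_K$ against an exponential coalescent density from
$\Delta t$ to $\infty$. (The sign of the third term follows from the defining
integral; the package's test suite verifies the expression against adaptive
quadrature to $10^{-8}$.) The discrete generation sum exceeds this continuous
integral by the Euler–Maclaurin boundary term $f_K(l, \Delta t)/(4N_e)$ —
about 2% at $\Delta t = 10$ — which vanishes for contemporaneous pairs; the
tests pin this relationship explicitly. The closed form is used where a fast
constant-size approximation suffices: initializing the optimizer via
`fit_constant_ne()` and defining the default false-positive density.

## Likelihood

Observed segments are binned into left-closed, right-open length bins
(defaults: 8–20 cM in 0.25 cM steps; below 8 cM ancient-DNA IBD calls are
unreliable, above 20 cM counts are dominated by close kin, and both
thresholds are configurable). Counts are pooled genome-wide per sample-set
pair and bin, and each bin count is modeled as Poisson with mean
$n_\mathrm{hap} f_N(\text{midpoint}) \Delta l$. The `nhap` haplotype-pair
count is $4 n_A n_B$ across sets and $2n(n-1)$ within a set — empirical IBD
callers only report inter-individual segments, so within-individual pairs are
excluded by default (`within_individual = TRUE` restores the literal
$\binom{2n}{2}$). The composite log-likelihood sums the $n + n(n-1)/2$
set-pair terms; bins and pairs are treated as independent, a composite
approximation whose adequacy is checked empirically by the parameter-recovery
experiments rather than assumed.

## Regularized fitting

The objective minimized over $x = \log N_e$ is

$$-\ell(\mathbf{N_e}) + \alpha \sum_t (x_{t-1} - 2x_t + x_{t+1})^2
  + \beta \sum_t w_t (x_t - x_{t-1})^2,
  \qquad w_t = e^{-9 (t - T_{\max})^2 / 2 T_{\max}^2}.$$

The curvature term discourages wiggly trajectories; the decayed
first-difference term is negligible near the present ($w_0 = e^{-4.5}$) and
strong near $T_{\max}$, anchoring the estimate where the IBD signal has faded.
$\beta$ defaults to 250; $\alpha$ is chosen by leave-chromosomes-out
cross-validation: candidate $\alpha \in 10^{-2} \dots 10^4$ (log-spaced),
folds of chromosomes held out in turn, and the *largest* $\alpha$ whose
held-out composite log-likelihood — summed over folds, i.e. the log-likelihood
of the whole genome with each chromosome held out exactly once — is within 2
units of the best grid point is selected. Regularization is thus pushed as
far as the data tolerate without a significant drop in goodness of fit.
Summing rather than averaging over folds keeps the score (and therefore the
meaning of the 2-unit threshold, which is on the scale of a likelihood-ratio
comparison) invariant to the number of folds; a per-fold mean would make the
threshold more permissive the more folds are used, to the point of always
selecting maximal smoothing. The exact selection statistic is this package's
design choice; alternatives (e.g. one-standard-error rules) would be equally
defensible.

Optimization uses box-bounded L-BFGS-B (`stats::optim`) on $\log N_e$ with
$N_e \in [10, 10^8]$, initialized at the constant-Ne MLE (itself fit from
start value 1000) plus i.i.d. Gaussian noise with standard deviation
$\hat{N}_e^\mathrm{const}/20$ — read as a standard deviation, the package's
resolution of an ambiguous parameterization — clipped at the lower bound. The
gradient is analytic: the Poisson term's chain rule through $\phi$ reduces to
a reversed cumulative sum, and tests require agreement with central finite
differences to $10^{-4}$ relative (observed: ~$10^{-9}$).

Confidence envelopes come from resampling chromosomes with replacement (200
replicates by default), rebuilding counts and the chromosome multiset —
a chromosome drawn twice contributes its counts and its expected rates twice —
and refitting with the *same* $\alpha$; per-generation 2.5%/97.5% percentiles
form the envelope. Re-selecting $\alpha$ per replicate would mix
hyperparameter instability into the sampling noise, which is why the
full-data $\alpha$ is reused (at the cost of understating, slightly, the
uncertainty attributable to the selection step).

## Detection errors

Empirical IBD calls suffer false positives, incomplete recall, and length
noise. The observed-scale density is modeled as

$$\hat\lambda(y) = \mathrm{FP}(y) + \int_{y-a}^{y+a}
  \lambda(z)\,\mathrm{Recall}(z)\, R(y \mid z)\, dz,$$

evaluated by summing 0.25 cM bins with a Gaussian kernel $R$ (sd 1.5 cM by
default), truncated at $a = 5$ cM and deliberately *not* renormalized — the
truncation discards ≤ 0.3% of the kernel mass at $3.33\sigma$, and keeping
the literal truncated integral preserves linearity in $\lambda$. Because the
theoretical density below the 8 cM analysis window feeds the convolution, the
rate machinery evaluates $f_N$ on a lattice extended 5 cM beyond the grid on
both sides. The default simulation model uses
$\mathrm{Recall}(l) = 1 - 1/(1 + 0.025\,l\,e^{0.25 l})$ and a false-positive
density equal to the genome-wide sharing rate of a constant population of
25,000 — roughly 1:1 noise-to-signal in the bottleneck benchmark. Empirical
error models are consumed as three-column tab-separated tables
(`bin_midpoint_cm`, `fp_density_per_pair_per_cm`, `recall`) plus a scalar
length-noise sd; estimating them from sequence data is out of scope.
`inject_errors()` runs the same model forward to corrupt ground-truth
segments (Poisson false positives at lattice midpoints, recall thinning,
length noise, 8 cM cutoff).

## Simulators, and what they do (not) show

Two generators with different purposes:

* `sample_ibd_from_model()` draws Poisson bin counts from the model's own
  expected rates — the exact inverse of the observation model. It is the
  right tool for parameter-recovery experiments (does the optimizer find the
  truth when the model is true?) and deliberately cannot detect model
  misspecification.
* `simulate_pair_ibd()` is an independent discrete-generation
  coalescent-with-recombination engine (C++): ancestral material of two
  haplotypes sampled $\Delta t$ apart is tracked as intervals; each meiosis
  scatters Poisson($\mathrm{span}$) breakpoints and splits material between
  the two haplotypes of a uniformly drawn diploid parent; lineages landing on
  the same haplotype merge, and overlapping A/B material records an IBD
  segment. It never uses the $f_K \cdot \phi$ factorization, so agreement of
  its binned means with `expected_ibd_density()` (checked at $N_e = 2000$,
  $L = 1$ Morgan, $\Delta t \in \{0, 15\}$, 10,000 replicates, every 0.25 cM
  bin from 2–20 cM within 3 Monte-Carlo SEs) is a genuine two-route
  verification. Simulations and the matched prediction both use a
  250-generation horizon: for $\ge 2$ cM segments the deeper tail contributes
  $\sim 10^{-4}$ of a bin's mass, two orders below Monte-Carlo error at this
  replication.

Neither simulator emulates population structure, admixture, selection, or the
LD/genotyping texture of real data; passing recovery tests therefore
demonstrates correctness of the inference machinery under the model's own
assumptions, not robustness to their violation — the panmixia caveat applies
to real analyses.

Benchmark demographies (`build_scenario()`): constant $N_e = 25{,}000$; an
instantaneous 10-fold bottleneck ($50{,}000 \to 5{,}000$) 30 generations ago
with exponential regrowth to $100{,}000$ at present; exponential growth from
$10{,}000$ to $250{,}000$ starting 50 generations ago.

## Numerical and design choices

* Units: Morgans internally everywhere; cM only at I/O surfaces (tables,
  grids, error models).
* Time: a single global integer generation clock; all pairs index one shared
  trajectory.
* The recovery experiments (test suite and acceptance script) use sample
  sizes of 30 diploids per set for the three-time-point bottleneck design and
  180 contemporaneous diploids for the error round trip, with cross-validated
  $\alpha$ selected once on the first replicate and reused — mirroring the
  bootstrap's reuse of the full-data $\alpha$.
* Cross-validation folds default to `min(11, #chromosomes)` (11 folds of 2
  for human autosomes); the recovery experiments use 4 folds.
* Degenerate inputs fail loudly: zero expected rate with observed counts
  yields a flagged `-Inf` rather than silence; all-zero histograms, unknown
  chromosome labels, non-covering convolution lattices and truncated tables
  are errors.
* Relatedness filtering (default: ≥ 3 segments > 12 cM, or > 100 cM summed in
  such segments) removes the lower-coverage member of each flagged pair,
  iterating until clean; dating uses 29 years/generation and 5-generation
  windows anchored at the most recent individual (the anchor is a package
  choice; grouping is invariant to uniform date shifts).

## Known limitations

* The composite likelihood ignores dependence between bins and between
  set pairs; confidence intervals inherit whatever optimism that induces,
  partly mitigated by bootstrapping over chromosomes.
* An instantaneous size change is recovered as a smoothed ramp; the
  transition band (here generations ~26–36) cannot match the truth pointwise
  under any curvature penalty.
* Estimates beyond ~50 generations before the oldest samples reflect the
  regularization more than the data.
* Each sample set is treated as sampled at a single generation. No correction
  for within-set date heterogeneity is provided: when individuals pooled into
  one set span many generations (poorly dated samples), the estimate acquires
  a moderate upward bias, and the honest remedies are finer grouping where
  dates allow, or acknowledging the bias.
* The genome-pooled Poisson likelihood is not numerically identical to the
  product of per-chromosome likelihoods (rates are additive; log-likelihoods
  are not); the package follows the pooled formulation throughout.
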