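# ibdtransect

Estimation of recent effective population size (Ne) trajectories from
identity-by-descent (IBD) segments shared within and across **time-stratified
sample sets**, as produced by ancient-DNA time transects.

Long IBD segments coalesce almost exclusively in the last ~50–100
generations, so their length distribution is a clean signal for *recent*
demography — but ancient-DNA samples are not contemporaneous, and ignoring
sampling-time differences biases contemporary-sample methods. `ibdtransect`
models the sampling times explicitly: for a haplotype pair sampled at
generations *t<sub>i</sub>* and *t<sub>j</sub>* and coalescing at generation
*g*, the branch length available for recombination is
*t\** = (*g* − *t<sub>i</sub>*) + (*g* − *t<sub>j</sub>*), and the expected
density of IBD segments of length *l* on a chromosome of genetic length *L*
Morgans is

&nbsp;&nbsp;&nbsp;&nbsp;*f<sub>N</sub>(l)* = Σ<sub>chrom</sub> Σ<sub>g</sub>
\[2*t\** e<sup>−*t\**·*l*</sup> + (*L* − *l*)(*t\**)² e<sup>−*t\**·*l*</sup>\] · φ(*g*),

with φ the discrete coalescent probability under the piecewise trajectory
**Ne**. Binned segment counts are Poisson with mean
*n*<sub>hap</sub>·*f<sub>N</sub>*·Δ*l*; the composite log-likelihood sums all
within- and cross-set sample pairs, and the trajectory is fit by box-bounded
L-BFGS-B on log Ne with a curvature penalty (weight α, chosen by
leave-chromosomes-out cross-validation) plus a positionally decayed
first-difference penalty (weight β = 250). Detection errors (false
positives, length-dependent recall, Gaussian length noise) enter the expected
rates through a truncated convolution; confidence intervals come from
bootstrapping chromosomes. The package also computes the posterior TMRCA
distribution of an observed segment, and ships two simulators — a fast
model-inverse Poisson sampler and an independent discrete-generation
coalescent-with-recombination engine (C++) used to verify the model equations.

For whom: population geneticists analysing IBD calls from imputed
ancient-DNA data (or any time-stratified diploid samples), and
methods-minded users who want a verifiable reference implementation of
time-transect IBD demographic inference.

## Worked example

Simulate the 10-fold-bottleneck benchmark (50,000 → 5,000 at generation 30,
exponential regrowth to 100,000) sampled at *t* = 0, 25, 35 with 30 diploids
each over the 22 human autosomes, then refit the trajectory:

```r
library(ibdtransect)
scheme  <- sampling_scheme(times = c(0, 25, 35), sizes = c(30, 30, 30))
cmap    <- human_autosome_map()
grid    <- length_grid(8, 20, 0.25)          # 8-20 cM in 0.25 cM bins
ne_true <- build_scenario("bottleneck", Tmax = 185)
hist    <- sample_ibd_from_model(ne_true, scheme, grid, cmap, G = 150, seed = 1)
print(hist)
#> IBD histogram: 6 set pair(s) x 48 bins x 22 chromosome(s), 486 segments

fit <- fit_trajectory(hist, scheme, cmap, alpha = 100, G = 150, seed = 1)
print(fit)
#> Ne trajectory fit: 185 generations, alpha=100, beta=250
#>   objective 3.5448 (neg. loglik -0.5507), convergence 0
#>   Ne at t=0: 49520; at t=184: 48821

round(rbind(truth    = ne_true[c(1, 16, 31, 41, 51)],
            estimate = fit$ne[c(1, 16, 31, 41, 51)]))
#>            [,1]  [,2]  [,3]  [,4]  [,5]
#> truth    100000 22361  5000 50000 50000
#> estimate  49520 23302 11515 40980 47684
```

The fitted trajectory (generations 0, 15, 30, 40, 50 shown) tracks the
regrowth, localizes the crash around generation 30, and recovers the
pre-bottleneck plateau; the instantaneous jump itself is smoothed by the
curvature penalty, and the estimate at *t* = 0 — constrained only by
within-set sharing of the most recent samples — is the least certain. In
practice `select_alpha()` chooses α and `bootstrap_ci()` adds a 95%
envelope. The TMRCA posterior of a 10 cM segment under the fitted trajectory:

```r
post <- tmrca_posterior(cm_to_morgan(10), 0, 0, fit$ne)
tmrca_quantile(post)      # 2.5% / 50% / 97.5%
#> [1]  4 18 34
```

A thin command-line interface wraps the same functions
(`exec/ibdtransect`): `infer`, `group`, `simulate-ibd`, `inject-errors`,
`tmrca`. Example:

```sh
ibdtransect infer --ibd segments.tsv --meta meta.tsv --map map.tsv \
    --out trajectory.tsv --bootstrap 200 --seed 1
```

Input formats are plain tab-separated tables: segments
(`id1 id2 chrom length_cm`), metadata (`id date coverage`, dates BP or CE),
genetic map (`chrom length_morgan`), optional error model
(`bin_midpoint_cm fp_density_per_pair_per_cm recall`). Small synthetic
examples live in `inst/extdata/`.

See the methods vignette (`vignettes/ne-from-time-transect-ibd.Rmd`) for the
model, penalties, error correction, simulator design and known limitations.

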