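# ppiFusion

Inference of protein–protein interaction (PPI) networks from multiple
heterogeneous data sources, for computational biologists who have a
partial interaction catalogue and a stack of pairwise-similarity
matrices (sequence, co-expression, domain profiles, topology) and want a
ranked list of missing interactions.

## Method

A PPI network $G = (V, E)$ with adjacency $A$ is split into a connected
training network $G_{tn}$ (random spanning tree + a few extra edges), a
validation edge set $G_{vn}$ and a test set $G_{tt}$. The training
adjacency and $n$ feature kernels are combined into a weighted fusion

$$K_{fusion} = W_0\,G_{tn} + \sum_{i=1}^{n} W_i K_i, \qquad W_i \in [0,1],$$

and every protein pair is scored by the regularized Laplacian graph
kernel of the fused matrix

$$RL = \sum_{k\ge 0} \alpha^k(-L)^k = (I + \alpha L)^{-1},
\qquad L = D - K_{fusion},\; 0 < \alpha < \rho(L)^{-1},$$

whose entries behave like random-walk-with-restart proximities for all
pairs at once and are read as interaction propensities $P_{ij}$. The
weights are learned by a population sampler: uniform initialisation,
differential-evolution proposals (DE/rand/1/bin, $F=0.8$, $CR=0.9$),
and Boltzmann acceptance $\min\{1, e^{(f_{new}-f_{old})/T_k}\}$ under
geometric annealing, where the fitness blends ranking quality (AUC) on
the training network and on the held-out validation edges. Evaluation
ranks all candidate pairs (held-out edges positive, non-edges of the
full gold network negative) and reports ROC/AUC, including the
long-range regime of test pairs more than 3 hops apart in $G_{tn}$ where
plain network-proximity scoring degrades.

See `vignettes/ppiFusion-methods.Rmd` for the full account of the model,
parameters and design decisions.

## Worked example

A fully synthetic, seeded benchmark: a 200-protein scale-free gold
network, one planted informative kernel (common-neighbour signal of the
full network at noise level 0.3) and two pure-noise kernels. The
pipeline learns the kernel weights and evaluates the optimised fusion
(OPT-K) against the equal-weight control (EW-K) and the bare training
network ($G_{tn}$-only):

```r
library(ppiFusion)

scen <- generateBenchmark(seed = 1)      # gold, split, kernels, truth
cfg  <- samplerConfig(maxGenerations = 15L, convergenceWindow = 15L,
                      seed = 1L)
res  <- runInference(scen, cfg)

round(res$auc, 3)
#>    opt_k     ew_k gtn_only
#>    0.635    0.533    0.538

round(res$aucFaraway, 3)                 # test pairs > 3 hops in G_tn
#>    opt_k     ew_k gtn_only
#>    0.616    0.534    0.491

round(res$weights, 3)
#>        G_tn informative     noise_1     noise_2
#>       1.000       0.014       0.000       0.000
```

Reading the output: the optimised fusion recovers held-out interactions
markedly better than both controls (AUC 0.64 vs 0.53–0.54), the margin
widens in the long-range regime where the bare training network is at
chance (0.62 vs 0.49), and the sampler puts its free weight on the
planted informative kernel while driving both noise kernels to zero.
Equal weighting is *worse* than ignoring the feature kernels altogether
— unweighted integration of noisy sources actively hurts, which is the
point of learning the weights.

Real data enter the same way: `readEdgeList()` +
`largestConnectedComponent()` for a DIP-style interaction file,
`loadKernelMatrix()` for precomputed genomic kernels (labelled dense
matrix format), `jaccardKernel()` / `sharedNeighborKernel()` for
topological kernels of the training network, then `splitNetwork()`,
`kernelSet()`, `runInference()`. A thin command-line driver with
`simulate` / `split` / `kernels` / `optimize` / `infer` / `evaluate` /
`run` subcommands is installed at
`system.file("scripts", "ppifusion.R", package = "ppiFusion")`.

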