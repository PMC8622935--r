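# hopnet

Learning binary Hopfield attractor networks by **minimum energy flow**, with
exact small-system Lenz–Ising diagnostics, classical comparison rules, a
hyperclique construction with robust exponential memory, and experiment
harnesses for clustering, hidden-clique learning, critical training ratios,
and spike-raster attractor labeling — all on synthetic, fully reproducible
data.

It is aimed at researchers in computational neuroscience and discrete
energy-based modeling who want (a) a scalable convex trainer whose fixed
points act as cluster prototypes, denoisers, or error-correcting codewords,
and (b) the exact numerical machinery to interrogate what that trainer
optimizes.

## The model and the objective

A Hopfield network on *n* binary nodes is a symmetric zero-diagonal weight
matrix *W* and thresholds *θ*, with energy

    E(x) = -½ xᵀWx + xᵀθ,          x ∈ {0,1}ⁿ.

Asynchronous threshold updates `x_i ← H(W_iᵀx − θ_i)` never increase the
energy and terminate at fixed points `x* = H(Wx* − θ)` — the network's
memories. The same parameters define the Lenz–Ising distribution
`p_x ∝ exp(−E(x))`.

Training minimizes the convex **energy flow** of the data distribution *q*:

    EF(W, θ) = Σ_x q_x Σ_{x' ∈ N₁(x)} exp((E(x) − E(x'))/2),

a sum over single-bit flips that costs O(mn²) to evaluate exactly and whose
minimization provably pushes the data patterns to be fixed points. For small
systems (n ≤ 12) the package builds the exact flow matrix *M* and verifies
the projection bound

    ‖q − (⟨q,p⟩/⟨p,p⟩) p‖₂ ≤ (2/σ₂(M)) · EF,

which ties the training objective to density estimation through the second
smallest singular value of *M*.

On top of the trainer, the package implements a two-parameter network over
the (d+1)-subsets of *v* vertices whose fixed points are the hyperclique
indicators of typical random d-uniform hypergraphs — exponentially many
robustly stored memories, i.e. a nonlinear error-correcting code — together
with the closed-form robustness indices (α = 1/2 at d = 1 for the
robustness-optimal weights, 1/4 for the energy-flow-optimal ones) and
Monte-Carlo decoders.

## A worked example

Two hidden 12-bit sources, 400 samples corrupted at 5 % bit flips; train,
inspect the attractors, then denoise a badly corrupted fresh copy:

```r
library(hopnet)
set.seed(7)

centers <- make_clusters(K = 2, n = 12)
samples <- sample_mixture(centers, m = 400, p = 0.05)

net <- train_mef(samples, mef_options(max_iterations = 200), quiet = TRUE)
energy_flow(net, samples)
#> [1] 4.994112

all(apply(centers, 1, function(x) is_fixed_point(net, x)))
#> [1] TRUE

summ <- attractor_summary(net, samples)
summ$n_attractors
#> [1] 2
summ$entropy
#> [1] 0.9991162

noisy <- corrupt(centers[1, ], p = 0.3)
sum(noisy != centers[1, ])       # bits flipped
#> [1] 4
all(converge(net, noisy) == centers[1, ])
#> [1] TRUE
```

Both hidden sources became exact fixed points; converging every training
sample finds exactly 2 attractors whose empirical distribution has entropy
≈ 1 bit (= log₂ 2, the true source entropy); and the dynamics pull a
4-bit-corrupted fresh pattern back to its source exactly.

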