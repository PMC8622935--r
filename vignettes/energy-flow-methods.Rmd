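---
title: "Learning Hopfield networks by minimum energy flow: models, diagnostics, and constructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Hopfield networks by minimum energy flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopnet)
```

## The model

A Hopfield network on $n$ binary nodes is a symmetric weight matrix
$W = W^\top$ with zero diagonal and a threshold vector $\theta$. A state
$x \in \{0,1\}^n$ has energy

$$E(x) = -\tfrac12 x^\top W x + x^\top \theta ,$$

and the asynchronous dynamics visit nodes in some order, setting
$x_i \leftarrow H(F_i)$ with feedforward input $F_i = W_i^\top x - \theta_i$
and Heaviside step $H$. Flipping bit $i$ changes the energy by
$-\Delta x_i F_i$, so the dynamics never increase energy and reach a fixed
point $x^* = H(W x^* - \theta)$ in finitely many passes. The same $(W,
\theta)$ parameterize a Lenz–Ising (Boltzmann) distribution
$p_x \propto e^{-E(x)}$, the maximum-entropy model matching first- and
second-order statistics, so a trained network doubles as a density estimate.

Two conventions are frozen throughout the package:

* **Ties go to zero.** $H(0) = 0$: a node with exactly zero drive switches
  off. Every update, fixed-point test, and decoder uses strict positivity.
* **States are $\{0,1\}$**, never spins. The one place a $\pm 1$ mapping
  appears is inside the Hebbian comparison rule, where it is the classical
  convention.

The node update order is an explicit argument everywhere (default:
ascending index), since different orders can reach different fixed points
from the same start; experiments that want randomized orders seed them
explicitly.

## The energy-flow objective

Training minimizes the *energy flow*

$$\mathrm{EF}(W, \theta) \;=\; \sum_{x} q_x \sum_{x' \in N_1(x)}
e^{(E(x) - E(x'))/2},$$

where $q$ is the empirical distribution of the data and $N_1(x)$ the
Hamming-1 neighborhood. Each term is $\exp(\Delta x_i F_i / 2)$ for the flip
of one bit, so the whole objective and its exact gradient cost $O(mn^2)$ —
no $2^n$ enumeration — and the objective is a positive sum of exponentials
of linear functions of $(W, \theta)$, hence convex. Driving it to zero
pushes every flip exponent negative, which is precisely the statement that
every data pattern is a strict fixed point: the convex surrogate provably
chases the nonlinear fixed-point identities.

Implementation choices:

* **Parameterization.** The optimizer works on the strict upper triangle of
  $W$ plus $\theta$, so symmetry and the zero diagonal are structural, and
  the batch gradient is automatically symmetric. The online single-pattern
  rule instead symmetrizes its raw local update as
  $(\Delta W + \Delta W^\top)/2$, which leaves the energy function
  unchanged; `mef_update_raw()` exposes the unsymmetrized termwise form
  (presynaptic activity times an exponential attenuation in the
  postsynaptic drive — depression, potentiation, and homeostatic damping in
  one expression). The rule is defined up to a learning-rate constant; the
  package fixes it to the exact gradient of the singleton objective so that
  online and batch training agree step for step.
* **Initialization and stopping.** Training always starts from the zero
  network — the objective is convex, so the start affects only the path —
  and stops at a projected-gradient tolerance of $10^{-6}$ or an iteration
  cap. Both a quasi-Newton path (L-BFGS) and a first-order path with
  backtracking line search are available; they must and do agree on the
  optimum to optimization tolerance.
* **No finite minimizer.** For degenerate data (a single pattern, or any
  set whose thresholds can be scaled indefinitely) the infimum of EF is
  zero and is not attained; weights grow until the iteration cap. The
  trainer warns and returns the best iterate rather than regularizing
  silently — the fixed-point property of interest is reached long before
  the cap matters.
* **Duplicate patterns** merge into empirical weights $q_x$ by default
  (`pattern_set(..., merge = TRUE)`); a flag keeps multiplicities when the
  caller wants uniform weighting of given rows.

## Exact small-system diagnostics

For $n \le 12$ the package enumerates all $2^n$ states (little-endian
order: bit $i$ of the state index is $x_i$; every exact object shares this
convention). `boltzmann()` shifts energies by their minimum before
exponentiating, so the probability vector is overflow-safe; the partition
function is also reported on the log scale.

The *flow matrix* $M$ has $M_{yx} = e^{(E_x - E_y)/2}$ for one-bit
neighbors $y$ of $x$, zeros elsewhere off the diagonal, and diagonal
entries making every column sum exactly zero. It satisfies detailed
balance with $p$, so $Mp = 0$, and the one-flip graph (the hypercube) is
connected, so the second smallest singular value $\sigma_2(M)$ is strictly
positive. The central inequality verified numerically by the test suite is

$$\Bigl\| q - \frac{\langle q, p\rangle}{\langle p, p\rangle} p \Bigr\|_2
 \;\le\; \frac{2}{\sigma_2(M)} \,\mathrm{EF}(q),$$

linking the distance from the data to its projection on the model with the
training objective. The constant matters: the bound follows the chain
$\|\cdot\|_2 \le \|Mq\|_2/\sigma_2 \le \|Mq\|_1/\sigma_2$, and then the
splitting of $M$ into its nonpositive diagonal part $D$ and nonnegative
off-diagonal part $T$ gives $\|Dq\|_1 = \|Tq\|_1 = \mathrm{EF}$, so
$\|Mq\|_1 \le 2\,\mathrm{EF}$. The factor is therefore $2/\sigma_2$, and
the suite checks every link of the chain separately so that no single
numeric coincidence can hide a wrong constant. The off-diagonal column
mass of $M$ also furnishes a second, independent route to EF
(`energy_flow_exact()`), cross-checked against the $O(mn^2)$ data-space
computation on random instances.

The enumeration cap of 12 nodes keeps the dense $4096 \times 4096$ singular
value decomposition around a minute on one CPU; raising it is a conscious
user act (`cap =`).

## Classical comparison rules

The comparison trainers implement one-line classical principles, with the
concrete forms chosen here (they are stand-ins consistent with those
principles, and the experiment harness treats rules as pluggable):

* **Outer product (Hebb):** $W = \frac1m \sum_x s(x) s(x)^\top$ on spins
  $s(x) = 2x - 1$, zero diagonal, zero thresholds.
* **Perceptron:** per-node perceptron updates with margin zero against
  target $x_i$, batch epochs, weights symmetrized and diagonal zeroed each
  epoch, pocket iterate returned on non-convergence.
* **Delta:** gradient descent on the logistic least-mean-square objective
  $\sum_x \sum_i (x_i - \sigma(F_i))^2$ with unit slope, symmetrized each
  epoch, with step halving to keep the objective non-increasing.

On the hidden-clique task these reproduce the expected qualitative
ordering: energy-flow training dominates the Hebbian rule at every
training ratio and reaches complete storage of all 28 six-cliques on
eight vertices.

## The hyperclique code

The combinatorial construction stores exponentially many patterns
robustly. Nodes are the $\binom{v}{d+1}$ subsets of size $d+1$ of a
$v$-vertex set, in colexicographic order. Two nodes are *adjacent* when
their subsets share all but one vertex — exactly $d$ common vertices. (For
$d = 1$ this is the familiar "edges sharing an endpoint"; for general $d$
it is the relation under which each node has exactly
$(d+1)(v-d-1)$ neighbors and the completeness counts below have their
stated scale. An intersection-size-one reading would make complete and
incomplete nodes statistically indistinguishable for $d \ge 2$ and the
construction collapses, so the share-$d$ reading is the one the arithmetic
forces.) Weights are a constant $x \ge 0$ on adjacent pairs, zero
elsewhere; thresholds a constant $z > 0$. Only the ratio $x/z$ matters for
the dynamics, so $z$ defaults to 1.

A $d$-uniform hypergraph $G$ (each $d$-subset an edge independently with
probability $1/2$ — the unique null model consistent with the typicality
expectations) is encoded as the indicator of its *hypercliques*: node $i$
is set iff all $d{+}1$ sub-edges of its subset are present. Writing
$w(G,i)$ for the number of complete neighbors of node $i$, the *typical
set* consists of hypergraphs where

1. every complete node has $w \ge (d+1) v 2^{-d} (1-\varepsilon)$,
2. every incomplete node has $w \le d v 2^{-d} (1+\varepsilon)$,
3. the number of complete nodes is within $1 \pm \varepsilon$ of
   $2^{-(d+1)} \binom{v}{d+1}$.

Conditions 1–2 are deliberately one-sided: they are the bounds the storage
argument consumes, and a node whose subset lies wholly outside $G$
legitimately has $w = 0$, so a two-sided band around $d v 2^{-d}$ would
reject every hypergraph.

**Slack.** The deviation scale of the underlying concentration argument is
$\sqrt{v}\log v$ on counts of order $v$, giving a relative slack
$\varepsilon(v) = c \log(v)/\sqrt{v}$ (default $c = 3$). At desk scales
this exceeds 1, so the package caps it at $0.95/(2(d+1))$: beyond
$1/(2(d+1))$ the complete and incomplete windows cross the decision
threshold of the analytic weights and typicality would no longer imply
storage. With the cap, membership in the typical set *guarantees* that the
codeword is an exact fixed point under the analytic weight
$x = 2^{d+1} z / ((2d+1)\,v)$, whose decision threshold $z/x =
(2d+1) v/2^{d+1}$ sits exactly midway between the two windows. That weight
is also where the structured energy flow of the construction is minimized
in the large-$z$ limit, and `fit_code_parameters()` recovers the ratio
numerically: the two-parameter objective has no finite minimizer (it
decays along a ray of growing $z$ at the optimal ratio), so the optimizer
runs to its gradient tolerance and the *ratio* is the estimate. At $v=32$
the fitted ratio sits a few percent above $2^{d+1}/((2d+1)v)$ — the exact
finite-$v$ optimum replaces $v$ by roughly $v - 2$ — comfortably within
the 15 % agreement the tests require.

**Robustness.** The closed-form robustness indices are
$\alpha = 1/(2^d(d+1) - 2d)$ for the robustness-optimal construction and
$\alpha = 1/(2^{d+1}(d+1) - 4d)$ for the energy-flow-optimal weights
($1/2$ and $1/4$ at $d = 1$). These are asymptotic statements: the
corrupted drive of a node concentrates at scale $\sqrt{v}$ around means
separated at scale $v(\alpha - p)$, so exact single-pass recovery of all
$\binom{v}{d+1}$ nodes requires $v$ far above desk scale once $p$
approaches $\alpha$. The simulation harness (`robustness_sim()`) reports
recovery fractions rather than asserting a threshold at fixed $v$; the
suite checks the two finite-size facts that are actually decidable at
desk scale — recovery is monotone non-increasing in $p$, and at fixed
$p < \alpha$ it increases with $v$. At $v = 64$, $d = 1$, exact single-pass
recovery is essentially certain only for $p$ up to a few percent; the
nominal $\alpha = 1/4$ for these weights is approached from below as $v$
grows. For $d = 2$ the finite-size gap is starker: at $v = 12$ the exact
complete-neighbor expectation $(d+1)(v-d-1)2^{-d} = 6.75$ sits 25 % below
the asymptotic center 9, further than any admissible slack, and the
per-node fluctuation ($\mathrm{sd} \approx 2.9$) overlaps the
complete/incomplete separation, so *no* random hypergraph on 12 vertices
is typical and exact storage of random triangle-codewords needs $v$ in the
hundreds. The rejection sampler fails loudly in that regime rather than
silently loosening the conditions.

## Experiments on synthetic data

**Cluster entropy.** $K$ distinct uniform random centers in $\{0,1\}^n$;
each sample picks a center uniformly and flips each bit with probability
$p$. After training, every sample is converged and the attractor
distribution's Shannon entropy (base 2) estimates the source entropy
$\log_2 K$. The reference regime is $K = 64$, $n = 256$, $m = 32768$,
$p = 0.1$ (512 samples per center), where training recovers exactly 64
attractors and entropy $\log_2 64 = 6$ bits to within hundredths of a bit;
with an order of magnitude fewer samples the network stores stray noisy
copies as extra attractors and the estimate overshoots — the suite checks
both regimes. The generator emulates i.i.d. bit-flip noise around
well-separated centers; it does not emulate correlated noise, unbalanced
mixtures, or centers with structure, so passing says nothing about those.

**Hidden cliques.** All $\binom{v}{k}$ $k$-cliques on $v$ vertices as
edge-indicator patterns over $\binom{v}{2}$ nodes. The learning-curve
harness trains on a sampled fraction and evaluates *exact fixed-point
storage* on all cliques. "Accuracy" in this package always means exact
storage of the test patterns, not corruption-recovery; that is the design
decision recorded here, and recovery-from-corruption remains available
separately through the decoding simulations for anyone wanting the
stricter reading.

**Critical ratio.** For $v \in \{16, 24, 32\}$, $k = v/2$, a bisection over
the training-set size finds the smallest number of random training cliques
reaching 50 % storage on 1000 random test cliques (sampled with
replacement; training samples without). The critical count grows slowly
(roughly 90 → 190 over this grid) while $\binom{v}{k}$ explodes, so the
ratio falls by orders of magnitude per step — the scaled-down form of the
exponential-decay phenomenon. Each bisection probe retrains from scratch
on a fresh sample, so the estimate is noisy but unbiased; five trials per
$v$ are averaged. The full-scale grid ($v$ up to 80, thousands of nodes)
is a cluster-sized computation and is deliberately out of the default
configuration; the code path is the same, only the sizes change.

**Raster labeling.** A synthetic spike raster (50 neurons × 2000 bins of
2 ms) carries two planted motif blocks over sparse Bernoulli background,
with 10 % bit-flip noise over the finished raster. Windows of the motif
width are extracted on the motif grid, a network is trained on all windows
(duplicates weighted by frequency), and each window is labeled by its
fixed point; identifiers are dense in order of first appearance, so the
timeline is deterministic and byte-identical across reruns at a fixed
seed. The window geometry is chosen so that the window count (1000)
comfortably exceeds the network's memorization capacity (roughly twice
the 100-bit window size): below capacity the convex objective happily
stores every noisy occurrence as its own attractor and no clustering
happens — the same small-sample failure mode as in the cluster-entropy
experiment, now controlled by window width rather than sample count. With
the default geometry, well over 90 % of planted occurrences are labeled
with their motif's attractor. The synthetic raster emulates exactly
repeating, grid-aligned motifs; it does not emulate temporal jitter,
rate-modulated backgrounds, or overlapping motifs.

## Numerical conventions and limitations

* Tie-breaking is $H(0) = 0$ everywhere; changing it would change fixed
  points on measure-zero parameter sets only, but it is frozen for
  reproducibility.
* Exact-module tolerances: detailed balance to $10^{-10}$ relative,
  $Mp = 0$ and the projection bound to $10^{-9}$ absolute slack; gradient
  versus central differences to $10^{-6}$ relative at $h = 10^{-5}$.
* The convergence cap on asynchronous passes ($10 \cdot n \cdot 2^{16}$) is
  a safety device; energy monotonicity makes it unreachable for valid
  symmetric networks.
* All randomness flows through R's global RNG; every experiment function
  is reproducible from `set.seed()`. Serialization round-trips weights at
  17 significant digits (exact for IEEE doubles).
* Finite-temperature (Glauber) dynamics, larger flip neighborhoods,
  $\ell_1$ regularization, Potts states, and third-order energies are out
  of scope.
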