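---
title: "Discriminative dictionary learning for electronic-nose data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative dictionary learning for electronic-nose data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elcksvd)
```

## The problem

An electronic nose measures an odor with an array of cross-sensitive
metal-oxide (MOS) gas sensors.  Every sensor responds to many volatile
compounds at once, so the array's steady-state response pattern is a
redundant, correlated fingerprint of the sample.  The task this package
addresses is classifying such fingerprints — here, juice samples grouped
by storage time, whose volatile profiles drift as the juice ages.

The usual pipeline treats feature extraction and classification as
separate stages.  Label-consistent K-SVD (LC-KSVD) couples them: a
dictionary, a code transform and a linear classifier are trained jointly,
so the learned sparse codes are shaped by the class labels from the
start.

## The model

### Sparse coding and K-SVD

A signal $y \in \mathbb{R}^n$ is approximated as $y \approx Dx$ with a
dictionary $D \in \mathbb{R}^{n \times K}$ of unit-norm atoms and a code
$x$ with at most $T$ nonzeros.  Codes are found by orthogonal matching
pursuit (OMP): greedily add the atom most correlated with the residual,
re-solve the least-squares fit on the accumulated support (by QR, for
stability), and repeat up to $T$ atoms.  Ties in the correlation are
broken toward the lowest atom index and the early-stop tolerance is
$\|r\| < 10^{-10}\|y\|$, so coding is deterministic.

K-SVD alternates batch OMP with per-atom updates: for atom $k$, the
restricted error matrix $E_k^R$ (reconstruction error of the samples
using atom $k$, with atom $k$ removed) is replaced by its best rank-1
approximation via SVD.  The update is exactly the minimizer, so a full
sweep can never increase $\|Y - DX\|_F$ — a property the test suite
asserts on every run.  Sign ambiguity of the SVD is fixed by making the
first nonzero entry of each atom positive; sweeps visit atoms in
ascending index order.  An atom used by no sample is replaced by the
normalized worst-reconstructed signal.

`ksvd_fit()` optionally performs *dictionary clearing* between sweeps
(off by default): an atom that duplicates another (coherence above 0.75)
or is used by fewer than 4 signals is replaced by the residual direction
of the worst-reconstructed signal.  Clearing is the standard escape from
duplicate-atom local minima in dictionary recovery; it is kept optional
because replacing a live atom breaks the strict per-sweep monotonicity
contract.

### Label-consistent K-SVD

Training minimizes, over $D, A, W, X$ with $\|x_i\|_0 \le T$,

$$\alpha\,\|Y - DX\|_2^2 \;+\; \beta\,\|Q - AX\|_2^2 \;+\;
  \gamma\,\|H - WX\|_2^2, \qquad \alpha + \beta + \gamma = 1,$$

where $Q$ is the binary label-consistency target ($Q_{ki} = 1$ iff atom
$k$ and sample $i$ share a class), $H$ the one-hot class indicator, $A$ a
linear code transform and $W$ the linear classifier.  Normalizing the
weights onto the simplex makes the relative influence of the three terms
explicit and gives the swarm optimizer a well-bounded search space.

The solver is the stacked-system trick: K-SVD is run on
$Y_{\mathrm{new}} = (\sqrt{\alpha}\,Y;\ \sqrt{\beta}\,Q;\ \sqrt{\gamma}\,H)$
with stacked dictionary
$(\sqrt{\alpha}\,D;\ \sqrt{\beta}\,A;\ \sqrt{\gamma}\,W)$, columns
normalized.  Afterwards the blocks are unstacked, divided by the stacking
constants, and de-normalized per column ($\hat d = d/\|d\|$,
$\hat a = a/\|d\|$, $\hat w = w/\|d\|$) so that coding against unit
atoms matches the classifier scale.  $A$ and $W$ are initialized by ridge
regression from the initial codes onto $Q$ and $H$
($\lambda = 10^{-4}$; a singular system with $\lambda = 0$ is refused
with advice rather than silently regularized).

Dictionary atoms are initialized from training samples with a per-class
quota ($\lfloor K/m \rfloor$ atoms per class, one extra for the first
$K \bmod m$ classes), which fixes the atom-to-class assignment that
defines $Q$.  Classification is
$\hat c = \arg\max_c (W x)_c$ with ties toward the lowest class index.

### Kernel embedding

Raw LC-KSVD codes are linear reconstructions, and E-nose class structure
is not linear.  The package therefore embeds each sample by its vector of
RBF similarities $k(x, r_j) = \exp(-\|x - r_j\|^2/\sigma^2)$ to the
training samples $r_j$ (the *empirical kernel map*), and runs LC-KSVD on
the embedded vectors.  The embedding dimension equals the training-set
size (64 under the default design).  This explicit map keeps every
downstream operation unchanged; a fully kernelized OMP is deliberately
not implemented.  Features are standardized per sensor with training
statistics before kernel evaluation (the RBF distance is scale
sensitive, and sensors have different voltage ranges); the constants are
frozen into the model, so test data never influences them.  Test samples
are mapped against the stored training reference, not a joint Gram
matrix — the conventional choice that keeps prediction independent of
the test batch.  When `sigma` is not given, the median heuristic
$\sigma = \sqrt{\mathrm{median}\ \|x_i - x_j\|^2}$ on standardized
training pairs is used.

### Sensor selection, weights, and the swarm

Because the array is cross-sensitive, some sensors contribute mostly
redundancy; a binary mask selects the subset used by the pipeline.  The
mask (15 bits), the objective weights and the kernel scale are optimized
jointly by particle swarm search over a 19-dimensional encoding:

* dims 1–3: weight logits, mapped by softmax onto the open simplex;
* dim 4: kernel scale, affine map of the coordinate onto
  $[\log \sigma_{\min}, \log \sigma_{\max}]$ (default range
  $[10^{-2}, 10^3]$ on standardized features), then exponentiated;
* dims 5–19: sensor bits, deterministically 1 iff the coordinate is
  positive.  A particle selecting no sensor is invalid and receives
  fitness $-\infty$.

The fitness is k-fold (default 4) cross-validated accuracy on the
training split only; using test accuracy would leak.  Three strategies
are available.  PSO is the classic velocity form (inertia 0.72).  QPSO
moves every coordinate to
$p \pm c_e\,|M - x|\,\ln(1/u)$, $u \sim U(0,1)$, where $p$ is the local
attractor $\varphi p_i + (1-\varphi) p_g$,
$\varphi = c_1 r_1/(c_1 r_1 + c_2 r_2)$, and $M$ the mean of the
personal bests; the contraction–expansion factor $c_e$ scales the step.
The enhanced variant (EQPSO) is a documented reconstruction built from
three separable components, each a flag so that disabling all three
recovers QPSO exactly:

1. $c_e$ decreases linearly from 1.0 to 0.5 over the run (diverse early
   search, tight late search; plain QPSO uses a constant 0.75);
2. the mean-best position weights personal bests by fitness rank
   (elitism);
3. after 10 improvement-free iterations the global best receives a
   Gaussian kick (sd = 5% of the range), accepted only if it improves.

The optimizer is seeded end to end and the incumbent configuration is
always injected as the first particle, so the search never returns
something whose cross-validated fitness is below the default's.

### Extreme learning machine

Plain K-SVD has no classifier of its own, so its sparse codes are
classified by an ELM: a single hidden layer with fixed uniform(-1, 1)
random weights, sigmoid activation ($L = 100$ units), and output weights
solved in closed form by ridge regression ($\lambda = 10^{-3}$) onto
one-hot targets.  This provides the comparison arm in which feature
extraction and classification remain separate stages.

## The synthetic data generator

No public E-nose storage-day dataset accompanies the method, so the
package ships a generator that emulates the sampling protocol: per
measurement, 5 min of clean air (baseline), 7 min of headspace gas
(injection), 5 min of clean air again (recovery), sampled at 10
points/min; 4 storage-day classes × 4 vessels × 6 repeat measurements =
96 samples on 15 sensors.  Within a curve the response rises along a
saturating logistic profile toward baseline + amplitude (saturated to
within 1% by the end of injection) and decays exponentially back during
recovery.  The feature of a sensor is its maximum voltage inside a
window; since such protocols never pin down "steady state"
numerically, the window defaults to the whole injection phase and is
configurable.

Class structure is an *aging trajectory*: the latent class signature
$g(u)$ is affine in the storage-time coordinate $u$ when
`nonlinearity = 0` and is bent by a quadratic curvature term as
`nonlinearity` grows.  Sensor amplitudes are $L\,g(u_c)$ with loadings
$L$ shared across sensors, which makes feature columns strongly
correlated (cross-sensitivity).  Two further nonlinear ingredients act at
the sample level: a random headspace concentration factor
($U(0.8, 1.2)$) entering through sensor-specific power laws (exponents
shrink below 1 with `nonlinearity`), and a multiplicative per-measurement
sensitivity jitter of each sensor (6% by default — the
measurement-to-measurement repeatability typical of MOS arrays).  White
measurement noise (0.05 V) is added per timepoint, and each vessel
carries a small additive intercept.  One sampling session per class is
generated, mirroring a design in which storage day and session coincide.

Two design iterations are worth recording because they shaped the model.
A generator with well-separated random class centroids is trivially
linearly separable, whatever the nonlinearity of the map that produced
the centroids — four tight clusters in 15 dimensions need no kernel.
Conversely, a generator in which classes differ mainly by overall
intensity, confounded with concentration, *favors* the raw-space method:
OMP coefficients absorb per-sample amplitude scaling natively, so
dictionary coding is the right tool for that nuisance and the kernel
embedding only fragments the classes.  The trajectory model is the
regime where the kernel genuinely earns its keep: intermediate classes
approach convex combinations of their neighbours, which entangles linear
sparse coding, while local RBF neighbourhoods remain class-pure.  Under
the defaults the kernelized pipeline matches or beats its raw-space twin
in 16 of 20 replicate designs (8/10 in each of two disjoint seed
decades), with test accuracies in the 70–100% band and a mean gap of
about six accuracy points.

What the generator does **not** emulate: sensor drift and aging,
humidity and temperature effects, compound-level chemistry, and session
effects beyond the vessel intercept.  Passing tests on this generator
therefore demonstrate the algorithmic claims (oracle agreement,
monotonicity, recovery, directional benefits), not field performance on
real juice headspace data.

## Numerical choices

* OMP: QR least squares on the support; unit-norm dictionary enforced to
  $10^{-8}$; lowest-index tie-break.
* Rank-1 updates: full SVD up to dimension 200, power iteration above
  (tolerance $10^{-10}$); deterministic sign convention.
* The planted-dictionary benchmark draws its ground truth with mutual
  coherence bounded by 0.6 (rejection sampling,
  `random_incoherent_dictionary()`): near-parallel true atoms make
  recovery at $|\mathrm{corr}| > 0.99$ ill-posed, so an unconstrained
  Gaussian draw would measure the draw, not the algorithm.
* The OMP exact-recovery fixture is a 8×16 frame annealed to coherence
  below 1/3 — the sharp sufficient condition for 2-sparse recovery
  ($\mu < 1/(2T-1)$).  Random 8×16 frames have coherence near 0.8, and
  the best packings of 16 lines in $\mathbb{R}^8$ sit near 0.3, so a
  "random incoherent" fixture at this size must be constructed, not
  drawn.
* Model archives serialize every array at full precision (`%.17g`), so a
  save/load round trip is bit-exact; CSV round trips preserve 12+
  significant digits.
* Class labels may be arbitrary; they are mapped to indices in
  first-seen order and the mapping is stored in the model.

## Problem sizes used by the test suite

The suite favors small, fully checkable instances: the OMP oracle runs
200 instances at $n \le 8$, $K \le 12$, $T \le 3$ against a brute-force
greedy reference; the atom-update oracle 50 instances against full SVDs;
the recovery benchmark is 16×32 with 600 signals and 60 iterations; the
swarm benchmark 30 particles × 100 iterations on the 4-dimensional
sphere; and the end-to-end directional checks use 10 replicate designs
of the full 96-sample study, with a 6-particle × 6-iteration swarm and
3-fold cross-validation in the optimized arm.  These sizes were chosen
so that every oracle can be exhaustive and every claim is re-checked on
every run.

## Known limitations

* The EQPSO variant is a reconstruction from its stated goals; the
  original references describe the idea, not the update rules, so other
  implementations may differ in detail.
* The empirical kernel map scales the signal dimension with the
  training-set size; for much larger studies a Nyström-type
  approximation would be needed (out of scope here).
* Whether the swarm fitness should be training, held-out, or
  cross-validated accuracy is genuinely open; cross-validation is the
  default because it neither leaks test data nor rewards overfitting the
  training split outright.
* The dictionary size `K` and the number of selected sensors are
  independent knobs: mask bits gate features, `K` is a configuration
  parameter.
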