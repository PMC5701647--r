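---
title: "Hemispheric asymmetry of weighted brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric asymmetry of weighted brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

# The analysis

`hemiconn` quantifies lateralization of brain network topology.  Starting
from per-subject whole-brain weighted connectomes over the 90-region AAL
parcellation (45 homotopic region pairs), the pipeline:

1. **builds** the connectomes — functional edges are Fisher r-to-z
   transformed positive Pearson correlations between ROI time series;
   structural edges are streamline densities, the streamline count divided
   by the summed volumes of the two regions;
2. **splits** each connectome into its two 45-node intrahemispheric
   networks, discarding interhemispheric connections and ordering nodes by
   homotopic pair so the left and right networks are node-aligned;
3. **measures** weighted small-world topology: Onnela clustering
   coefficient $C_w$, characteristic path length $L_w$ (edge length
   $1/w_{ij}$), global, local and nodal efficiency, and small-worldness
   $\sigma = \gamma/\lambda$ with $\gamma = C_w/C_w^{rand}$ and
   $\lambda = L_w/L_w^{rand}$ against degree-preserving rewired nulls;
4. **scores** lateralization per subject and metric with
   $AS(X) = 100\,[X(R) - X(L)]/[X(R) + X(L)] \in [-100, 100]$;
5. **localizes** lateralized connections with a paired network-based
   statistic (NBS): edge-wise paired t tests between homotopic edges,
   suprathreshold connected components, and a left/right label-swap
   permutation null of maximal component size;
6. **infers** at the group level: hemisphere-effect ANCOVA with a gender
   covariate and Benjamini–Hochberg FDR across metrics/regions, plus
   partial correlations (age, gender, handedness, education adjusted)
   between asymmetry scores and a 12-score neuropsychological battery.

Functional networks are additionally thresholded to fixed sparsity over the
grid 0.10–0.35 in steps of 0.01 (26 levels, the supra-threshold weights
retained) and every functional metric is integrated over that range
(trapezoid average), which equates wiring cost across subjects before
topology is compared.  Structural streamline-density networks are analyzed
once, unthresholded.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| sparsity grid | 0.10–0.35 by 0.01 | fraction of the 990 possible intrahemispheric edges retained (functional arm); the floor keeps networks reachable, the ceiling keeps small-world structure prominent |
| `nNull` | 100 (`smallWorldness`) | rewired nulls behind $\gamma, \lambda, \sigma$; the pipeline default is scaled down (see below) |
| `swapsPerEdge` | 10 | attempted double-edge swaps per edge in the null model |
| `tThreshold` | 3.0 | NBS component-forming threshold; NBS inference is threshold-dependent, so the value is always recorded in the output |
| `nPerm` | 5000 (`nbsPaired`) | permutations for the NBS null |
| `fdrQ` | 0.05 | FDR level for the hemisphere-effect scan |

# Design choices in detail

**Weight normalization.**  Onnela's $C_w$ is bounded by 1 only for weights
in $[0,1]$.  We divide both of a subject's hemispheric networks by their
*joint* maximum weight.  Per-hemisphere normalization would instead divide
each side by its own maximum — exactly cancelling the global weight
asymmetry the analysis is designed to detect.  Joint normalization leaves
every $AS(X)$ of a scale-homogeneous metric unchanged (all path-based and
clustering metrics scale linearly, or inversely for $L_w$, in a common
weight factor), which is also the package's primary closed-form oracle: if
the left weights are exactly $c$ times the homotopic right weights,
$AS(X) = 100(1-c)/(1+c)$ for $C_w$ and all efficiencies, with the sign
flipped for $L_w$, and $AS(\sigma) = 0$ in expectation because $\sigma$ is
scale-invariant.

**Shortest paths.**  Edge length is the reciprocal weight; distances come
from a dense vectorized Floyd–Warshall pass, which at 45 nodes is faster
than repeated graph construction and is cross-checked in the tests against
`igraph::distances` and against a brute-force all-simple-paths oracle on
small graphs.  Disconnection is represented, not an error: $L_w$ averages
finite distances only and reports the unreachable pair count, while
efficiencies use $1/\infty = 0$.

**Nodal/global efficiency normalization.**  Both use $1/(N-1)$ per-node
averaging (the inverse harmonic mean convention).  $AS(X)$ is invariant to
this constant, so downstream asymmetry results do not depend on the choice.

**Degree-preserving nulls.**  Maslov–Sneppen double-edge swaps with the
weights traveling on their edges, so the binary degree sequence and the
weight multiset are preserved exactly.  Swaps creating self-loops or
multi-edges are rejected; if a rewire of a connected network disconnects
it, the whole rewiring is retried (up to 10 times) before returning the
last attempt with a flag.  A complete graph admits no swap and is returned
unchanged — which makes $\sigma = 1$ exactly, a useful calibration point.
No installed graph library rewires with weight-carrying edges *and*
connectedness enforcement, hence the in-package implementation.

**Sparsity thresholding.**  The edge budget is
$K = \mathrm{round}(s \cdot N(N-1)/2)$, rounding half away from zero, with
ties at the cutoff broken deterministically (descending weight, then
ascending row/column index).  This makes edge sets nested across the grid
and outputs bit-reproducible.  When a network has fewer nonzero edges than
$K$, all are kept and an `unreachableSparsity` flag is raised.

**Degenerate correlations.**  Pearson correlations are clipped to
$|r| \le 0.999999$ before `atanh`, keeping perfectly correlated inputs
finite; negative z values are set to zero (only positive connections are
retained).

**NBS conventions.**  Two-tailed analysis is run as two one-tailed
component analyses (components of mixed sign are not meaningful
subnetworks), each tail compared against its own permutation null.  The
permutation swaps each subject's hemispheres with an independent fair coin;
a balanced (exactly half) swap scheme is a known alternative, but
independent flips match the sign-flip test for paired differences and admit
exact enumeration of all $2^n$ patterns for small cohorts, which the
`exhaustive` mode implements.  Monte-Carlo p-values use the $+1$
finite-permutation correction and therefore never return 0.  Edges whose
paired differences have zero variance (e.g. absent in every subject) are
excluded from component formation.

**ANCOVA form.**  Hemisphere is a between-observation factor on stacked
data ($2n$ observations, denominator df $2n-3$; 149 at $n=76$), not a
repeated-measures model.  FDR families are one per modality × level: 5
global metrics, 45 regional efficiencies.  Association p-values between
asymmetry scores and behavior are reported uncorrected by default and
flagged exploratory; an optional BH flag corrects across the scan.

# The synthetic cohort generator

No suitable public dataset pairs structural and functional connectomes
with known ground-truth lateralization, so validation uses a generator
whose injected effects are recorded in a `truth` block.  All generator
choices are the package's own; no empirical generative model is implied.

*Structural arm.*  One sparse anatomical template per cohort:
intrahemispheric edges are Bernoulli(0.3) with log-normal weights (meanlog
$\log 0.05$, sdlog 0.8) — the sparse, right-skewed character of
streamline-density networks — mirrored to the other hemisphere.  The
template is shared across the cohort's subjects (as human subjects share
gross anatomy), each of whom applies independent multiplicative log-normal
noise (sdlog 0.1) per hemisphere; sharing the template also makes the
injected paired effect size exact, since the template weight cancels from
each edge's paired t statistic.  With noise off and a null
asymmetry spec, the left block equals the mirrored right block exactly
(the mirror-null invariant).  Interhemispheric edges (density 0.1) are
generated for realism but carry no asymmetry, since the analysis discards
them.  Asymmetry is injected multiplicatively into one hemisphere's block
at three scales: global ($\times(1+\delta)$ on every edge), nodal (all
edges of a region), and edge-subnetwork (a listed set of homotopic edges,
forced to exist in the template).  For a target paired effect size $d$ on
the homotopic edge difference, `pairedEffectDelta()` inverts the
log-normal moments: with noise factors $e = \exp N(0, s^2)$ the difference
$T(e_L(1+\delta) - e_R)$ has mean $T\delta e^{s^2/2}$ and variance
$T^2 v((1+\delta)^2 + 1)$, $v = e^{s^2}(e^{s^2}-1)$, and the quadratic in
$\delta$ is solved exactly.

*Functional arm.*  ROI time series are zero-mean multivariate normal draws
(default 200 time points, matching a typical resting-state acquisition
after volume discarding) from a block-modular correlation: modules of 5
regions at $\rho_{in} = 0.5$, between-module $\rho_{out} = 0.1$, mirrored
across hemispheres, homotopic correlation 0.3 and other interhemispheric
pairs 0.1.  The asymmetry spec scales one hemisphere's off-diagonal
covariance; a non-positive-definite result is repaired by nearest-PD
adjustment with a warning (or errors when repair is disabled).

*Cohort level.*  Per-subject seeds are an affine hash of the master seed
and subject index, so the bundle is reproducible independent of iteration
order.  The subject-level global delta is drawn around the configured
value (SD 0.05 by default), giving each subject a well-defined true
generating asymmetry score $100(1-c_i)/(1+c_i)$; behavioral scores couple
to that true score (not the estimated one), which keeps recovery tests
well-defined.  Covariates emulate a community-dwelling older-adult cohort:
age 60–82 (mean 70.1, SD 5.3), ~80% female, education 0–15 years, all
right-handed — which is why the handedness covariate is dropped (with a
warning) in partial correlations.  The 12 behavioral scores use the
battery's published-scale means and SDs (e.g. MMSE 28.25 ± 1.81).

*What the generator does not emulate:* spatial embedding and
distance-dependent connectivity, hemodynamics and physiological noise
spectra, motion artifacts, tractography biases, and non-Gaussian BOLD
marginals.  Passing tests therefore demonstrate correctness of the
*procedure* and recoverability of *injected* effects, not empirical claims
about real cohorts.

# Problem sizes used in the tests

The shipped test-suite and acceptance checks run the method at sizes the
package's authors consider statistically informative for a desk-scale
validation: 1,000 random graphs for the shortest-path oracle; 50
independent null draws for the $AS(\sigma)$ calibration (8 nulls each); 20
random 45-node graphs (20 nulls each) for the $\sigma$ calibration; 200
null cohorts of 30 subjects at 1,000 permutations for the NBS
false-positive rate plus 50 planted-effect replicates at 500 permutations;
and a 20-subject cohort for the end-to-end determinism check with 5 nulls
per network and 500 NBS permutations.  The `pipelineConfig()` defaults
mirror these scaled-down analysis settings; for production use, raise
`nNull` to 100 and `nbs$nPerm` to 5000, the conventional full-scale
choices.

# Known limitations

- The NBS component-forming threshold is a free parameter; results must be
  read conditional on it.
- Rewired nulls preserve the degree sequence and weight multiset but not
  the weight–degree correlation structure; $\gamma$ on weight-heterogeneous
  networks partly reflects weight-topology coupling.
- The ANCOVA treats the two hemispheres of a subject as independent
  observations (the stacked-data convention); a repeated-measures model
  would be more conservative.
- Sparsity integration assumes the metric varies smoothly over the grid;
  at very low densities disconnection inflates the unreachable-pair count,
  which is reported per network.
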