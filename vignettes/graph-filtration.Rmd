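---
title: "Threshold-free topology of time-delayed cross-frequency brain networks"
author: "xfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free topology of time-delayed cross-frequency brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfnet)
```

## The problem and the model

Gating of long-term memory encoding — letting relevant information in while
blocking irrelevant information — has been linked to a negative relationship
between posterior alpha-band power before a stimulus and gamma-band power
during the stimulus. `xfnet` analyses this relationship at the level of a
distributed cortical network: for each subject and task condition (Remember
vs. No-Remember cue), the across-trial Pearson correlation is computed
between alpha power during the cue epoch ("cue-alpha") at ROI $i$ and gamma
power during the item epoch ("item-gamma") at ROI $j$, for all $p \times p$
ROI pairs of a cortical parcellation (38 regions per hemisphere, $p = 76$).

Because rows (cue-alpha) and columns (item-gamma) index *different* node
sets, the natural object is a **bipartite graph** on $2p$ nodes whose weight
matrix is asymmetric: the coupling of cue-alpha at A with item-gamma at B is
not the coupling of cue-alpha at B with item-gamma at A. Only negative
correlations carry the gating signal (and discarding positive couplings also
removes trivial spatial-adjacency effects), so correlations are transformed
to distances by

$$ d_{ij} = \begin{cases} 1 - |r_{ij}| & r_{ij} < 0 \\ 1 & r_{ij} \ge 0, \end{cases} $$

with $d = 1$ acting as the *non-edge sentinel*. Distances live in $[0, 1]$;
smaller means tighter negative coupling.

## Graph filtration instead of a threshold

Binarizing a weighted network requires an arbitrary threshold and discards
information. Instead the package sweeps the threshold: at each filtration
value $\varepsilon$, an edge exists iff $d \le \varepsilon$ (closed
convention), giving a nested family of graphs over $\varepsilon \in [0, 1)$.
Weight-1 entries are never edges — including them would force trivial full
connectivity at $\varepsilon = 1$. The topological summary tracked is
Betti-0, the number of connected components, and everything reported is a
function of the merge events of a single union-find sweep:

* **Per-partition Betti-0 curves and barcodes.** A bipartite filtration has
  no canonical single barcode, so components of the full graph are projected
  onto one node set and counted there: the cue-alpha curve starts at $p$ and
  drops by one whenever two components that both contain cue-alpha nodes
  merge. This is the unique construction that is consistent with bipartite
  connectivity and yields exactly $p$ bars per set (bars born at 0, censored
  at 1 if they survive).
* **Single-linkage matrix (SLM).** Entry $(i, j)$ is the first
  $\varepsilon$ at which cue-alpha node $i$ and item-gamma node $j$ share a
  component — equivalently the minimax (bottleneck) path distance. It is the
  local, pairwise counterpart of the barcode.
* **Projected ultrametrics and dendrograms.** Within one partition, the
  first-connection values form an exact ultrametric; the dendrogram is the
  single-linkage tree whose cophenetic matrix reproduces it exactly.

Ties between equal edge weights are processed in fixed row-major order;
component counts and SLM values are tie-invariant (only the event
bookkeeping can differ). The sweep itself is implemented in C++ because the
permutation engines below re-run it hundreds of thousands of times.

## Statistics

* **diff_max.** Two Betti-0 curves are compared by the signed difference
  evaluated on the union of their breakpoints (step functions change nowhere
  else), returning the value of maximal absolute size; ties are broken by the
  smallest $\varepsilon$, then by positive sign. The tie rule is a package
  choice — only $|$diff_max$|$ enters the test statistics, so any fixed rule
  works.
* **Network-type contrast.** Per-subject diff_max values (cross-frequency
  vs. within-frequency curves) are tested against zero with a two-sided
  Wilcoxon signed-rank test. Zeros are dropped before ranking (the standard
  signed-rank convention; the data source does not state its handling) and an
  all-zero sample returns $p = 1$.
* **Trial-relabeling permutation tests.** Condition contrasts never assume a
  distribution. For the barcode test the statistic is the one-sample $t$
  across subjects of per-subject diff_max(R, NR) (200 iterations by
  default); for the SLM test it is the elementwise paired $t$ of
  $\mathrm{SLM}_R - \mathrm{SLM}_{NR}$ (5000 iterations, tested per pair at
  $\alpha = 0.0005$, deliberately uncorrected across the $p^2$ grid). Under
  the null each subject's trials are pooled across conditions and re-split
  into pseudo-conditions of the original sizes; trial-count equalization is
  re-applied inside every iteration with an iteration-derived sub-seed, so
  the null mirrors the observed pipeline exactly. P-values use add-one
  smoothing, $p = (1 + \#\{|t_\mathrm{null}| \ge |t_\mathrm{obs}|\})/(1 +
  n_\mathrm{perm})$, guaranteeing $p \ge 1/(n_\mathrm{perm}+1) > 0$; all
  tests are two-sided with the direction read off the sign afterwards
  ("R < NR" = tighter coupling under Remember).
* **Group permutation.** Good and poor memory performers (memory d-prime
  above/below 1.0) are compared on the per-subject SLM condition differences
  by permuting group labels with sizes preserved.
* **Behavior.** Instruction compliance is the d-prime of R-hits vs.
  NR-hits; memory performance the d-prime of R-hits vs. false alarms.
  Extreme rates are guarded at $1/(2N)$ — the correction used is not stated
  by the data source, and this standard guard keeps scores finite and
  monotone. Correlations between flagged-pair SLM differences and behavior
  use Pearson $r$ with a $t$-based two-sided p-value ($n-2$ df) and a
  Bonferroni factor equal to the number of flagged pairs.

Degenerate spreads are resolved by convention: a paired difference vector
with zero variance has $t = 0$ when its mean is 0 (so $p = 1$) and
$t = \pm\infty$ otherwise.

## What the synthetic generator emulates — and what it does not

No trial-level MEG data were deposited with the source study, so the test
bed is synthetic. The generator emulates the *correlation-level* structure
the pipeline consumes, nothing deeper: cue-alpha powers are independent
Gaussians around per-ROI baselines (normalized power $\approx 1 \pm 0.25$);
at each planted pair the item-gamma column is built as
$y = \nu + \sigma(\gamma z_i + \sqrt{1-\gamma^2}\, w)$ so the planted
Pearson correlation is exactly $\gamma$ in population (an additive-noise
form would only approximate the target correlation, which matters when a
criterion plants a specific $\gamma$). Per-subject couplings jitter around
the condition values (sd 0.1); trial counts are slightly unequal by default
(190/200, as after artifact rejection) so equalization is always exercised.
Defaults mirror the study scale: 23 subjects, 76 ROIs, one pair coupled at
$-0.6$ (R) vs. $-0.1$ (NR).

Behavioral counts are binomial draws whose rates are tied to the latent
coupling contrast: the compliance d-prime is `behavior_link_slope` (default
1.2) times $\gamma_{NR} - \gamma_R$ plus noise, calibrated so mean hit and
false-alarm rates sit near the published 57% / 33% / 24%. Stronger Remember
coupling therefore implies shorter single-linkage distances in R and higher
compliance — a *negative* correlation between the SLM condition difference
and compliance, matching the direction of the real effect.

A null cohort shares one per-subject jitter draw across conditions, making
R and NR trials exchangeable by construction — the property that the type-I
calibration test relies on.

The generator does **not** emulate oscillatory time series, 1/f spectra,
source leakage, spatial correlation between ROIs, or any forward model. A
green test therefore establishes that the *pipeline* is correct and
calibrated on data with known correlation structure — not that the pipeline
would recover effects from raw MEG with realistic artifacts.

## Numerical choices and conventions

* Closed threshold ($d \le \varepsilon$); sentinel 1 excluded from the sweep;
  censored bars and never-connected SLM pairs take the value 1.
* Undefined correlations (zero-variance columns) are reported, never
  silently replaced; downstream they default to distance 1 (no
  negative-coupling evidence), with a `strict` policy available.
* Within-frequency networks force the diagonal to 1: self-correlation is +1
  by construction and would otherwise create spurious zero-distance edges.
* Diagonal (intra-regional) entries of the bipartite matrix are ordinary
  entries: cue-alpha and item-gamma at the same region are different nodes.
* Trial subsampling is one random draw under a recorded seed; permutation
  engines derive one sub-seed per iteration so runs are exactly
  reproducible from the master seed.
* Dendrograms are built by the package's own agglomeration replay (not
  `stats::hclust`), so the test suite can use `hclust` + `cophenetic` as an
  independent oracle.

## Calibration checks and their interpretation

The acceptance suite verifies, among exact oracle equivalences, that under
null cohorts both permutation engines reject at the nominal 5% level within
the exact binomial 95% interval for 200 independent cohorts. For the
elementwise SLM test the rejection rate is pooled over the 64 matrix
entries of each cohort; entries are positively correlated within a cohort,
and pooling correlated indicators can only reduce the variance of the
pooled rate relative to one indicator per cohort, so the $n = 200$ binomial
interval remains valid (conservative) for the pooled rate. Planted-effect
recovery is asserted on the observed paired-$t$ ranking — the permutation
null is not needed to rank effects, which keeps the check fast; the
engines' null behaviour is covered by the calibration test.

## Known limitations

* Betti-0 only; higher-order topology (cycles, voids) is out of scope, as
  are weighted-graph metrics and any fixed-threshold analysis.
* Positive couplings are discarded by design; the package cannot be used to
  study positive cross-frequency coupling without changing the distance
  transform.
* The permutation engines recompute the full pipeline per iteration;
  at study scale (76 ROIs, 5000 iterations, 23 subjects) an SLM test takes
  tens of minutes on one CPU.
* Causality is not addressed: a tight negative coupling says nothing about
  the direction of influence between the alpha and gamma sources.
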