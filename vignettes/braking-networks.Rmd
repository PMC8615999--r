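---
title: "Braking-state detection from EEG brain networks: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Braking-state detection from EEG brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfcs)
```

## The problem and the model

A driver's EEG differs between emergency braking and ordinary driving, and
the difference is visible not only in per-channel spectra but in the
*coupling structure* across channels. This package treats each 1-s epoch as
a functional brain network: channels are nodes, and the edge weight between
two channels is their **cross-sample entropy** (CsEn) — an entropy-rate
statistic that is low when two series share dynamics and high when they are
unrelated. Classification then reduces to a network question: *which nodes
matter, and how does that change between states?*

The pipeline has five stages: band-pass preprocessing, CsEn connectivity,
threshold binarization, K-order propagation number node importance, and SVM
classification with a threshold/feature-selection layer on top.

## Cross-sample entropy

For two series of length $N$, templates of length $m$ (and $m+1$) are taken
at positions $1..N-m$ of each series and compared across series under the
Chebyshev distance. With $B$ cross-template matches at length $m$ and $A$ at
length $m+1$ within tolerance $r$,

$$\mathrm{CsEn}(m, r) = -\ln(A/B).$$

This is the Richman–Moorman convention: symmetric in its arguments, no
self-match exclusion (the series are different channels), and $A/B$ is the
conditional probability that series which track each other for $m$ samples
keep tracking for one more.

**Parameters.** `m = 2` and `r_coeff = 0.2` are the field's standard
choices for short physiological series. The tolerance is resolved *per
channel pair* as $r = 0.2 \cdot \mathrm{sd}(\{x, y\})$ — the pooled standard
deviation of the two series being compared. We considered resolving one $r$
per epoch from the pooled SD of all channels, but rejected it: when a subset
of channels carries a strong shared source, their amplitudes inflate
relative to an epoch-global $r$, and the apparent entropy of exactly those
pairs *rises*, inverting the physiology the statistic is meant to capture.
Under the per-pair convention, simulation confirms the expected direction:
epochs with a planted shared source show lower hub-pair CsEn than epochs
without (the suite tests this, including monotonicity in the coupling gain).

**Undefined entries.** On 1-s epochs zero-match pairs occur. The default
policy caps the entropy at $-\ln(1/(N-m)^2)$ — the largest value estimable
from $(N-m)^2$ comparisons — and counts the capped entries on the returned
object; a `strict` policy raises instead. Below roughly 100 samples per
epoch the cap starts to dominate pair statistics, which is why the package
defaults to 250 Hz sampling for 1-s epochs and why scaled-down tests stay at
or above 128 samples.

**Normalization.** Matrices are min-max normalized per matrix over the
off-diagonal entries (the diagonal is fixed at zero and excluded from every
statistic). Per-matrix scaling was chosen over per-subject or pooled scaling
because it makes the threshold grid comparable across epochs regardless of
slow drifts in overall entropy level; the raw matrices remain available
(`normalize = FALSE`) for group-level mean-CsEn comparisons.

## Binarization and the edge-rule ambiguity

A threshold `tri` converts the weighted matrix into a 0–1 network. Two
readings are defensible and they are *opposite*: (a) a higher threshold
should make the network sparser, which forces "edge where weight ≥ tri";
(b) low entropy means strong correlation, suggesting "edge where weight ≤
tri". Both are implemented (`rule = "ge"` / `"le"`). The default is `ge`,
which preserves the monotone-sparsification property (edge sets nested under
increasing `tri`) that the Z-score density analysis relies on. For
*interpreting* importance maps — e.g. recovering which channels carry a
shared source — the `le` rule is the physiologically meaningful one, and the
end-to-end tests use it for hub recovery. For *classification accuracy* the
choice matters little: the SVM can exploit either encoding, and the sweep is
run on whichever rule the caller selects.

`threshold_from_zscore()` expresses a threshold as mean $+ z \cdot$ sd of
the off-diagonal weights (sample sd), so network density can be reported on
a scale comparable across epochs and subjects.

## K-order propagation number importance

On the binary network with distance matrix $l$ and diameter $d$:

- $N_i^K = 1 + |\{j \ne i : l_{ij} \le K\}|$, the K-hop neighbourhood size
  (self included). Unreachable pairs never satisfy the condition. The
  indicator is 1 when $l_{ij} \le K$ — the only reading under which
  $N_i^K$ counts reachable nodes and a star's center outranks its leaves.
- $H_K = -\sum_i p_i \ln p_i$ with $p_i = N_i^K / \sum_j N_j^K$: the
  structure entropy at scale $K$. $H_0 = \ln n$ always; $H_K = \ln n$ iff
  the counts are uniform.
- $S_i^K$ is the min-max normalization of $N^K$; $c_K = 1 - (H_K - \min
  H)/(\max H - \min H)$, so the scale with the *largest* importance
  differences (lowest entropy) gets weight 1.
- $Q_i = \sum_{K=0}^{d} c_K S_i^K$.

**Degenerate conventions.** When all counts at a scale are equal, $S^K
\equiv 0$; when all $H_K$ are equal, $c_K \equiv 1/(d+1)$. These choices
avoid division by zero and make vertex-transitive graphs (complete graphs,
cycles) yield uniform $Q$ — the behaviour one wants from an importance
measure on a symmetric graph. An edgeless graph has $d = 0$ and $Q \equiv 0$.

**Logarithm base.** The entropy base rescales every $H_K$ by the same
factor and cancels in the min-max of $c_K$, so $Q$ is base-invariant; the
suite asserts this rather than assuming it.

**Disconnected graphs.** $d$ is the largest *finite* distance, and
unreachable pairs never enter a count. This keeps the algorithm total on
every input the threshold sweep can produce, including empty graphs.

The per-epoch feature vector is $Q$ in channel order by default, preserving
the spatial identity that regional channel grouping needs; a `sorted_desc`
ordering is available where channel identity is deliberately discarded.

## Classifier

The contract calls for an RBF-kernel SVM with standardized features,
stratified 10-fold cross-validation and seeded fold assignment. No SVM
solver ships in the target environment, so the package implements a
**least-squares SVM** (Suykens & Vandewalle 1999): same decision function
$\mathrm{sign}(\sum_i \alpha_i K(x_i, x) + b)$, trained by one linear solve
of the $(n+1)$-dimensional LS-SVM system instead of a QP. This keeps
training deterministic and dependency-free; the equality-constraint
formulation gives up sparsity in $\alpha$, which is irrelevant at the
sample sizes involved. Defaults: $C = 1$, $\gamma = 1/p$ on per-fold
standardized features (equivalent to the common "scale" heuristic since
standardized features have unit variance); both configurable. Features are
standardized with training-fold statistics only, so no information leaks
from test folds.

## Threshold sweep, GOTV, core-node selection

The `tri` grid is 50 evenly spaced values between the global min and max
off-diagonal weight across the subject's matrices (grid size configurable —
the trade-off is purely compute vs. resolution). Ties in cross-validated
accuracy break toward the smallest threshold. Per-subject best thresholds
are summarized by `gotv_summary()` as mean and sample (n−1) standard
deviation — reported rounded to 2 and 3 decimals respectively, matching
the convention for published threshold tables. For a new subject the
adaptive threshold searches only grid points within one sd of the GOTV,
which is the time-saving role GOTV plays.

Core-node selection reconstructs a procedure whose published description
names the ingredients (KNN grouping, LOOCV) but not the algorithm. The
package's reading, chosen as the simplest deterministic one: group $M_i$ is
channel $i$ plus its $k$ nearest montage neighbours (Euclidean distance,
ties toward the lower channel index); groups are ranked by LOOCV accuracy of
the SVM restricted to the group's columns; groups are then accumulated
greedily — a group is kept when the union's LOOCV accuracy strictly
improves — and accumulation stops at the first non-improvement. The centers
of the accumulated groups are the core channels. By construction the final
accuracy never falls below the top-ranked group's accuracy.

Note that the accuracy attached to a selected core set is a *maximum over
evaluated models*. Its null distribution therefore sits above 0.5; tests of
"no better than chance" use a Šidák-corrected band over the number of
models the greedy pass can evaluate, not the single-accuracy binomial band.
The same logic applies to the maximum of a 50-point threshold sweep.

## Preprocessing

The band-pass is a windowed-sinc (Hamming) FIR built as the difference of
two unit-DC-gain low-pass kernels, applied once with reflection padding and
group-delay removal. Consequences worth knowing: DC gain is exactly zero by
construction (not merely attenuated); the symmetric kernel plus delay
compensation makes the filter zero-phase, so epoch onsets are not smeared;
and the kernel length is auto-chosen from the transition-band rule
(~3.3·fs/Δf taps) but capped at the signal length — for short signals the
effective transition widens rather than the call failing. Artifact cleaning
is a hook (`clean_artifacts`) that accepts any recording-to-recording
function and enforces only that the channel count is preserved: no
component-rejection rule is bundled because none is well defined enough to
reproduce.

Epoch extraction uses 0-based, half-open sample windows
$[\mathrm{round}(t \cdot fs), \mathrm{round}(t \cdot fs) + n)$, so adjacent
1-s events never share samples; event files store onsets in seconds.

## The synthetic generator: what a green test establishes

Each epoch is independent Gaussian noise per channel; during "braking"
epochs a shared band-limited (0.5–45 Hz) latent source, scaled by the
coupling gain, is added to the hub channels. Defaults state the world the
tests assume: braking gain $= 2 \times$ noise sd, normal gain 0, fs 250 Hz,
1-s epochs, 20 epochs per class, hubs = the first $n/8$ channels (minimum
2). Per-subject variation redraws noise sd in [0.8, 1.2] and the braking
gain multiplier in [1.5, 2.5] from per-subject seeds. Everything is
deterministic given the config seed, with an RNG sandbox so generation never
perturbs the caller's RNG state.

The generator emulates exactly one mechanism — class-dependent coupling
structure — and none of the things that make real EEG hard: no 1/f
spectrum, no volume conduction (which couples *all* channels through the
skull), no blinks or EMG, no non-stationarity within epochs, no
per-channel impedance differences. A green end-to-end test therefore
establishes that the pipeline *recovers planted coupling structure and
stays at chance when none exists* — it does not establish real-data
accuracy, which depends on recordings this package does not ship.

## Known limitations

- EDF input is declared in the interface but not available in this build
  (no EDF reader in the dependency budget); delimited text is the supported
  interchange format and round-trips exactly.
- The LS-SVM substitutes for a QP-trained SVM; decision boundaries can
  differ slightly from libsvm's on the same data, though both are RBF
  discriminants and all contract-level behaviour (separability, chance-level
  nulls, duplicated-column invariance) is tested.
- CsEn on 1-s epochs is variance-limited; below ~128 samples per epoch the
  undefined-entropy cap dominates and results should not be trusted.
- The core-node selection rule is a reconstruction; other readings (e.g.
  re-ranking after each accepted group) are defensible and would select
  different sets on near-tied data.
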