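---
title: "Saliency-injected descriptors and hashed retrieval: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency-injected descriptors and hashed retrieval: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sincir)
```

## The retrieval problem

Content-based medical image retrieval ranks a database of grayscale
radiographs by visual and semantic similarity to a query image, instead of
relying on text metadata. Clinically interesting queries often hinge on a
small conspicuous region — a fracture line, a calcified spot, a mass —
while the rest of the image provides anatomical context. `sincir`
implements a pipeline that represents each image by a *fusion* of a
whole-image feature code and a feature code of its most salient region,
and indexes the fused descriptors with kernelized locality-sensitive
hashing (KLSH) so that queries need not scan the whole database.

## Preprocessing

Feature extractors expect a fixed square input of side $T = 224$. An
image of width $w$ and height $h$ is rescaled by
$S_f = T/h$ if $h > w$, else $T/w$, so that its longer side becomes
exactly $T$; the rescaled sides are $w_R = \mathrm{round}(w S_f)$ and
$h_R = \mathrm{round}(h S_f)$. The shorter axis is zero-padded
symmetrically so content sits in the centre. Three numerical details are
deliberate choices the formulas leave open:

* rounding of $w_R, h_R$ is half-away-from-zero (deterministic and
  symmetric);
* resampling is bilinear, the minimal artifact-free kernel;
* an odd padding remainder goes to the trailing (bottom/right) side.

The square is replicated into three identical planes and a per-pixel
*mean image* is subtracted to remove average brightness. The mean image
is computed over the index (training) set only and persisted with the
index; queries reuse it, so query-time representation is a pure function
of the fitted index.

## Graph-based saliency

Saliency is computed channel-wise at a working resolution $r \times r$
(default $r = 32$, capped so the graph stays tractable at $r^2 \le
2304$ nodes). The channel set is the minimal faithful one: downsampled
intensity plus gradient-orientation energy at 0°, 45°, 90° and 135°,
single scale. Each feature map $M$ is normalized to maximum 1 and
clamped at $\varepsilon = 10^{-6}$ so the logarithmic dissimilarity

$$d((i,j)\,\|\,(p,q)) = \left|\log \frac{M(i,j)}{M(p,q)}\right|$$

is always defined. A fully connected directed graph over the grid
carries edge weights $d \cdot F$, with the proximity kernel
$F(a,b) = \exp(-(a^2+b^2)/2\sigma^2)$ and $\sigma$ one tenth of the map
width by default (configurable up to one fifth). Row-normalizing the
weights gives a Markov chain whose equilibrium distribution assigns high
mass to locations that differ from their neighbourhood — the activation
map. A second, mass-concentration chain (edge weight into a node
proportional to that node's activation times proximity) sharpens the
map; we run one concentration pass per channel. Equilibria are computed
by power iteration from a uniform start vector to an L1 change below
$10^{-9}$ (cap 10,000 iterations); a constant feature map has all-zero
weights and is defined to have the uniform equilibrium, since a
featureless channel has no preferred location. Channel maps are
averaged, bilinearly upsampled to image resolution, and affinely
rescaled to $[0,1]$ (a constant map becomes 0.5 everywhere).

The salient region keeps the pixels at or above the dynamic threshold
$\tau = \frac{1}{MN}\sum_{x,y} S(x,y)$, the map mean; the masked image
equals the input on the mask and is exactly zero elsewhere. Masks of
fewer than 16 pixels fall back to the whole image. The patch handed to
feature extraction is the bounding-box crop of the masked image, then
preprocessed like any image — cropping (rather than keeping the masked
full frame) gives the extractor resolution on the region itself; the
alternative is one configuration flag away in `codes_for_image()`.

A property worth knowing: because the dissimilarity is a log *ratio*,
the intensity channel is invariant to rescaling the image intensities
but not to shifting them by a constant — a shift compresses the ratios.
The orientation-energy channels are exactly shift-invariant. Tests
assert precisely this.

## Feature codes and fusion

The extractor is a *contract*: any pure deterministic function from the
preprocessed input to a fixed-length vector can be registered. The
built-in backbone partitions the $T \times T$ plane into $g \times g$
cells (default 4) and concatenates per-cell, magnitude-weighted
histograms of unsigned gradient orientation with $o$ bins (default 8),
each cell L2-normalized with an $\varepsilon$ guard — code length
$n = g^2 o = 128$. This replaces a learned convolutional backbone with
something local, deterministic, and download-free; a fine-tuned network
can be plugged in through the same contract without touching the rest of
the pipeline.

Whole-image and salient-region codes are fused elementwise:

$$\mathrm{SiNC} = \alpha\, \mathrm{NC}_I + \beta\, \mathrm{NC}_S,
\qquad \alpha + \beta = 1,$$

defaults $\alpha = 0.4$, $\beta = 0.6$, weighting the salient region
slightly higher than the context. $\alpha = 1$ ignores saliency;
$\alpha = 0$ keeps only the salient patch. Before hashing, descriptors
are min-max normalized with the *global scalar* minimum and maximum over
all entries of the fitted collection — the singular reading of the
normalization rule — with a per-dimension variant behind a flag.
Query-time values outside the fitted range are clamped to $[0,1]$
rather than rejected, since queries are not part of the fitted set.

## Kernelized locality-sensitive hashing

$\rho$ anchors (default 300) are sampled from the normalized
descriptors; their RBF kernel matrix $K_{ij} =
\exp(-\gamma\|x_i-x_j\|^2)$ is double-centred. The bandwidth defaults to
the median heuristic $\gamma = 1/\mathrm{median}(\|x_i - x_j\|^2)$,
which adapts to the descriptor scale. Each of the $b = 128$ bits draws
$t = 30$ anchor indices to form an indicator $e_s$ and uses the weight
row $w = K^{-1/2} e_s$; a descriptor's bit is the sign (with
$\mathrm{sign}(0) \to 1$) of $\sum_i w_i\, \kappa(x, x_i)$.

$K^{-1/2}$ deserves care. Double-centring makes the all-ones direction
an exact null vector of $K$, and every $e_s$ has the same projection
$t/\sqrt{\rho}$ onto it. Inverting a floored near-zero eigenvalue would
amplify that common component by orders of magnitude and drive every bit
to the same sign, destroying locality. We therefore take the inverse
square root on the *retained eigenspace* only: eigencomponents with
$\lambda < 10^{-12}$ are dropped. Near-duplicate anchor sets still
produce finite weights; an all-identical anchor set (no retained
eigenvalue) is a degenerate-kernel error.

Hashed queries gather candidates bucket-by-bucket in increasing Hamming
radius — each started radius is completed, so the candidate set equals a
brute-force Hamming scan at the final cutoff — stopping once $3k$
candidates are collected or the radius exceeds `max_radius` (default
16), then rerank candidates by similarity. With `max_radius = b` the
search is exhaustive and provably identical to the linear scan.
Similarity is cosine on the normalized (hence non-negative) descriptors,
which lies in $[0,1]$ as required; ties are broken by ascending record
id for reproducibility.

## Evaluation machinery

Precision is $N_R/(N_R+N_I)$ and recall $N_R/T_R$ with relevance
defined as sharing the query's category label. PR curves use standard
interpolated precision on the fixed recall grid $\{0.1, \dots, 1.0\}$
(at each level, the maximum precision over cutoffs reaching that
recall; unreached levels score 0), macro-averaged over queries; the
averaging convention and interpolation are package choices since
neither is forced by the definitions. AUC is the trapezoidal integral
with the first grid value extended to recall 0. The fusion sweep
recomputes retrieval at each $(\alpha, 1-\alpha)$ from *cached* codes,
so it isolates the weight effect; it reports both precision@10 and
interpolated precision at recall 0.1. The noise sweep corrupts queries
only (salt & pepper flip probability, or zero-mean Gaussian variance in
intensity units squared), with and without a 3×3 median filter; level 0
reproduces the clean baseline bit-for-bit.

## The synthetic generator

The generator is a *test fixture*, not a radiograph simulator: its job
is category structure and plantable, maskable anomalies, with enough
within-category coherence that retrieval is clearly above chance.
Eight parametric motifs (elliptical "skull" shell, banded "chest" with
lung-like hypodensities, a "long bone" rod with end knobs, fanned "hand"
rods, paired "pelvis" rings, jointed "knee" rods, horizontal "ribs",
diagonal "shoulder" rod plus ring) are cycled over categories with
jittered parameters. Per image: a random side in $[120, 512]$ pixels
(the span of typical radiograph archives), smooth-shaded motif
rendering, an optional anomaly — a bright Gaussian blob of amplitude
100–135 on the ~25-intensity textured background (calcification-like)
or a dark transverse gap across a rod (fracture-like), recorded in a
pixel mask — additive Gaussian noise ($\sigma = 4$), a linear
illumination gradient (relative slope up to 0.2), and a 50% horizontal
flip. Every image derives its own RNG stream from `(seed, image
index)`, so datasets are bit-reproducible and stable under partial
generation.

What passing tests on this generator do *not* show: robustness to
projection geometry, exposure variation, anatomical deformation, or the
texture statistics of real radiographs. They do show that the
pipeline's mechanics — saliency localization of conspicuous structure,
the benefit of fusing context with region codes, locality of the hash,
and all bookkeeping — behave as designed.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at desk scale:

* hashing/retrieval benchmarks use a 500-image, 10-category index with
  128-bit keys and a saliency working side of $r = 16$;
* the fusion and noise experiments use 8 categories × 25 images with
  5 held-out queries per category, $r = 16$;
* the saliency-localization benchmark uses 100 blob-bearing images of
  side 160–256 at $r = 24$. The default $r = 32$ spends most of its
  time in the dense power iteration ($r^2 \times r^2$ transition
  matrices); $r = 24$ preserves localization quality on blobs of this
  scale while keeping the benchmark brisk.

Other numerical decisions collected in one place: feature maps clamped
at $10^{-6}$; power iteration tolerance $10^{-9}$ (L1), cap 10,000,
uniform start; eigenvalue retention floor $10^{-12}$; per-cell L2
normalization guard $10^{-12}$; sign(0) hashes to bit 1; salient-mask
fallback below 16 pixels; bounding boxes 1-based inclusive (R
convention); anchor distances computed from explicit pairwise
differences rather than the Gram identity, which loses all precision on
near-duplicate anchors.

## Known limitations

* The built-in backbone is intentionally simple; absolute retrieval
  quality on real images depends on plugging in a stronger extractor.
* Saliency at working side 16–32 cannot localize structures much
  smaller than one working cell.
* Single hash table: recall of the hashed search at small radii depends
  on key balance; the radius bound trades recall for candidate count.
* The bounded-radius search can return fewer than `k` results when few
  keys fall within `max_radius`; exhaustive behaviour is one argument
  away.
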