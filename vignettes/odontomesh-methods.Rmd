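---
title: "Classifying 3D tooth meshes as triangle sequences: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying 3D tooth meshes as triangle sequences: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odontomesh)
```

## The problem and the method

Identifying the anatomical type of an isolated tooth from its 3D surface is
a recurring task in dental diagnostics and forensic odontology, where teeth
are often the most durable evidence available for victim identification.
`odontomesh` implements a sequence-model approach to this problem: a
triangular surface mesh $M = (V, F)$ — vertices $V \subset \mathbb{R}^3$ and
triangular faces $F$ indexing into $V$ — is reduced to a fixed budget of
$T$ triangles, each triangle is summarized by 12 numbers (the three corner
vertex coordinates and the centroid, the arithmetic mean of the corners),
and the resulting $T \times 12$ matrix is min–max scaled into a grayscale
feature image. Reading the image row by row turns the mesh into a length-$T$
sequence of 12-dimensional observations, which a stack of two recurrent
layers of 128 gated recurrent units (GRUs) consumes; a 64-unit fully
connected ReLU layer and a softmax head with 4, 8 or 16 outputs produce the
class posterior. Training minimizes sparse categorical cross-entropy with
Adam at learning rate 0.0005.

The three label granularities mirror clinical usage on maxillary teeth:
16 types (8 anatomical types, sided left/right), 8 types (side dropped) and
4 major categories (incisors, canines, premolars, molars). Integer class
codes are assigned alphabetically within a scheme.

## Pipeline stages and the parameters that matter

**Decimation.** Intraoral-scan surfaces carry on the order of $10^5$
triangles; the encoder needs exactly $T$ (default 900). We simplify with
quadric-error-metric (QEM) edge collapse — each candidate edge is scored by
the quadric error of its optimal collapse position, with area-weighted
plane quadrics — because QEM is the standard fixed-budget simplifier and
only the output count is externally constrained. Exactness is enforced
mechanically: collapses run until the count is at or below target, and if
boundary collapses overshoot by one, the longest boundary edge is split to
restore the count. On a closed surface $2E = 3F$ forces an even face
count, so an odd target on a closed mesh is rejected rather than
approximated. Collapses that would flip a surviving face normal are
rejected; if that guard ever exhausts the candidate heap, a second pass
without it finishes the job. Decimation is deterministic (the heap orders
by error with vertex-index tie-breaks).

**Augmentation.** Dataset expansion applies random rigid motions. The
rotation operator, in its default `single` mode, is a one-parameter matrix
in the angle $\alpha$ (degrees) whose nine entries are fixed trigonometric
expressions; this matrix is *exactly* the extrinsic Euler composition
$R_z(\alpha) R_y(\alpha) R_x(\alpha)$ with equal angles — an algebraic
identity we verified symbolically and test numerically — so it is always a
proper rotation. A `triple` mode with three independent axis angles is
provided for the reading in which the three axes rotate independently; it
is an option, not a silent substitution. Angles are sampled uniformly on
$[0, 360)$ degrees and translation components uniformly on $[0, 90]$
(scanner length units). One policy detail deserves a note:
`variants_per_original` (default 6) counts *every* emitted object,
including the untransformed identity copy. With the study-scale census of
448 originals this reproduces the 2688-object expanded set and the
$\lfloor 0.70 \times 2688 \rfloor = 1881 / 807$ train/test split
downstream; the count is configurable for other protocols. Sampling order
is fixed (per mesh, per variant: rotation draws before translation draws)
so expansions are bitwise reproducible under a seed.

**Encoding.** Feature rows follow the mesh's stored face order by default —
the minimal assumption, since nothing canonical orders the triangles of a
decimated mesh — with an optional `canonical` sort by centroid (z, then y,
then x) that gives a consistent spatial scan across meshes. Min–max
scaling is *joint* over the whole matrix, not per column: a grayscale
image has a single intensity scale, and per-column scaling would distort
the relative geometry between coordinates. A constant matrix (degenerate
range) maps to the all-zero image, avoiding division by zero with a
defined, testable output. Float images in $[0,1]$ are the training
representation and are exactly invertible (the scaling bounds are stored);
8-bit quantization exists for PNG export and interoperability only, so no
quantization loss enters the learner. Note that min–max normalization does
*not* make the encoding translation- or rotation-invariant in general —
which is precisely why rigid augmentation is informative rather than a
no-op.

**Classifier.** The first recurrent layer returns its full output
sequence, the second only its final state — the standard stacked
recurrent-classifier shape. Baselines for the architecture comparison
mirror the GRU's capacity: LSTM and vanilla RNN with identical layer/unit
counts, and a CNN of two 3×3 convolution blocks (32 then 64 filters, ReLU,
2×2 max-pool) over the 1-channel feature image followed by the same
FC(64) head, so differences reflect the inductive bias, not parameter
budget. Because no deep-learning framework is available to R in this
stack, the networks are implemented in-package as a small BLAS-backed
matrix engine with hand-derived backpropagation-through-time; gradients of
every variant are verified against numerical differentiation in the test
suite.

**Training.** Defaults are standard small-data practice: up to 100 epochs,
batch size 32, a 10% validation carve-out with early stopping (patience
10) and restoration of the best-validation-loss checkpoint. Global
gradient-norm clipping at 5 stabilizes the recurrent variants. Argmax ties
at prediction break toward the lowest class index; a class with no
predicted positives gets precision 0 rather than NaN. All percentages in
evaluation reports are reported to 2 decimals. Runs are deterministic
given the initialization and training seeds (single-threaded BLAS).

**Splitting.** The default protocol splits the *augmented* objects (70%
train, floor rounding, stratified by class): this matches the expansion
arithmetic above, but lets rigid-motion variants of one physical tooth
land on both sides of the split — an information leak inherent to that
protocol. The `group_aware` flag splits by source tooth instead, and
exists to quantify the leak; it is off by default to keep the default
protocol faithful to the expansion arithmetic.

## The synthetic tooth generator

The study-style scan data this method targets is not publicly deposited,
so the package ships a parametric generator that emulates the *census and
separability structure* of such a collection: 28 subjects × 16 tooth
types = 448 meshes, dense enough to need decimation. Each class is a
superellipsoid crown scaled by class-specific width/depth/height ratios
(base crown size 4 mm per unit ratio), with a class-fixed number of
Gaussian cusp bumps (amplitude 0.35 × crown height, width 0.16 × crown
radius) on the occlusal face: incisors thin and tall with 0–1 cusps,
canines tall with one, premolars two, molars short and boxy with 4–5.
Right-sided classes mirror x. Subject variation multiplies every shape
parameter by $1 + 0.05\,N(0,1)$.

What this emulates: class-dependent geometry with within-class subject
variation, realistic face counts, deterministic regeneration. What it does
not: real anatomical morphology, root geometry, scanner noise, occlusal
wear, or the inter-class *similarity* of real teeth (synthetic classes are
cleanly separable by construction — a rule using only bounding-box aspect
and cusp count already gets ≥90% at 4 categories, and the test suite
checks that). Passing benchmarks here therefore certifies the pipeline's
correctness and the classifier's capacity, not clinical performance; the
headline accuracies reported for real scan data are data-bound and out of
scope.

## Problem sizes for desk-scale runs

Tests and the acceptance script run everything on one CPU, so problem
sizes are chosen as compact as the property under test allows:

- The dataset-arithmetic checks (448 → 2688 → 1881/807) run the real
  generator/augmenter/splitter at low mesh density, since the counts do not
  depend on density; the 900-face decimation check uses one full
  scan-density (≥100 000 faces) mesh.
- `synthetic_benchmark()` — the class-recovery bar — keeps the full 28
  subjects, 448 meshes and the full-scale 2×128 GRU, but uses a
  120-triangle budget, no augmentation, canonical row order and up to 80
  epochs, which lands a run at a few minutes while staying comfortably
  above its ≥95% test-accuracy bar (median over 3 seeds).
- The ablation harness demonstrates the {GRU, LSTM, RNN, CNN} ×
  {vertices, centers, both} grid on 8 subjects with a 96-triangle budget
  and few epochs; its purpose is a complete, seed-reproducible comparison
  table, and accuracies at that scale are not meant to rank architectures.

## Numerical and representational choices

- Face indices are 1-based inside R structures (the R ecosystem
  convention); OBJ/PLY's index bases are converted at the file boundary.
- STL files carry no connectivity, so corners are welded on load with an
  exact-coordinate match (tolerance 0) for reproducible topology; binary
  STL stores 32-bit floats, bounding its round-trip precision at about
  1e-7 relative.
- Coordinates pass through I/O and decimation untouched (no unit
  rescaling); all normalization happens in the encoder, per mesh.
- QEM collapse positions solve a 3×3 system; near-singular quadrics fall
  back to the best of the two endpoints and the midpoint.
- The LSTM forget-gate bias initializes to 1; all other weights are
  Glorot-uniform from the model seed; Adam uses the standard
  $(\beta_1, \beta_2, \epsilon) = (0.9, 0.999, 10^{-8})$.
- Epoch training loss is accumulated as a per-sample average, so with a
  frozen model (learning rate 0) it is invariant to the batch partition —
  which the tests exploit.

## Known limitations

- Synthetic separability overstates real-world performance by design (see
  above); no claim about clinical accuracy is made or tested.
- The default split protocol leaks augmented variants across the split;
  use `group_aware = TRUE` to measure the difference.
- Boundary behavior of decimation on open surfaces is not pinned beyond
  exact face counts: collapse of boundary edges is allowed and boundary
  shape may simplify.
- The pure-R network engine targets desk-scale sequence lengths; training
  at the full 900-step budget with thousands of objects is possible but
  slow on one CPU, and no GPU path is provided.
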