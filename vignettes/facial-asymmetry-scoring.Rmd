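---
title: "Scoring facial asymmetry with spatially augmented histograms"
author: "facesym package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring facial asymmetry with spatially augmented histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesym)
```

## The problem and the model

Human faces are nearly — but never perfectly — bilaterally symmetric, and
the amount and spatial pattern of normal asymmetry varies across the face:
the corners of the lips and eyes tolerate more asymmetry than the nasal
tip. `facesym` quantifies a subject's facial asymmetry from a 3D surface
scan by comparing the face to its own mirror image at densely
corresponding points, and then summarizes how that subject's asymmetry
pattern deviates from a population model of *normal* asymmetry. The
resulting scalar score is a quantitative phenotype suitable for genetic
association.

The pipeline has five stages:

1. **Alignment.** Each subject mesh is rigidly aligned into a common frame
   by a least-squares (Kabsch) fit of its named anatomical landmarks to a
   reference configuration. Scaling is deliberately excluded: downstream
   features are physical distances in mm. The aligned convention is
   midsagittal plane at $x = 0$, $+y$ superior, $+z$ anterior; `_l`
   landmarks sit on the subject's anatomical left at $x > 0$.

2. **Dense correspondence.** For every point of a base mesh, the
   corresponding point on each subject surface is found by a thin-plate
   spline warp driven by the landmarks (3D kernel $U(r) = r$ plus an
   affine part; exact interpolation by default, a ridge parameter
   `lambda` is available for noisy landmarks) followed by exact
   closest-point projection onto the subject's triangles. Averaging the
   corresponded positions over the cohort yields the average mesh, which
   becomes the common coordinate system for all per-point maps.

3. **Mirroring and local features.** Each aligned subject is reflected
   about $x = 0$ (with left/right landmark relabeling) and both the
   original and mirrored surfaces are sampled through dense
   correspondences from the average mesh. The *asymmetry flow vector* at
   an average-mesh point is the displacement from the corresponding point
   on the original surface to the corresponding point on the mirrored
   surface. Three local features are derived per point:
   * **angle of surface orientation** — the angle between the unit
     normals at the two corresponding points (degrees; asymmetry of local
     orientation, independent of its magnitude);
   * **angle of deformation** — the angle between the flow vector and the
     original surface normal (degrees; the direction of the mirror
     transformation). Where the flow magnitude falls below `epsFlow`
     ($10^{-6}$ mm) the angle is defined as 0: a symmetric point
     contributes no asymmetry rather than an undefined direction;
   * **deformation magnitude** — the Euclidean length of the flow vector
     (mm).

   All scoring is restricted to the face *below the eyes* (vertices at or
   below the mean height of the two endocanthion landmarks), the region
   where real scans are reliable and where the landmark set lives.

4. **Normal model.** For each feature, the per-point sample mean
   $\mu_j$ and sample SD $\sigma_j$ (denominator $n-1$) over a cohort
   form the model of normal
   asymmetry. $\sigma_j$ is floored at `epsSD` ($10^{-6}$) so standardized
   errors stay finite where a cohort is numerically constant.

5. **Spatially augmented histogram score.** A subject's feature map is
   reduced to a histogram over $B$ fixed bins whose bins additionally
   carry their *coherent regions*: connected components (on the mesh
   adjacency graph) of the bin's points with at least $\tau$ members
   (default $\tau = 20$; smaller components are pooled as incoherent).
   The spatial weight of bin $b$ against a reference map is
   $$\Psi_b = \sum_i \frac{|r_{bi}|}{\sum_k |r_{bk}|}\;
     \frac{1}{|r_{bi}|}\sum_{j \in r_{bi}}
     \frac{|A(x_j) - A'(x_j)|}{\sigma_j},$$
   the region-size-weighted mean standardized error over the bin's
   coherent points; incoherent points count toward the bin population but
   not toward $\Psi$. The directed distance is
   $$d(h, h') = \sum_b \Psi_b \left(1 - \sqrt{p_b\,p'_b}\right)$$
   with $p_b = n_b / N$ the normalized bin frequencies, and the score is
   the symmetrized $\rho(h,h') = \tfrac12\,(d(h,h') + d(h',h))$. A
   subject's asymmetry score is $\rho$ between its feature map and the
   model's mean map, standardized by the model's $\sigma_j$.

Two baseline phenotypes are included for contrast: the **mean deformation
magnitude** over the scored region (the classical surface-registration
summary), and the **landmark Procrustes score** (mirror the bilaterally
paired landmarks, rigidly re-align, average the paired distances) — the
traditional sparse phenotype that by construction cannot see asymmetry
between landmarks.

## Numerical and design choices

Several pieces are under-determined in the literature this package
implements, and the following decisions are our own.

* **Histogram dissimilarity.** A product of raw bin counts is not a
  usable dissimilarity (it is unbounded and sign-inverted), so the
  per-bin frequency factor is the Bhattacharyya-style
  $1 - \sqrt{p_b p'_b}$ on normalized frequencies, the standard choice in
  the spatiogram literature. A ratio variant $1 - \min/\max$ is available
  via `variant = "ratio"` for sensitivity analysis; both satisfy
  $d \ge 0$ with $d = 0$ for identical maps.
* **Bin ranges.** Bins are equal-width on $[0, \max]$ with the maximum
  taken over the cohort (capped at 180° for angles). Normal-face
  orientation asymmetry stays far below 180°, so binning the theoretical
  angle range would collapse essentially all mass into one bin and reduce
  the score to a threshold artifact.
* **Bin count.** The default is $B = 10$. With many more bins, the
  iso-value bands of a smooth feature map become thinner than $\tau$
  nearly everywhere, the coherent-region sets empty out, and the spatial
  weights carry no signal; with very few bins the histogram loses its
  discriminative value. $B$ and $\tau$ remain user parameters of every
  scoring function.
* **Coherence threshold.** A component is coherent iff its size is
  $\ge \tau$ (the inclusive reading), with $\tau = 20$ by default. At the
  reference mesh density used throughout (about 20,000–30,000 scored
  points), $\tau = 20$ is at most 0.1% of the image.
* **Normals.** Vertex normals are area-weighted face-normal averages;
  normals at correspondence targets are barycentrically interpolated and
  renormalized, which avoids facet quantization noise.
* **Ties and determinism.** Coherent regions are ordered largest-first
  (ties by smallest vertex index); genotype PC signs are fixed by forcing
  each component's largest-magnitude loading positive; all stochastic
  generators take explicit seeds.

## Scoring against a model: two regimes

The score measures *abnormality*: $|A - \mu|/\sigma$ is two-sided, so a
face that is markedly **more symmetric** than the reference population
also deviates from it. Two consequences matter in practice:

* When a cohort is scored against its own pooled model
  (`asymmetryPipeline()`), the score is U-shaped around the cohort's
  typical asymmetry level. In a small cohort there is a second artifact:
  a subject's own asymmetry inflates the model SD at exactly its own
  points and partly standardizes itself away. The pipeline therefore
  scores leave-one-out by default (`leaveOneOut = TRUE`); at population
  scale the two model versions coincide.
* When the question is "how asymmetric is this face, absolutely?" — as
  in any validation against a known ground truth — the model should come
  from a fixed reference cohort, and new subjects should be scored
  against it with `scoreWithModel()`. With a near-symmetric control
  reference, the score is monotone in true asymmetry from zero upward.

## The synthetic cohort generator

Real 3D facial scan cohorts with genotypes are access-controlled, so the
package ships a generator that emulates the study conditions end to end.

* **Template.** `makeTemplate(resolution)` builds a smooth face-like
  height field (ellipsoidal dome plus nose, lip and chin bumps) that is
  mirror-symmetric to machine precision — the height function is even in
  $x$, the $x$ grid is exactly negation-symmetric, and the triangulation
  mirrors its diagonals across $x = 0$. It carries the 18-landmark schema
  (6 midline, 6 bilateral pairs). Resolution 72 ($145^2 = 21{,}025$
  vertices, roughly 16,000 scored points after the crop) reproduces the
  point-count regime the method is designed for and is what the
  validation experiments use; resolution 20 is used in fast unit tests.
* **Subject asymmetry.** By default each subject carries a smooth
  whole-face asymmetry field: six Gaussian patches at random locations
  and signs (widths 10–25 mm), antisymmetrized about the midline and
  scaled so that the subject's peak deformation magnitude equals their
  asymmetry amplitude. Amplitudes follow a folded normal
  $|N(0, 0.8\,\text{mm})|$ — most faces nearly symmetric with a
  right-skewed tail, the shape of real asymmetry-magnitude
  distributions. Gaussian vertex noise (SD 0.02 mm) emulates residual
  scan noise. A single-bump mode (`asymmetryModel = "bump"`,
  `injectAsymmetry()`) provides controlled localized deformations —
  normal-direction bumps, tangential shear, or regional rotation with a
  cosine taper and a smooth one-sided mask — used for unit tests and for
  the landmark-baseline contrast.
* **Genotypes.** SNPs are drawn binomially with per-SNP MAF uniform on
  $[0.05, 0.5]$; one causal SNP adds `causalEffect` mm per minor allele
  to the amplitude. With the default amplitude distribution, an effect of
  0.5 mm explains at least ~8% of amplitude variance at any MAF in the
  simulated range. Ages are uniform on 3–40 years and sexes balanced,
  matching the covariate structure the association stage controls for.

What the generator does *not* emulate: acquisition artifacts (hair,
eyelashes, holes), non-rigid expression differences, correlated scanner
noise, linkage disequilibrium between SNPs, and population structure
beyond what the PC covariates are exercised on in tests. Passing the
synthetic validation therefore shows that the implementation recovers
planted signal under clean conditions, not that the score is robust to
real-world acquisition problems.

## The association stage

`associationScan()` reimplements the quantitative-trait stage from
scratch: SNPs whose minor allele is carried by fewer than 5 subjects are
removed (carrier count, the literal reading of "present in" a subject;
an allele-count mode is available), the first four principal components
of the standardized genotype matrix join age and sex as covariates, each
SNP is tested by OLS with a two-sided $t$-test on the genotype
coefficient, and Benjamini–Hochberg adjustment is applied globally over
the pooled tests of all phenotypes. `covariateTests()` provides the
Pearson (age) and Kendall tau-b (sex) phenotype checks; the Kendall test
avoids the normality assumption that a dichotomous covariate violates.
Missing genotypes are dropped per SNP (complete cases); inside the PCA
they are mean-imputed.

The validation experiment for this stage uses the generator's true
amplitude as the phenotype at $n = 500$ subjects and 2,000 SNPs. Running
the full mesh pipeline on 20 such cohorts would dominate the runtime
without changing what is being tested, and the mesh experiments establish
separately that the spatiogram score tracks amplitude (Spearman
$\ge 0.8$); the association experiment tests the statistical stage
against its own ground truth.

## Validation summary

The test suite asserts, among others:

* the complete spatiogram score equals an independently written
  brute-force implementation to $10^{-9}$ on 400-point meshes;
* an exactly symmetric subject yields all-zero feature maps and zero
  scores; $\rho$ is symmetric to $10^{-12}$; mirroring is a bit-exact
  involution; BH-adjusted p-values never drop below raw ones;
* on a 50-subject graded cohort at resolution 72 scored against a
  symmetric-control model, the Spearman correlation between injected
  amplitude and the orientation-angle score is $\ge 0.8$, the
  mean-magnitude baseline is monotone, and the landmark baseline stays at
  zero for off-landmark deformations;
* the planted causal SNP is the top hit in $\ge 95\%$ of 20 seeded runs
  with its effect estimate inside 2 SE, and the type-I error of the
  linear model on null SNPs is nominal.

`scripts/acceptance.R` recomputes all of these quantities from scratch on
a fresh seed.

## Known limitations

* The score is a *relative* phenotype: its scale depends on the cohort,
  the bin edges and $\tau$; scores are comparable only within one model
  and configuration (the model archive records that configuration).
* Dense correspondence is landmark-driven TPS plus closest-point
  projection; strongly non-facial geometry or landmark errors degrade it
  silently (use `lambda > 0` for noisy landmarks). No non-rigid ICP
  refinement is attempted.
* The midline is defined by the aligned frame, not re-estimated per
  subject; a systematic landmarking bias would fold into the asymmetry
  estimate.
* At desk-scale cohorts the in-sample score is U-shaped around the cohort
  norm (see above); interpreting it as an absolute asymmetry measure
  requires a reference-model design.

## A minimal worked example

```{r example, eval = FALSE}
tpl <- makeTemplate(30)
cohort <- simulateCohort(cohortConfig(nSubjects = 12, seed = 42),
                         template = tpl)
fit <- asymmetryPipeline(cohort$meshes, cohort$landmarks,
                         baseMesh = tpl$mesh,
                         baseLandmarks = tpl$landmarks)
head(fit$scores)
head(fit$baselines)
```
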